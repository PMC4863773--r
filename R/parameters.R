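#' @keywords internal
"_PACKAGE"

# Outcome columns of a transition row, in canonical order: for each living
# destination class a (no-hospitalization, hospitalization) pair, then the two
# death causes. Ten entries per living state.
TP_COLS <- c(
  "toI_noh", "toI_h", "toII_noh", "toII_h",
  "toIII_noh", "toIII_h", "toIV_noh", "toIV_h",
  "cv_death", "noncv_death"
)
LIVING_COLS <- TP_COLS[1:8]
DEATH_COLS <- c("cv_death", "noncv_death")
HOSP_COLS <- c("toI_h", "toII_h", "toIII_h", "toIV_h")
NOH_COLS <- c("toI_noh", "toII_noh", "toIII_noh", "toIV_noh")

#' NYHA health states of the model
#'
#' The model has exactly five states: the four New York Heart Association
#' functional classes (I mildest to IV severest) and an absorbing dead state.
#'
#' @param living If `TRUE`, return only the four living classes.
#' @return Character vector of state labels.
#' @export
nyha_states <- function(living = FALSE) {
  s <- c("I", "II", "III", "IV", "DEAD")
  if (living) s[1:4] else s
}

#' Destination living class of each transition-row column
#'
#' @return Named character vector mapping the eight living outcome columns to
#'   their destination class; death columns map to `"DEAD"`.
#' @keywords internal
outcome_destination <- function() {
  c(
    toI_noh = "I", toI_h = "I", toII_noh = "II", toII_h = "II",
    toIII_noh = "III", toIII_h = "III", toIV_noh = "IV", toIV_h = "IV",
    cv_death = "DEAD", noncv_death = "DEAD"
  )
}

#' Construct a per-cycle transition row for one living NYHA class
#'
#' A transition row holds the ten per-cycle outcome probabilities from one
#' living class: eight (destination class x hospitalization) entries, plus
#' cardiovascular and non-cardiovascular death. Deaths are mutually exclusive
#' with non-fatal hospitalization within a cycle.
#'
#' @param probs Numeric vector of length 10, named with (or supplied in) the
#'   canonical column order `toI_noh, toI_h, ..., cv_death, noncv_death`.
#' @param from_class Living NYHA class the row leaves from.
#' @param tol Tolerance for the row-sum-to-one check.
#' @return Named numeric vector of class `hf_row` with a `from_class` attribute.
#' @export
transition_row <- function(probs, from_class, tol = 1e-9) {
  from_class <- match.arg(from_class, nyha_states(living = TRUE))
  if (length(probs) != 10L) {
    stop("transition row for class ", from_class, " needs 10 entries, got ",
      length(probs),
      call. = FALSE
    )
  }
  if (is.null(names(probs))) names(probs) <- TP_COLS
  if (!setequal(names(probs), TP_COLS)) {
    stop("transition row columns must be: ", paste(TP_COLS, collapse = ", "),
      call. = FALSE
    )
  }
  probs <- probs[TP_COLS]
  row <- structure(as.numeric(probs),
    names = TP_COLS,
    from_class = from_class, class = "hf_row"
  )
  validate_transition_row(row, tol = tol)
}

#' @keywords internal
validate_transition_row <- function(row, tol = 1e-9) {
  from_class <- attr(row, "from_class")
  if (any(row < 0 | row > 1)) {
    bad <- names(row)[row < 0 | row > 1][1]
    stop(
      "row ", from_class, ": entry ", bad, " = ",
      format(row[[bad]], digits = 12), " outside [0, 1]",
      call. = FALSE
    )
  }
  s <- sum(row)
  if (abs(s - 1) > tol) {
    stop(
      "row ", from_class, ": entries sum to ", format(s, digits = 12),
      ", not 1 (tol ", format(tol), ")",
      call. = FALSE
    )
  }
  row
}

#' Construct a transition table for the four living NYHA classes
#'
#' @param mat Numeric 4 x 10 matrix; rows `I, II, III, IV`, columns in the
#'   canonical order (see [transition_row()]).
#' @param provenance `"weighted-average"` (one table for all cycles) or
#'   `"per-year"` (one of a cycle-specific set).
#' @param tol Tolerance for the row-sum check.
#' @return Matrix of class `hf_table`.
#' @export
transition_table <- function(mat, provenance = c("weighted-average", "per-year"),
                             tol = 1e-9) {
  provenance <- match.arg(provenance)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- nyha_states(living = TRUE)
  if (is.null(colnames(mat))) colnames(mat) <- TP_COLS
  if (!setequal(rownames(mat), nyha_states(living = TRUE))) {
    stop("transition table needs rows I, II, III, IV", call. = FALSE)
  }
  mat <- mat[nyha_states(living = TRUE), TP_COLS, drop = FALSE]
  storage.mode(mat) <- "double"
  tab <- structure(mat, class = "hf_table", provenance = provenance)
  validate_transition_table(tab, tol = tol)
}

#' Validate a transition table
#'
#' Checks that all four living-class rows exist, every entry lies in
#' \[0, 1\], and each row's ten entries sum to one within `tol`.
#'
#' @param table An `hf_table`.
#' @param tol Row-sum tolerance.
#' @return The table, unchanged, on success; otherwise an error naming the
#'   offending row and its sum.
#' @export
validate_transition_table <- function(table, tol = 1e-9) {
  stopifnot(inherits(table, "hf_table"))
  for (cls in nyha_states(living = TRUE)) {
    row <- structure(table[cls, ], from_class = cls, class = "hf_row")
    validate_transition_row(row, tol = tol)
  }
  table
}

#' Extract one row of a transition table as an `hf_row`
#' @keywords internal
table_row <- function(table, cls) {
  structure(table[cls, ], from_class = cls, class = "hf_row")
}

#' Replace one row of a transition table
#' @keywords internal
set_table_row <- function(table, cls, row) {
  table[cls, ] <- as.numeric(row[TP_COLS])
  table
}

#' Proportionally renormalize transition-table rows that miss 1
#'
#' Printed probability tables are rounded for display; rows may sum to, e.g.,
#' 0.999. This rescales each row to sum exactly to one and warns with the
#' original sum, keeping the cohort trace conservative of probability mass.
#'
#' @param mat 4 x 10 numeric matrix (rows I..IV).
#' @param warn Emit a warning naming each renormalized row.
#' @param max_dev Largest row-sum deviation treated as printed rounding;
#'   beyond it the row is rejected (sensitivity-analysis callers pass `Inf`
#'   because deliberate perturbations move row sums far from one).
#' @return The renormalized matrix.
#' @export
renormalize_rows <- function(mat, warn = TRUE, max_dev = 0.05) {
  for (i in seq_len(nrow(mat))) {
    s <- sum(mat[i, ])
    if (s <= 0) stop("row ", rownames(mat)[i], " has nonpositive mass", call. = FALSE)
    if (abs(s - 1) > max_dev) {
      stop("row ", rownames(mat)[i], ": entries sum to ", format(s, digits = 8),
        ", too far from 1 to be printed rounding",
        call. = FALSE
      )
    }
    if (abs(s - 1) > 1e-12) {
      if (warn && abs(s - 1) > 1e-9) {
        warning("renormalizing row ", rownames(mat)[i], " (sum ",
          format(s, digits = 8), ")",
          call. = FALSE
        )
      }
      mat[i, ] <- mat[i, ] / s
    }
  }
  mat
}

#' Hazard-ratio set for eplerenone versus placebo
#'
#' Point estimates and 95% confidence intervals for the three treatment
#' effects: heart-failure hospitalization, cardiovascular death, and all-cause
#' death.
#'
#' @param hf_hosp,cv_death,all_cause_death Numeric length-3 vectors
#'   `c(point, lo, hi)`.
#' @return List of class `hf_hrs`.
#' @export
hazard_ratio_set <- function(hf_hosp, cv_death, all_cause_death) {
  one <- function(x, what) {
    x <- as.numeric(x)
    if (length(x) != 3L) stop(what, ": need c(point, lo, hi)", call. = FALSE)
    if (any(x <= 0)) stop(what, ": hazard ratios must be > 0", call. = FALSE)
    if (!(x[2] <= x[1] && x[1] <= x[3])) {
      stop(what, ": need lo <= point <= hi", call. = FALSE)
    }
    list(point = x[1], lo = x[2], hi = x[3])
  }
  structure(
    list(
      hf_hosp = one(hf_hosp, "hf_hosp"),
      cv_death = one(cv_death, "cv_death"),
      all_cause_death = one(all_cause_death, "all_cause_death")
    ),
    class = "hf_hrs"
  )
}

#' Age-related mortality trend
#'
#' Relative multiplier on the per-cycle cardiovascular and non-cardiovascular
#' death probabilities as the cohort ages, normalized to 1 at the baseline
#' age. The shipped default is a smooth exponential stand-in for
#' all-population mortality growth (risk doubling roughly every 8 years of
#' age); a transcribed life-table can be supplied instead as an (age,
#' multiplier) table.
#'
#' @param baseline_age Age (years) at cycle 1; multiplier is 1 here.
#' @param ages,multipliers Optional explicit trend table (both same length);
#'   if omitted, the exponential stand-in with growth `growth` is built for
#'   ages `baseline_age..110`.
#' @param growth Per-year log growth of the death risks for the stand-in.
#' @param standin Flag recording whether the trend is the synthetic stand-in.
#' @return List of class `hf_age_trend`.
#' @export
age_trend <- function(baseline_age = 68, ages = NULL, multipliers = NULL,
                      growth = 0.087, standin = is.null(ages)) {
  standin <- isTRUE(standin) # force before `ages` is filled in below
  if (is.null(ages)) {
    ages <- baseline_age:110
    multipliers <- exp(growth * (ages - baseline_age))
  }
  ages <- as.numeric(ages)
  multipliers <- as.numeric(multipliers)
  if (length(ages) != length(multipliers)) {
    stop("ages and multipliers must have the same length", call. = FALSE)
  }
  if (any(multipliers <= 0)) stop("trend multipliers must be > 0", call. = FALSE)
  if (is.unsorted(ages)) {
    o <- order(ages)
    ages <- ages[o]
    multipliers <- multipliers[o]
  }
  base_m <- trend_lookup(ages, multipliers, baseline_age)
  multipliers <- multipliers / base_m
  structure(
    list(
      baseline_age = baseline_age, ages = ages,
      multipliers = multipliers, standin = isTRUE(standin)
    ),
    class = "hf_age_trend"
  )
}

# Linear interpolation inside the table, flat extension outside (so no age
# below 110 ever errors).
trend_lookup <- function(ages, multipliers, age) {
  stats::approx(ages, multipliers, xout = age, rule = 2)$y
}

#' Trend multiplier relative to baseline age
#'
#' @param trend An [age_trend()] object.
#' @param age Age in years (vectorized).
#' @return Multiplier(s) `trend(age) / trend(baseline_age)`.
#' @export
trend_multiplier <- function(trend, age) {
  stopifnot(inherits(trend, "hf_age_trend"))
  trend_lookup(trend$ages, trend$multipliers, age)
}

#' Unit costs of the model (2014 AUD)
#'
#' @param background_annual Named vector (I..IV): annual NYHA-class-specific
#'   chronic background treatment cost applied per year of life lived.
#' @param hf_hosp_event Cost of one heart-failure hospitalization.
#' @param cvd_death_admission Cost of a terminal cardiovascular admission.
#' @param death_in_hospital_fraction Fraction of deaths assumed to occur in
#'   hospital (both causes); the effective per-death unit cost is
#'   `fraction * cvd_death_admission`.
#' @param eplerenone_annual Annual eplerenone drug cost.
#' @param epl_monitor_first_cycle Electrolyte/urea monitoring cost in cycle 1.
#' @param epl_monitor_annual Annual monitoring cost for cycles 2 and beyond.
#' @param spiro_annual Annual spironolactone drug cost.
#' @param spiro_monitor_annual Annual spironolactone monitoring cost.
#' @param hosp_events_per_cycle_cap Hospitalizations costed per
#'   hospitalization transition (base case 1).
#' @param cv_death_unit,noncv_death_unit Per-death unit costs by cause;
#'   default to `death_in_hospital_fraction * cvd_death_admission`.
#' @return List of class `hf_costs` with derived field `death_event_unit`.
#' @export
cost_set <- function(background_annual,
                     hf_hosp_event,
                     cvd_death_admission,
                     death_in_hospital_fraction = 0.5,
                     eplerenone_annual,
                     epl_monitor_first_cycle,
                     epl_monitor_annual,
                     spiro_annual,
                     spiro_monitor_annual,
                     hosp_events_per_cycle_cap = 1,
                     cv_death_unit = NULL,
                     noncv_death_unit = NULL) {
  background_annual <- unlist(background_annual)[nyha_states(living = TRUE)]
  death_event_unit <- death_in_hospital_fraction * cvd_death_admission
  if (is.null(cv_death_unit)) cv_death_unit <- death_event_unit
  if (is.null(noncv_death_unit)) noncv_death_unit <- death_event_unit
  costs <- list(
    background_annual = background_annual,
    hf_hosp_event = hf_hosp_event,
    cvd_death_admission = cvd_death_admission,
    death_in_hospital_fraction = death_in_hospital_fraction,
    death_event_unit = death_event_unit,
    cv_death_unit = cv_death_unit,
    noncv_death_unit = noncv_death_unit,
    eplerenone_annual = eplerenone_annual,
    epl_monitor_first_cycle = epl_monitor_first_cycle,
    epl_monitor_annual = epl_monitor_annual,
    spiro_annual = spiro_annual,
    spiro_monitor_annual = spiro_monitor_annual,
    hosp_events_per_cycle_cap = hosp_events_per_cycle_cap
  )
  if (any(unlist(costs[setdiff(names(costs), "background_annual")]) < 0) ||
    any(background_annual < 0)) {
    stop("all costs must be >= 0", call. = FALSE)
  }
  structure(costs, class = "hf_costs")
}

#' Assemble and validate a full model configuration
#'
#' @param table Placebo (usual care without treatment effect)
#'   weighted-average [transition_table()].
#' @param per_year_tables Optional named list of per-year placebo tables for
#'   cycles 1-4 (used by the `yearly_tp_first4` scenario).
#' @param hrs [hazard_ratio_set()].
#' @param hr_mode `"cv-only"` (cardiovascular-death hazard ratio applied to CV
#'   death only, non-CV death untouched) or `"all-cause-split"` (total death
#'   mass scaled by the all-cause hazard ratio with cause shares preserved).
#' @param mix Named vector (I..IV): fraction of usual-care patients per class
#'   on spironolactone (assigned eplerenone efficacy).
#' @param utilities Named vector (I..IV): state utility weights in \[0, 1\].
#' @param costs [cost_set()].
#' @param discount List `rate` (annual fraction) and `start_cycle` (first
#'   discounted cycle; 2 means "after the first cycle").
#' @param trend [age_trend()].
#' @param horizon Number of yearly cycles.
#' @param start_state Living class the cohort starts in.
#' @param cohort_size Persons for per-1000-style event reporting.
#' @param accrual `"cycle-start"` (occupants at cycle start earn the full
#'   cycle) or `"cycle-end"` (survivors earn it), a sensitivity switch.
#' @param trend_order `"trend-first"` (age trend applied before the treatment
#'   effect, the default) or `"treatment-first"`.
#' @param monitor_year1_combined If `TRUE`, cycle 1 accrues first-cycle plus
#'   annual monitoring cost for eplerenone.
#' @return List of class `hf_config`.
#' @export
model_config <- function(table,
                         hrs,
                         mix,
                         utilities,
                         costs,
                         discount = list(rate = 0.05, start_cycle = 2),
                         trend = age_trend(),
                         horizon = 10,
                         start_state = "II",
                         cohort_size = 1000,
                         per_year_tables = NULL,
                         hr_mode = c("cv-only", "all-cause-split"),
                         accrual = c("cycle-start", "cycle-end"),
                         trend_order = c("trend-first", "treatment-first"),
                         monitor_year1_combined = FALSE) {
  hr_mode <- match.arg(hr_mode)
  accrual <- match.arg(accrual)
  trend_order <- match.arg(trend_order)
  start_state <- match.arg(start_state, nyha_states(living = TRUE))
  stopifnot(inherits(table, "hf_table"), inherits(hrs, "hf_hrs"),
            inherits(costs, "hf_costs"), inherits(trend, "hf_age_trend"))
  if (horizon < 1) stop("horizon must be >= 1, got ", horizon, call. = FALSE)
  mix <- unlist(mix)[nyha_states(living = TRUE)]
  utilities <- unlist(utilities)[nyha_states(living = TRUE)]
  if (any(is.na(mix)) || any(mix < 0 | mix > 1)) {
    stop("spironolactone fractions must be in [0, 1] for classes I..IV",
      call. = FALSE
    )
  }
  if (any(is.na(utilities)) || any(utilities < 0 | utilities > 1)) {
    stop("utilities must be in [0, 1] for classes I..IV", call. = FALSE)
  }
  if (is.null(discount$start_cycle)) discount$start_cycle <- 2
  if (discount$rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (!is.null(per_year_tables)) {
    stopifnot(all(vapply(per_year_tables, inherits, TRUE, "hf_table")))
  }
  structure(
    list(
      table = table, per_year_tables = per_year_tables,
      hrs = hrs, hr_mode = hr_mode, mix = mix, utilities = utilities,
      costs = costs, discount = discount, trend = trend,
      horizon = as.integer(horizon), start_state = start_state,
      cohort_size = cohort_size, accrual = accrual,
      trend_order = trend_order,
      monitor_year1_combined = isTRUE(monitor_year1_combined)
    ),
    class = "hf_config"
  )
}

# Synthetic stand-in for the usual-care placebo transition table. The source
# table is published only as a figure, so these values are NOT the published
# ones: they are plausible per-cycle magnitudes consistent with the trial
# event rates quoted in prose (placebo primary-outcome risk about 15%/year
# from class II), chosen once and frozen. The NYHA IV row equals the NYHA III
# row, mirroring the published assumption.
standin_placebo_matrix <- function() {
  m <- rbind(
    I   = c(0.720, 0.040, 0.130, 0.030, 0.020, 0.010, 0.004, 0.001, 0.030, 0.015),
    II  = c(0.080, 0.005, 0.620, 0.100, 0.080, 0.030, 0.010, 0.005, 0.050, 0.020),
    III = c(0.010, 0.002, 0.090, 0.030, 0.500, 0.170, 0.040, 0.018, 0.100, 0.040),
    IV  = c(0.010, 0.002, 0.090, 0.030, 0.500, 0.170, 0.040, 0.018, 0.100, 0.040)
  )
  colnames(m) <- TP_COLS
  m
}

#' Default parameter pack
#'
#' Returns the model configuration encoding the published Australian
#' 2014-AUD inputs: hazard ratios 0.58 (0.47-0.70) for heart-failure
#' hospitalization, 0.76 (0.61-0.94) for cardiovascular death and 0.76
#' (0.62-0.93) for all-cause death; spironolactone usage 0%/43.7%/93.7%/93.7%
#' by NYHA class; utilities 0.815/0.720/0.590/0.508; unit costs (background
#' 151/175/226/242, hospitalization 7136, CV-death admission 3642 with 50%
#' of deaths in hospital giving a per-death unit of 1821, eplerenone 1374,
#' monitoring 35.60 then 71.20, spironolactone 45.29 + 71.20); 5% annual
#' discounting after the first cycle; baseline age 68; 10-year horizon.
#'
#' The placebo transition table and the age trend are synthetic stand-ins
#' (the published table and life-table appendix are available only as
#' figures); both are flagged as such and replaceable via [load_config()].
#'
#' @return An [model_config()] object.
#' @export
default_parameters <- function() {
  model_config(
    table = transition_table(standin_placebo_matrix()),
    hrs = hazard_ratio_set(
      hf_hosp = c(0.58, 0.47, 0.70),
      cv_death = c(0.76, 0.61, 0.94),
      all_cause_death = c(0.76, 0.62, 0.93)
    ),
    mix = c(I = 0.0, II = 0.437, III = 0.937, IV = 0.937),
    utilities = c(I = 0.815, II = 0.720, III = 0.590, IV = 0.508),
    costs = cost_set(
      background_annual = c(I = 151, II = 175, III = 226, IV = 242),
      hf_hosp_event = 7136,
      cvd_death_admission = 3642,
      death_in_hospital_fraction = 0.5,
      eplerenone_annual = 1374,
      epl_monitor_first_cycle = 35.60,
      epl_monitor_annual = 71.20,
      spiro_annual = 45.29,
      spiro_monitor_annual = 71.20
    ),
    discount = list(rate = 0.05, start_cycle = 2),
    trend = age_trend(baseline_age = 68),
    horizon = 10,
    start_state = "II",
    cohort_size = 1000
  )
}
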