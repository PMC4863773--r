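# Transition-row algebra: treatment-effect transformation, usual-care
# mixture, and age-trend mortality scaling.

ARM_LABELS <- c("EG", "UCG", "PLACEBO")

#' Apply treatment hazard ratios to a transition row
#'
#' Treatment effects are applied as direct probability multiplication,
#' mirroring how the eplerenone transition probabilities were obtained from
#' the placebo arm: each hospitalization entry is multiplied by the
#' heart-failure-hospitalization hazard ratio, with the freed mass moved to
#' the same-destination no-hospitalization entry (so the destination-class
#' distribution is preserved). Under `mode = "cv-only"` the cardiovascular
#' death probability is multiplied by its hazard ratio and non-CV death is
#' untouched; under `"all-cause-split"` total death mass is scaled by the
#' all-cause hazard ratio with the CV/non-CV shares preserved. Death mass
#' freed by the treatment effect is redistributed proportionally across the
#' eight living entries, so the row still sums to one.
#'
#' @param row An `hf_row`.
#' @param hrs A [hazard_ratio_set()].
#' @param mode Death-adjustment mode; see above.
#' @param hr_values Optional named overrides `c(hf_hosp=, cv_death=,
#'   all_cause_death=)` replacing the point estimates (used by sensitivity
#'   analyses and time-varying scenarios).
#' @return The transformed `hf_row` (sums to 1 within 1e-12).
#' @export
apply_hazard_ratios <- function(row, hrs, mode = c("cv-only", "all-cause-split"),
                                hr_values = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(row, "hf_row"), inherits(hrs, "hf_hrs"))
  hv <- c(
    hf_hosp = hrs$hf_hosp$point,
    cv_death = hrs$cv_death$point,
    all_cause_death = hrs$all_cause_death$point
  )
  if (!is.null(hr_values)) hv[names(hr_values)] <- hr_values
  if (any(hv <= 0)) stop("hazard ratios must be > 0", call. = FALSE)

  out <- as.numeric(row)
  names(out) <- names(row)

  # hospitalization effect: class distribution preserved
  freed <- out[HOSP_COLS] * (1 - hv[["hf_hosp"]])
  out[HOSP_COLS] <- out[HOSP_COLS] - freed
  out[NOH_COLS] <- out[NOH_COLS] + freed

  # death effect
  if (mode == "cv-only") {
    new_cv <- out[["cv_death"]] * hv[["cv_death"]]
    new_noncv <- out[["noncv_death"]]
  } else {
    total <- out[["cv_death"]] + out[["noncv_death"]]
    new_total <- total * hv[["all_cause_death"]]
    if (total > 0) {
      new_cv <- new_total * out[["cv_death"]] / total
      new_noncv <- new_total * out[["noncv_death"]] / total
    } else {
      new_cv <- 0
      new_noncv <- 0
    }
  }
  freed_death <- (out[["cv_death"]] + out[["noncv_death"]]) - (new_cv + new_noncv)
  out[["cv_death"]] <- new_cv
  out[["noncv_death"]] <- new_noncv
  living_mass <- sum(out[LIVING_COLS])
  if (living_mass > 0) {
    out[LIVING_COLS] <- out[LIVING_COLS] * (living_mass + freed_death) / living_mass
  } else if (abs(freed_death) > 0) {
    # no living mass to absorb the freed probability: give it back to deaths
    out[["cv_death"]] <- out[["cv_death"]] + freed_death
  }

  bad <- which(out < -1e-12 | out > 1 + 1e-12)
  if (length(bad)) {
    stop("transformed probability ", names(out)[bad[1]], " = ",
      format(out[bad[1]], digits = 10), " infeasible",
      call. = FALSE
    )
  }
  out <- pmin(pmax(out, 0), 1)
  structure(out,
    from_class = attr(row, "from_class"),
    class = "hf_row"
  )
}

#' Blend placebo and treated rows into a usual-care row
#'
#' The usual-care arm is a mixture: per class, a spironolactone-treated
#' fraction (assigned eplerenone efficacy) and the complementary placebo
#' fraction. The blended row is the entry-wise convex combination
#' `fraction * treated + (1 - fraction) * placebo`.
#'
#' @param placebo,treated `hf_row`s sharing the same origin class.
#' @param spiro_fraction Treated fraction in \[0, 1\].
#' @return The blended `hf_row`.
#' @export
blend_usual_care <- function(placebo, treated, spiro_fraction) {
  stopifnot(inherits(placebo, "hf_row"), inherits(treated, "hf_row"))
  if (!identical(attr(placebo, "from_class"), attr(treated, "from_class"))) {
    stop("rows to blend must share the same origin class", call. = FALSE)
  }
  if (spiro_fraction < 0 || spiro_fraction > 1) {
    stop("spiro_fraction must be in [0, 1], got ", spiro_fraction, call. = FALSE)
  }
  out <- spiro_fraction * as.numeric(treated) +
    (1 - spiro_fraction) * as.numeric(placebo)
  structure(stats::setNames(out, TP_COLS),
    from_class = attr(placebo, "from_class"), class = "hf_row"
  )
}

#' Scale a row's death probabilities by the age trend
#'
#' Multiplies both death probabilities by the trend multiplier at `age`
#' relative to the baseline age, caps total death mass at one, and rescales
#' the living entries proportionally so the row sums to one.
#'
#' @param row An `hf_row`.
#' @param age Current age in years (>= baseline).
#' @param trend An [age_trend()].
#' @return The age-adjusted `hf_row`.
#' @export
apply_age_trend <- function(row, age, trend) {
  stopifnot(inherits(row, "hf_row"))
  m <- trend_multiplier(trend, age)
  out <- as.numeric(row)
  names(out) <- names(row)
  death <- out[DEATH_COLS] * m
  total_death <- sum(death)
  if (total_death >= 1) {
    death <- death / total_death
    out[LIVING_COLS] <- 0
    total_death <- 1
  } else {
    old_living <- sum(out[LIVING_COLS])
    if (old_living > 0) {
      out[LIVING_COLS] <- out[LIVING_COLS] * (1 - total_death) / old_living
    }
  }
  out[DEATH_COLS] <- death
  structure(out, from_class = attr(row, "from_class"), class = "hf_row")
}

placebo_table_for_cycle <- function(config, cycle) {
  pyt <- config$per_year_tables
  if (!is.null(pyt) && cycle <= length(pyt)) pyt[[cycle]] else config$table
}

#' Build the per-cycle transition tables for one model arm
#'
#' For each cycle the configured placebo table (weighted-average, or the
#' per-year table when present) is taken, the age trend is applied at age
#' `baseline_age + cycle - 1`, and then the arm's treatment effect: the
#' eplerenone arm (`"EG"`) applies the hazard ratios to every row; usual care
#' (`"UCG"`) blends each class's placebo and treated rows with that class's
#' spironolactone fraction; `"PLACEBO"` applies no treatment effect. With
#' `config$trend_order = "treatment-first"` the two steps are swapped.
#'
#' @param config An `hf_config`.
#' @param arm `"EG"`, `"UCG"` or `"PLACEBO"`.
#' @param hr_values_by_cycle Optional function `(cycle) -> named hr overrides`
#'   for time-varying treatment effects (scenario use).
#' @return List of `hf_table`, one per cycle, each validated.
#' @export
build_arm_tables <- function(config, arm = c("EG", "UCG", "PLACEBO"),
                             hr_values_by_cycle = NULL) {
  arm <- match.arg(arm)
  lapply(seq_len(config$horizon), function(cycle) {
    tab <- placebo_table_for_cycle(config, cycle)
    age <- config$trend$baseline_age + cycle - 1
    hr_values <- if (is.null(hr_values_by_cycle)) NULL else hr_values_by_cycle(cycle)
    transform_row <- function(row) {
      step_trend <- function(r) apply_age_trend(r, age, config$trend)
      step_treat <- function(r) {
        if (arm == "PLACEBO") {
          return(r)
        }
        treated <- apply_hazard_ratios(r, config$hrs,
          mode = config$hr_mode, hr_values = hr_values
        )
        if (arm == "EG") {
          treated
        } else {
          blend_usual_care(r, treated, config$mix[[attr(r, "from_class")]])
        }
      }
      if (config$trend_order == "trend-first") {
        step_treat(step_trend(row))
      } else {
        step_trend(step_treat(row))
      }
    }
    m <- do.call(rbind, lapply(nyha_states(living = TRUE), function(cls) {
      as.numeric(transform_row(table_row(tab, cls)))
    }))
    rownames(m) <- nyha_states(living = TRUE)
    colnames(m) <- TP_COLS
    transition_table(m, provenance = attr(tab, "provenance"), tol = 1e-9)
  })
}
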