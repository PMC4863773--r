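# Fixtures built in code: small rows/tables/configs used across the suite.

# A transition row with named entries set and the rest zero.
make_row <- function(from_class, ...) {
  probs <- stats::setNames(numeric(10), hfcea:::TP_COLS)
  vals <- list(...)
  probs[names(vals)] <- unlist(vals)
  transition_row(probs, from_class)
}

# Random valid row (Dirichlet-ish via normalized exponentials).
random_row <- function(from_class = "II") {
  p <- stats::rexp(10)
  transition_row(p / sum(p), from_class)
}

# Table where every class follows the same entries.
uniform_table <- function(...) {
  rows <- lapply(nyha_states(living = TRUE), function(cls) {
    as.numeric(make_row(cls, ...))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- nyha_states(living = TRUE)
  colnames(m) <- hfcea:::TP_COLS
  transition_table(m)
}

flat_trend <- function() age_trend(baseline_age = 68, growth = 0)

# Small config: flat age trend and undiscounted by default, so hand-traced
# expectations stay simple.
tiny_config <- function(table, horizon = 2, rate = 0, trend = flat_trend(),
                        mix = c(I = 0, II = 0.437, III = 0.937, IV = 0.937),
                        ...) {
  model_config(
    table = table,
    hrs = hazard_ratio_set(
      hf_hosp = c(0.58, 0.47, 0.70),
      cv_death = c(0.76, 0.61, 0.94),
      all_cause_death = c(0.76, 0.62, 0.93)
    ),
    mix = mix,
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
    discount = list(rate = rate, start_cycle = 2),
    trend = trend,
    horizon = horizon,
    ...
  )
}

# Probability-conservation check on a cohort trace.
expect_trace_conserved <- function(results, tol = 1e-9) {
  tr <- results$trace
  total <- rowSums(tr[, nyha_states(living = TRUE)]) +
    tr$cum_cv_death + tr$cum_noncv_death
  expect_true(all(abs(total - 1) < tol))
  expect_true(all(as.matrix(tr[, nyha_states(living = TRUE)]) >= 0))
}
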