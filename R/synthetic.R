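# Patient-level microsimulation with the exact generative structure the
# cohort engine assumes (per-cycle multinomial draws over the 10 outcomes),
# plus maximum-likelihood estimators recovering transition tables from event
# logs. This is the package's independent oracle and parameter-recovery
# harness: no external data are required to test anything.

#' Simulate patient-level NYHA trajectories
#'
#' Each patient starts in `start_state`; each cycle, one of the ten outcomes
#' of their current class's row in that cycle's table is drawn. Dead is
#' absorbing. The event log is flat and CSV-exportable so the estimators can
#' be cross-checked with external tooling.
#'
#' @param arm_tables List of per-cycle `hf_table`s.
#' @param n Number of patients (>= 1).
#' @param seed Integer RNG seed; the log is reproducible given the seed.
#' @param start_state Living NYHA class at cycle 1.
#' @return Object of class `hf_event_log`: data frame `events` with columns
#'   `patient_id, cycle, from_state, to_state, hospitalized, death_cause`,
#'   plus `n_patients` and `seed` attributes.
#' @export
simulate_patients <- function(arm_tables, n, seed = 1, start_state = "II") {
  stopifnot(n >= 1, length(arm_tables) >= 1)
  start_state <- match.arg(start_state, nyha_states(living = TRUE))
  set.seed(seed)
  living <- nyha_states(living = TRUE)
  dest <- outcome_destination()
  hosp_flag <- TP_COLS %in% HOSP_COLS
  cause <- ifelse(TP_COLS == "cv_death", "cv",
    ifelse(TP_COLS == "noncv_death", "noncv", NA_character_)
  )

  state <- rep(start_state, n)
  alive <- rep(TRUE, n)
  logs <- vector("list", length(arm_tables))

  for (cycle in seq_along(arm_tables)) {
    tab <- arm_tables[[cycle]]
    idx_alive <- which(alive)
    if (!length(idx_alive)) break
    outcome <- integer(length(idx_alive))
    for (cls in living) {
      in_cls <- state[idx_alive] == cls
      k <- sum(in_cls)
      if (!k) next
      outcome[in_cls] <- sample.int(10L, k, replace = TRUE, prob = tab[cls, ])
    }
    to_state <- dest[TP_COLS[outcome]]
    logs[[cycle]] <- data.frame(
      patient_id = idx_alive,
      cycle = cycle,
      from_state = state[idx_alive],
      to_state = unname(to_state),
      hospitalized = hosp_flag[outcome],
      death_cause = cause[outcome],
      stringsAsFactors = FALSE
    )
    died <- to_state == "DEAD"
    state[idx_alive] <- unname(to_state)
    alive[idx_alive[died]] <- FALSE
  }
  events <- do.call(rbind, logs)
  events <- events[order(events$patient_id, events$cycle), ]
  rownames(events) <- NULL
  structure(
    list(events = events, n_patients = n, seed = seed),
    class = "hf_event_log"
  )
}

#' Write an event log to CSV
#' @param log An `hf_event_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log_csv <- function(log, path) {
  utils::write.csv(log$events, path, row.names = FALSE)
  invisible(path)
}

#' Per-cycle state frequencies of an event log
#'
#' Occupancy of each living state at the *end* of each cycle, plus cumulative
#' death fractions, as fractions of the starting cohort — directly comparable
#' to a [run_cohort()] trace.
#'
#' @param log An `hf_event_log`.
#' @return Data frame with one row per cycle.
#' @export
log_occupancy <- function(log) {
  ev <- log$events
  n <- log$n_patients
  cycles <- sort(unique(ev$cycle))
  out <- lapply(cycles, function(cy) {
    upto <- ev[ev$cycle <= cy, ]
    last <- upto[!duplicated(upto$patient_id, fromLast = TRUE), ]
    counts <- table(factor(last$to_state, levels = nyha_states()))
    data.frame(
      cycle = cy,
      t(as.matrix(counts / n)),
      check.names = FALSE
    )
  })
  do.call(rbind, out)
}

#' Estimate a transition table from an event log
#'
#' Maximum-likelihood multinomial estimates: each of the ten outcome
#' probabilities per origin class is the count of that (class, outcome) pair
#' divided by the at-risk person-cycles of the class, over the chosen
#' cycles. A class never observed at risk yields an all-`NA` row flagged in
#' the `missing_rows` attribute rather than invented values.
#'
#' @param log An `hf_event_log`.
#' @param cycles Cycle subset to pool over (default: all).
#' @return An `hf_table` (rows may contain `NA` when unobserved), with
#'   attributes `at_risk` (person-cycles per class) and `missing_rows`.
#' @export
estimate_transition_table <- function(log, cycles = NULL) {
  ev <- log$events
  if (!is.null(cycles)) ev <- ev[ev$cycle %in% cycles, ]
  if (!nrow(ev)) stop("event log empty over the chosen cycles", call. = FALSE)
  living <- nyha_states(living = TRUE)

  outcome_of <- function(to_state, hospitalized, death_cause) {
    ifelse(!is.na(death_cause),
      ifelse(death_cause == "cv", "cv_death", "noncv_death"),
      paste0("to", to_state, ifelse(hospitalized, "_h", "_noh"))
    )
  }
  ev$outcome <- outcome_of(ev$to_state, ev$hospitalized, ev$death_cause)

  counts <- table(
    factor(ev$from_state, levels = living),
    factor(ev$outcome, levels = TP_COLS)
  )
  at_risk <- rowSums(counts)
  m <- matrix(NA_real_, 4, 10, dimnames = list(living, TP_COLS))
  obs <- at_risk > 0
  m[obs, ] <- counts[obs, , drop = FALSE] / at_risk[obs]
  missing_rows <- living[!obs]
  if (!length(missing_rows)) {
    tab <- transition_table(m, provenance = "weighted-average")
  } else {
    tab <- structure(m,
      class = "hf_table",
      provenance = "weighted-average"
    )
  }
  attr(tab, "at_risk") <- at_risk
  attr(tab, "missing_rows") <- missing_rows
  tab
}

#' Simulate, re-estimate, and rerun: parameter-recovery report
#'
#' Generates a synthetic trial-like event log from the configuration's base
#' placebo table (the trial data the transition probabilities would be
#' estimated from precede the model's age-trend extrapolation, so the
#' simulation deliberately holds the trend flat), re-estimates the table by
#' maximum likelihood, rebuilds the configuration around the estimate, reruns
#' the full model, and reports the relative error of the headline outputs
#' against the truth-configuration run.
#'
#' @param config An `hf_config` (the truth).
#' @param n Patients to simulate.
#' @param seed Integer RNG seed.
#' @param cycles Cycles of follow-up to simulate and pool (default 4,
#'   emulating four years of trial follow-up).
#' @return List of class `hf_recovery`: `estimated_table`, truth and
#'   recovered ICERs, and `relative_error` on LY, QALY, cost, and
#'   ICER-per-QALY.
#' @export
parameter_recovery_suite <- function(config, n = 50000, seed = 1, cycles = 4) {
  flat_tables <- rep(list(config$table), cycles)
  # start every patient in each living class in turn so all four rows are
  # observed with useful at-risk counts even from a class-II start
  logs <- lapply(seq_along(nyha_states(living = TRUE)), function(i) {
    cls <- nyha_states(living = TRUE)[i]
    simulate_patients(flat_tables,
      n = ceiling(n / 4),
      seed = (seed + i * 131) %% 2147483647, start_state = cls
    )
  })
  merged <- logs[[1]]
  offset <- 0
  all_events <- lapply(logs, function(l) {
    ev <- l$events
    ev$patient_id <- ev$patient_id + offset
    offset <<- offset + l$n_patients
    ev
  })
  merged$events <- do.call(rbind, all_events)
  merged$n_patients <- offset

  est <- estimate_transition_table(merged)
  if (length(attr(est, "missing_rows"))) {
    stop("recovery failed: unobserved rows ",
      paste(attr(est, "missing_rows"), collapse = ", "),
      call. = FALSE
    )
  }

  truth_arms <- run_arms(config)
  truth_icer <- icer(truth_arms$UCG, truth_arms$EG)

  cfg_hat <- config
  cfg_hat$table <- transition_table(unclass(est),
    provenance = "weighted-average"
  )
  hat_arms <- run_arms(cfg_hat)
  hat_icer <- icer(hat_arms$UCG, hat_arms$EG)

  rel <- function(hat, truth) abs(hat - truth) / abs(truth)
  structure(
    list(
      estimated_table = est,
      n_patients = merged$n_patients,
      seed = seed,
      truth_icer = truth_icer,
      recovered_icer = hat_icer,
      relative_error = c(
        ly = rel(hat_arms$EG$ly_disc, truth_arms$EG$ly_disc),
        qaly = rel(hat_arms$EG$qaly_disc, truth_arms$EG$qaly_disc),
        cost = rel(hat_arms$EG$cost_disc, truth_arms$EG$cost_disc),
        icer_per_qaly = rel(hat_icer$icer_per_qaly, truth_icer$icer_per_qaly)
      )
    ),
    class = "hf_recovery"
  )
}
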