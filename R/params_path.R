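# Dotted parameter paths ("utility.II", "cost.hf_hosp_event", "tp.II.toII_h",
# "hr.hf_hosp", "discount.rate", "mix.III") used by the deterministic and
# probabilistic sensitivity analyses to perturb a single scalar input.

#' Read a scalar model input by path
#'
#' @param config An `hf_config`.
#' @param path Dotted path, e.g. `"utility.II"`, `"cost.background.III"`,
#'   `"tp.II.cv_death"`, `"hr.hf_hosp"`, `"discount.rate"`, `"mix.II"`.
#' @return The scalar value.
#' @export
get_param <- function(config, path) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  switch(p[1],
    utility = config$utilities[[p[2]]],
    mix = config$mix[[p[2]]],
    hr = config$hrs[[p[2]]]$point,
    discount = config$discount[[p[2]]],
    tp = config$table[p[2], p[3]],
    cost = if (p[2] == "background") {
      config$costs$background_annual[[p[3]]]
    } else {
      config$costs[[p[2]]]
    },
    stop("unknown parameter path: ", path, call. = FALSE)
  )
}

rebuild_costs <- function(costs, ...) {
  upd <- list(...)
  fields <- list(
    background_annual = costs$background_annual,
    hf_hosp_event = costs$hf_hosp_event,
    cvd_death_admission = costs$cvd_death_admission,
    death_in_hospital_fraction = costs$death_in_hospital_fraction,
    eplerenone_annual = costs$eplerenone_annual,
    epl_monitor_first_cycle = costs$epl_monitor_first_cycle,
    epl_monitor_annual = costs$epl_monitor_annual,
    spiro_annual = costs$spiro_annual,
    spiro_monitor_annual = costs$spiro_monitor_annual,
    hosp_events_per_cycle_cap = costs$hosp_events_per_cycle_cap
  )
  fields[names(upd)] <- upd
  do.call(cost_set, fields)
}

#' Set a scalar model input by path
#'
#' Returns a modified copy of the configuration. Setting
#' `cost.cvd_death_admission` or `cost.death_in_hospital_fraction` re-derives
#' the per-death unit cost. Transition-probability paths (`tp.<class>.<col>`)
#' set the raw entry; call [renormalize_config_table()] afterwards to restore
#' row sums (done automatically by the sensitivity drivers).
#'
#' @param config An `hf_config`.
#' @param path Dotted path (see [get_param()]).
#' @param value New scalar value.
#' @return The modified `hf_config`.
#' @export
set_param <- function(config, path, value) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  switch(p[1],
    utility = {
      config$utilities[[p[2]]] <- value
    },
    mix = {
      config$mix[[p[2]]] <- value
    },
    hr = {
      h <- config$hrs[[p[2]]]
      h$point <- value
      h$lo <- min(h$lo, value)
      h$hi <- max(h$hi, value)
      config$hrs[[p[2]]] <- h
    },
    discount = {
      config$discount[[p[2]]] <- value
    },
    tp = {
      m <- unclass(config$table)
      m[p[2], p[3]] <- value
      config$table <- structure(m,
        class = "hf_table",
        provenance = attr(config$table, "provenance")
      )
    },
    cost = {
      config$costs <- if (p[2] == "background") {
        b <- config$costs$background_annual
        b[[p[3]]] <- value
        rebuild_costs(config$costs, background_annual = b)
      } else {
        do.call(rebuild_costs, stats::setNames(
          list(config$costs, value), c("costs", p[2])
        ))
      }
    },
    stop("unknown parameter path: ", path, call. = FALSE)
  )
  config
}

#' Renormalize the configuration's transition-table rows after perturbation
#'
#' @param config An `hf_config`.
#' @return The configuration with each row of the placebo table rescaled to
#'   sum to one (validated).
#' @export
renormalize_config_table <- function(config) {
  m <- renormalize_rows(unclass(config$table), warn = FALSE, max_dev = Inf)
  config$table <- transition_table(m,
    provenance = attr(config$table, "provenance")
  )
  config
}
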