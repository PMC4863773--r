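# Incremental economics: ICERs, dominance, events averted, NNT.

#' Incremental cost-effectiveness of an intervention versus a reference arm
#'
#' Deltas are intervention minus reference on the *discounted* per-person
#' values; ratios are incremental cost over incremental effect, reported as
#' AUD per year of life saved (YoLS) and AUD per QALY gained, computed from
#' full-precision deltas (not display-rounded ones). Dominance is classified
#' from the sign quadrant: cheaper and more effective = intervention
#' dominant; costlier and less effective = intervention dominated. A zero
#' effect delta flags the corresponding ratio as undefined (`NA`) rather than
#' erroring.
#'
#' @param reference,intervention `hf_arm_results` from the same configuration.
#' @return List of class `hf_icer` with `delta_cost`, `delta_ly`,
#'   `delta_qaly`, `icer_per_yols`, `icer_per_qaly`, `dominance`.
#' @export
icer <- function(reference, intervention) {
  stopifnot(
    inherits(reference, "hf_arm_results"),
    inherits(intervention, "hf_arm_results")
  )
  dc <- intervention$cost_disc - reference$cost_disc
  dly <- intervention$ly_disc - reference$ly_disc
  dq <- intervention$qaly_disc - reference$qaly_disc
  ratio <- function(effect) if (effect == 0) NA_real_ else dc / effect
  dominance <- if (dc <= 0 && dq >= 0 && (dc < 0 || dq > 0)) {
    "intervention-dominant"
  } else if (dc >= 0 && dq <= 0 && (dc > 0 || dq < 0)) {
    "intervention-dominated"
  } else {
    "none"
  }
  structure(
    list(
      delta_cost = dc, delta_ly = dly, delta_qaly = dq,
      icer_per_yols = ratio(dly), icer_per_qaly = ratio(dq),
      dominance = dominance
    ),
    class = "hf_icer"
  )
}

#' @export
print.hf_icer <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Incremental analysis (intervention - reference)\n",
      "  delta cost:  AUD %.0f\n",
      "  delta LY:    %.3f   delta QALY: %.3f\n",
      "  ICER: AUD %s per YoLS, AUD %s per QALY\n",
      "  dominance: %s\n"
    ),
    x$delta_cost, x$delta_ly, x$delta_qaly,
    ifelse(is.na(x$icer_per_yols), "NA", sprintf("%.0f", x$icer_per_yols)),
    ifelse(is.na(x$icer_per_qaly), "NA", sprintf("%.0f", x$icer_per_qaly)),
    x$dominance
  ))
  invisible(x)
}

#' Events averted and number needed to treat
#'
#' Events averted are reference minus intervention per 1000 starting persons
#' (undiscounted counts). The NNT is the reciprocal cumulative risk
#' difference over the horizon, i.e. `1000 / averted-per-1000`; it is flagged
#' not-applicable (`NA`) when no events are averted. Both the full-precision
#' and display-rounded (1 decimal) NNTs are returned.
#'
#' @param reference,intervention `hf_arm_results`.
#' @return List of class `hf_event_diff`.
#' @export
event_diff <- function(reference, intervention) {
  hosp_averted <- reference$hospitalizations_per_1000 -
    intervention$hospitalizations_per_1000
  deaths_averted <- reference$deaths_per_1000 - intervention$deaths_per_1000
  nnt <- function(averted) if (averted > 0) 1000 / averted else NA_real_
  structure(
    list(
      hospitalizations_averted_per_1000 = hosp_averted,
      deaths_averted_per_1000 = deaths_averted,
      nnt_hosp = nnt(hosp_averted),
      nnt_death = nnt(deaths_averted),
      nnt_hosp_display = round(nnt(hosp_averted), 1),
      nnt_death_display = round(nnt(deaths_averted), 1)
    ),
    class = "hf_event_diff"
  )
}

#' @export
print.hf_event_diff <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Events averted per 1000 over the horizon\n",
      "  hospitalizations: %.0f (NNT %.1f)\n",
      "  deaths:           %.0f (NNT %.1f)\n"
    ),
    x$hospitalizations_averted_per_1000, x$nnt_hosp,
    x$deaths_averted_per_1000, x$nnt_death
  ))
  invisible(x)
}
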