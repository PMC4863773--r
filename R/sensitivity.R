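# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis (Monte Carlo over beta/uniform/triangular parameter
# distributions, with CEAC and percentile intervals).

#' Default one-way sensitivity specifications
#'
#' Hazard ratios vary over their published 95% confidence intervals; all
#' other inputs over +/-50% of the base value (utilities and fractions capped
#' at 1, consistent with their domain).
#'
#' @param config An `hf_config`.
#' @return Data frame with columns `path`, `base`, `low`, `high`.
#' @export
default_dsa_specs <- function(config) {
  specs <- list(
    list("hr.hf_hosp", config$hrs$hf_hosp$lo, config$hrs$hf_hosp$hi),
    list("hr.cv_death", config$hrs$cv_death$lo, config$hrs$cv_death$hi)
  )
  for (cls in nyha_states(living = TRUE)) {
    b <- config$utilities[[cls]]
    specs <- c(specs, list(list(
      paste0("utility.", cls), 0.5 * b, min(1, 1.5 * b)
    )))
    bc <- config$costs$background_annual[[cls]]
    specs <- c(specs, list(list(
      paste0("cost.background.", cls), 0.5 * bc, 1.5 * bc
    )))
  }
  for (cn in c("hf_hosp_event", "cvd_death_admission")) {
    b <- config$costs[[cn]]
    specs <- c(specs, list(list(paste0("cost.", cn), 0.5 * b, 1.5 * b)))
  }
  specs <- c(specs, list(
    list("discount.rate", 0.5 * config$discount$rate, 1.5 * config$discount$rate),
    list("mix.II", 0.5 * config$mix[["II"]], min(1, 1.5 * config$mix[["II"]]))
  ))
  data.frame(
    path = vapply(specs, `[[`, "", 1),
    base = vapply(specs, function(s) get_param(config, s[[1]]), 0),
    low = vapply(specs, `[[`, 0, 2),
    high = vapply(specs, `[[`, 0, 3),
    stringsAsFactors = FALSE
  )
}

run_at <- function(config, path, value) {
  cfg <- set_param(config, path, value)
  if (startsWith(path, "tp.")) cfg <- renormalize_config_table(cfg)
  arms <- run_arms(cfg)
  icer(arms$UCG, arms$EG)
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the full model at each specification's low and high value with all
#' other inputs at base, and tabulates the resulting ICERs, ordered for a
#' tornado diagram by the width of the ICER-per-QALY range. A perturbation
#' that makes the model infeasible is recorded as `NA` for that bound and
#' flagged; the run continues.
#'
#' @param config An `hf_config`.
#' @param specs Data frame as returned by [default_dsa_specs()] (`path`,
#'   `low`, `high`; `base` optional). Must satisfy low <= base <= high.
#' @return Data frame (class `hf_dsa`) with low/high ICERs per YoLS and per
#'   QALY, the range width, and an `infeasible` flag, widest range first.
#' @export
run_dsa <- function(config, specs = default_dsa_specs(config)) {
  base_arms <- run_arms(config)
  base_icer <- icer(base_arms$UCG, base_arms$EG)
  if (!is.null(specs$base)) {
    bad <- which(!(specs$low <= specs$base & specs$base <= specs$high))
    if (length(bad)) {
      stop("DSA spec for ", specs$path[bad[1]], ": need low <= base <= high",
        call. = FALSE
      )
    }
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    one <- function(v) {
      tryCatch(run_at(config, specs$path[i], v),
        error = function(e) NULL
      )
    }
    lo <- one(specs$low[i])
    hi <- one(specs$high[i])
    gv <- function(r, f) if (is.null(r)) NA_real_ else r[[f]]
    data.frame(
      path = specs$path[i], low = specs$low[i], high = specs$high[i],
      icer_yols_low = gv(lo, "icer_per_yols"),
      icer_yols_high = gv(hi, "icer_per_yols"),
      icer_qaly_low = gv(lo, "icer_per_qaly"),
      icer_qaly_high = gv(hi, "icer_per_qaly"),
      infeasible = is.null(lo) || is.null(hi),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$range_qaly <- abs(out$icer_qaly_high - out$icer_qaly_low)
  out <- out[order(-out$range_qaly), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("hf_dsa", class(out))
  out
}

#' Triangular deviates by inverse CDF
#'
#' @param n Number of draws.
#' @param min,mode,max Triangle support and mode.
#' @return Numeric vector.
#' @export
rtriangular <- function(n, min, mode, max) {
  if (max <= min) {
    return(rep(mode, n))
  }
  u <- stats::runif(n)
  f <- (mode - min) / (max - min)
  ifelse(u < f,
    min + sqrt(u * (max - min) * (mode - min)),
    max - sqrt((1 - u) * (max - min) * (max - mode))
  )
}

beta_from_moments <- function(mean, se) {
  v <- se^2
  if (mean <= 0 || mean >= 1 || v >= mean * (1 - mean)) {
    return(NULL)
  }
  k <- mean * (1 - mean) / v - 1
  list(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Build the probabilistic-sensitivity-analysis parameter distributions
#'
#' Families follow the published mapping: utilities get beta distributions
#' (method-of-moments on the base value with SE = (hi - lo) / (2 x 1.96),
#' range +/-50% capped at 1; falls back to uniform with a warning when the
#' variance is infeasible for a beta); costs get uniform distributions on
#' +/-50% of base; transition probabilities get triangular distributions with
#' mode at base and +/-50% limits capped into \[0, 1\], each of a row's ten
#' entries sampled independently then renormalized. Treatment drug and
#' monitoring costs are fixed and excluded.
#'
#' @param config An `hf_config`.
#' @return List of distribution specs (`path`, `family`, parameters).
#' @export
build_psa_distributions <- function(config) {
  dists <- list()
  for (cls in nyha_states(living = TRUE)) {
    b <- config$utilities[[cls]]
    lo <- 0.5 * b
    hi <- min(1, 1.5 * b)
    bp <- beta_from_moments(b, (hi - lo) / (2 * 1.96))
    if (is.null(bp)) {
      warning("beta moment-matching infeasible for utility.", cls,
        "; falling back to uniform",
        call. = FALSE
      )
      dists <- c(dists, list(list(
        path = paste0("utility.", cls),
        family = "uniform", min = lo, max = hi
      )))
    } else {
      dists <- c(dists, list(list(
        path = paste0("utility.", cls), family = "beta",
        shape1 = bp$shape1, shape2 = bp$shape2
      )))
    }
  }
  for (cls in nyha_states(living = TRUE)) {
    b <- config$costs$background_annual[[cls]]
    dists <- c(dists, list(list(
      path = paste0("cost.background.", cls),
      family = "uniform", min = 0.5 * b, max = 1.5 * b
    )))
  }
  for (cn in c("hf_hosp_event", "cvd_death_admission")) {
    b <- config$costs[[cn]]
    dists <- c(dists, list(list(
      path = paste0("cost.", cn),
      family = "uniform", min = 0.5 * b, max = 1.5 * b
    )))
  }
  for (cls in nyha_states(living = TRUE)) {
    for (col in TP_COLS) {
      b <- config$table[cls, col]
      dists <- c(dists, list(list(
        path = paste0("tp.", cls, ".", col), family = "triangular",
        min = max(0, 0.5 * b), mode = b, max = min(1, 1.5 * b)
      )))
    }
  }
  dists
}

sample_distribution <- function(d) {
  switch(d$family,
    beta = stats::rbeta(1, d$shape1, d$shape2),
    uniform = stats::runif(1, d$min, d$max),
    triangular = rtriangular(1, d$min, d$mode, d$max),
    degenerate = d$value,
    stop("unknown distribution family: ", d$family, call. = FALSE)
  )
}

apply_samples <- function(config, dists, values) {
  tp_mask <- startsWith(vapply(dists, `[[`, "", "path"), "tp.")
  for (i in which(!tp_mask)) {
    config <- set_param(config, dists[[i]]$path, values[i])
  }
  if (any(tp_mask)) {
    m <- unclass(config$table)
    for (i in which(tp_mask)) {
      p <- strsplit(dists[[i]]$path, ".", fixed = TRUE)[[1]]
      m[p[2], p[3]] <- values[i]
    }
    config$table <- transition_table(
      renormalize_rows(m, warn = FALSE, max_dev = Inf),
      provenance = attr(config$table, "provenance")
    )
  }
  config
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Per iteration, every distribution from [build_psa_distributions()] is
#' sampled (transition rows renormalized after sampling), both arms are
#' rerun, and the incremental cost, life-years and QALYs are recorded. The
#' fraction cost-effective at a willingness-to-pay threshold lambda is the
#' fraction of iterations with nonnegative incremental net monetary benefit
#' `lambda * delta_QALY - delta_cost`. Percentile (2.5/97.5) intervals of the
#' iteration-level ICERs are computed on the positive-effect quadrant, with
#' the quadrant composition reported; net-benefit percentile intervals are
#' also returned. Fully reproducible for a given seed (each iteration uses a
#' counter-derived substream).
#'
#' @param config An `hf_config`.
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Integer RNG seed.
#' @param threshold Willingness-to-pay threshold (AUD/QALY) for the headline
#'   percent-cost-effective.
#' @param ceac_thresholds Grid of thresholds for the acceptability curve.
#' @param dists Distribution list; defaults to [build_psa_distributions()].
#' @return List of class `hf_psa`: `draws` (per-iteration deltas), `ceac`,
#'   `pct_ce_at_threshold`, `icer_ci_yols`, `icer_ci_qaly`, `nmb_ci`,
#'   `quadrants`, `n_failed`, `seed`.
#' @export
run_psa <- function(config, n_iter = 10000, seed = 1,
                    threshold = 50000,
                    ceac_thresholds = seq(0, 100000, by = 2500),
                    dists = build_psa_distributions(config)) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  draws <- matrix(NA_real_, nrow = n_iter, ncol = 3,
    dimnames = list(NULL, c("delta_cost", "delta_ly", "delta_qaly"))
  )
  n_failed <- 0L
  for (i in seq_len(n_iter)) {
    set.seed((abs(seed) + i * 10007) %% 2147483647L)
    vals <- vapply(dists, sample_distribution, 0)
    res <- tryCatch(
      {
        cfg <- apply_samples(config, dists, vals)
        arms <- run_arms(cfg)
        ic <- icer(arms$UCG, arms$EG)
        c(ic$delta_cost, ic$delta_ly, ic$delta_qaly)
      },
      error = function(e) NULL
    )
    if (is.null(res)) n_failed <- n_failed + 1L else draws[i, ] <- res
  }
  ok <- stats::complete.cases(draws)
  d <- as.data.frame(draws)
  d$iteration <- seq_len(n_iter)
  dq <- draws[ok, "delta_qaly"]
  dly <- draws[ok, "delta_ly"]
  dc <- draws[ok, "delta_cost"]

  ceac <- data.frame(
    threshold = ceac_thresholds,
    fraction = vapply(
      ceac_thresholds,
      function(l) mean(l * dq - dc >= 0), 0
    )
  )
  pct_ce <- mean(threshold * dq - dc >= 0)

  icer_ci <- function(effect) {
    pos <- effect > 0
    if (!any(pos)) {
      return(c(NA_real_, NA_real_))
    }
    stats::quantile(dc[pos] / effect[pos], c(0.025, 0.975), names = FALSE)
  }
  nmb <- threshold * dq - dc
  structure(
    list(
      draws = d[, c("iteration", "delta_cost", "delta_ly", "delta_qaly")],
      ceac = ceac,
      threshold = threshold,
      pct_ce_at_threshold = pct_ce,
      icer_ci_yols = icer_ci(dly),
      icer_ci_qaly = icer_ci(dq),
      nmb_ci = stats::quantile(nmb, c(0.025, 0.975), names = FALSE),
      quadrants = c(
        ne = mean(dc >= 0 & dq > 0), se = mean(dc < 0 & dq > 0),
        nw = mean(dc >= 0 & dq <= 0), sw = mean(dc < 0 & dq <= 0)
      ),
      n_iter = n_iter, n_failed = n_failed, seed = seed
    ),
    class = "hf_psa"
  )
}

#' @export
print.hf_psa <- function(x, ...) {
  cat(sprintf(
    paste0(
      "PSA: %d iterations (seed %d, %d failed)\n",
      "  %.1f%% cost-effective at AUD %.0f per QALY\n",
      "  ICER 95%% interval: %.0f-%.0f per YoLS, %.0f-%.0f per QALY\n"
    ),
    x$n_iter, x$seed, x$n_failed, 100 * x$pct_ce_at_threshold, x$threshold,
    x$icer_ci_yols[1], x$icer_ci_yols[2],
    x$icer_ci_qaly[1], x$icer_ci_qaly[2]
  ))
  invisible(x)
}

#' Export PSA scatter and CEAC to CSV
#'
#' @param psa An `hf_psa`.
#' @param scatter_path,ceac_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_psa_csv <- function(psa, scatter_path = NULL, ceac_path = NULL) {
  if (!is.null(scatter_path)) {
    utils::write.csv(psa$draws, scatter_path, row.names = FALSE)
  }
  if (!is.null(ceac_path)) {
    utils::write.csv(psa$ceac, ceac_path, row.names = FALSE)
  }
  invisible(c(scatter = scatter_path, ceac = ceac_path))
}
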