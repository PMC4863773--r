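# Structured run reports (JSON), config hashing, and the command-line
# driver behind inst/cli/hfcea.

#' Deterministic hash of a model configuration
#'
#' A short hex digest over the canonical YAML serialization of the
#' configuration, so a report deterministically identifies its inputs.
#' (Implemented as a 64-bit FNV-style multiplicative hash over the
#' serialized text; no external digest package is required.)
#'
#' @param config An `hf_config`.
#' @return Character scalar, 16 hex digits.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  bytes <- as.integer(charToRaw(paste(readLines(tmp, warn = FALSE),
    collapse = "\n"
  )))
  # FNV-1a, 64-bit, carried as two 32-bit halves to stay in double precision
  h <- c(0x84222325, 0xcbf29ce4) # lo, hi of 0xcbf29ce484222325
  prime_lo <- 0x1b3
  for (b in bytes) {
    # xor only touches the low byte (b < 256); stay in doubles throughout
    h[1] <- (h[1] %/% 256) * 256 + bitwXor(h[1] %% 256, b)
    lo <- h[1] * prime_lo
    hi <- h[2] * prime_lo + floor(lo / 2^32)
    h[1] <- lo %% 2^32
    h[2] <- hi %% 2^32
  }
  # format each 32-bit half as two 16-bit pieces (sprintf %x needs < 2^31)
  hex16 <- function(x) sprintf("%04x%04x", as.integer(x %/% 65536),
    as.integer(x %% 65536))
  paste0(hex16(h[2]), hex16(h[1]))
}

arm_summary <- function(res) {
  list(
    ly_disc = res$ly_disc, ly_undisc = res$ly_undisc,
    qaly_disc = res$qaly_disc, qaly_undisc = res$qaly_undisc,
    cost_disc = res$cost_disc, cost_undisc = res$cost_undisc,
    hospitalizations_per_1000 = res$hospitalizations_per_1000,
    deaths_per_1000 = res$deaths_per_1000
  )
}

#' Build a structured run report
#'
#' Runs the base case (and optionally DSA, PSA and scenarios) and collects
#' everything into one serializable report: per-arm results, incremental
#' economics, events averted/NNT, the configuration hash, package version and
#' timestamp. Internals stay full precision; display rounding happens only
#' when printing.
#'
#' @param config An `hf_config`.
#' @param dsa Include a one-way sensitivity table.
#' @param psa_iterations If > 0, run a PSA with this many iterations.
#' @param scenarios Character vector of scenario names to run (default none).
#' @param seed Seed for the PSA.
#' @param threshold Willingness-to-pay threshold for the PSA.
#' @return List of class `hf_report`.
#' @export
run_report <- function(config, dsa = FALSE, psa_iterations = 0,
                       scenarios = character(), seed = 1, threshold = 50000) {
  arms <- run_arms(config)
  ic <- icer(arms$UCG, arms$EG)
  ev <- event_diff(arms$UCG, arms$EG)
  report <- list(
    package_version = as.character(utils::packageVersion("hfcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = config_hash(config),
    seed = seed,
    arms = lapply(arms, arm_summary),
    incremental = unclass(ic),
    events = unclass(ev)
  )
  if (dsa) {
    report$dsa <- as.data.frame(run_dsa(config))
  }
  if (psa_iterations > 0) {
    psa <- run_psa(config,
      n_iter = psa_iterations, seed = seed,
      threshold = threshold
    )
    report$psa <- list(
      n_iter = psa$n_iter, n_failed = psa$n_failed, seed = psa$seed,
      pct_ce_at_threshold = psa$pct_ce_at_threshold,
      threshold = psa$threshold,
      icer_ci_yols = psa$icer_ci_yols, icer_ci_qaly = psa$icer_ci_qaly,
      nmb_ci = psa$nmb_ci, quadrants = as.list(psa$quadrants)
    )
    attr(report, "psa_full") <- psa
  }
  for (sc in scenarios) {
    s <- run_scenario(sc, config)
    report$scenarios[[sc]] <- list(
      description = s$description,
      incremental = unclass(s$icer),
      arms = lapply(s$arms, arm_summary)
    )
  }
  class(report) <- "hf_report"
  report
}

#' Write a run report to JSON
#'
#' @param report An `hf_report`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: hfcea <subcommand> [options]",
    "subcommands:",
    "  run       base-case report        --config FILE --out DIR [--horizon N] [--discount R]",
    "  dsa       one-way sensitivity     --config FILE --out DIR",
    "  psa       probabilistic analysis  --config FILE --out DIR --iterations N --seed S --threshold T",
    "  scenario  named scenario          --config FILE --out DIR --name NAME (or --list)",
    "  simulate  synthetic event log     --config FILE --out DIR --n N --seed S --arm ARM",
    "  validate  config check only       --config FILE",
    sep = "\n"
  )
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (key %in% c("list")) {
      flags[[key]] <- TRUE
      i <- i + 1
    } else {
      if (i + 1 > length(args)) stop("flag --", key, " needs a value", call. = FALSE)
      flags[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  flags
}

#' Command-line driver
#'
#' Thin, testable entry point behind the `inst/cli/hfcea` script. Subcommands:
#' `run`, `dsa`, `psa`, `scenario`, `simulate`, `validate`. Returns the exit
#' status instead of calling `quit()`, so it can be driven in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch(
    {
      if (!length(args)) {
        message(cli_usage())
        return(invisible(2L))
      }
      sub <- args[1]
      flags <- parse_flags(args[-1])
      if (!sub %in% c("run", "dsa", "psa", "scenario", "simulate", "validate")) {
        message("unknown subcommand: ", sub, "\n", cli_usage())
        return(invisible(2L))
      }
      if (sub == "scenario" && isTRUE(flags$list)) {
        reg <- scenario_registry()
        message(paste(sprintf("%-24s %s", reg$name, reg$description),
          collapse = "\n"
        ))
        return(invisible(0L))
      }
      config <- if (is.null(flags$config)) {
        default_parameters()
      } else {
        load_config(flags$config)
      }
      if (!is.null(flags$horizon)) config$horizon <- as.integer(flags$horizon)
      if (!is.null(flags$discount)) {
        config$discount$rate <- as.numeric(flags$discount)
      }
      seed <- if (is.null(flags$seed)) 1L else as.integer(flags$seed)
      out <- flags$out
      need_out <- sub != "validate"
      if (need_out && is.null(out)) stop("--out DIR is required", call. = FALSE)
      if (need_out && !dir.exists(out)) dir.create(out, recursive = TRUE)

      if (sub == "validate") {
        validate_transition_table(config$table)
        message("config OK (hash ", config_hash(config), ")")
      } else if (sub == "run") {
        rep <- run_report(config, seed = seed)
        write_report(rep, file.path(out, "report.json"))
        arms <- run_arms(config)
        write_trace_csv(arms$EG, file.path(out, "trace_EG.csv"))
        write_trace_csv(arms$UCG, file.path(out, "trace_UCG.csv"))
        message("report written to ", file.path(out, "report.json"))
      } else if (sub == "dsa") {
        tab <- run_dsa(config)
        utils::write.csv(as.data.frame(tab), file.path(out, "dsa.csv"),
          row.names = FALSE
        )
        message("DSA table written to ", file.path(out, "dsa.csv"))
      } else if (sub == "psa") {
        n_iter <- if (is.null(flags$iterations)) 10000L else as.integer(flags$iterations)
        threshold <- if (is.null(flags$threshold)) 50000 else as.numeric(flags$threshold)
        psa <- run_psa(config, n_iter = n_iter, seed = seed, threshold = threshold)
        write_psa_csv(psa,
          scatter_path = file.path(out, "psa_scatter.csv"),
          ceac_path = file.path(out, "psa_ceac.csv")
        )
        jsonlite::write_json(
          list(
            n_iter = psa$n_iter, n_failed = psa$n_failed, seed = psa$seed,
            threshold = psa$threshold,
            pct_ce_at_threshold = psa$pct_ce_at_threshold,
            icer_ci_yols = psa$icer_ci_yols, icer_ci_qaly = psa$icer_ci_qaly
          ),
          file.path(out, "psa_summary.json"),
          auto_unbox = TRUE, digits = NA
        )
        message("PSA outputs written to ", out)
      } else if (sub == "scenario") {
        if (is.null(flags$name)) stop("--name NAME is required", call. = FALSE)
        s <- run_scenario(flags$name, config)
        jsonlite::write_json(
          list(
            name = s$name, description = s$description,
            incremental = unclass(s$icer),
            arms = lapply(s$arms, arm_summary)
          ),
          file.path(out, paste0("scenario_", s$name, ".json")),
          auto_unbox = TRUE, digits = NA, na = "null"
        )
        message("scenario report written to ", out)
      } else if (sub == "simulate") {
        n <- if (is.null(flags$n)) 1000L else as.integer(flags$n)
        arm <- if (is.null(flags$arm)) "UCG" else flags$arm
        tables <- build_arm_tables(config, arm)
        log <- simulate_patients(tables, n = n, seed = seed,
          start_state = config$start_state
        )
        write_event_log_csv(log, file.path(out, "events.csv"))
        message("event log written to ", file.path(out, "events.csv"))
      }
      0L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}
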