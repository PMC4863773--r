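# Config file I/O: YAML or JSON parameter packs with inline or CSV-referenced
# transition tables.

#' Read a transition table from CSV
#'
#' One row per living origin class, columns `from_class` then the ten canonical
#' outcome columns `toI_noh, toI_h, ..., cv_death, noncv_death`.
#'
#' @param path CSV file path.
#' @param provenance Table provenance tag.
#' @param renormalize Proportionally rescale rows whose printed values miss 1
#'   (warned); otherwise sums are validated strictly.
#' @return An `hf_table`.
#' @export
read_transition_csv <- function(path, provenance = "weighted-average",
                                renormalize = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("from_class", TP_COLS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("transition CSV ", path, " missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(df[, TP_COLS])
  rownames(m) <- df$from_class
  if (renormalize) m <- renormalize_rows(m)
  transition_table(m, provenance = provenance)
}

#' Write a transition table to CSV
#'
#' @param table An `hf_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(table, path) {
  df <- data.frame(from_class = rownames(table), unclass(table)[, TP_COLS],
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

config_field <- function(x, section, name, default = NULL) {
  v <- x[[name]]
  if (is.null(v)) {
    if (!is.null(default)) return(default)
    stop("config section [", section, "]: missing field '", name, "'",
      call. = FALSE
    )
  }
  v
}

parse_table_block <- function(block, dir, section = "transition_table") {
  if (is.null(block)) stop("config: missing section [", section, "]", call. = FALSE)
  provenance <- if (is.null(block$provenance)) "weighted-average" else block$provenance
  if (!is.null(block$csv)) {
    p <- block$csv
    if (!file.exists(p)) p <- file.path(dir, block$csv)
    if (!file.exists(p)) {
      stop("config section [", section, "]: CSV not found: ", block$csv,
        call. = FALSE
      )
    }
    return(read_transition_csv(p, provenance = provenance))
  }
  rows <- config_field(block, section, "rows")
  m <- do.call(rbind, lapply(nyha_states(living = TRUE), function(cls) {
    r <- rows[[cls]]
    if (is.null(r)) {
      stop("config section [", section, "]: missing row for class ", cls,
        call. = FALSE
      )
    }
    as.numeric(unlist(r))
  }))
  rownames(m) <- nyha_states(living = TRUE)
  colnames(m) <- TP_COLS
  transition_table(renormalize_rows(m), provenance = provenance)
}

#' Load a model configuration from a YAML or JSON parameter pack
#'
#' The file carries sections `model`, `transition_table` (inline rows or a
#' `csv:` reference resolved relative to the file), `hazard_ratios`,
#' `mixture`, `utilities`, `costs`, `discount` and `age_trend`, plus an
#' optional `per_year_tables` list. Missing fields raise named-field errors;
#' rows not summing to one are renormalized with a warning (or rejected when
#' grossly off).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [model_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  dir <- dirname(path)

  model <- config_field(raw, "top", "model")
  tab <- parse_table_block(raw$transition_table, dir)

  per_year <- NULL
  if (!is.null(raw$per_year_tables)) {
    per_year <- lapply(seq_along(raw$per_year_tables), function(i) {
      blk <- raw$per_year_tables[[i]]
      blk$provenance <- "per-year"
      parse_table_block(blk, dir, section = paste0("per_year_tables[", i, "]"))
    })
  }

  hr_blk <- config_field(raw, "top", "hazard_ratios")
  hr_one <- function(name) {
    v <- config_field(hr_blk, "hazard_ratios", name)
    as.numeric(unlist(v))
  }
  hrs <- hazard_ratio_set(
    hf_hosp = hr_one("hf_hosp"),
    cv_death = hr_one("cv_death"),
    all_cause_death = hr_one("all_cause_death")
  )

  mix <- unlist(config_field(raw, "top", "mixture"))
  utilities <- unlist(config_field(raw, "top", "utilities"))

  cb <- config_field(raw, "top", "costs")
  costs <- cost_set(
    background_annual = unlist(config_field(cb, "costs", "background_annual")),
    hf_hosp_event = config_field(cb, "costs", "hf_hosp_event"),
    cvd_death_admission = config_field(cb, "costs", "cvd_death_admission"),
    death_in_hospital_fraction =
      config_field(cb, "costs", "death_in_hospital_fraction", 0.5),
    eplerenone_annual = config_field(cb, "costs", "eplerenone_annual"),
    epl_monitor_first_cycle = config_field(cb, "costs", "epl_monitor_first_cycle"),
    epl_monitor_annual = config_field(cb, "costs", "epl_monitor_annual"),
    spiro_annual = config_field(cb, "costs", "spiro_annual"),
    spiro_monitor_annual = config_field(cb, "costs", "spiro_monitor_annual"),
    hosp_events_per_cycle_cap =
      config_field(cb, "costs", "hosp_events_per_cycle_cap", 1)
  )

  db <- config_field(raw, "top", "discount")
  at <- config_field(raw, "top", "age_trend")
  trend <- if (!is.null(at$ages)) {
    age_trend(
      baseline_age = config_field(at, "age_trend", "baseline_age"),
      ages = as.numeric(unlist(at$ages)),
      multipliers = as.numeric(unlist(at$multipliers)),
      standin = isTRUE(at$standin)
    )
  } else {
    age_trend(
      baseline_age = config_field(at, "age_trend", "baseline_age", 68),
      growth = config_field(at, "age_trend", "growth", 0.087)
    )
  }

  model_config(
    table = tab,
    per_year_tables = per_year,
    hrs = hrs,
    hr_mode = config_field(model, "model", "hr_mode", "cv-only"),
    mix = mix,
    utilities = utilities,
    costs = costs,
    discount = list(
      rate = config_field(db, "discount", "rate"),
      start_cycle = config_field(db, "discount", "start_cycle", 2)
    ),
    trend = trend,
    horizon = config_field(model, "model", "horizon"),
    start_state = config_field(model, "model", "start_state", "II"),
    cohort_size = config_field(model, "model", "cohort_size", 1000),
    accrual = config_field(model, "model", "accrual", "cycle-start"),
    trend_order = config_field(model, "model", "trend_order", "trend-first"),
    monitor_year1_combined =
      config_field(model, "model", "monitor_year1_combined", FALSE)
  )
}

#' Write a model configuration to a YAML parameter pack
#'
#' Inverse of [load_config()]; the transition tables are written inline so the
#' file is self-contained and round-trips to identical values.
#'
#' @param config An `hf_config`.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  table_block <- function(tab) {
    list(
      provenance = attr(tab, "provenance"),
      rows = stats::setNames(
        lapply(nyha_states(living = TRUE), function(cls) {
          as.list(stats::setNames(as.numeric(tab[cls, ]), TP_COLS))
        }),
        nyha_states(living = TRUE)
      )
    )
  }
  out <- list(
    model = list(
      horizon = config$horizon,
      start_state = config$start_state,
      cohort_size = config$cohort_size,
      hr_mode = config$hr_mode,
      accrual = config$accrual,
      trend_order = config$trend_order,
      monitor_year1_combined = config$monitor_year1_combined
    ),
    transition_table = table_block(config$table),
    hazard_ratios = lapply(
      config$hrs,
      function(h) c(h$point, h$lo, h$hi)
    ),
    mixture = as.list(config$mix),
    utilities = as.list(config$utilities),
    costs = list(
      background_annual = as.list(config$costs$background_annual),
      hf_hosp_event = config$costs$hf_hosp_event,
      cvd_death_admission = config$costs$cvd_death_admission,
      death_in_hospital_fraction = config$costs$death_in_hospital_fraction,
      eplerenone_annual = config$costs$eplerenone_annual,
      epl_monitor_first_cycle = config$costs$epl_monitor_first_cycle,
      epl_monitor_annual = config$costs$epl_monitor_annual,
      spiro_annual = config$costs$spiro_annual,
      spiro_monitor_annual = config$costs$spiro_monitor_annual,
      hosp_events_per_cycle_cap = config$costs$hosp_events_per_cycle_cap
    ),
    discount = config$discount,
    age_trend = list(
      baseline_age = config$trend$baseline_age,
      ages = config$trend$ages,
      multipliers = config$trend$multipliers,
      standin = config$trend$standin
    )
  )
  if (!is.null(config$per_year_tables)) {
    out$per_year_tables <- lapply(config$per_year_tables, table_block)
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
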