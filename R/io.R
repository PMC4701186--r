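#' Persist pipeline artifacts
#'
#' Writes the intermediate and summary artifacts of one pipeline run as
#' flat CSV plus one JSON summary: `ledger.csv`, `chw_reports.csv`,
#' `chw_events.csv`, `chw_missing_months.csv`, `birth_histories.csv`,
#' `per_window_metrics.csv`, `summary.json`. The seed is recorded in the
#' summary; every rendered number is recomputable from the CSVs.
#'
#' @param report a [run_pipeline()] result.
#' @param ledger,chw,fbh the run's intermediate objects.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report_artifacts <- function(report, ledger, chw, fbh, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(data.table::as.data.table(x),
                                          file.path(out_dir, f))
  fw(ledger, "ledger.csv")
  fw(chw$reports, "chw_reports.csv")
  fw(chw$events, "chw_events.csv")
  fw(chw$missing_months, "chw_missing_months.csv")
  fw(fbh, "birth_histories.csv")
  fw(report$per_window, "per_window_metrics.csv")
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Summary list for JSON serialization
#'
#' @param report a [run_pipeline()] result.
#' @return plain list mirroring the rendered summary tables.
#' @export
report_summary <- function(report) {
  tabs <- render_tables(report)
  list(
    seed = report$seed,
    n_windows = nrow(report$windows),
    population = report$population,
    coverage_pct = report$coverage,
    completeness = report$completeness,
    accuracy_annual_average = as.list(report$accuracy$annual_average),
    accuracy_per_window = report$accuracy$per_window,
    quality = report$quality,
    cost = if (is.null(report$cost)) NULL else unclass(report$cost),
    tables = tabs
  )
}

#' Read and write pipeline configurations
#'
#' Configurations are stored as one YAML (or JSON) document with
#' `simulation`, `capture`, `survey`, `analysis`, optional `costing`
#' sections and a top-level `seed`. Fields are passed through the
#' section constructors, so unknown fields and out-of-range values are
#' rejected (the constructors are the schema).
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return [read_pipeline_config()]: a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (sec in c("simulation", "capture", "survey")) {
    if (is.null(raw[[sec]])) stop("config missing required section: ", sec)
  }
  costing <- NULL
  if (!is.null(raw$costing)) {
    cs <- raw$costing
    costing <- list(
      ledger = cost_ledger(as.data.frame(cs$items),
                           cpi_series = unlist(cs$cpi_series),
                           fx_rate = cs$fx_rate %||% 1,
                           base_year = cs$base_year),
      n_events = cs$n_events
    )
  }
  pipeline_config(
    simulation = do.call(sim_config, raw$simulation),
    capture = do.call(capture_model, raw$capture),
    survey = do.call(survey_model, raw$survey),
    analysis = raw$analysis %||% list(),
    costing = costing,
    seed = raw$seed %||% 1L
  )
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @return [write_pipeline_config()]: `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  doc <- list(
    simulation = unclass(config$simulation),
    capture = unclass(config$capture),
    survey = unclass(config$survey),
    analysis = config$analysis,
    seed = config$seed
  )
  if (!is.null(config$costing)) {
    led <- config$costing$ledger
    doc$costing <- list(items = led$items,
                        cpi_series = as.list(led$cpi_series),
                        fx_rate = led$fx_rate,
                        base_year = as.integer(led$base_year),
                        n_events = config$costing$n_events)
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Column map for DHS-style birth recode ingestion
#'
#' Renames DHS birth-recode style columns to the layout [tabulate_fbh()]
#' expects: `b3` (birth CMC), `b4` (sex, 1 male / 2 female), `b5` (alive
#' flag), `b7` (age at death in completed months), `v008` (interview
#' CMC). Death dates are reconstructed as `b3 + b7` where absent.
#'
#' @param df data.frame with DHS-style columns.
#' @return data.frame in the package's birth-history layout.
#' @export
from_birth_recode <- function(df) {
  need <- c("b3", "b4", "b5")
  if (!all(need %in% names(df))) stop("need columns b3, b4, b5")
  dead <- df$b5 == 0 | tolower(as.character(df$b5)) %in% c("no", "dead")
  age_m <- if ("b7" %in% names(df)) as.integer(df$b7) else NA_integer_
  out <- data.frame(
    birth_cmc = as.integer(df$b3),
    sex = ifelse(df$b4 == 1 | tolower(as.character(df$b4)) == "male",
                 "male", "female"),
    dead = dead,
    age_at_death_months = ifelse(dead, age_m, NA_integer_),
    age_at_death_days = NA_integer_,
    death_cmc = ifelse(dead, as.integer(df$b3) + age_m, NA_integer_)
  )
  if ("v008" %in% names(df)) out$interview_cmc <- as.integer(df$v008)
  out
}
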