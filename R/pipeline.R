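#' Assemble a pipeline configuration
#'
#' Bundles the four model sections plus the analysis period into one
#' validated configuration. All randomness in [run_pipeline()] derives
#' from the single `seed` by a fixed stream-splitting rule: the simulator
#' uses `seed`, the CHW observation `seed + 1`, the survey observation
#' `seed + 2`.
#'
#' @param simulation a [sim_config()].
#' @param capture a [capture_model()].
#' @param survey a [survey_model()].
#' @param analysis list with `period_start_cmc`, `period_end_cmc`
#'   (within the simulated span) and `population` (resident population
#'   used as CBR/completeness denominator; defaults to 5 residents per
#'   simulated woman).
#' @param costing optional [cost_ledger()] plus `n_events` override;
#'   `NULL` to skip cost metrics.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            capture = capture_model(),
                            survey = survey_model(),
                            analysis = list(),
                            costing = NULL,
                            seed = 1L) {
  stopifnot(inherits(simulation, "sim_config"),
            inherits(capture, "capture_model"),
            inherits(survey, "survey_model"))
  n_women <- simulation$n_catchments * simulation$households_per_catchment *
    simulation$women_per_household
  analysis <- utils::modifyList(list(
    period_start_cmc = simulation$sim_start_cmc,
    period_end_cmc = simulation$sim_end_cmc,
    population = n_women * 5L
  ), analysis)
  if (analysis$period_start_cmc < simulation$sim_start_cmc ||
      analysis$period_end_cmc > simulation$sim_end_cmc) {
    stop("analysis period must lie within the simulated span")
  }
  if (analysis$period_end_cmc - analysis$period_start_cmc + 1L < 12L) {
    stop("analysis period must span at least 12 months")
  }
  if (survey$interview_cmc < simulation$sim_end_cmc) {
    stop("survey interview must not precede the simulated span's end")
  }
  structure(list(simulation = simulation, capture = capture, survey = survey,
                 analysis = analysis, costing = costing,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Named scenario presets
#'
#' Illustrative observation regimes on a common demographic world
#' (defaults of [sim_config()], simulated Jan 2010 -- Dec 2013, survey
#' interview Jan 2014):
#' \describe{
#'   \item{gold}{error-free everything: perfect capture, no missing
#'     reports, census survey with no recall error. Completeness and all
#'     accuracy ratios are exactly 100.}
#'   \item{mali_like}{high capture (births 0.903, deaths 0.908), no
#'     missing reports, census survey with mild recall omission and age
#'     heaping; 15-month analysis period.}
#'   \item{malawi_like}{moderate capture (births 0.659, deaths 0.506),
#'     3.4\% missing reports, 25\% household sample; 48-month period.}
#'   \item{ethiopia_like}{low capture (births 0.30, deaths 0.22), 4.3\%
#'     missing reports, 25\% household sample; 15-month period.}
#' }
#' Capture values echo published completeness figures from field pilots;
#' they are scenario illustrations, not estimates.
#'
#' @param name preset name.
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
pipeline_preset <- function(name = c("gold", "mali_like", "malawi_like",
                                     "ethiopia_like"),
                            seed = 1L) {
  name <- match.arg(name)
  sim <- sim_config(seed = seed)
  interview <- cmc(2014, 1)
  cfg <- switch(name,
    gold = pipeline_config(
      simulation = sim,
      capture = capture_model(),
      survey = survey_model("census", interview_cmc = interview),
      seed = seed),
    mali_like = pipeline_config(
      simulation = sim,
      capture = capture_model(p_capture_birth = 0.903,
                              p_capture_death_neonatal = 0.908,
                              p_capture_death_postneonatal = 0.908,
                              p_capture_death_child = 0.908,
                              p_monthly_report_missing = 0,
                              p_stillbirth_as_neonatal = 0.03),
      survey = survey_model("census", interview_cmc = interview,
                            p_omit_per_year_recall = 0.04,
                            p_heap_to_12m = 0.3),
      analysis = list(period_start_cmc = cmc(2012, 7),
                      period_end_cmc = cmc(2013, 9)),
      seed = seed),
    malawi_like = pipeline_config(
      simulation = sim,
      capture = capture_model(p_capture_birth = 0.659,
                              p_capture_death_neonatal = 0.506,
                              p_capture_death_postneonatal = 0.506,
                              p_capture_death_child = 0.506,
                              p_monthly_report_missing = 0.034),
      survey = survey_model("household_sample", sample_fraction = 0.25,
                            interview_cmc = interview,
                            p_omit_per_year_recall = 0.03,
                            p_heap_to_12m = 0.3),
      seed = seed),
    ethiopia_like = pipeline_config(
      simulation = sim,
      capture = capture_model(p_capture_birth = 0.30,
                              p_capture_death_neonatal = 0.22,
                              p_capture_death_postneonatal = 0.22,
                              p_capture_death_child = 0.22,
                              p_monthly_report_missing = 0.043),
      survey = survey_model("household_sample", sample_fraction = 0.25,
                            interview_cmc = interview,
                            p_omit_per_year_recall = 0.03,
                            p_heap_to_12m = 0.3),
      analysis = list(period_start_cmc = cmc(2012, 1),
                      period_end_cmc = cmc(2013, 3)),
      seed = seed)
  )
  cfg
}

#' Run the full validation pipeline
#'
#' simulate -> observe (CHW and survey) -> tabulate per rolling window ->
#' completeness, accuracy, data-quality and cost metrics. For sampled
#' survey designs the reference CBR denominator is the population scaled
#' by the realised household sampling fraction, so the survey estimates
#' area-level rates; mortality rates are ratios and need no scaling.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the ledger, CHW
#'   reports, captured-event register, birth histories, per-window
#'   metrics (CSV) and a summary JSON are written there. Outputs are
#'   byte-identical across runs with equal config and seed.
#' @param quiet suppress per-stage count logging.
#' @return a list of class `validation_report`; see the package vignette
#'   for the field layout.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (!quiet) message(sprintf(...))

  sim <- config$simulation
  sim$seed <- config$seed
  ledger <- simulate_ledger(sim)
  log_msg("simulated %d pregnancy outcomes (%d live births, %d deaths)",
          nrow(ledger), sum(!ledger$stillbirth), sum(ledger$died))

  chw <- apply_chw_observation(ledger, config$capture, seed = config$seed + 1L,
                               period_start_cmc = config$analysis$period_start_cmc,
                               period_end_cmc = config$analysis$period_end_cmc)
  log_msg("CHW observation: %d events captured, %d catchment-months suppressed",
          nrow(chw$events), nrow(chw$missing_months))

  fbh <- apply_survey_observation(ledger, config$survey, seed = config$seed + 2L)
  log_msg("survey observation: %d children from %d households",
          nrow(fbh), attr(fbh, "n_households_selected"))

  windows <- rolling_windows(config$analysis$period_start_cmc,
                             config$analysis$period_end_cmc)
  population <- config$analysis$population
  n_hh_total <- sim$n_catchments * sim$households_per_catchment
  frac <- attr(fbh, "n_households_selected") / n_hh_total
  ref_population <- population * frac

  rows <- list()
  rmm_rates <- ref_rates <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    cc <- tabulate_chw(chw, w)
    fc <- suppressMessages(tabulate_fbh(fbh, w))
    rmm_rates[[i]] <- period_rates(cc, population)
    ref_rates[[i]] <- period_rates(fc, ref_population)
    eb <- expected_births(ref_rates[[i]]$cbr, population)
    ed <- expected_under5_deaths(ref_rates[[i]]$u5mr, eb)
    rows[[i]] <- data.frame(
      window = w$label, start_cmc = w$start_cmc, end_cmc = w$end_cmc,
      chw_births = cc$births, chw_births_male = cc$births_male,
      chw_births_female = cc$births_female,
      chw_deaths_neonatal = cc$deaths_neonatal,
      chw_deaths_infant = cc$deaths_infant,
      chw_deaths_under5 = cc$deaths_under5,
      fbh_births = fc$births, fbh_births_male = fc$births_male,
      fbh_births_female = fc$births_female,
      fbh_deaths_neonatal = fc$deaths_neonatal,
      fbh_deaths_infant = fc$deaths_infant,
      fbh_deaths_under5 = fc$deaths_under5,
      expected_births = eb, expected_under5_deaths = ed,
      completeness_births = completeness(cc$births, eb)$percent,
      completeness_under5_deaths = completeness(cc$deaths_under5, ed)$percent,
      chw_cbr = rmm_rates[[i]]$cbr, chw_nmr = rmm_rates[[i]]$nmr,
      chw_imr = rmm_rates[[i]]$imr, chw_u5mr = rmm_rates[[i]]$u5mr,
      fbh_cbr = ref_rates[[i]]$cbr, fbh_nmr = ref_rates[[i]]$nmr,
      fbh_imr = ref_rates[[i]]$imr, fbh_u5mr = ref_rates[[i]]$u5mr
    )
  }
  per_window <- do.call(rbind, rows)
  accuracy <- accuracy_ratios(rmm_rates, ref_rates, labels = windows$label)
  quality <- .quality_metrics(per_window, fbh)
  coverage <- reporting_coverage(chw)

  cost <- NULL
  if (!is.null(config$costing)) {
    total <- adjust_costs(config$costing$ledger)
    n_events <- config$costing$n_events
    if (is.null(n_events)) {
      n_events <- sum(chw$reports$births_male + chw$reports$births_female +
                        chw$reports$deaths_neonatal +
                        chw$reports$deaths_postneonatal +
                        chw$reports$deaths_child)
    }
    months <- config$analysis$period_end_cmc - config$analysis$period_start_cmc + 1L
    cost <- cost_metrics(total, population, months, n_events)
  }

  report <- structure(list(
    windows = windows,
    per_window = per_window,
    completeness = list(
      births = mean(per_window$completeness_births),
      under5_deaths = mean(per_window$completeness_under5_deaths)
    ),
    accuracy = accuracy,
    quality = quality,
    coverage = coverage,
    cost = cost,
    population = population,
    seed = config$seed,
    config = config
  ), class = "validation_report")

  if (!is.null(out_dir)) write_report_artifacts(report, ledger, chw, fbh, out_dir)
  report
}

.quality_metrics <- function(per_window, fbh) {
  srb_win <- function(m, f) 100 * m / f
  chw_srb <- mean(srb_win(per_window$chw_births_male, per_window$chw_births_female))
  fbh_srb <- mean(srb_win(per_window$fbh_births_male, per_window$fbh_births_female))
  avg <- function(x) mean(x)
  chw_nn <- avg(per_window$chw_deaths_neonatal)
  chw_inf <- avg(per_window$chw_deaths_infant)
  chw_u5 <- avg(per_window$chw_deaths_under5)
  fbh_nn <- avg(per_window$fbh_deaths_neonatal)
  fbh_inf <- avg(per_window$fbh_deaths_infant)
  fbh_u5 <- avg(per_window$fbh_deaths_under5)
  ages <- fbh$age_at_death_months[fbh$dead]
  heap <- if (any(!is.na(ages) & ages >= 10 & ages <= 14)) {
    heaping_index_12m(ages)
  } else NA_real_
  list(
    chw = list(srb = chw_srb,
               srb_in_reference_band = chw_srb >= 102 && chw_srb <= 107,
               avg_deaths_neonatal = chw_nn, avg_deaths_infant = chw_inf,
               avg_deaths_under5 = chw_u5,
               pct_neonatal_of_infant = if (chw_inf > 0) death_ratio(chw_nn, chw_inf) else NA_real_,
               pct_infant_of_under5 = if (chw_u5 > 0) death_ratio(chw_inf, chw_u5) else NA_real_),
    fbh = list(srb = fbh_srb,
               srb_in_reference_band = fbh_srb >= 102 && fbh_srb <= 107,
               avg_deaths_neonatal = fbh_nn, avg_deaths_infant = fbh_inf,
               avg_deaths_under5 = fbh_u5,
               pct_neonatal_of_infant = if (fbh_inf > 0) death_ratio(fbh_nn, fbh_inf) else NA_real_,
               pct_infant_of_under5 = if (fbh_u5 > 0) death_ratio(fbh_inf, fbh_u5) else NA_real_,
               heaping_index_12m = heap)
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d windows; coverage %.1f%%\n",
              nrow(x$windows), x$coverage))
  cat(sprintf("  completeness: births %.1f%%, under-five deaths %.1f%%\n",
              x$completeness$births, x$completeness$under5_deaths))
  aa <- x$accuracy$annual_average
  cat(sprintf("  accuracy (avg annual ratio %%): CBR %.1f, NMR %.1f, IMR %.1f, U5MR %.1f\n",
              aa["cbr"], aa["nmr"], aa["imr"], aa["u5mr"]))
  if (!is.null(x$cost)) {
    cat(sprintf("  cost: $%.1f per 1,000 per year, $%.1f per event\n",
                x$cost$annual_per_1000, x$cost$per_event))
  }
  invisible(x)
}

#' Render summary tables from a validation report
#'
#' Produces the two headline tables: a process/completeness/accuracy/cost
#' summary (one row) and a death-count/ratio panel comparing the CHW and
#' birth-history sources. All values are presentation-rounded to one
#' decimal with [round1()]; every number is recomputable from the
#' per-window CSV the pipeline persists.
#'
#' @param report a [run_pipeline()] result (or a compatible list).
#' @return list with `summary` and `death_ratios` data.frames.
#' @export
render_tables <- function(report) {
  if (is.null(report$per_window) || !nrow(report$per_window)) {
    stop("report has no analysis windows")
  }
  aa <- report$accuracy$annual_average
  summary <- data.frame(
    pct_catchments_reporting = round1(report$coverage),
    completeness_births = round1(report$completeness$births),
    completeness_under5_deaths = round1(report$completeness$under5_deaths),
    ratio_nmr = round1(aa[["nmr"]]),
    ratio_imr = round1(aa[["imr"]]),
    ratio_u5mr = round1(aa[["u5mr"]]),
    annual_cost_per_1000 = if (is.null(report$cost)) NA_real_ else round1(report$cost$annual_per_1000)
  )
  q <- report$quality
  death_ratios <- data.frame(
    source = c("chw", "fbh"),
    avg_deaths_neonatal = round1(c(q$chw$avg_deaths_neonatal, q$fbh$avg_deaths_neonatal)),
    avg_deaths_infant = round1(c(q$chw$avg_deaths_infant, q$fbh$avg_deaths_infant)),
    avg_deaths_under5 = round1(c(q$chw$avg_deaths_under5, q$fbh$avg_deaths_under5)),
    pct_neonatal_of_infant = round1(c(q$chw$pct_neonatal_of_infant, q$fbh$pct_neonatal_of_infant)),
    pct_infant_of_under5 = round1(c(q$chw$pct_infant_of_under5, q$fbh$pct_infant_of_under5))
  )
  list(summary = summary, death_ratios = death_ratios)
}
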