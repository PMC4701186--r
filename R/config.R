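#' Simulation configuration
#'
#' Describes the demographic regime of a simulated study site: population
#' structure, fertility, sex ratio at birth, age-specific under-five
#' mortality hazards, stillbirth risk and the simulated calendar span.
#'
#' Defaults describe a high-fertility, high-mortality rural setting of the
#' kind community-based surveillance pilots target: a per-woman-month birth
#' probability of 0.02 (roughly TFR 7 over a 30-year reproductive span) and
#' hazards of 0.040 / 0.0625 / 0.18 for the neonatal, post-neonatal and
#' child segments, which imply NMR 40, IMR 100 and U5MR 262 per 1,000
#' births on a closed cohort.
#'
#' @param n_catchments number of CHW catchment areas.
#' @param households_per_catchment households per catchment.
#' @param women_per_household women of reproductive age per household.
#' @param monthly_birth_prob per-woman-month probability of a pregnancy
#'   outcome (live birth or stillbirth).
#' @param srb_true true sex ratio at birth, male births per 100 female.
#' @param hazard_neonatal probability a live birth dies in days 0--27.
#' @param hazard_postneonatal probability of death in months 1--11 given
#'   neonatal survival.
#' @param hazard_child probability of death in months 12--59 given infant
#'   survival.
#' @param stillbirth_prob probability a pregnancy outcome is a stillbirth.
#' @param sim_start_cmc,sim_end_cmc simulated span in century month codes
#'   (inclusive).
#' @param seed RNG seed recorded with the configuration.
#' @return a list of class `sim_config`.
#' @seealso [simulate_ledger()]
#' @export
sim_config <- function(n_catchments = 20L,
                       households_per_catchment = 100L,
                       women_per_household = 1L,
                       monthly_birth_prob = 0.02,
                       srb_true = 105,
                       hazard_neonatal = 0.040,
                       hazard_postneonatal = 0.0625,
                       hazard_child = 0.18,
                       stillbirth_prob = 0.02,
                       sim_start_cmc = cmc(2010, 1),
                       sim_end_cmc = cmc(2013, 12),
                       seed = 1L) {
  cfg <- list(
    n_catchments = as.integer(n_catchments),
    households_per_catchment = as.integer(households_per_catchment),
    women_per_household = as.integer(women_per_household),
    monthly_birth_prob = monthly_birth_prob,
    srb_true = srb_true,
    hazard_neonatal = hazard_neonatal,
    hazard_postneonatal = hazard_postneonatal,
    hazard_child = hazard_child,
    stillbirth_prob = stillbirth_prob,
    sim_start_cmc = as.integer(sim_start_cmc),
    sim_end_cmc = as.integer(sim_end_cmc),
    seed = as.integer(seed)
  )
  counts <- cfg[c("n_catchments", "households_per_catchment", "women_per_household")]
  if (any(unlist(counts) < 1L)) stop("population counts must be >= 1")
  probs <- cfg[c("monthly_birth_prob", "hazard_neonatal", "hazard_postneonatal",
                 "hazard_child", "stillbirth_prob")]
  .check_probs(probs)
  if (cfg$srb_true <= 0) stop("srb_true must be positive")
  if (cfg$sim_start_cmc >= cfg$sim_end_cmc) stop("sim_start_cmc must precede sim_end_cmc")
  structure(cfg, class = "sim_config")
}

#' CHW capture model
#'
#' Observation model for community health worker reporting: each true event
#' is independently captured with a type-specific probability, stillbirths
#' may be misclassified as neonatal deaths, and whole catchment-month
#' reports may never be submitted (events captured in such months are lost;
#' no adjustment is made for missing reports).
#'
#' @param p_capture_birth probability a live birth is captured.
#' @param p_capture_death_neonatal,p_capture_death_postneonatal,p_capture_death_child
#'   capture probability for deaths in each age class.
#' @param p_monthly_report_missing probability a catchment-month report is
#'   never submitted.
#' @param p_stillbirth_as_neonatal probability a stillbirth is reported as
#'   a neonatal death.
#' @return a list of class `capture_model`.
#' @seealso [apply_chw_observation()]
#' @export
capture_model <- function(p_capture_birth = 1,
                          p_capture_death_neonatal = 1,
                          p_capture_death_postneonatal = 1,
                          p_capture_death_child = 1,
                          p_monthly_report_missing = 0,
                          p_stillbirth_as_neonatal = 0) {
  m <- list(
    p_capture_birth = p_capture_birth,
    p_capture_death_neonatal = p_capture_death_neonatal,
    p_capture_death_postneonatal = p_capture_death_postneonatal,
    p_capture_death_child = p_capture_death_child,
    p_monthly_report_missing = p_monthly_report_missing,
    p_stillbirth_as_neonatal = p_stillbirth_as_neonatal
  )
  .check_probs(m)
  structure(m, class = "capture_model")
}

#' Retrospective survey observation model
#'
#' Observation model for the full birth/pregnancy history validation
#' instrument: household selection (census or Bernoulli household sample),
#' recall omission of dead children growing with years since death, age
#' heaping of deaths at 10--14 months onto exactly 12 months, and normal
#' displacement of reported birth dates. Birth histories record live births
#' only; stillbirths never appear in the output.
#'
#' @param design `"census"` (all households) or `"household_sample"`.
#' @param sample_fraction per-household inclusion probability when
#'   `design = "household_sample"`.
#' @param interview_cmc interview month (CMC); must not precede the end of
#'   the simulated span.
#' @param p_omit_per_year_recall per-year-of-recall omission probability
#'   for dead children; a child dead `y` years before interview is omitted
#'   with probability `1 - (1 - p)^y`.
#' @param p_heap_to_12m probability a death at true age 10--14 months is
#'   reported as exactly 12 months.
#' @param date_displacement_sd standard deviation (months) of the rounded
#'   normal displacement applied to reported birth dates.
#' @return a list of class `survey_model`.
#' @seealso [apply_survey_observation()]
#' @export
survey_model <- function(design = c("census", "household_sample"),
                         sample_fraction = 1,
                         interview_cmc = cmc(2014, 1),
                         p_omit_per_year_recall = 0,
                         p_heap_to_12m = 0,
                         date_displacement_sd = 0) {
  design <- match.arg(design)
  m <- list(
    design = design,
    sample_fraction = sample_fraction,
    interview_cmc = as.integer(interview_cmc),
    p_omit_per_year_recall = p_omit_per_year_recall,
    p_heap_to_12m = p_heap_to_12m,
    date_displacement_sd = date_displacement_sd
  )
  .check_probs(m[c("sample_fraction", "p_omit_per_year_recall", "p_heap_to_12m")])
  if (m$date_displacement_sd < 0) stop("date_displacement_sd must be >= 0")
  structure(m, class = "survey_model")
}

.check_probs <- function(x) {
  bad <- vapply(x, function(p) !is.numeric(p) || is.na(p) || p < 0 || p > 1, logical(1))
  if (any(bad)) {
    stop("probabilities outside [0,1]: ", paste(names(x)[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  n_women <- x$n_catchments * x$households_per_catchment * x$women_per_household
  cat(sprintf("  %d catchments, %d households, %d women; months %d..%d (seed %d)\n",
              x$n_catchments, x$n_catchments * x$households_per_catchment, n_women,
              x$sim_start_cmc, x$sim_end_cmc, x$seed))
  cat(sprintf("  birth prob/woman-month %.4f; SRB %.1f; hazards nn %.4f, pnn %.4f, child %.4f; stillbirth %.4f\n",
              x$monthly_birth_prob, x$srb_true, x$hazard_neonatal,
              x$hazard_postneonatal, x$hazard_child, x$stillbirth_prob))
  cat(sprintf("  implied cohort rates per 1,000 births: NMR %.1f, IMR %.1f, U5MR %.1f\n",
              1000 * x$hazard_neonatal,
              1000 * (1 - (1 - x$hazard_neonatal) * (1 - x$hazard_postneonatal)),
              1000 * implied_u5mr(x)))
  invisible(x)
}

#' Cohort under-five mortality implied by configured hazards
#'
#' Returns the probability of death before age five implied by the three
#' hazard segments, `1 - (1-h_nn)(1-h_pnn)(1-h_child)`. Multiplied by 1,000
#' this is the closed-cohort U5MR the simulator converges to under
#' error-free observation.
#'
#' @param config a [sim_config()].
#' @return probability of death before age 60 months.
#' @export
implied_u5mr <- function(config) {
  1 - (1 - config$hazard_neonatal) * (1 - config$hazard_postneonatal) *
    (1 - config$hazard_child)
}
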