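#' Published multi-country reference tables
#'
#' Headline figures from published field assessments of CHW vital-events
#' reporting in three sub-Saharan sites, bundled as plain CSV inputs for
#' worked examples and cross-checks: site demographics (population,
#' number of CHWs, analysis period), process/completeness/accuracy
#' percentages, programme costs, and the average annualized death counts
#' with their class ratios for both data sources.
#'
#' These are published point values used as *inputs* (e.g. population per
#' CHW, cost per 1,000 population, death-ratio worked examples); nothing
#' in the package estimates them from the underlying field data, which
#' are not public.
#'
#' @return a data.frame (one row per site).
#' @export
reference_sites <- function() {
  utils::read.csv(system.file("extdata", "site_reference.csv",
                              package = "chwvitals"))
}

#' @rdname reference_sites
#' @export
reference_death_ratios <- function() {
  utils::read.csv(system.file("extdata", "death_ratio_reference.csv",
                              package = "chwvitals"))
}
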