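#' Expected births in a window
#'
#' The expected number of births CHWs should have documented: the
#' reference crude birth rate for the window (estimated from the
#' validation survey) multiplied by the resident population of the
#' catchment area, `cbr * population / 1000`.
#'
#' @param cbr_reference crude birth rate per 1,000 population per year.
#' @param population resident population.
#' @return expected births (real-valued).
#' @examples
#' expected_births(45.3, 32128)  # 1455.4
#' @export
expected_births <- function(cbr_reference, population) {
  if (cbr_reference <= 0 || population <= 0) {
    stop("cbr_reference and population must be positive")
  }
  cbr_reference * population / 1000
}

#' Expected under-five deaths in a window
#'
#' Reference under-five mortality rate (per 1,000 births) applied to the
#' expected births, `u5mr * expected_births / 1000`.
#'
#' @param u5mr_reference under-five mortality rate per 1,000 births.
#' @param expected_births expected births from [expected_births()].
#' @return expected under-five deaths (real-valued).
#' @examples
#' expected_under5_deaths(262, 1455.4)  # 381.3
#' @export
expected_under5_deaths <- function(u5mr_reference, expected_births) {
  if (u5mr_reference <= 0 || expected_births <= 0) {
    stop("u5mr_reference and expected_births must be positive")
  }
  u5mr_reference * expected_births / 1000
}

#' Reporting completeness
#'
#' Documented events as a percentage of expected events. Values above
#' 100 are reported as-is (over-documentation is informative, not an
#' error).
#'
#' @param documented events documented by CHWs.
#' @param expected expected events (must be positive).
#' @return a list of class `completeness_result` with `documented`,
#'   `expected`, `percent`.
#' @export
completeness <- function(documented, expected) {
  if (expected <= 0) stop("expected events must be positive")
  if (documented < 0) stop("documented events must be non-negative")
  structure(list(documented = documented, expected = expected,
                 percent = 100 * documented / expected),
            class = "completeness_result")
}

#' @export
print.completeness_result <- function(x, ...) {
  cat(sprintf("<completeness> %s / %.1f expected = %.1f%%\n",
              format(x$documented), x$expected, x$percent))
  invisible(x)
}

#' Accuracy ratios of CHW rates to reference rates
#'
#' Per-window percent ratios `100 * rmm / reference` for CBR, NMR, IMR
#' and U5MR, plus their unweighted mean over windows (the "average annual
#' ratio"). Window lists must be matched one-to-one and reference rates
#' must be positive.
#'
#' @param rmm list of [period_rates()] results from CHW data, one per
#'   window.
#' @param reference matched list of [period_rates()] results from the
#'   validation data.
#' @param labels optional window labels.
#' @return a list of class `accuracy_result` with `per_window`
#'   (data.frame: window, cbr, nmr, imr, u5mr) and `annual_average`
#'   (named numeric).
#' @export
accuracy_ratios <- function(rmm, reference, labels = NULL) {
  if (length(rmm) != length(reference) || !length(rmm)) {
    stop("rmm and reference must be matched non-empty window lists")
  }
  rates <- c("cbr", "nmr", "imr", "u5mr")
  per <- vapply(seq_along(rmm), function(i) {
    a <- rmm[[i]]; b <- reference[[i]]
    stopifnot(inherits(a, "rate_set"), inherits(b, "rate_set"))
    ref <- unlist(b[rates])
    if (any(ref <= 0)) stop("zero reference rate in window ", i)
    100 * unlist(a[rates]) / ref
  }, numeric(4))
  per_window <- data.frame(
    window = if (is.null(labels)) seq_along(rmm) else labels,
    t(per)
  )
  names(per_window)[-1] <- rates
  structure(list(per_window = per_window,
                 annual_average = colMeans(per_window[rates])),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy> average annual ratios (%%): CBR %.1f, NMR %.1f, IMR %.1f, U5MR %.1f over %d windows\n",
              x$annual_average["cbr"], x$annual_average["nmr"],
              x$annual_average["imr"], x$annual_average["u5mr"],
              nrow(x$per_window)))
  invisible(x)
}

#' Sex ratio at birth
#'
#' Male births per 100 female births, with a flag for the 102--107
#' reference band expected in most populations.
#'
#' @param births_male,births_female birth counts by sex;
#'   `births_female` must be positive.
#' @return list with `srb` and `in_reference_band`.
#' @export
sex_ratio_at_birth <- function(births_male, births_female) {
  if (births_female <= 0) stop("births_female must be positive")
  srb <- 100 * births_male / births_female
  list(srb = srb, in_reference_band = srb >= 102 && srb <= 107)
}

#' Death class ratio
#'
#' Percentage one death class makes of an enclosing class (e.g. neonatal
#' of infant deaths, infant of under-five deaths). Internal values are
#' full precision; apply [round1()] only at presentation.
#'
#' @param numerator_deaths,denominator_deaths death counts;
#'   denominator must be positive.
#' @return percentage (full precision).
#' @examples
#' round1(death_ratio(125, 188))  # 66.5
#' @export
death_ratio <- function(numerator_deaths, denominator_deaths) {
  if (denominator_deaths <= 0) stop("denominator_deaths must be positive")
  if (numerator_deaths < 0) stop("numerator_deaths must be non-negative")
  100 * numerator_deaths / denominator_deaths
}

#' Age-heaping index at 12 months
#'
#' Digit-preference diagnostic for ages at death: the count of deaths
#' reported at exactly 12 months relative to the average count over the
#' 10--14 month band, `5 * d(12) / [d(10)+...+d(14)]`. 1 means no
#' heaping; 5 means every band death is reported at 12 months.
#'
#' @param ages_at_death_months integer vector of reported ages at death
#'   in months; at least one age must fall in 10--14.
#' @return heaping index (>= 0).
#' @examples
#' heaping_index_12m(rep(10:14, times = c(2, 2, 10, 2, 2)))  # 2.78
#' @export
heaping_index_12m <- function(ages_at_death_months) {
  a <- ages_at_death_months[!is.na(ages_at_death_months)]
  band <- a[a >= 10L & a <= 14L]
  if (!length(band)) stop("no deaths with age at death in 10-14 months")
  5 * sum(band == 12L) / length(band)
}

#' Monthly reporting coverage
#'
#' Mean over months of the percentage of catchment areas whose monthly
#' report was submitted.
#'
#' @param reports an [apply_chw_observation()] result, or a data.frame
#'   with `catchment_id` and `cmc` (one row per submitted report).
#' @param n_catchments catchments expected to report each month.
#' @param months vector of report months (CMC) the coverage is averaged
#'   over; defaults to the reporting period for `chw_reports` input.
#' @return percent coverage.
#' @export
reporting_coverage <- function(reports, n_catchments = NULL, months = NULL) {
  if (inherits(reports, "chw_reports")) {
    if (is.null(n_catchments)) n_catchments <- reports$n_catchments
    if (is.null(months)) months <- seq.int(reports$period[1], reports$period[2])
    reports <- reports$reports
  }
  if (is.null(n_catchments) || is.null(months)) {
    stop("n_catchments and months are required for plain data.frame input")
  }
  if (n_catchments <= 0 || !length(months)) stop("n_catchments and months must be positive")
  per_month <- vapply(months, function(m) {
    100 * length(unique(reports$catchment_id[reports$cmc == m])) / n_catchments
  }, numeric(1))
  mean(per_month)
}

#' Round half up to one decimal
#'
#' Presentation rounding used for reported tables (round-half-up, unlike
#' base R's round-half-even).
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
round1 <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
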