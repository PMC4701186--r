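#' Event counts for one analysis window
#'
#' Container for the numerators and denominators of the period rates:
#' births by sex and deaths in the standard nested age classes
#' (neonatal < 28 days, infant < 12 completed months, under-five < 60
#' completed months), so `deaths_neonatal <= deaths_infant <=
#' deaths_under5`.
#'
#' @param births_male,births_female live births by sex.
#' @param deaths_neonatal,deaths_infant,deaths_under5 nested death counts.
#' @return a list of class `event_counts` with a `births` total.
#' @export
event_counts <- function(births_male = 0L, births_female = 0L,
                         deaths_neonatal = 0L, deaths_infant = 0L,
                         deaths_under5 = 0L) {
  x <- list(births_male = births_male, births_female = births_female,
            births = births_male + births_female,
            deaths_neonatal = deaths_neonatal,
            deaths_infant = deaths_infant,
            deaths_under5 = deaths_under5)
  if (any(unlist(x) < 0)) stop("counts must be non-negative")
  if (deaths_neonatal > deaths_infant || deaths_infant > deaths_under5) {
    stop("death classes must nest: neonatal <= infant <= under-five")
  }
  structure(x, class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat(sprintf("<event_counts> births %d (M %d / F %d); deaths NN %d <= infant %d <= U5 %d\n",
              x$births, x$births_male, x$births_female,
              x$deaths_neonatal, x$deaths_infant, x$deaths_under5))
  invisible(x)
}

#' Tabulate CHW-reported events in a window
#'
#' Sums submitted monthly report counts whose report month falls inside
#' the window (both endpoints inclusive). Suppressed catchment-months
#' simply contribute nothing: no imputation is performed.
#'
#' @param reports an [apply_chw_observation()] result, or a data.frame in
#'   its `reports` layout.
#' @param window one row of [rolling_windows()], or any list with
#'   `start_cmc` and `end_cmc`.
#' @return an [event_counts()].
#' @export
tabulate_chw <- function(reports, window) {
  rep_df <- if (inherits(reports, "chw_reports")) reports$reports else reports
  w <- .as_window(window)
  sel <- rep_df$cmc >= w$start_cmc & rep_df$cmc <= w$end_cmc
  r <- rep_df[sel, , drop = FALSE]
  nn <- sum(r$deaths_neonatal)
  pnn <- sum(r$deaths_postneonatal)
  ch <- sum(r$deaths_child)
  event_counts(
    births_male = sum(r$births_male),
    births_female = sum(r$births_female),
    deaths_neonatal = nn,
    deaths_infant = nn + pnn,
    deaths_under5 = nn + pnn + ch
  )
}

#' Tabulate birth-history events in a window
#'
#' Births are counted by reported birth month, deaths by reported death
#' month, classed by age at death (neonatal < 28 days, infant < 12
#' months, under-five < 60 months). Records with a missing birth date,
#' or flagged dead with a missing death date, are skipped with a message
#' giving the skipped count. A death is counted in the window of its
#' death date even when the matching birth falls outside the window.
#'
#' @param histories an [apply_survey_observation()] result, or any
#'   data.frame with `birth_cmc`, `dead`, `age_at_death_months`,
#'   `age_at_death_days`, `death_cmc` and `sex`.
#' @param window one row of [rolling_windows()], or any list with
#'   `start_cmc` and `end_cmc`.
#' @return an [event_counts()].
#' @export
tabulate_fbh <- function(histories, window) {
  h <- as.data.frame(histories)
  w <- .as_window(window)
  bad <- is.na(h$birth_cmc) | (h$dead & is.na(h$death_cmc))
  if (any(bad)) {
    message(sum(bad), " record(s) missing dates skipped in tabulation")
    h <- h[!bad, , drop = FALSE]
  }
  in_b <- h$birth_cmc >= w$start_cmc & h$birth_cmc <= w$end_cmc
  d <- h[h$dead & !is.na(h$death_cmc) &
           h$death_cmc >= w$start_cmc & h$death_cmc <= w$end_cmc, , drop = FALSE]
  is_nn <- (!is.na(d$age_at_death_days) & d$age_at_death_days < 28L) |
    (is.na(d$age_at_death_days) & d$age_at_death_months == 0L)
  is_u5 <- d$age_at_death_months < 60L
  is_inf <- d$age_at_death_months < 12L
  event_counts(
    births_male = sum(in_b & h$sex == "male"),
    births_female = sum(in_b & h$sex == "female"),
    deaths_neonatal = sum(is_nn & is_u5),
    deaths_infant = sum(is_inf & is_u5),
    deaths_under5 = sum(is_u5)
  )
}

.as_window <- function(window) {
  if (is.data.frame(window)) {
    if (nrow(window) != 1L) stop("window must be a single row")
    window <- as.list(window)
  }
  if (is.null(window$start_cmc) || is.null(window$end_cmc)) {
    stop("window needs start_cmc and end_cmc")
  }
  window
}

#' Period vital rates from window counts
#'
#' Rates follow the period-ratio definition used for validating
#' community-based reporting: mortality rates are deaths dated to the
#' window per 1,000 births dated to the same window (not synthetic-cohort
#' probabilities), and the crude birth rate is births per 1,000 resident
#' population per year. With zero births in the window the mortality
#' rates are undefined and an error is raised rather than propagating
#' NaN.
#'
#' @param counts an [event_counts()].
#' @param population resident population of the catchment area (held at
#'   its census value for all windows).
#' @return a list of class `rate_set` with `cbr`, `nmr`, `imr`, `u5mr`
#'   (per 1,000) and the input counts attached.
#' @examples
#' period_rates(event_counts(5, 5, 0, 0, 1), population = 10000)
#' @export
period_rates <- function(counts, population) {
  stopifnot(inherits(counts, "event_counts"))
  if (population <= 0) stop("population must be positive")
  if (counts$births <= 0) {
    stop("zero births in window: mortality rates undefined")
  }
  structure(list(
    cbr = 1000 * counts$births / population,
    nmr = 1000 * counts$deaths_neonatal / counts$births,
    imr = 1000 * counts$deaths_infant / counts$births,
    u5mr = 1000 * counts$deaths_under5 / counts$births,
    counts = counts,
    population = population
  ), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> CBR %.1f; NMR %.1f, IMR %.1f, U5MR %.1f per 1,000 (births %d, pop %d)\n",
              x$cbr, x$nmr, x$imr, x$u5mr, x$counts$births, as.integer(x$population)))
  invisible(x)
}
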