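#' Century month code (CMC) conversion
#'
#' The century month code is the DHS convention for dating vital events:
#' the number of months elapsed since January 1900, so that January 1900
#' is CMC 1 and January 2012 is CMC 1345.
#'
#' @param year calendar year (integer vector).
#' @param month calendar month, 1--12 (integer vector, recycled).
#' @return integer vector of century month codes.
#' @examples
#' cmc(2012, 1)        # 1345
#' cmc_to_ym(1345)     # year 2012, month 1
#' @export
cmc <- function(year, month) {
  if (any(is.na(year)) || any(is.na(month))) stop("year/month must be non-missing")
  month <- as.integer(month)
  if (any(month < 1L | month > 12L)) stop("month must be in 1..12")
  as.integer((as.integer(year) - 1900L) * 12L + month)
}

#' @rdname cmc
#' @param x century month code (integer vector).
#' @return `cmc_to_ym()`: a data.frame with columns `year` and `month`.
#' @export
cmc_to_ym <- function(x) {
  x <- as.integer(x)
  data.frame(year = 1900L + (x - 1L) %/% 12L, month = (x - 1L) %% 12L + 1L)
}

#' Rolling 12-month analysis windows
#'
#' Constructs the rolling 12-month periods over which all completeness and
#' accuracy metrics are computed: windows span exactly 12 months (endpoints
#' inclusive), start at the beginning of the analysis period, and successive
#' windows start exactly three months apart. Only windows that fit entirely
#' within the period are returned.
#'
#' @param period_start_cmc,period_end_cmc first and last month (CMC,
#'   inclusive) of the analysis period; the period must span at least
#'   12 months.
#' @param step months between successive window starts (default 3).
#' @return a data.frame of class `analysis_windows` with columns
#'   `start_cmc`, `end_cmc` (= start + 11) and `label` ("YYYY-MM..YYYY-MM").
#' @examples
#' # a 15-month period yields 2 windows; a 48-month period yields 13
#' nrow(rolling_windows(cmc(2012, 1), cmc(2013, 3)))
#' nrow(rolling_windows(cmc(2010, 1), cmc(2013, 12)))
#' @export
rolling_windows <- function(period_start_cmc, period_end_cmc, step = 3L) {
  period_start_cmc <- as.integer(period_start_cmc)
  period_end_cmc <- as.integer(period_end_cmc)
  span <- period_end_cmc - period_start_cmc + 1L
  if (span < 12L) stop("analysis period must span at least 12 months, got ", span)
  starts <- seq.int(period_start_cmc, period_end_cmc - 11L, by = as.integer(step))
  ym1 <- cmc_to_ym(starts)
  ym2 <- cmc_to_ym(starts + 11L)
  out <- data.frame(
    start_cmc = starts,
    end_cmc = starts + 11L,
    label = sprintf("%d-%02d..%d-%02d", ym1$year, ym1$month, ym2$year, ym2$month)
  )
  class(out) <- c("analysis_windows", "data.frame")
  out
}
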