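#' Prospective cost ledger
#'
#' Line-item cost accounting for a surveillance programme: amounts in
#' local currency by category and calendar year, a local consumer price
#' index series, and the exchange rate (local currency per USD) at the
#' base year everything is inflated to.
#'
#' @param items data.frame with columns `category`, `amount`, `year`
#'   (and optionally `currency`).
#' @param cpi_series named numeric vector, year -> CPI.
#' @param fx_rate local currency units per USD at the base year.
#' @param base_year year costs are expressed in (must be present in
#'   `cpi_series`).
#' @return a list of class `cost_ledger`.
#' @export
cost_ledger <- function(items, cpi_series, fx_rate = 1, base_year) {
  items <- as.data.frame(items)
  need <- c("category", "amount", "year")
  if (!all(need %in% names(items))) stop("items need columns category, amount, year")
  if (any(items$amount < 0)) stop("amounts must be non-negative")
  if (any(cpi_series <= 0)) stop("CPI values must be positive")
  if (fx_rate <= 0) stop("fx_rate must be positive")
  base_year <- as.character(base_year)
  if (!base_year %in% names(cpi_series)) stop("base year missing from cpi_series")
  structure(list(items = items, cpi_series = cpi_series,
                 fx_rate = fx_rate, base_year = base_year),
            class = "cost_ledger")
}

#' Inflate and convert a cost ledger to base-year USD
#'
#' Each line item is scaled by `cpi(base_year) / cpi(year)` and converted
#' at the base-year exchange rate; the scaled amounts are summed. An
#' empty ledger totals 0.
#'
#' @param ledger a [cost_ledger()].
#' @return total cost in base-year USD.
#' @examples
#' led <- cost_ledger(data.frame(category = "training", amount = 100, year = 2012),
#'                    cpi_series = c(`2012` = 100, `2014` = 110),
#'                    fx_rate = 2, base_year = 2014)
#' adjust_costs(led)  # 55
#' @export
adjust_costs <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  items <- ledger$items
  if (!nrow(items)) return(0)
  yrs <- as.character(items$year)
  missing_cpi <- setdiff(unique(yrs), names(ledger$cpi_series))
  if (length(missing_cpi)) stop("CPI missing for year(s): ", paste(missing_cpi, collapse = ", "))
  cpi_base <- ledger$cpi_series[[ledger$base_year]]
  sum(items$amount * cpi_base / ledger$cpi_series[yrs]) / ledger$fx_rate
}

#' Programme cost metrics
#'
#' The three headline cost figures for a surveillance method: total cost,
#' average annual cost per 1,000 population
#' (`total * (12 / months) / (population / 1000)`), and cost per vital
#' event reported (`total / n_events`).
#'
#' @param total_usd total programme cost in base-year USD.
#' @param population resident population served.
#' @param months observation months the total covers.
#' @param n_events vital events reported over the period.
#' @return list of class `cost_metrics` with `total`, `annual_per_1000`,
#'   `per_event`.
#' @examples
#' cost_metrics(353782, population = 203741, months = 48, n_events = 16500)
#' @export
cost_metrics <- function(total_usd, population, months, n_events) {
  if (population <= 0 || months <= 0 || n_events <= 0) {
    stop("population, months and n_events must be positive")
  }
  if (total_usd < 0) stop("total_usd must be non-negative")
  structure(list(
    total = total_usd,
    annual_per_1000 = total_usd * (12 / months) / (population / 1000),
    per_event = total_usd / n_events
  ), class = "cost_metrics")
}

#' @export
print.cost_metrics <- function(x, ...) {
  cat(sprintf("<cost_metrics> total $%.0f; $%.1f per 1,000 population per year; $%.1f per event\n",
              x$total, x$annual_per_1000, x$per_event))
  invisible(x)
}
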