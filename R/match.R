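#' Match a sampled event register against a reference register
#'
#' Greedy one-to-one matching of sampled events (e.g. CHW-reported births
#' and deaths drawn for home-visit verification) to a reference register
#' (village health registers, facility family folders). A sampled event
#' can only match a reference event in the same catchment with the same
#' event type whose month differs by at most `date_tolerance_months`.
#' Sampled events are processed in month order; each takes the nearest
#' available reference event, ties broken by the earliest reference
#' month. The report gives the proportion matched and, among matches, the
#' proportion with exact month agreement (date consistency).
#'
#' @param sample data.frame of sampled events with columns
#'   `catchment_id`, `type`, `cmc`.
#' @param reference data.frame with the same columns.
#' @param date_tolerance_months maximum month difference for a match
#'   (default 1).
#' @return a list of class `match_report` with `n_sampled`, `n_matched`,
#'   `pct_matched`, `pct_date_consistent` (the percents are `NA` for an
#'   empty sample or no matches respectively) and `pairs`, the matched
#'   index pairs with their month difference.
#' @export
match_registers <- function(sample, reference, date_tolerance_months = 1L) {
  need <- c("catchment_id", "type", "cmc")
  if (!all(need %in% names(sample)) || !all(need %in% names(reference))) {
    stop("registers need columns catchment_id, type, cmc")
  }
  n_s <- nrow(sample)
  ord <- order(sample$cmc, seq_len(n_s))
  used <- rep(FALSE, nrow(reference))
  pairs <- vector("list", n_s)
  for (i in ord) {
    cand <- which(!used &
                    reference$catchment_id == sample$catchment_id[i] &
                    reference$type == sample$type[i] &
                    abs(reference$cmc - sample$cmc[i]) <= date_tolerance_months)
    if (!length(cand)) next
    dd <- abs(reference$cmc[cand] - sample$cmc[i])
    best <- cand[dd == min(dd)]
    j <- best[which.min(reference$cmc[best])]  # tie -> earliest reference
    used[j] <- TRUE
    pairs[[i]] <- data.frame(sample_row = i, reference_row = j,
                             month_diff = abs(reference$cmc[j] - sample$cmc[i]))
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  n_m <- if (is.null(pairs)) 0L else nrow(pairs)
  structure(list(
    n_sampled = n_s,
    n_matched = n_m,
    pct_matched = if (n_s > 0) 100 * n_m / n_s else NA_real_,
    pct_date_consistent = if (n_m > 0) 100 * mean(pairs$month_diff == 0) else NA_real_,
    pairs = pairs
  ), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d/%d matched (%.1f%%); %.1f%% of matches date-consistent\n",
              x$n_matched, x$n_sampled, x$pct_matched, x$pct_date_consistent))
  invisible(x)
}
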