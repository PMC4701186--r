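#' Simulate a ground-truth vital-events ledger
#'
#' Generates the event ledger the observation models act on. Every woman
#' contributes an independent Bernoulli draw per calendar month of the
#' simulated span; each pregnancy outcome is a stillbirth with
#' `stillbirth_prob`, otherwise a live birth whose sex is male with odds
#' `srb_true:100`. Survival is drawn sequentially through the neonatal
#' (days 0--27), post-neonatal (months 1--11) and child (months 12--59)
#' hazard segments; ages at death are uniform within the dying segment.
#' Time is monthly (CMC); neonatal deaths additionally carry an age in
#' days, uniform on 0--27, and are dated to the birth month.
#'
#' Deaths occurring after `sim_end_cmc` are retained in the ledger with
#' their true dates: downstream observation models decide what is visible
#' (a CHW reporting period truncates by event date; a retrospective survey
#' records as alive any child whose death postdates the interview).
#'
#' @param config a [sim_config()].
#' @return a `data.table` of class `event_ledger`, one row per pregnancy
#'   outcome, with columns `child_id`, `mother_id`, `household_id`,
#'   `catchment_id`, `birth_cmc`, `sex` ("male"/"female"), `stillbirth`,
#'   `died`, `age_at_death_days` (neonatal deaths only),
#'   `age_at_death_months`, `death_cmc`. Attributes carry the config.
#' @examples
#' led <- simulate_ledger(sim_config(n_catchments = 2,
#'                                   households_per_catchment = 10))
#' table(led$stillbirth, led$died)
#' @export
simulate_ledger <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_women <- config$n_catchments * config$households_per_catchment *
    config$women_per_household
  if (n_women < 1L) stop("zero population configured")
  months <- seq.int(config$sim_start_cmc, config$sim_end_cmc)

  set.seed(config$seed)

  # woman roster: ids encode catchment/household membership
  hh_per_catch <- config$households_per_catchment
  wom_per_hh <- config$women_per_household
  woman_id <- seq_len(n_women)
  household_id <- (woman_id - 1L) %/% wom_per_hh + 1L
  catchment_id <- (household_id - 1L) %/% hh_per_catch + 1L

  n_draws <- n_women * length(months)
  hit <- stats::runif(n_draws) < config$monthly_birth_prob
  if (!any(hit)) {
    return(.empty_ledger(config))
  }
  idx <- which(hit)
  w <- (idx - 1L) %% n_women + 1L                # woman index varies fastest
  m <- months[(idx - 1L) %/% n_women + 1L]

  n <- length(idx)
  stillbirth <- stats::runif(n) < config$stillbirth_prob
  p_male <- config$srb_true / (config$srb_true + 100)
  sex <- ifelse(stats::runif(n) < p_male, "male", "female")

  # sequential survival draws; only live births face mortality
  u_nn <- stats::runif(n)
  u_pnn <- stats::runif(n)
  u_child <- stats::runif(n)
  die_nn <- !stillbirth & u_nn < config$hazard_neonatal
  die_pnn <- !stillbirth & !die_nn & u_pnn < config$hazard_postneonatal
  die_child <- !stillbirth & !die_nn & !die_pnn & u_child < config$hazard_child

  age_days <- rep(NA_integer_, n)
  age_months <- rep(NA_integer_, n)
  age_days[die_nn] <- sample(0:27, sum(die_nn), replace = TRUE)
  age_months[die_nn] <- 0L
  age_months[die_pnn] <- sample(1:11, sum(die_pnn), replace = TRUE)
  age_months[die_child] <- sample(12:59, sum(die_child), replace = TRUE)

  died <- die_nn | die_pnn | die_child
  death_cmc <- rep(NA_integer_, n)
  death_cmc[died] <- m[died] + age_months[died]

  led <- data.table::data.table(
    child_id = seq_len(n),
    mother_id = w,
    household_id = household_id[w],
    catchment_id = catchment_id[w],
    birth_cmc = as.integer(m),
    sex = sex,
    stillbirth = stillbirth,
    died = died,
    age_at_death_days = age_days,
    age_at_death_months = age_months,
    death_cmc = death_cmc
  )
  data.table::setkeyv(led, c("catchment_id", "birth_cmc", "child_id"))
  data.table::setattr(led, "config", config)
  data.table::setattr(led, "class", c("event_ledger", class(led)))
  led[]
}

.empty_ledger <- function(config) {
  led <- data.table::data.table(
    child_id = integer(), mother_id = integer(), household_id = integer(),
    catchment_id = integer(), birth_cmc = integer(), sex = character(),
    stillbirth = logical(), died = logical(), age_at_death_days = integer(),
    age_at_death_months = integer(), death_cmc = integer()
  )
  data.table::setattr(led, "config", config)
  data.table::setattr(led, "class", c("event_ledger", class(led)))
  led[]
}

#' @export
print.event_ledger <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<event_ledger> %d pregnancy outcomes (%d stillbirths, %d live births, %d under-five deaths)\n",
              nrow(x), sum(x$stillbirth), sum(!x$stillbirth), sum(x$died)))
  if (!is.null(cfg)) {
    cat(sprintf("  span CMC %d..%d, %d catchments, seed %d\n",
                cfg$sim_start_cmc, cfg$sim_end_cmc, cfg$n_catchments, cfg$seed))
  }
  NextMethod()
}
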