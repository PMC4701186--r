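#' Derive a retrospective birth-history dataset from a ground-truth ledger
#'
#' Emulates the full birth/pregnancy history validation instrument.
#' Households are selected per design (census, or independent Bernoulli
#' household sampling). Birth histories record live births only:
#' stillbirths are excluded. A child whose death postdates the interview
#' is recorded as alive. Each dead child is omitted with probability
#' `1 - (1 - p_omit_per_year_recall)^(years since death)`; deaths at true
#' ages 10--14 months are relabelled exactly 12 months with
#' `p_heap_to_12m`; reported birth dates are displaced by a rounded
#' normal jitter (capped so no birth postdates the interview). Reported
#' death dates are reconstructed as reported birth date plus reported age
#' at death, mirroring how survey birth recodes derive them.
#'
#' All random draws are generated up-front in fixed ledger order
#' (selection, omission, heaping, jitter) so runs with equal seeds but
#' different error probabilities are coupled: e.g. raising
#' `p_omit_per_year_recall` can only grow the omitted set.
#'
#' @param ledger an [simulate_ledger()] result.
#' @param model a [survey_model()]; `interview_cmc` must not precede the
#'   simulated span's end.
#' @param seed RNG seed for the observation draws.
#' @return a `data.table` of class `birth_history`, one row per reported
#'   child: `mother_id`, `child_id`, `catchment_id`, `household_id`,
#'   `birth_cmc`, `sex`, `dead`, `age_at_death_days`,
#'   `age_at_death_months`, `death_cmc`, `interview_cmc`. Attributes
#'   record the design and the number of selected households.
#' @export
apply_survey_observation <- function(ledger, model, seed = 1L) {
  stopifnot(inherits(ledger, "event_ledger"), inherits(model, "survey_model"))
  cfg <- attr(ledger, "config")
  if (!is.null(cfg) && model$interview_cmc < cfg$sim_end_cmc) {
    stop("interview_cmc precedes the end of the simulated span")
  }
  if (nrow(ledger) && model$interview_cmc < max(ledger$birth_cmc)) {
    stop("interview_cmc precedes simulated events")
  }
  led <- data.table::as.data.table(ledger)
  data.table::setorderv(led, "child_id")  # fixed draw order

  set.seed(as.integer(seed))
  all_hh <- if (!is.null(cfg)) {
    seq_len(cfg$n_catchments * cfg$households_per_catchment)
  } else {
    sort(unique(led$household_id))
  }
  u_hh <- stats::runif(length(all_hh))
  u_omit <- stats::runif(nrow(led))
  u_heap <- stats::runif(nrow(led))
  jitter <- as.integer(round(stats::rnorm(nrow(led), 0, max(model$date_displacement_sd, 1e-12))))
  if (model$date_displacement_sd == 0) jitter[] <- 0L

  selected_hh <- if (model$design == "census") all_hh else all_hh[u_hh < model$sample_fraction]
  if (!length(selected_hh)) stop("household sample came back empty")

  keep <- !led$stillbirth & led$household_id %in% selected_hh
  # survival status as of interview
  dead_obs <- led$died & !is.na(led$death_cmc) & led$death_cmc <= model$interview_cmc

  years_recall <- ifelse(dead_obs, (model$interview_cmc - led$death_cmc) / 12, 0)
  p_omit <- 1 - (1 - model$p_omit_per_year_recall)^years_recall
  omitted <- dead_obs & u_omit < p_omit
  keep <- keep & !omitted

  age_rep <- led$age_at_death_months
  heapable <- dead_obs & !is.na(age_rep) & age_rep >= 10L & age_rep <= 14L
  age_rep[heapable & u_heap < model$p_heap_to_12m] <- 12L

  birth_rep <- pmin(led$birth_cmc + jitter, model$interview_cmc)

  out <- data.table::data.table(
    mother_id = led$mother_id[keep],
    child_id = led$child_id[keep],
    catchment_id = led$catchment_id[keep],
    household_id = led$household_id[keep],
    birth_cmc = birth_rep[keep],
    sex = led$sex[keep],
    dead = dead_obs[keep],
    age_at_death_days = ifelse(dead_obs[keep], led$age_at_death_days[keep], NA_integer_),
    age_at_death_months = ifelse(dead_obs[keep], age_rep[keep], NA_integer_),
    death_cmc = ifelse(dead_obs[keep], birth_rep[keep] + age_rep[keep], NA_integer_),
    interview_cmc = model$interview_cmc
  )
  data.table::setattr(out, "design", model$design)
  data.table::setattr(out, "n_households_selected", length(selected_hh))
  data.table::setattr(out, "n_omitted_deaths", sum(omitted & !led$stillbirth &
                                                     led$household_id %in% selected_hh))
  data.table::setattr(out, "seed", as.integer(seed))
  data.table::setattr(out, "class", c("birth_history", class(out)))
  out[]
}

#' @export
print.birth_history <- function(x, ...) {
  cat(sprintf("<birth_history> %d children from %d households (%s design), %d reported deaths, interview CMC %d\n",
              nrow(x), attr(x, "n_households_selected"), attr(x, "design"),
              sum(x$dead), if (nrow(x)) x$interview_cmc[1] else NA_integer_))
  NextMethod()
}
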