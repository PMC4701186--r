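#' Derive CHW monthly reports from a ground-truth ledger
#'
#' Applies the CHW capture model to the simulated ledger. Each live birth
#' and each under-five death inside the reporting period is independently
#' captured with its type-specific probability; each stillbirth is added
#' as a spurious neonatal death (dated to its delivery month) with
#' `p_stillbirth_as_neonatal`. Each catchment-month report is then
#' suppressed wholesale with `p_monthly_report_missing`; events captured
#' in a suppressed month are lost and no adjustment is made.
#'
#' Random draws are generated up-front in a fixed ledger order (birth
#' capture, death capture, stillbirth misclassification, report
#' suppression), so runs with the same seed but different probabilities
#' are coupled through common random numbers.
#'
#' @param ledger an [simulate_ledger()] result.
#' @param model a [capture_model()].
#' @param seed RNG seed for the observation draws.
#' @param period_start_cmc,period_end_cmc reporting period (defaults to
#'   the simulated span). Events dated outside the period are not
#'   reportable.
#' @return an object of class `chw_reports`: a list with
#'   \describe{
#'     \item{reports}{submitted monthly reports, one row per
#'       catchment-month that was not suppressed: `catchment_id`, `cmc`,
#'       `births_male`, `births_female`, `deaths_neonatal`,
#'       `deaths_postneonatal`, `deaths_child`.}
#'     \item{events}{the individual captured events behind those counts
#'       (`catchment_id`, `cmc`, `type`, `age_class`, `sex`, `child_id`),
#'       usable as a register for record matching.}
#'     \item{missing_months}{suppressed catchment-months.}
#'     \item{period}{`c(start, end)` of the reporting period.}
#'     \item{n_catchments}{number of catchments expected to report.}
#'   }
#' @export
apply_chw_observation <- function(ledger, model, seed = 1L,
                                  period_start_cmc = NULL,
                                  period_end_cmc = NULL) {
  stopifnot(inherits(ledger, "event_ledger"), inherits(model, "capture_model"))
  cfg <- attr(ledger, "config")
  if (is.null(period_start_cmc)) period_start_cmc <- cfg$sim_start_cmc
  if (is.null(period_end_cmc)) period_end_cmc <- cfg$sim_end_cmc
  period_start_cmc <- as.integer(period_start_cmc)
  period_end_cmc <- as.integer(period_end_cmc)
  if (period_start_cmc > period_end_cmc) stop("empty reporting period")
  n_catchments <- if (!is.null(cfg)) cfg$n_catchments else max(ledger$catchment_id, 1L)

  led <- data.table::as.data.table(ledger)
  data.table::setorderv(led, "child_id")  # fixed draw order

  set.seed(as.integer(seed))
  u_birth <- stats::runif(nrow(led))
  u_death <- stats::runif(nrow(led))
  u_sb <- stats::runif(nrow(led))

  birth_cmc <- death_cmc <- catchment_id <- stillbirth <- died <- NULL
  age_at_death_months <- NULL  # NSE locals for R CMD check

  live <- led[stillbirth == FALSE]
  u_b <- u_birth[!led$stillbirth]
  in_birth <- live$birth_cmc >= period_start_cmc & live$birth_cmc <= period_end_cmc
  cap_birth <- in_birth & u_b < model$p_capture_birth

  dead <- led$died
  age_class <- rep(NA_character_, nrow(led))
  age_class[led$died & led$age_at_death_months == 0L] <- "neonatal"
  age_class[led$died & led$age_at_death_months >= 1L &
              led$age_at_death_months <= 11L] <- "postneonatal"
  age_class[led$died & led$age_at_death_months >= 12L] <- "child"
  p_death <- rep(NA_real_, nrow(led))
  p_death[!is.na(age_class) & age_class == "neonatal"] <- model$p_capture_death_neonatal
  p_death[!is.na(age_class) & age_class == "postneonatal"] <- model$p_capture_death_postneonatal
  p_death[!is.na(age_class) & age_class == "child"] <- model$p_capture_death_child
  in_death <- dead & led$death_cmc >= period_start_cmc & led$death_cmc <= period_end_cmc
  cap_death <- in_death & !is.na(p_death) & u_death < p_death

  # stillbirths misreported as neonatal deaths in the delivery month
  sb_in <- led$stillbirth & led$birth_cmc >= period_start_cmc &
    led$birth_cmc <= period_end_cmc
  sb_as_nn <- sb_in & u_sb < model$p_stillbirth_as_neonatal

  ev_birth <- data.table::data.table(
    catchment_id = live$catchment_id[cap_birth],
    cmc = live$birth_cmc[cap_birth],
    type = "birth",
    age_class = NA_character_,
    sex = live$sex[cap_birth],
    child_id = live$child_id[cap_birth]
  )
  ev_death <- data.table::data.table(
    catchment_id = led$catchment_id[cap_death],
    cmc = led$death_cmc[cap_death],
    type = "death",
    age_class = age_class[cap_death],
    sex = led$sex[cap_death],
    child_id = led$child_id[cap_death]
  )
  ev_sb <- data.table::data.table(
    catchment_id = led$catchment_id[sb_as_nn],
    cmc = led$birth_cmc[sb_as_nn],
    type = "death",
    age_class = "neonatal",
    sex = led$sex[sb_as_nn],
    child_id = led$child_id[sb_as_nn]
  )
  events <- data.table::rbindlist(list(ev_birth, ev_death, ev_sb))

  # wholesale suppression of catchment-month reports
  grid <- data.table::CJ(catchment_id = seq_len(n_catchments),
                         cmc = seq.int(period_start_cmc, period_end_cmc))
  grid$missing <- stats::runif(nrow(grid)) < model$p_monthly_report_missing
  missing_months <- grid[grid$missing, c("catchment_id", "cmc")]
  if (nrow(missing_months)) {
    events <- events[!missing_months, on = c("catchment_id", "cmc")]
  }

  submitted <- grid[!grid$missing, c("catchment_id", "cmc")]
  type <- sex <- NULL
  counts <- events[, list(
    births_male = sum(type == "birth" & sex == "male"),
    births_female = sum(type == "birth" & sex == "female"),
    deaths_neonatal = sum(type == "death" & age_class == "neonatal"),
    deaths_postneonatal = sum(type == "death" & age_class == "postneonatal"),
    deaths_child = sum(type == "death" & age_class == "child")
  ), by = c("catchment_id", "cmc")]
  reports <- merge(submitted, counts, by = c("catchment_id", "cmc"),
                   all.x = TRUE, sort = TRUE)
  for (col in setdiff(names(reports), c("catchment_id", "cmc"))) {
    data.table::set(reports, which(is.na(reports[[col]])), col, 0L)
  }

  structure(list(reports = reports[], events = events[],
                 missing_months = missing_months[],
                 period = c(period_start_cmc, period_end_cmc),
                 n_catchments = n_catchments,
                 model = model, seed = as.integer(seed)),
            class = "chw_reports")
}

#' @export
print.chw_reports <- function(x, ...) {
  cat(sprintf("<chw_reports> %d catchment-month reports (%d suppressed), %d captured events, period CMC %d..%d\n",
              nrow(x$reports), nrow(x$missing_months), nrow(x$events),
              x$period[1], x$period[2]))
  invisible(x)
}
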