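test_that("simulate_ledger honours degenerate configurations", {
  led0 <- simulate_ledger(tiny_config(monthly_birth_prob = 0))
  expect_identical(nrow(led0), 0L)

  led1 <- simulate_ledger(tiny_config(hazard_neonatal = 1, stillbirth_prob = 0))
  expect_true(all(led1$died))
  expect_true(all(led1$age_at_death_days < 28))
  expect_true(all(led1$age_at_death_months == 0))
  expect_true(all(led1$death_cmc == led1$birth_cmc))
})

test_that("simulate_ledger rejects invalid configurations", {
  expect_error(sim_config(hazard_neonatal = 1.2), "\\[0,1\\]")
  expect_error(sim_config(n_catchments = 0), ">= 1")
  expect_error(sim_config(sim_start_cmc = 100, sim_end_cmc = 99), "precede")
})

test_that("total births fall within 3 binomial SD of expectation", {
  # 100 women x 100 months at p = 0.02 -> 10,000 woman-month draws
  cfg <- sim_config(n_catchments = 1L, households_per_catchment = 100L,
                    monthly_birth_prob = 0.02,
                    sim_start_cmc = 1200L, sim_end_cmc = 1299L, seed = 99L)
  led <- simulate_ledger(cfg)
  expect_lt(abs(nrow(led) - 200), 3 * sqrt(10000 * 0.02 * 0.98))
})

test_that("ledger invariants hold and seeds are reproducible", {
  led <- simulate_ledger(tiny_config(seed = 21L, stillbirth_prob = 0.05))
  d <- led[led$died, ]
  expect_true(all(d$death_cmc >= d$birth_cmc))
  expect_true(all(d$age_at_death_months < 60))
  nn <- d[!is.na(d$age_at_death_days), ]
  expect_true(all(nn$age_at_death_days < 28 & nn$age_at_death_months == 0))
  sb <- led[led$stillbirth, ]
  expect_true(all(!sb$died) && all(is.na(sb$death_cmc)))
  expect_true(all(led$sex %in% c("male", "female")))
  # bit-for-bit reproducibility under a fixed seed
  led2 <- simulate_ledger(tiny_config(seed = 21L, stillbirth_prob = 0.05))
  expect_identical(as.data.frame(led), as.data.frame(led2))
})

test_that("sex assignment and cohort mortality track configured parameters", {
  cfg <- sim_config(n_catchments = 10L, households_per_catchment = 60L,
                    sim_start_cmc = 1200L, sim_end_cmc = 1289L, seed = 5L,
                    stillbirth_prob = 0)
  led <- simulate_ledger(cfg)
  n <- nrow(led)
  p_male <- 105 / 205
  expect_lt(abs(sum(led$sex == "male") - n * p_male), 3 * sqrt(n * p_male * (1 - p_male)))
  q5 <- implied_u5mr(cfg)
  expect_lt(abs(mean(led$died) - q5), 3 * sqrt(q5 * (1 - q5) / n))
})

test_that("CHW observation is exact under perfect capture and zero under no capture", {
  led <- simulate_ledger(tiny_config(seed = 31L))
  chw <- apply_chw_observation(led, capture_model(), seed = 1)
  cfg <- attr(led, "config")
  w <- list(start_cmc = cfg$sim_start_cmc, end_cmc = cfg$sim_end_cmc)
  cc <- tabulate_chw(chw, w)
  expect_equal(cc$births, sum(!led$stillbirth))
  in_period <- led$died & led$death_cmc <= cfg$sim_end_cmc
  expect_equal(cc$deaths_under5, sum(in_period))
  # every submitted catchment-month present, none suppressed
  expect_identical(nrow(chw$missing_months), 0L)
  expect_identical(nrow(chw$reports),
                   cfg$n_catchments * (cfg$sim_end_cmc - cfg$sim_start_cmc + 1L))

  none <- apply_chw_observation(led, capture_model(p_capture_birth = 0), seed = 1)
  expect_equal(sum(none$reports$births_male + none$reports$births_female), 0)
})

test_that("captured births fall within 3 binomial SD at p = 0.5", {
  cfg <- sim_config(n_catchments = 5L, households_per_catchment = 50L,
                    monthly_birth_prob = 0.04, stillbirth_prob = 0,
                    sim_start_cmc = 1200L, sim_end_cmc = 1299L, seed = 77L)
  led <- simulate_ledger(cfg)
  n_true <- nrow(led)
  expect_gt(n_true, 800)  # ~1000 true births
  chw <- apply_chw_observation(led, capture_model(p_capture_birth = 0.5), seed = 3)
  got <- sum(chw$reports$births_male + chw$reports$births_female)
  expect_lt(abs(got - 0.5 * n_true), 3 * sqrt(n_true * 0.25))
})

test_that("reported events are a subset of truth plus misclassified stillbirths, no duplicates", {
  led <- simulate_ledger(tiny_config(seed = 41L, stillbirth_prob = 0.05))
  m <- capture_model(p_capture_birth = 0.8, p_capture_death_neonatal = 0.7,
                     p_capture_death_postneonatal = 0.7, p_capture_death_child = 0.7,
                     p_monthly_report_missing = 0.1, p_stillbirth_as_neonatal = 0.5)
  chw <- apply_chw_observation(led, m, seed = 8)
  ev <- chw$events
  expect_false(any(duplicated(ev[, c("child_id", "type")])))
  b <- ev[ev$type == "birth", ]
  expect_true(all(b$child_id %in% led$child_id[!led$stillbirth]))
  d <- ev[ev$type == "death", ]
  truth_dead_or_sb <- led$child_id[led$died | led$stillbirth]
  expect_true(all(d$child_id %in% truth_dead_or_sb))
  # events never fall in suppressed catchment-months
  key_ev <- paste(ev$catchment_id, ev$cmc)
  key_miss <- paste(chw$missing_months$catchment_id, chw$missing_months$cmc)
  expect_false(any(key_ev %in% key_miss))
})

test_that("stillbirth misclassification adds spurious neonatal deaths at the configured rate", {
  cfg <- tiny_config(seed = 51L, stillbirth_prob = 0.5, monthly_birth_prob = 0.05)
  led <- simulate_ledger(cfg)
  n_sb <- sum(led$stillbirth)
  expect_gt(n_sb, 100)
  chw <- apply_chw_observation(
    led, capture_model(p_capture_death_neonatal = 0, p_capture_death_postneonatal = 0,
                       p_capture_death_child = 0, p_capture_birth = 0,
                       p_stillbirth_as_neonatal = 0.4), seed = 9)
  got <- sum(chw$reports$deaths_neonatal)
  expect_lt(abs(got - 0.4 * n_sb), 3 * sqrt(n_sb * 0.4 * 0.6))
})

test_that("a faithful census reproduces the ledger's live births and deaths", {
  led <- simulate_ledger(tiny_config(seed = 61L, stillbirth_prob = 0.05))
  cfg <- attr(led, "config")
  sv <- survey_model("census", interview_cmc = cfg$sim_end_cmc + 1L)
  fbh <- apply_survey_observation(led, sv, seed = 2)
  live <- led[!led$stillbirth, ]
  expect_identical(sort(fbh$child_id), sort(live$child_id))
  m <- merge(as.data.frame(fbh), as.data.frame(live), by = "child_id")
  expect_true(all(m$birth_cmc.x == m$birth_cmc.y))
  died_by_interview <- m$died & !is.na(m$death_cmc.y) &
    m$death_cmc.y <= sv$interview_cmc
  expect_identical(m$dead, died_by_interview)
  expect_true(all(m$death_cmc.x[m$dead] == m$death_cmc.y[m$dead]))
})

test_that("survey sampling, heaping and omission behave as specified", {
  # sample_fraction = 0.25 over 4,000 households -> 3 binomial SD of 1,000
  cfg <- sim_config(n_catchments = 40L, households_per_catchment = 100L,
                    monthly_birth_prob = 0.01,
                    sim_start_cmc = 1340L, sim_end_cmc = 1360L, seed = 71L)
  led <- simulate_ledger(cfg)
  sv <- survey_model("household_sample", sample_fraction = 0.25,
                     interview_cmc = 1361L)
  fbh <- apply_survey_observation(led, sv, seed = 4)
  n_sel <- attr(fbh, "n_households_selected")
  expect_lt(abs(n_sel - 1000), 3 * sqrt(4000 * 0.25 * 0.75))

  # p_heap_to_12m = 1 with deaths only at 10-14 months -> all reported at 12
  led2 <- simulate_ledger(tiny_config(seed = 72L, hazard_neonatal = 0,
                                      hazard_postneonatal = 0, hazard_child = 0.9))
  led2$age_at_death_months[led2$died] <- sample(10:14, sum(led2$died), TRUE)
  led2$death_cmc[led2$died] <- led2$birth_cmc[led2$died] +
    led2$age_at_death_months[led2$died]
  sv2 <- survey_model("census", interview_cmc = cmc(2014, 1) + 60L,
                      p_heap_to_12m = 1)
  fbh2 <- apply_survey_observation(led2, sv2, seed = 5)
  expect_true(all(fbh2$age_at_death_months[fbh2$dead] == 12L))

  # recall omission only removes dead children
  sv3 <- survey_model("census", interview_cmc = cmc(2014, 1) + 60L,
                      p_omit_per_year_recall = 0.5)
  fbh3 <- apply_survey_observation(led2, sv3, seed = 5)
  expect_identical(sum(!fbh3$dead), sum(!fbh2$dead))
  expect_lt(sum(fbh3$dead), sum(fbh2$dead))
  expect_error(apply_survey_observation(led2,
    survey_model("census", interview_cmc = cmc(2013, 1))), "interview")
})
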