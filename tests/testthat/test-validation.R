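test_that("expected events follow the rate-times-population construction", {
  expect_equal(expected_births(50, 10000), 500)
  expect_equal(expected_births(45.3, 32128), 1455.3984)
  expect_error(expected_births(0, 1000), "positive")
  expect_equal(expected_under5_deaths(200, 500), 100)
  expect_equal(expected_under5_deaths(262, 1455.4), 381.3148)
  expect_error(expected_under5_deaths(0, 100), "positive")
})

test_that("completeness is a plain percent of expected, not clipped at 100", {
  expect_equal(completeness(500, 500)$percent, 100)
  expect_equal(completeness(0, 500)$percent, 0)
  expect_equal(completeness(600, 500)$percent, 120)
  expect_error(completeness(10, 0), "positive")
  # one-line brute-force agreement on random inputs
  set.seed(3)
  for (i in 1:20) {
    d <- rpois(1, 200); e <- runif(1, 50, 400)
    expect_equal(completeness(d, e)$percent, 100 * d / e)
  }
})

test_that("accuracy ratios are per-window percents averaged without weights", {
  mk <- function(b, nn, inf, u5, pop = 5000) {
    period_rates(event_counts(b %/% 2, b - b %/% 2, nn, inf, u5), pop)
  }
  same <- list(mk(100, 2, 5, 10), mk(120, 3, 6, 12))
  acc <- accuracy_ratios(same, same)
  expect_equal(unname(acc$annual_average), rep(100, 4))
  half <- list(mk(100, 1, 2, 5), mk(120, 1, 3, 6))
  full <- list(mk(100, 2, 4, 10), mk(120, 2, 6, 12))
  acc2 <- accuracy_ratios(half, full)
  expect_equal(unname(acc2$annual_average[["u5mr"]]), 50)
  # brute-force agreement: mean of elementwise percent ratios
  set.seed(4)
  rnest <- function(b) {
    nn <- rpois(1, 3) + 1; inf <- nn + rpois(1, 3); u5 <- inf + rpois(1, 3)
    mk(b, nn, inf, u5)
  }
  a <- lapply(1:4, function(i) rnest(100 + i))
  b <- lapply(1:4, function(i) rnest(110 + i))
  acc3 <- accuracy_ratios(a, b)
  oracle <- mean(sapply(1:4, function(i) 100 * a[[i]]$u5mr / b[[i]]$u5mr))
  expect_equal(unname(acc3$annual_average[["u5mr"]]), oracle)
  expect_true(acc3$annual_average[["u5mr"]] >= min(acc3$per_window$u5mr) &&
                acc3$annual_average[["u5mr"]] <= max(acc3$per_window$u5mr))
  expect_error(accuracy_ratios(a, b[1:2]), "matched")
})

test_that("sex ratio at birth and its reference band", {
  r <- sex_ratio_at_birth(105, 100)
  expect_equal(r$srb, 105)
  expect_true(r$in_reference_band)
  r2 <- sex_ratio_at_birth(100, 100)
  expect_false(r2$in_reference_band)
  expect_error(sex_ratio_at_birth(10, 0), "positive")
  # large simulation recovers the configured ratio within 3 binomial SE
  cfg <- sim_config(n_catchments = 20L, households_per_catchment = 50L,
                    monthly_birth_prob = 0.04, stillbirth_prob = 0,
                    sim_start_cmc = 1300L, sim_end_cmc = 1399L, seed = 15L)
  led <- simulate_ledger(cfg)
  n <- nrow(led)
  p <- 105 / 205
  m <- sum(led$sex == "male")
  se_p <- sqrt(p * (1 - p) / n)
  phat <- m / n
  expect_lt(abs(phat - p), 3 * se_p)
})

test_that("death_ratio reproduces published worked examples at printed precision", {
  ref <- reference_death_ratios()
  eth <- ref[ref$site == "ethiopia", ]
  mali <- ref[ref$site == "mali", ]
  expect_equal(round1(death_ratio(eth$deaths_neonatal, eth$deaths_infant)), 66.5)
  expect_equal(round1(death_ratio(mali$deaths_neonatal, mali$deaths_infant)), 50.0)
  expect_equal(round1(death_ratio(eth$deaths_infant, eth$deaths_under5)), 77.0)
  expect_equal(round1(death_ratio(mali$deaths_infant, mali$deaths_under5)), 59.2)
  expect_error(death_ratio(1, 0), "positive")
  set.seed(5)
  for (i in 1:10) {
    a <- rpois(1, 50); b <- a + rpois(1, 50) + 1
    expect_equal(death_ratio(a, b), 100 * a / b)
  }
})

test_that("heaping index spans no-heaping to maximal heaping", {
  expect_equal(heaping_index_12m(rep(10:14, each = 4)), 1)
  expect_equal(round(heaping_index_12m(rep(10:14, times = c(2, 2, 10, 2, 2))), 2), 2.78)
  expect_equal(heaping_index_12m(rep(12L, 9)), 5)
  expect_error(heaping_index_12m(c(3, 50)), "10-14")
  # ages outside the band are ignored
  expect_equal(heaping_index_12m(c(rep(10:14, each = 2), 0, 0, 36)), 1)
})

test_that("reporting coverage matches the suppression probability", {
  led <- simulate_ledger(tiny_config(seed = 81L))
  full <- apply_chw_observation(led, capture_model(), seed = 1)
  expect_equal(reporting_coverage(full), 100)
  none <- apply_chw_observation(
    led, capture_model(p_monthly_report_missing = 1), seed = 1)
  expect_equal(reporting_coverage(none), 0)
  some <- apply_chw_observation(
    led, capture_model(p_monthly_report_missing = 0.05), seed = 6)
  n_cm <- attr(led, "config")$n_catchments * 36L
  se <- 100 * sqrt(0.05 * 0.95 / n_cm)
  expect_lt(abs(reporting_coverage(some) - 95), 3 * se)
})

test_that("register matching is greedy nearest-date with one-to-one pairing", {
  set.seed(6)
  ref <- data.frame(catchment_id = sample(1:3, 50, TRUE),
                    type = sample(c("birth", "death"), 50, TRUE),
                    cmc = sample(1340:1360, 50, TRUE))
  self <- match_registers(ref, ref)
  expect_equal(self$pct_matched, 100)
  expect_equal(self$pct_date_consistent, 100)

  other <- ref; other$catchment_id <- other$catchment_id + 10L
  expect_equal(match_registers(other, ref)$pct_matched, 0)

  # deterministic 10% deletion: exactly 90% of a 50-event sample matches
  thin <- ref[-seq(1, 50, by = 10), ]
  del <- match_registers(ref, thin, date_tolerance_months = 0)
  expect_equal(del$n_matched, 45L)
  expect_equal(del$pct_matched, 90)

  # tolerance admits a 1-month slip but flags it as date-inconsistent
  s <- data.frame(catchment_id = 1, type = "birth", cmc = 1350)
  r <- data.frame(catchment_id = 1, type = "birth", cmc = 1351)
  m <- match_registers(s, r, date_tolerance_months = 1)
  expect_equal(m$pct_matched, 100)
  expect_equal(m$pct_date_consistent, 0)
  # tie between equidistant candidates -> earliest reference month
  r2 <- data.frame(catchment_id = 1, type = "birth", cmc = c(1351, 1349))
  m2 <- match_registers(s, r2)
  expect_equal(m2$pairs$reference_row, 2L)
  # empty sample -> undefined percents, not NaN crashes
  e <- match_registers(ref[0, ], ref)
  expect_true(is.na(e$pct_matched))
})
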