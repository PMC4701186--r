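# Independent brute-force oracles and small random fixtures.
# Everything here is deliberately loop-based base R, sharing no code with
# the package's vectorised implementations.

# count monthly-report events falling in [ws, we] one row at a time
brute_tabulate_chw <- function(reports, ws, we) {
  bm <- bf <- nn <- pnn <- ch <- 0L
  for (i in seq_len(nrow(reports))) {
    if (reports$cmc[i] >= ws && reports$cmc[i] <= we) {
      bm <- bm + reports$births_male[i]
      bf <- bf + reports$births_female[i]
      nn <- nn + reports$deaths_neonatal[i]
      pnn <- pnn + reports$deaths_postneonatal[i]
      ch <- ch + reports$deaths_child[i]
    }
  }
  list(births_male = bm, births_female = bf, births = bm + bf,
       deaths_neonatal = nn, deaths_infant = nn + pnn,
       deaths_under5 = nn + pnn + ch)
}

# classify and count birth-history records one row at a time
brute_tabulate_fbh <- function(h, ws, we) {
  bm <- bf <- nn <- inf <- u5 <- 0L
  for (i in seq_len(nrow(h))) {
    if (!is.na(h$birth_cmc[i]) && h$birth_cmc[i] >= ws && h$birth_cmc[i] <= we) {
      if (h$sex[i] == "male") bm <- bm + 1L else bf <- bf + 1L
    }
    if (isTRUE(h$dead[i]) && !is.na(h$death_cmc[i]) &&
        h$death_cmc[i] >= ws && h$death_cmc[i] <= we) {
      am <- h$age_at_death_months[i]
      ad <- h$age_at_death_days[i]
      if (!is.na(am) && am < 60) {
        u5 <- u5 + 1L
        if (am < 12) inf <- inf + 1L
        neon <- if (!is.na(ad)) ad < 28 else am == 0
        if (neon) nn <- nn + 1L
      }
    }
  }
  list(births_male = bm, births_female = bf, births = bm + bf,
       deaths_neonatal = nn, deaths_infant = inf, deaths_under5 = u5)
}

# enumerate rolling 12-month windows by stepping a candidate start
brute_windows <- function(ps, pe, step = 3L) {
  starts <- integer()
  s <- ps
  while (s + 11L <= pe) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

random_reports <- function(n_catch = 3L, n_months = 24L, start = 1345L) {
  grid <- expand.grid(catchment_id = seq_len(n_catch),
                      cmc = seq.int(start, start + n_months - 1L))
  grid$births_male <- rpois(nrow(grid), 1.2)
  grid$births_female <- rpois(nrow(grid), 1.2)
  grid$deaths_neonatal <- rpois(nrow(grid), 0.2)
  grid$deaths_postneonatal <- rpois(nrow(grid), 0.2)
  grid$deaths_child <- rpois(nrow(grid), 0.2)
  grid
}

random_history <- function(n = 60L, start = 1300L) {
  birth <- sample(start:(start + 47L), n, replace = TRUE)
  dead <- runif(n) < 0.35
  age_m <- ifelse(dead, sample(0:70, n, replace = TRUE), NA_integer_)
  age_d <- ifelse(dead & age_m == 0, sample(0:27, n, replace = TRUE), NA_integer_)
  data.frame(
    birth_cmc = birth,
    sex = sample(c("male", "female"), n, replace = TRUE),
    dead = dead,
    age_at_death_months = age_m,
    age_at_death_days = age_d,
    death_cmc = ifelse(dead, birth + age_m, NA_integer_)
  )
}

expect_counts_equal <- function(counts, oracle) {
  for (f in c("births_male", "births_female", "births",
              "deaths_neonatal", "deaths_infant", "deaths_under5")) {
    expect_equal(counts[[f]], oracle[[f]], ignore_attr = TRUE,
                 label = paste0("counts$", f))
  }
}

# small fast simulation world shared across tests
tiny_config <- function(seed = 7L, ...) {
  sim_config(n_catchments = 4L, households_per_catchment = 150L,
             sim_start_cmc = cmc(2011, 1), sim_end_cmc = cmc(2013, 12),
             seed = seed, ...)
}
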