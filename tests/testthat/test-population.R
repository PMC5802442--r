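test_that("birth years span exactly the cohorts aged 30-84 during the horizon", {
  cfg <- small_config(n = 5000)
  pop <- build_population(cfg)
  expect_true(all(pop$birth_year >= 1932 & pop$birth_year <= 2000))
  expect_equal(nrow(pop), 5000)
  # every person is study-aged for at least one year of 2016-2030
  age16 <- 2016 - pop$birth_year
  age30 <- 2030 - pop$birth_year
  expect_true(all(age30 >= 30 & age16 <= 84))
})

test_that("zero growth rate gives a uniform birth-year distribution", {
  cfg <- small_config(n = 100000, seed = 3)
  cfg$population$cohort_growth_rate <- 0
  pop <- build_population(cfg)
  tab <- table(factor(pop$birth_year, levels = 1932:2000))
  gof <- suppressWarnings(stats::chisq.test(tab, p = rep(1 / 69, 69)))
  expect_gt(gof$p.value, 0.001)
})

test_that("populations are reproducible bit for bit from the master seed", {
  cfg <- small_config(n = 3000, seed = 99)
  expect_identical(build_population(cfg), build_population(cfg))
  # and a different seed gives a different population
  expect_false(identical(build_population(cfg), build_population(cfg, master_seed = 100)))
})

test_that("ever-smoker fraction matches the configured initiation probability", {
  cfg <- small_config()
  params <- cfg$smoking
  n <- 100000
  sm <- sample_smoking_history(rep(1950L, n), "male", params, 5, seq_len(n))
  p <- initiation_probability(1950L, "male", params)
  phat <- mean(!is.na(sm$initiation_age))
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("degenerate smoking parameters produce degenerate histories", {
  cfg <- small_config()
  params <- cfg$smoking
  params$init_prob_1950_male <- 0
  params$init_prob_1950_female <- 0
  sm <- sample_smoking_history(rep(1950L, 2000), "male", params, 5, 1:2000)
  expect_true(all(is.na(sm$initiation_age))) # 100% never smokers
  expect_true(all(is.na(sm$cessation_age)))

  params <- cfg$smoking
  params$cess_prob_annual <- 0
  sm <- sample_smoking_history(rep(1950L, 2000), "female", params, 5, 1:2000)
  expect_true(all(is.na(sm$cessation_age))) # no former smokers ever
})

test_that("ever-smoking prevalence declines across birth cohorts under a negative trend", {
  cfg <- small_config()
  decades <- seq(1935L, 1995L, by = 10L)
  prev <- vapply(decades, function(by) {
    sm <- sample_smoking_history(rep(by, 20000), "male", cfg$smoking, 17, 1:20000)
    mean(!is.na(sm$initiation_age))
  }, numeric(1))
  expect_lt(cfg$smoking$init_trend, 0)
  expect_true(all(diff(prev) < 0))
  # the configured probability itself is strictly decreasing in birth year
  p <- initiation_probability(1932:2000, "female", cfg$smoking)
  expect_true(all(diff(p) < 0))
})

test_that("pack-years follow the piecewise-constant exposure definition", {
  # 20 cigarettes/day (one pack) from age 20, still smoking at 50: 30 pack-years
  expect_equal(pack_years_at(hist_df(20, NA, 20), 50), 30)
  # never smoker accrues nothing
  expect_equal(pack_years_at(hist_df(), 70), 0)
  # 30/day ages 18-48, queried at 60: 1.5 packs * 30 years = 45, frozen at quit
  expect_equal(pack_years_at(hist_df(18, 48, 30), 60), 45)
  expect_error(pack_years_at(hist_df(20, NA, 20), -1), "age")
})

test_that("smoking status and quit-years at age follow the history boundaries", {
  h <- hist_df(18, 40, 20)
  expect_identical(smoker_status_at(h, 39), "current")
  expect_true(is.na(quit_years_at(h, 39)))
  expect_identical(smoker_status_at(h, 54), "former")
  expect_equal(quit_years_at(h, 54), 14)
  expect_identical(smoker_status_at(hist_df(), 70), "never")
  expect_identical(smoker_status_at(h, 10), "never") # before initiation
})

test_that("eligibility-relevant quantities agree with per-year brute-force accumulation", {
  set.seed(42)
  n <- 1000
  init <- runif(n, 12, 35)
  dur <- rexp(n, 1 / 25)
  cess <- ifelse(runif(n) < 0.5, init + dur, NA)
  cpd <- runif(n, 1, 60)
  never <- runif(n) < 0.2
  h <- hist_df(
    ifelse(never, NA, init), ifelse(never, NA, cess), ifelse(never, NA, cpd)
  )
  ages <- sample(30:90, n, replace = TRUE)

  brute <- vapply(seq_len(n), function(i) {
    if (is.na(h$initiation_age[i])) {
      return(0)
    }
    acc <- 0
    top <- if (is.na(h$cessation_age[i])) ages[i] else min(h$cessation_age[i], ages[i])
    for (y in 0:(ages[i] - 1)) { # accumulate year slices [y, y+1)
      overlap <- max(0, min(y + 1, top) - max(y, h$initiation_age[i]))
      acc <- acc + h$cigarettes_per_day[i] / 20 * overlap
    }
    acc
  }, numeric(1))
  expect_equal(pack_years_at(h, ages), brute, tolerance = 1e-10)

  brute_status <- vapply(seq_len(n), function(i) {
    if (is.na(h$initiation_age[i]) || ages[i] < h$initiation_age[i]) {
      return("never")
    }
    if (!is.na(h$cessation_age[i]) && ages[i] >= h$cessation_age[i]) {
      return("former")
    }
    "current"
  }, character(1))
  expect_identical(smoker_status_at(h, ages), brute_status)

  qy <- quit_years_at(h, ages)
  expect_true(all(is.na(qy[brute_status != "former"])))
  expect_equal(
    qy[brute_status == "former"],
    (ages - h$cessation_age)[brute_status == "former"]
  )
})

test_that("pack-years are non-decreasing in age and zero at initiation", {
  set.seed(7)
  for (i in 1:50) {
    init <- runif(1, 12, 35)
    h <- hist_df(init, if (runif(1) < 0.5) init + rexp(1, 1 / 20) else NA, runif(1, 1, 40))
    ages <- sort(runif(20, 0, 100))
    py <- pack_years_at(h, ages)
    expect_true(all(diff(py) >= -1e-12))
    expect_equal(pack_years_at(h, init), 0)
  }
})

test_that("other-cause death ages follow the Gompertz baseline when hazard ratios are 1", {
  cfg <- small_config()
  cfg$natural_history$oc_hr_current <- 1
  cfg$natural_history$oc_hr_former <- 1
  n <- 100000
  persons <- person_row(
    person_id = seq_len(n), init = 25, cess = 50, cpd = 20, birth_year = 1950L
  )
  x <- sample_other_cause_death_age(persons, cfg, master_seed = 8)
  expect_true(all(x <= 100)) # lifespan cap
  b <- cfg$natural_history$oc_gompertz_rate
  g <- cfg$natural_history$oc_gompertz_shape
  cdf <- function(a) 1 - exp(-b / g * (exp(g * a) - 1))
  trunc_cdf <- function(a) cdf(a) / cdf(100)
  ks <- suppressWarnings(stats::ks.test(x[x < 100], trunc_cdf))
  expect_gt(ks$p.value, 0.001)
})

test_that("a higher smoking hazard ratio shifts other-cause death earlier", {
  cfg <- small_config()
  cfg$natural_history$oc_hr_current <- 2
  n <- 100000
  current <- person_row(person_id = seq_len(n), init = 15, cess = NA_real_, cpd = 20)
  never <- person_row(
    person_id = seq_len(n),
    init = NA_real_, cess = NA_real_, cpd = NA_real_
  )
  x_cur <- sample_other_cause_death_age(current, cfg, master_seed = 8)
  x_nev <- sample_other_cause_death_age(never, cfg, master_seed = 8)
  expect_lt(stats::median(x_cur), stats::median(x_nev))
  # shared substream: paired draws are never later for the elevated hazard
  expect_true(all(x_cur <= x_nev))
})
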