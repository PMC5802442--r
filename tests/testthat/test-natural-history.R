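test_that("a zero dose-response coefficient removes the smoking effect on onset", {
  cfg <- small_config()
  cfg$natural_history$dose_coef <- 0
  n <- 100000
  heavy <- hist_df(rep(15, n), NA_real_, 40)
  never <- hist_df(rep(NA_real_, n), NA_real_, NA_real_)
  # distinct substreams (different ids) so the two samples are independent
  a_heavy <- sample_onset_age(heavy, cfg, master_seed = 4, person_id = 1:n)
  a_never <- sample_onset_age(never, cfg, master_seed = 4, person_id = n + (1:n))
  ks <- suppressWarnings(
    stats::ks.test(a_heavy[!is.na(a_heavy)], a_never[!is.na(a_never)])
  )
  expect_gt(ks$p.value, 0.001)
})

test_that("never smokers with zero baseline hazard never develop lung cancer", {
  cfg <- small_config()
  cfg$natural_history$onset_base_rate <- 0
  h <- hist_df(rep(NA_real_, 1000), NA_real_, NA_real_)
  expect_true(all(is.na(sample_onset_age(h, cfg, master_seed = 4))))
})

test_that("cumulative onset incidence orders current > former > never", {
  cfg <- small_config()
  n <- 100000
  mk <- function(init, cess, cpd) hist_df(rep(init, n), cess, cpd)
  inc <- function(h, off) {
    a <- sample_onset_age(h, cfg, master_seed = 9, person_id = off + (1:n))
    mean(!is.na(a) & a <= 84)
  }
  i_cur <- inc(mk(17, NA_real_, 20), 0)
  i_for <- inc(mk(17, 45, 20), n)
  i_nev <- inc(mk(NA_real_, NA_real_, NA_real_), 2 * n)
  expect_gt(i_cur, i_for)
  expect_gt(i_for, i_nev)
  expect_gt(i_nev, 0) # never smokers are not structurally excluded
})

test_that("onset ages invert the closed-form cumulative hazard for never smokers", {
  # independent oracle: baseline-only onset is Gompertz-in-age; compare the
  # sampler's conditional distribution to the truncated closed-form CDF
  cfg <- small_config()
  nh <- cfg$natural_history
  n <- 100000
  h <- hist_df(rep(NA_real_, n), NA_real_, NA_real_)
  a <- sample_onset_age(h, cfg, master_seed = 21, person_id = 1:n)
  cdf <- function(x) 1 - exp(-nh$onset_base_rate / nh$onset_age_slope *
    (exp(nh$onset_age_slope * x) - 1))
  ks <- suppressWarnings(stats::ks.test(a[!is.na(a)], function(x) cdf(x) / cdf(100)))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(!is.na(a)), cdf(100), tolerance = 4 * sqrt(cdf(100) / n))
})

test_that("histology assignment reproduces the configured mixture", {
  cfg <- small_config()
  n <- 100000
  draws <- assign_histology(cfg, master_seed = 6, person_id = 1:n)
  expect_setequal(unique(draws), names(cfg$natural_history$histology_probs))
  freq <- table(draws)[names(cfg$natural_history$histology_probs)]
  for (k in seq_along(freq)) {
    p <- cfg$natural_history$histology_probs[k]
    expect_lt(abs(freq[[k]] / n - p), 3 * sqrt(p * (1 - p) / n))
  }

  cfg$natural_history$histology_probs <- c(
    adenocarcinoma = 1, squamous = 0, large_cell = 0, small_cell = 0, other = 0
  )
  expect_true(all(assign_histology(cfg, 6, 1:500) == "adenocarcinoma"))

  cfg$natural_history$histology_probs[1] <- 0.5
  expect_error(assign_histology(cfg, 6, 1:5), "histology_probs")
})

test_that("limit cases of the clinical-detection hazard behave as limits", {
  cfg <- small_config()
  n <- 2000
  onset <- rep(60, n)
  histol <- rep("adenocarcinoma", n)

  cfg$natural_history$clinical_detection_rate <- c(I = 1e9, II = 1e9, III = 1e9, IV = 1e9)
  course <- sample_preclinical_course(onset, histol, cfg, 3, 1:n)
  expect_true(all(course$clin_stage == 1L)) # instant detection in stage I
  expect_equal(course$clin_detect_age, onset, tolerance = 1e-6)

  cfg$natural_history$clinical_detection_rate <- c(I = 0, II = 0, III = 0, IV = 0)
  course <- sample_preclinical_course(onset, histol, cfg, 3, 1:n)
  expect_true(all(is.infinite(course$clin_detect_age))) # never detected
  expect_true(all(is.na(course$clin_stage)))
})

test_that("stage entries increase and small cell progresses faster", {
  cfg <- small_config()
  n <- 20000
  onset <- rep(55, n)
  c_ad <- sample_preclinical_course(onset, rep("adenocarcinoma", n), cfg, 3, 1:n)
  c_sc <- sample_preclinical_course(onset, rep("small_cell", n), cfg, 3, 1:n)
  mat <- as.matrix(c_ad[paste0("entry_", c("I", "II", "III", "IV"))])
  expect_true(all(diff(t(mat)) > 0))
  expect_lt(mean(c_sc$entry_IV - c_sc$entry_I), mean(c_ad$entry_IV - c_ad$entry_I))
})

test_that("stage at clinical detection matches a discrete-event brute-force oracle", {
  cfg <- small_config()
  nh <- cfg$natural_history
  n <- 100000
  course <- sample_preclinical_course(rep(50, n), rep("squamous", n), cfg, 13, 1:n)
  got <- prop.table(table(factor(course$clin_stage, levels = 1:4)))

  # oracle: step-by-step competing exponentials with R's own RNG
  set.seed(1)
  prog <- c(1 / nh$sojourn_mean, 0)
  det <- nh$clinical_detection_rate
  oracle_stage <- replicate(n, {
    for (k in 1:4) {
      t_prog <- if (prog[k] > 0) rexp(1, prog[k]) else Inf
      t_det <- rexp(1, det[k])
      if (t_det < t_prog) {
        return(k)
      }
    }
    NA_integer_
  })
  want <- prop.table(table(factor(oracle_stage, levels = 1:4)))
  for (k in 1:4) {
    se <- sqrt(want[[k]] * (1 - want[[k]]) / n)
    expect_lt(abs(got[[k]] - want[[k]]), 4 * sqrt(2) * se)
  }
})

test_that("survival is a comonotone cure-mixture across stages", {
  cfg <- small_config()
  # a quantile in the cure region of every stage (1 - q below all cure
  # fractions) means cure regardless of stage
  expect_true(all(sample_lc_death_age(1:4, "adenocarcinoma", 60, cfg,
    rep(0.999, 4)
  ) == Inf))
  # fixed median quantile: stage I death never earlier than stage IV
  d <- sample_lc_death_age(c(1L, 4L), "adenocarcinoma", 60, cfg, 0.5)
  expect_gte(d[1], d[2])
  # exhaustive grid over quantiles, stage pairs and histologies
  qs <- seq(0, 0.999, by = 0.001)
  for (hs in c("adenocarcinoma", "small_cell")) {
    deaths <- vapply(
      1:4, function(s) sample_lc_death_age(s, hs, 60, cfg, qs),
      numeric(length(qs))
    )
    # each row: death age non-increasing as stage worsens I -> IV
    expect_true(all(deaths[, 1] >= deaths[, 2]))
    expect_true(all(deaths[, 2] >= deaths[, 3]))
    expect_true(all(deaths[, 3] >= deaths[, 4]))
  }
  expect_error(
    sample_lc_death_age(1L, "other", 60, cfg, 1.0), "quantile"
  )
})

test_that("cure fractions of 1 eliminate lung cancer deaths", {
  cfg <- small_config()
  cfg$natural_history$cure_fraction <- c(I = 1, II = 1, III = 1, IV = 1)
  d <- sample_lc_death_age(
    sample(1:4, 1000, TRUE), "adenocarcinoma", 60, cfg,
    seq(0, 0.999, length.out = 1000)
  )
  expect_true(all(d == Inf))
})

test_that("stage-specific 5-year survival matches the closed-form mixture", {
  cfg <- small_config()
  nh <- cfg$natural_history
  q <- (seq_len(100000) - 0.5) / 100000 # uniform quantile grid
  for (s in 1:4) {
    d <- sample_lc_death_age(s, "large_cell", 70, cfg, q)
    surv5 <- mean(d > 75)
    cure <- nh$cure_fraction[[s]]
    want <- cure + (1 - cure) * exp(-5 * nh$survival_rate[[s]])
    expect_lt(abs(surv5 - want), 2e-5) # grid quantiles: error is one cell
  }
  # small cell: adjusted cure and residual hazard
  q <- (seq_len(100000) - 0.5) / 100000
  for (s in c(1L, 4L)) {
    d <- sample_lc_death_age(s, "small_cell", 70, cfg, q)
    cure <- nh$cure_fraction[[s]] * nh$small_cell_cure_multiplier
    rate <- nh$survival_rate[[s]] * nh$small_cell_mortality_multiplier
    want <- cure + (1 - cure) * exp(-5 * rate)
    expect_lt(abs(mean(d > 75) - want), 2e-5)
  }
})
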