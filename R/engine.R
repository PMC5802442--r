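# Paired counterfactual engine. Both scenarios (no screening vs CMS annual CT
# screening) are evaluated on the same population with identical latent draws
# (common random numbers): other-cause death age, tumor onset, histology,
# preclinical trajectory and the survival quantile are shared; only detection
# mode/age/stage — and through the comonotone survival coupling, the
# lung-cancer death age — may differ.
#
# Lung-cancer death is anchored at the latent clinical-detection age in both
# scenarios: death = clin_detect_age + residual(stage at diagnosis, quantile).
# Screen detection improves the stage entering the survival function but does
# not move the anchor, so earlier detection confers no spurious lead-time
# "survival" and the per-person non-harm property (screen death age >=
# no-screen death age) is exact.

# All latent, scenario-invariant quantities for a population.
simulate_latent <- function(population, config, master_seed) {
  n <- nrow(population)
  id <- population$person_id
  hist <- population[c("initiation_age", "cessation_age", "cigarettes_per_day")]

  onset <- sample_onset_age(hist, config, master_seed, id)
  has <- !is.na(onset)
  histology <- rep(NA_character_, n)
  course <- data.frame(
    entry_I = rep(NA_real_, n), entry_II = NA_real_, entry_III = NA_real_,
    entry_IV = NA_real_, clin_detect_age = Inf, clin_stage = NA_integer_
  )
  if (any(has)) {
    histology[has] <- assign_histology(config, master_seed, id[has])
    course[has, ] <- sample_preclinical_course(
      onset[has], histology[has], config, master_seed, id[has]
    )
  }
  q <- stream_uniform(master_seed, id, "survival")

  # latent no-screen lung-cancer death age (Inf if cured / never detected)
  lc_ns <- rep(Inf, n)
  dx <- has & is.finite(course$clin_detect_age)
  if (any(dx)) {
    lc_ns[dx] <- sample_lc_death_age(
      course$clin_stage[dx], histology[dx], course$clin_detect_age[dx],
      config, q[dx]
    )
  }
  list(
    onset = onset, histology = histology, course = course,
    survival_quantile = q, lc_ns = lc_ns
  )
}

# Screen-scenario detection and death for given policy/adherence.
screen_scenario <- function(population, latent, config, policy, master_seed,
                            adherent = NULL) {
  n <- nrow(population)
  scr <- run_screens(population, latent$course, policy, config, master_seed,
    adherent = adherent
  )
  sdet <- is.finite(scr$screen_detect_age)
  clin_det <- latent$course$clin_detect_age
  stage_dx <- ifelse(sdet, scr$screen_detect_stage, latent$course$clin_stage)

  lc_s <- latent$lc_ns
  redo <- sdet & is.finite(clin_det) # anchor finite: survival can improve
  if (any(redo)) {
    lc_s[redo] <- sample_lc_death_age(
      stage_dx[redo], latent$histology[redo], clin_det[redo],
      config, latent$survival_quantile[redo]
    )
  }
  lc_s[sdet & !is.finite(clin_det)] <- Inf # diagnosed, never lethal

  list(
    scr = scr, screen_detected = sdet, stage_dx = stage_dx, lc_death = lc_s
  )
}

# life-years lived inside the observation window while study-aged
life_years_in_horizon <- function(birth_year, death_age, config) {
  p <- config$population
  start_cal <- pmax(p$start_year, birth_year + p$min_age)
  end_cal <- p$end_year + 1
  pmax(0, pmin(birth_year + death_age, end_cal) - start_cal)
}

#' Simulate the screening and no-screening scenarios for a population
#'
#' Runs both scenarios under common random numbers and returns the paired
#' person-level event log: one row per person with latent natural history,
#' no-screen (`ns_`) and screen (`s_`) diagnosis, death and exam fields.
#' Persons are followed to death (lifespan cap) for cause-of-death
#' classification even when death falls past the reporting horizon.
#'
#' @param population data.frame from [build_population()]
#' @param config full configuration
#' @param master_seed seed (defaults to the configured master seed)
#' @param policy screening policy override (defaults to `config$screening`)
#' @param adherent optional logical vector overriding adherence assignment
#' @return list with `pairs` (person-level paired log) and `screens`
#'   (per-year exam structure from the screening pass)
#' @export
simulate_pairs <- function(population, config, master_seed = NULL,
                           policy = NULL, adherent = NULL) {
  seed <- if (is.null(master_seed)) config$population$master_seed else master_seed
  if (is.null(policy)) policy <- config$screening
  latent <- simulate_latent(population, config, seed)
  scen <- screen_scenario(population, latent, config, policy, seed, adherent)
  build_pairs(population, latent, scen, config, policy)
}

build_pairs <- function(population, latent, scen, config, policy) {
  n <- nrow(population)
  oc <- population$oc_death_age
  clin_det <- latent$course$clin_detect_age
  scr <- scen$scr

  # realized deaths: min of other-cause and (anchored) lung-cancer death
  death_ns <- pmin(oc, latent$lc_ns)
  cause_ns <- ifelse(latent$lc_ns < oc, "lung_cancer", "other")
  death_s <- pmin(oc, scen$lc_death)
  cause_s <- ifelse(scen$lc_death < oc, "lung_cancer", "other")

  # diagnoses require being alive at detection (lung-cancer death cannot
  # precede the detection anchor, so only other-cause death can censor)
  ns_diag <- is.finite(clin_det) & clin_det < oc
  s_diag_age <- pmin(scr$screen_detect_age, clin_det)
  s_diag <- scen$screen_detected | ns_diag
  s_mode <- ifelse(scen$screen_detected, "screen",
    ifelse(ns_diag, "clinical", NA_character_)
  )

  # scenario-invariant smoker-type attribution at the diagnosis anchor
  hist <- population[c("initiation_age", "cessation_age", "cigarettes_per_day")]
  attr_age <- ifelse(is.finite(clin_det), clin_det, s_diag_age)
  smoker_type_dx <- rep(NA_character_, n)
  any_dx <- s_diag | ns_diag
  if (any(any_dx)) {
    smoker_type_dx[any_dx] <- smoker_status_at(hist[any_dx, ], attr_age[any_dx])
  }

  pairs <- data.frame(
    population[c(
      "person_id", "sex", "birth_year", "initiation_age", "cessation_age",
      "cigarettes_per_day", "adherence_uniform", "weight", "oc_death_age"
    )],
    onset_age = latent$onset,
    histology = latent$histology,
    clin_detect_age = clin_det,
    clin_stage = latent$course$clin_stage,
    survival_quantile = latent$survival_quantile,
    smoker_type_dx = smoker_type_dx,
    ns_diag = ns_diag,
    ns_diag_age = ifelse(ns_diag, clin_det, NA_real_),
    ns_diag_stage = ifelse(ns_diag, latent$course$clin_stage, NA_integer_),
    ns_diag_mode = ifelse(ns_diag, "clinical", NA_character_),
    ns_lc_death_age = latent$lc_ns,
    ns_death_age = death_ns,
    ns_death_cause = cause_ns,
    ns_exams = 0L,
    s_diag = s_diag,
    s_diag_age = ifelse(s_diag, s_diag_age, NA_real_),
    s_diag_stage = ifelse(s_diag, scen$stage_dx, NA_integer_),
    s_diag_mode = s_mode,
    s_lc_death_age = scen$lc_death,
    s_death_age = death_s,
    s_death_cause = cause_s,
    s_exams = scr$exams,
    stringsAsFactors = FALSE
  )
  pairs$ns_life_years <- life_years_in_horizon(pairs$birth_year, death_ns, config)
  pairs$s_life_years <- life_years_in_horizon(pairs$birth_year, death_s, config)
  list(pairs = pairs, screens = scr)
}

#' Simulate one person under both scenarios
#'
#' Per-person wrapper over the common-random-numbers engine. For nonadherent
#' or never-eligible persons the two outcomes are identical field for field.
#'
#' @param person one-row data.frame as produced by [build_population()]
#' @param config full configuration
#' @param master_seed seed
#' @return list of two one-row data.frames, `no_screen` and `screen`, each
#'   with diagnosis (age/stage/mode), death age and cause, exam count and
#'   life-years within the horizon
#' @export
simulate_person_pair <- function(person, config, master_seed = NULL) {
  res <- simulate_pairs(person, config, master_seed)
  p <- res$pairs
  shared <- p[c("person_id", "sex", "birth_year")]
  no_screen <- cbind(shared, data.frame(
    scenario = "no_screen",
    diag_age = p$ns_diag_age, diag_stage = p$ns_diag_stage,
    diag_mode = p$ns_diag_mode, death_age = p$ns_death_age,
    death_cause = p$ns_death_cause, exams = p$ns_exams,
    life_years = p$ns_life_years, stringsAsFactors = FALSE
  ))
  screen <- cbind(shared, data.frame(
    scenario = "screen",
    diag_age = p$s_diag_age, diag_stage = p$s_diag_stage,
    diag_mode = p$s_diag_mode, death_age = p$s_death_age,
    death_cause = p$s_death_cause, exams = p$s_exams,
    life_years = p$s_life_years, stringsAsFactors = FALSE
  ))
  list(no_screen = no_screen, screen = screen)
}

# Weighted sum of x[f] by calendar year over the horizon.
year_tab <- function(event_year, weight, keep, years) {
  out <- numeric(length(years))
  if (any(keep)) {
    t <- tapply(weight[keep], factor(event_year[keep], levels = years), sum)
    out <- ifelse(is.na(t), 0, t)
  }
  out
}

# Annual aggregates for both scenarios from a paired log.
aggregate_annual <- function(pairs, screens, config, policy) {
  p <- config$population
  years <- seq.int(p$start_year, p$end_year)
  b <- pairs$birth_year
  w <- pairs$weight
  hist <- pairs[c("initiation_age", "cessation_age", "cigarettes_per_day")]

  study_pop <- eligible <- screens_total <- screens_current <-
    screens_former <- numeric(length(years))
  for (j in seq_along(years)) {
    y <- years[j]
    age <- y - b
    alive <- b + pairs$ns_death_age > y
    in_study <- alive & age >= p$min_age & age <= p$max_age
    study_pop[j] <- sum(w[in_study])
    elig <- alive & pairs$clin_detect_age > age & is_eligible(hist, age, policy)
    eligible[j] <- sum(w[elig])
    jj <- match(y, screens$years)
    if (!is.na(jj)) {
      ex <- screens$exam_years[, jj]
      if (any(ex)) {
        st <- smoker_status_at(hist[ex, ], age[ex])
        screens_total[j] <- sum(w[ex])
        screens_current[j] <- sum(w[ex][st == "current"])
        screens_former[j] <- sum(w[ex][st == "former"])
      }
    }
  }

  one_scenario <- function(scen, diag, diag_age, diag_mode, death_age, cause) {
    dy <- floor(b + death_age)
    gy <- floor(b + diag_age)
    lung <- cause == "lung_cancer"
    st <- pairs$smoker_type_dx
    data.frame(
      year = years,
      scenario = scen,
      study_pop = study_pop,
      eligible = eligible,
      screens = if (scen == "screen") screens_total else 0,
      screens_current = if (scen == "screen") screens_current else 0,
      screens_former = if (scen == "screen") screens_former else 0,
      cases = year_tab(gy, w, diag, years),
      cases_screen_detected = year_tab(gy, w, diag & diag_mode %in% "screen", years),
      lc_deaths = year_tab(dy, w, lung, years),
      lc_deaths_current = year_tab(dy, w, lung & st %in% "current", years),
      lc_deaths_former = year_tab(dy, w, lung & st %in% "former", years),
      lc_deaths_never = year_tab(dy, w, lung & st %in% "never", years),
      oc_deaths = year_tab(dy, w, !lung, years),
      stringsAsFactors = FALSE
    )
  }
  rbind(
    one_scenario(
      "no_screen", pairs$ns_diag, pairs$ns_diag_age, pairs$ns_diag_mode,
      pairs$ns_death_age, pairs$ns_death_cause
    ),
    one_scenario(
      "screen", pairs$s_diag, pairs$s_diag_age, pairs$s_diag_mode,
      pairs$s_death_age, pairs$s_death_cause
    )
  )
}

#' Run one simulation replication
#'
#' Builds a fresh population from the replication seed, simulates both
#' scenarios under common random numbers, and aggregates annual outcomes.
#' Deterministic given the seed: rerunning with the same seed reproduces the
#' result bit for bit.
#'
#' @param config full configuration
#' @param replication_seed seed for this replication (defaults to the
#'   configured master seed)
#' @return object of class `lungsim_replication`: list with `pairs`
#'   (person-level paired log), `annual` (per-year per-scenario aggregates),
#'   `seed` and `config`
#' @export
run_replication <- function(config, replication_seed = NULL) {
  config <- validate_config(config)
  seed <- if (is.null(replication_seed)) config$population$master_seed else replication_seed
  population <- build_population(config, master_seed = seed)
  res <- simulate_pairs(population, config, master_seed = seed)
  out <- list(
    pairs = res$pairs,
    annual = aggregate_annual(res$pairs, res$screens, config, config$screening),
    seed = seed,
    config = config
  )
  class(out) <- c("lungsim_replication", "list")
  out
}

#' Scalar outcome metrics for one replication
#'
#' Cumulative (within-horizon) counts and the derived benefit/harm metrics
#' for a single replication, as one row.
#'
#' @param rep `lungsim_replication` object
#' @return one-row data.frame of metrics
#' @export
replication_metrics <- function(rep) {
  pairs <- rep$pairs
  config <- rep$config
  ann <- rep$annual
  ns <- ann[ann$scenario == "no_screen", ]
  sc <- ann[ann$scenario == "screen", ]

  deaths_ns <- sum(ns$lc_deaths)
  deaths_s <- sum(sc$lc_deaths)
  avoided <- deaths_ns - deaths_s
  w <- pairs$weight

  overdiag <- sum(w[pairs$s_diag_mode %in% "screen" & pairs$s_death_cause == "other"])
  screen_det <- sum(sc$cases_screen_detected)
  screened <- pairs$s_exams > 0

  horizon_lung_deaths <- function(death_age, cause, keep) {
    dy <- floor(pairs$birth_year + death_age)
    sum(w[keep & cause == "lung_cancer" &
      dy >= config$population$start_year & dy <= config$population$end_year])
  }
  deaths_ns_screened <- horizon_lung_deaths(pairs$ns_death_age, pairs$ns_death_cause, screened)
  deaths_s_screened <- horizon_lung_deaths(pairs$s_death_age, pairs$s_death_cause, screened)

  data.frame(
    seed = rep$seed,
    study_pop_first = ns$study_pop[1],
    eligible_first = ns$eligible[1],
    eligible_last = ns$eligible[nrow(ns)],
    screens = sum(sc$screens),
    cases_no_screen = sum(ns$cases),
    cases_screen = sum(sc$cases),
    screen_detected = screen_det,
    lc_deaths_no_screen = deaths_ns,
    lc_deaths_screen = deaths_s,
    lc_deaths_no_screen_current = sum(ns$lc_deaths_current),
    lc_deaths_no_screen_former = sum(ns$lc_deaths_former),
    lc_deaths_no_screen_never = sum(ns$lc_deaths_never),
    deaths_avoided = avoided,
    deaths_avoided_current = sum(ns$lc_deaths_current) - sum(sc$lc_deaths_current),
    deaths_avoided_former = sum(ns$lc_deaths_former) - sum(sc$lc_deaths_former),
    mr_total_pct = if (deaths_ns > 0) 100 * avoided / deaths_ns else NA_real_,
    mr_screened_pct = if (deaths_ns_screened > 0) {
      100 * (deaths_ns_screened - deaths_s_screened) / deaths_ns_screened
    } else {
      NA_real_
    },
    life_years_gained = sum(w * (pairs$s_life_years - pairs$ns_life_years)),
    overdiagnoses = overdiag,
    overdiag_per_100_avoided = if (avoided > 0) 100 * overdiag / avoided else NA_real_,
    overdiag_rate_pct = if (screen_det > 0) 100 * overdiag / screen_det else NA_real_,
    excess_diag_rate_pct = if (sum(sc$cases) > 0) {
      100 * (sum(sc$cases) - sum(ns$cases)) / sum(sc$cases)
    } else {
      NA_real_
    }
  )
}

#' Summarize replications: means and 95\% confidence intervals
#'
#' Across-replication mean and normal-approximation 95\% CI
#' (mean +/- 1.96 * sd / sqrt(R)) for every scalar metric and for the annual
#' series.
#'
#' @param results list of `lungsim_replication` objects (length >= 2), or a
#'   data.frame with one row of metrics per replication
#' @return list with `metrics` (metric, mean, sd, ci_lo, ci_hi) and, when
#'   full replication objects are given, `annual` (per year/scenario means
#'   and CIs)
#' @export
summarize_runs <- function(results) {
  if (is.data.frame(results)) {
    per_rep <- results
    annual <- NULL
  } else {
    if (length(results) < 2) {
      stop("summarize_runs requires at least 2 replications (CI undefined)",
        call. = FALSE
      )
    }
    per_rep <- do.call(rbind, lapply(results, replication_metrics))
    annual <- do.call(rbind, lapply(results, function(r) r$annual))
  }
  if (nrow(per_rep) < 2) {
    stop("summarize_runs requires at least 2 replications (CI undefined)",
      call. = FALSE
    )
  }
  num <- vapply(per_rep, is.numeric, logical(1))
  num["seed"] <- FALSE
  summ <- function(x) {
    x <- x[!is.na(x)] # metrics undefined in a run (e.g. zero denominators)
    m <- mean(x)
    s <- stats::sd(x)
    half <- 1.96 * s / sqrt(length(x))
    c(mean = m, sd = s, ci_lo = m - half, ci_hi = m + half)
  }
  mat <- t(vapply(per_rep[num], summ, numeric(4)))
  metrics <- data.frame(
    metric = rownames(mat), mat,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- list(metrics = metrics, n_replications = nrow(per_rep))
  if (!is.null(annual)) {
    keys <- c("year", "scenario")
    vals <- setdiff(names(annual), keys)
    agg <- stats::aggregate(
      annual[vals],
      by = annual[keys],
      FUN = mean
    )
    sds <- stats::aggregate(annual[vals], by = annual[keys], FUN = stats::sd)
    half <- 1.96 * as.matrix(sds[vals]) / sqrt(nrow(per_rep))
    lo <- agg
    hi <- agg
    lo[vals] <- agg[vals] - half
    hi[vals] <- agg[vals] + half
    out$annual <- agg
    out$annual_ci_lo <- lo
    out$annual_ci_hi <- hi
  }
  out
}

#' Run the full replicated simulation
#'
#' Runs `replications` independent replications (fresh population each, seeds
#' derived from the master seed) and summarizes them.
#'
#' @param config full configuration
#' @param replications number of replications (default
#'   `config$run$n_replications`)
#' @param seed master seed override
#' @return object of class `lungsim_simulation`: list with `replications`
#'   (list of `lungsim_replication`), `summary` (from [summarize_runs()]),
#'   `per_replication` (one metrics row per run), `config`, `master_seed`
#' @export
run_simulation <- function(config, replications = NULL, seed = NULL) {
  config <- validate_config(config)
  if (is.null(replications)) replications <- config$run$n_replications
  master <- if (is.null(seed)) config$population$master_seed else seed
  reps <- lapply(seq_len(replications), function(r) {
    run_replication(config, replication_seed = master * 1000 + r)
  })
  per_rep <- do.call(rbind, lapply(reps, replication_metrics))
  out <- list(
    replications = reps,
    per_replication = per_rep,
    summary = if (replications >= 2) summarize_runs(reps) else NULL,
    config = config,
    master_seed = master
  )
  class(out) <- c("lungsim_simulation", "list")
  out
}
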