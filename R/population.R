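#' Build the multi-birth-cohort synthetic population
#'
#' Generates `n_persons` simulated individuals covering every birth cohort that
#' is aged within `[min_age, max_age]` at some point in
#' `[start_year, end_year]` (by default, cohorts 1932--2000 for a 2016--2030
#' horizon over ages 30--84). Successive cohorts grow geometrically at
#' `cohort_growth_rate` per birth year. Each person receives a sex, a smoking
#' history sampled from the birth-cohort smoking model (later cohorts initiate
#' less when the trend coefficient is negative), an adherence coupling draw,
#' and an other-cause (competing mortality) death age.
#'
#' @param config validated configuration from [default_config()] /
#'   [load_config()]
#' @param master_seed optional seed override (defaults to
#'   `config$population$master_seed`)
#' @return data.frame with one row per person: `person_id`, `sex`,
#'   `birth_year`, `initiation_age`, `cessation_age`, `cigarettes_per_day`
#'   (NA for never smokers; NA cessation for persistent current smokers),
#'   `adherence_uniform`, `oc_death_age`, `weight`
#' @export
build_population <- function(config, master_seed = NULL) {
  config <- validate_config(config)
  p <- config$population
  seed <- if (is.null(master_seed)) p$master_seed else master_seed
  n <- as.integer(p$n_persons)
  id <- seq_len(n)

  # birth cohorts with geometric relative sizes
  span <- birth_year_span(config)
  w <- (1 + p$cohort_growth_rate)^(span - span[1])
  cdf <- cumsum(w) / sum(w)
  u_by <- stream_uniform(seed, id, "birth_year")
  birth_year <- span[findInterval(u_by, cdf, left.open = TRUE) + 1L]

  u_sex <- stream_uniform(seed, id, "sex")
  sex <- ifelse(u_sex < p$sex_fraction_male, "male", "female")

  sm <- sample_smoking_history_vec(birth_year, sex, config$smoking, seed, id)

  pop <- data.frame(
    person_id = id,
    sex = sex,
    birth_year = birth_year,
    initiation_age = sm$initiation_age,
    cessation_age = sm$cessation_age,
    cigarettes_per_day = sm$cigarettes_per_day,
    adherence_uniform = stream_uniform(seed, id, "adherence"),
    weight = p$person_weight,
    stringsAsFactors = FALSE
  )
  pop$oc_death_age <- sample_other_cause_death_age(pop, config, master_seed = seed)
  pop
}

#' Ever-smoking initiation probability for a birth cohort
#'
#' Logistic in birth year: `plogis(qlogis(p1950[sex]) + trend * (by - 1950))`.
#' With a negative trend coefficient the probability is strictly decreasing in
#' birth year — the declining-prevalence mechanism that drives falling
#' screening eligibility in later cohorts.
#'
#' @param birth_year integer vector
#' @param sex "male"/"female" vector
#' @param params `smoking` block of the configuration
#' @return vector of probabilities
#' @export
initiation_probability <- function(birth_year, sex, params) {
  p0 <- ifelse(sex == "male", params$init_prob_1950_male,
    params$init_prob_1950_female
  )
  # degenerate 0/1 anchors stay degenerate
  out <- stats::plogis(stats::qlogis(p0) + params$init_trend * (birth_year - 1950))
  out[p0 == 0] <- 0
  out[p0 == 1] <- 1
  out
}

# Vectorized smoking-history sampler (internal work-horse).
sample_smoking_history_vec <- function(birth_year, sex, params, master_seed, person_id) {
  n <- length(birth_year)
  p_init <- initiation_probability(birth_year, sex, params)
  ever <- stream_uniform(master_seed, person_id, "smoke_init") < p_init

  # initiation age: truncated normal on [init_age_min, init_age_max]
  u_age <- stream_uniform(master_seed, person_id, "smoke_init_age")
  lo <- stats::pnorm(params$init_age_min, params$init_age_mean, params$init_age_sd)
  hi <- stats::pnorm(params$init_age_max, params$init_age_mean, params$init_age_sd)
  init_age <- stats::qnorm(lo + u_age * (hi - lo), params$init_age_mean, params$init_age_sd)

  # intensity: lognormal cigarettes/day, capped, at least 1
  u_cpd <- stream_uniform(master_seed, person_id, "smoke_cpd")
  cpd <- pmax(1, pmin(params$cpd_max, stats::qlnorm(u_cpd, params$cpd_meanlog, params$cpd_sdlog)))

  # cessation: geometric waiting time with annual quit probability; quitting
  # beyond the lifespan cap is treated as never quitting (persistent smoker)
  u_cess <- stream_uniform(master_seed, person_id, "smoke_cess")
  pc <- params$cess_prob_annual
  if (pc > 0) {
    years_smoked <- ceiling(log1p(-u_cess) / log1p(-pc))
    cess_age <- init_age + years_smoked
    cess_age[cess_age >= 100] <- NA_real_
  } else {
    cess_age <- rep(NA_real_, n)
  }

  data.frame(
    initiation_age = ifelse(ever, init_age, NA_real_),
    cessation_age = ifelse(ever, cess_age, NA_real_),
    cigarettes_per_day = ifelse(ever, cpd, NA_real_)
  )
}

#' Sample one smoking history
#'
#' Draws never/ever status from the cohort- and sex-specific initiation
#' probability, then initiation age, cigarettes per day and cessation age for
#' ever smokers. Deterministic given `(master_seed, person_id)`.
#'
#' @param birth_year integer scalar (or vector)
#' @param sex "male" or "female" (recycled)
#' @param params `smoking` block of the configuration
#' @param master_seed integer seed
#' @param person_id integer id(s) selecting the random substream
#' @return data.frame with `initiation_age`, `cessation_age`,
#'   `cigarettes_per_day` (all NA for never smokers)
#' @export
sample_smoking_history <- function(birth_year, sex, params, master_seed, person_id) {
  n <- max(length(birth_year), length(sex), length(person_id))
  sample_smoking_history_vec(
    rep_len(birth_year, n), rep_len(sex, n), params,
    master_seed, rep_len(person_id, n)
  )
}

#' Pack-years of smoking accumulated by a given age
#'
#' One pack-year is one pack (20 cigarettes) per day for one year, so
#' pack-years at age a equal
#' `cigarettes_per_day / 20 * (min(a, cessation_age) - initiation_age)`,
#' clamped below at 0; never smokers have 0 at every age. Non-decreasing in
#' age and constant after cessation.
#'
#' @param history data.frame/list with `initiation_age`, `cessation_age`,
#'   `cigarettes_per_day` (vectors allowed)
#' @param age age in years, scalar or vector (recycled against history rows)
#' @return numeric vector of pack-years
#' @export
pack_years_at <- function(history, age) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  init <- history$initiation_age
  cess <- history$cessation_age
  cpd <- history$cigarettes_per_day
  end <- pmin(age, ifelse(is.na(cess), Inf, cess))
  py <- cpd / 20 * pmax(0, end - init)
  ifelse(is.na(init), 0, py)
}

#' Smoking status at a given age
#'
#' `current` iff initiation_age <= age < cessation_age (or no cessation),
#' `former` iff age >= cessation_age, else `never`.
#'
#' @inheritParams pack_years_at
#' @return character vector in {"never", "current", "former"}
#' @export
smoker_status_at <- function(history, age) {
  init <- history$initiation_age
  cess <- history$cessation_age
  n <- max(length(init), length(age))
  init <- rep_len(init, n)
  cess <- rep_len(cess, n)
  age <- rep_len(age, n)
  status <- rep("never", n)
  started <- !is.na(init) & age >= init
  status[started] <- "current"
  status[started & !is.na(cess) & age >= cess] <- "former"
  status
}

#' Years since smoking cessation at a given age
#'
#' `age - cessation_age` for former smokers; NA for never and current smokers.
#'
#' @inheritParams pack_years_at
#' @return numeric vector (NA where not a former smoker)
#' @export
quit_years_at <- function(history, age) {
  status <- smoker_status_at(history, age)
  cess <- rep_len(history$cessation_age, length(status))
  age <- rep_len(age, length(status))
  ifelse(status == "former", age - cess, NA_real_)
}

#' Sample age at death from causes other than lung cancer
#'
#' Competing mortality follows a Gompertz baseline hazard
#' `b * exp(g * age)` multiplied by a smoking-status hazard ratio
#' (current > former > never) that switches at the initiation and cessation
#' ages. Sampled by exact piecewise inversion of the cumulative hazard from
#' the person's dedicated substream; capped at
#' `config$population$max_lifespan_age`.
#'
#' @param persons data.frame with `person_id`, `initiation_age`,
#'   `cessation_age` columns
#' @param config full configuration
#' @param master_seed optional seed override
#' @return numeric vector of death ages (years)
#' @export
sample_other_cause_death_age <- function(persons, config, master_seed = NULL) {
  nh <- config$natural_history
  seed <- if (is.null(master_seed)) config$population$master_seed else master_seed
  cap <- config$population$max_lifespan_age
  b <- nh$oc_gompertz_rate
  g <- nh$oc_gompertz_shape

  u <- stream_uniform(seed, persons$person_id, "oc_death")
  target <- -log1p(-u)

  init <- ifelse(is.na(persons$initiation_age), Inf, persons$initiation_age)
  cess <- ifelse(is.na(persons$cessation_age), Inf, persons$cessation_age)
  hr <- c(nh$oc_hr_never, nh$oc_hr_current, nh$oc_hr_former)

  # cumulative hazard of one Gompertz piece [t1, t2] scaled by m
  piece <- function(m, t1, t2) m * b / g * (exp(g * t2) - exp(g * t1))
  # invert m*b/g*(exp(g*a) - exp(g*t1)) = e for a >= t1 (e clamped at 0 so
  # unselected ifelse branches stay finite)
  invert <- function(m, t1, e) log(exp(g * t1) + pmax(e, 0) * g / (b * m)) / g

  h1 <- piece(hr[1], 0, init) # never-smoker piece
  h2 <- piece(hr[2], pmin(init, cess), cess) # current piece (0-length if never)
  age <- ifelse(
    target <= h1,
    invert(hr[1], 0, target),
    ifelse(
      target <= h1 + h2,
      invert(hr[2], init, target - h1),
      invert(hr[3], cess, target - h1 - h2)
    )
  )
  pmin(age, cap)
}
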