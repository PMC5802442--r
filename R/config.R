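#' Default simulation configuration
#'
#' Returns the full nested configuration used by the simulator, with all
#' defaults filled in. Four blocks: `population` (cohort structure and master
#' seed), `smoking` (birth-cohort smoking history generator), `natural_history`
#' (onset, progression, detection, survival, competing mortality) and
#' `screening` (CMS eligibility policy and adherence), plus a `run` block.
#'
#' Defaults describe a US-like multi-birth-cohort population aged 30--84
#' followed 2016--2030, with ever-smoking prevalence declining for later birth
#' cohorts so that the screening-eligible share of the population starts near
#' 6\% and falls toward 3\% over the horizon.
#'
#' @return nested named list (class `lungsim_config`)
#' @export
default_config <- function() {
  cfg <- list(
    population = list(
      start_year = 2016L,
      end_year = 2030L,
      min_age = 30L,
      max_age = 84L,
      n_persons = 100000L,
      person_weight = 1,
      sex_fraction_male = 0.49,
      cohort_growth_rate = 0.005,
      master_seed = 20160L,
      max_lifespan_age = 100,
      birth_years = NULL # optional c(from, to) override (single-cohort mode)
    ),
    smoking = list(
      # probability of ever initiating, logistic in birth year per sex:
      # p(by, sex) = plogis(qlogis(init_prob_1950[sex]) + init_trend*(by-1950))
      init_prob_1950_male = 0.64,
      init_prob_1950_female = 0.50,
      init_trend = -0.075, # per birth year, logit scale; < 0 => declining cohorts
      init_age_mean = 17,
      init_age_sd = 3,
      init_age_min = 11,
      init_age_max = 35,
      cpd_meanlog = 3.0, # cigarettes/day, lognormal (median exp(3) ~ 20/day)
      cpd_sdlog = 0.45,
      cpd_max = 60,
      cess_prob_annual = 0.025 # annual probability of quitting after initiation
    ),
    natural_history = list(
      # lung cancer onset: hazard(age) = onset_base_rate*exp(onset_age_slope*age)*rr
      onset_base_rate = 4.5e-07,
      onset_age_slope = 0.09,
      dose_coef = 1.3, # rr = 1 + dose_coef * cigarettes_per_day while smoking
      quit_decay_rate = 0.05, # excess rr decays exp(-rate * years since quitting)
      histology_probs = c(
        adenocarcinoma = 0.40, squamous = 0.22, large_cell = 0.08,
        small_cell = 0.15, other = 0.15
      ),
      # mean preclinical sojourn (years) in stages I-III; stage IV is absorbing
      sojourn_mean = c(I = 2.5, II = 1.0, III = 1.0),
      small_cell_progression_multiplier = 2.5,
      clinical_detection_rate = c(I = 0.18, II = 0.50, III = 1.20, IV = 2.50),
      cure_fraction = c(I = 0.05, II = 0.03, III = 0.02, IV = 0.005),
      survival_rate = c(I = 0.20, II = 0.35, III = 0.55, IV = 0.95),
      small_cell_cure_multiplier = 0.5, # small cell is less often curable
      small_cell_mortality_multiplier = 1.5, # and kills faster when not cured
      # competing (other-cause) mortality: Gompertz baseline x smoking hazard ratio
      oc_gompertz_rate = 4e-05,
      oc_gompertz_shape = 0.09,
      oc_hr_current = 1.6,
      oc_hr_former = 1.25,
      oc_hr_never = 1.0
    ),
    screening = list(
      min_age = 55L,
      max_age = 77L,
      min_pack_years = 30,
      max_quit_years = 15, # exclusive: exactly 15 quit-years is NOT eligible
      interval = 1L,
      adherence_rate = 0.45,
      start_year = 2016L,
      sensitivity = c(I = 0.85, II = 0.90, III = 0.95, IV = 0.97),
      specificity = 0.90
    ),
    run = list(
      n_replications = 20L
    )
  )
  class(cfg) <- c("lungsim_config", "list")
  cfg
}

#' Load and validate a configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration file, overlays it
#' on [default_config()], rejects unknown keys, and validates every block.
#' Omitted keys take their defaults.
#'
#' @param path path to a YAML/JSON configuration file
#' @return validated configuration (class `lungsim_config`)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file does not exist: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user, path = "config")
  validate_config(cfg)
}

#' Write a configuration to a YAML file
#'
#' @param config configuration list
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # stage-/category-indexed vectors become YAML maps so names survive
  for (f in c(
    "histology_probs", "sojourn_mean", "clinical_detection_rate",
    "cure_fraction", "survival_rate"
  )) {
    cfg$natural_history[[f]] <- as.list(cfg$natural_history[[f]])
  }
  cfg$screening$sensitivity <- as.list(cfg$screening$sensitivity)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

# Overlay user values on defaults, rejecting keys that do not exist.
merge_config <- function(base, user, path) {
  if (!is.list(user)) {
    stop("configuration block '", path, "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop("unknown configuration key: ", path, "$", unknown[[1]], call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
      !nm %in% c("histology_probs", "sojourn_mean", "clinical_detection_rate",
                 "cure_fraction", "survival_rate", "sensitivity")) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], paste0(path, "$", nm))
    } else if (nm %in% c("histology_probs", "sojourn_mean",
                         "clinical_detection_rate", "cure_fraction",
                         "survival_rate", "sensitivity")) {
      base[[nm]] <- unlist(user[[nm]])
    } else if (is.null(user[[nm]])) {
      base[nm] <- list(NULL) # keep explicit-null keys (e.g. birth_years: ~)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

cfg_fail <- function(field, msg) {
  stop("invalid configuration: ", field, " ", msg, call. = FALSE)
}

#' Validate a configuration
#'
#' Checks every type invariant (probabilities in \[0,1\], positive rates,
#' histology mixture summing to 1, cure fractions non-increasing and residual
#' hazards non-decreasing across stages I--IV, year/age bounds). Errors name
#' the offending field.
#'
#' @param config configuration list as from [default_config()]
#' @return the validated configuration, invisibly classed `lungsim_config`
#' @export
validate_config <- function(config) {
  p <- config$population
  if (!is.numeric(p$start_year) || !is.numeric(p$end_year) ||
    p$start_year > p$end_year) {
    cfg_fail("population$start_year/end_year", "must satisfy start_year <= end_year")
  }
  if (p$min_age >= p$max_age) cfg_fail("population$min_age", "must be < max_age")
  if (!is.numeric(p$n_persons) || p$n_persons < 1) {
    cfg_fail("population$n_persons", "must be >= 1")
  }
  if (p$person_weight <= 0) cfg_fail("population$person_weight", "must be > 0")
  if (p$sex_fraction_male < 0 || p$sex_fraction_male > 1) {
    cfg_fail("population$sex_fraction_male", "must be a probability")
  }
  if (p$master_seed < 0) cfg_fail("population$master_seed", "must be non-negative")
  if (p$max_lifespan_age <= p$max_age) {
    cfg_fail("population$max_lifespan_age", "must exceed max_age")
  }
  if (!is.null(p$birth_years)) {
    if (length(p$birth_years) != 2 || p$birth_years[1] > p$birth_years[2]) {
      cfg_fail("population$birth_years", "must be c(from, to) with from <= to")
    }
  }

  s <- config$smoking
  for (f in c("init_prob_1950_male", "init_prob_1950_female", "cess_prob_annual")) {
    if (s[[f]] < 0 || s[[f]] > 1) cfg_fail(paste0("smoking$", f), "must be in [0,1]")
  }
  if (s$init_age_sd <= 0) cfg_fail("smoking$init_age_sd", "must be > 0")
  if (s$init_age_min >= s$init_age_max) {
    cfg_fail("smoking$init_age_min", "must be < init_age_max")
  }
  if (s$cpd_max <= 0) cfg_fail("smoking$cpd_max", "must be > 0")

  nh <- config$natural_history
  if (nh$onset_base_rate < 0) cfg_fail("natural_history$onset_base_rate", "must be >= 0")
  if (abs(sum(nh$histology_probs) - 1) > 1e-9) {
    cfg_fail("natural_history$histology_probs", "must sum to 1")
  }
  if (any(nh$histology_probs < 0)) {
    cfg_fail("natural_history$histology_probs", "must be non-negative")
  }
  if (length(nh$histology_probs) != 5) {
    cfg_fail("natural_history$histology_probs", "must have 5 categories")
  }
  if (any(nh$sojourn_mean <= 0) || length(nh$sojourn_mean) != 3) {
    cfg_fail("natural_history$sojourn_mean", "must be 3 positive stage means (I-III)")
  }
  if (any(nh$clinical_detection_rate < 0) || length(nh$clinical_detection_rate) != 4) {
    cfg_fail("natural_history$clinical_detection_rate", "must be 4 non-negative rates")
  }
  if (any(nh$cure_fraction < 0 | nh$cure_fraction > 1)) {
    cfg_fail("natural_history$cure_fraction", "must be probabilities")
  }
  if (is.unsorted(rev(nh$cure_fraction))) {
    cfg_fail("natural_history$cure_fraction", "must be non-increasing from stage I to IV")
  }
  if (any(nh$survival_rate <= 0) || is.unsorted(nh$survival_rate)) {
    cfg_fail(
      "natural_history$survival_rate",
      "must be positive and non-decreasing from stage I to IV (comonotone coupling)"
    )
  }
  if (nh$small_cell_cure_multiplier < 0 || nh$small_cell_cure_multiplier > 1) {
    cfg_fail("natural_history$small_cell_cure_multiplier", "must be in [0,1]")
  }
  if (nh$small_cell_mortality_multiplier < 1) {
    cfg_fail("natural_history$small_cell_mortality_multiplier", "must be >= 1")
  }
  if (nh$oc_gompertz_rate <= 0 || nh$oc_gompertz_shape <= 0) {
    cfg_fail("natural_history$oc_gompertz_rate", "Gompertz parameters must be > 0")
  }
  if (nh$oc_hr_current < nh$oc_hr_former || nh$oc_hr_former < nh$oc_hr_never) {
    cfg_fail("natural_history$oc_hr_current", "hazard ratios must order current >= former >= never")
  }

  sc <- config$screening
  if (sc$min_age > sc$max_age) cfg_fail("screening$min_age", "must be <= max_age")
  if (sc$adherence_rate < 0 || sc$adherence_rate > 1) {
    cfg_fail("screening$adherence_rate", "must be in [0,1]")
  }
  if (any(sc$sensitivity < 0 | sc$sensitivity > 1) || length(sc$sensitivity) != 4) {
    cfg_fail("screening$sensitivity", "must be 4 stage-specific probabilities")
  }
  if (sc$specificity < 0 || sc$specificity > 1) {
    cfg_fail("screening$specificity", "must be a probability")
  }
  if (sc$min_pack_years < 0) cfg_fail("screening$min_pack_years", "must be >= 0")
  if (sc$max_quit_years <= 0) cfg_fail("screening$max_quit_years", "must be > 0")

  r <- config$run
  if (r$n_replications < 1) cfg_fail("run$n_replications", "must be >= 1")

  class(config) <- c("lungsim_config", "list")
  invisible(config)
}

# Birth-year span implied by a configuration.
birth_year_span <- function(config) {
  p <- config$population
  if (!is.null(p$birth_years)) {
    return(as.integer(p$birth_years[1]:p$birth_years[2]))
  }
  as.integer((p$start_year - p$max_age):(p$end_year - p$min_age))
}
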