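# Lung cancer natural history: smoking-dependent onset, histology, preclinical
# stage progression with clinical detection, and cure-mixture survival.
#
# Onset hazard at age a:
#   h(a) = onset_base_rate * exp(onset_age_slope * a) * rr(a)
# with relative risk rr(a) = 1 before initiation, 1 + dose_coef * cpd while
# smoking, and 1 + dose_coef * cpd * exp(-quit_decay_rate * (a - cess)) after
# cessation. The cumulative hazard is closed-form piecewise; onset ages are
# drawn by inverting it at an exponential target (vectorized bisection).

HISTOLOGIES <- c("adenocarcinoma", "squamous", "large_cell", "small_cell", "other")
STAGES <- c("I", "II", "III", "IV")

# Cumulative onset hazard H(a) for each person (vectorized over persons; `age`
# may be scalar or per-person).
onset_cumhaz <- function(age, init, cess, cpd, nh) {
  c0 <- nh$onset_base_rate
  c1 <- nh$onset_age_slope
  beta <- nh$dose_coef
  delta <- nh$quit_decay_rate
  init <- ifelse(is.na(init), Inf, init)
  cess <- ifelse(is.na(cess), Inf, cess)
  excess <- ifelse(is.finite(init), beta * cpd, 0)
  excess[is.na(excess)] <- 0

  base_int <- function(t1, t2) c0 / c1 * (exp(c1 * pmax(t2, t1)) - exp(c1 * t1))
  # integral of the decaying excess term from cess to t (t >= cess)
  decay_int <- function(t) {
    lo <- pmin(cess, t)
    if (abs(c1 - delta) < 1e-12) {
      excess * c0 * exp(delta * lo) * (pmax(t, lo) - lo)
    } else {
      excess * c0 * exp(delta * lo) / (c1 - delta) *
        (exp((c1 - delta) * pmax(t, lo)) - exp((c1 - delta) * lo))
    }
  }

  h <- base_int(0, pmin(age, init)) # never-smoking segment
  h <- h + (1 + excess) * base_int(pmin(init, age), pmin(cess, age)) # active smoking
  post <- is.finite(cess) & age > cess
  if (any(post)) {
    extra <- base_int(cess, age) + decay_int(age)
    h[post] <- h[post] + extra[post]
  }
  h
}

#' Sample the age of latent lung cancer onset
#'
#' Inverts the person-specific cumulative onset hazard at an exponential
#' target drawn from the person's onset substream. Returns NA when no onset
#' occurs before the lifespan cap. Never smokers face the baseline hazard
#' only; the smoking excess decays exponentially after cessation.
#'
#' @param history data.frame with `initiation_age`, `cessation_age`,
#'   `cigarettes_per_day` (one row per person)
#' @param config full configuration
#' @param master_seed seed (defaults to the configured master seed)
#' @param person_id integer ids (default `seq_len(nrow(history))`)
#' @return numeric vector of onset ages (NA = no onset within lifespan)
#' @export
sample_onset_age <- function(history, config, master_seed = NULL,
                             person_id = seq_len(nrow(history))) {
  nh <- config$natural_history
  seed <- if (is.null(master_seed)) config$population$master_seed else master_seed
  cap <- config$population$max_lifespan_age
  u <- stream_uniform(seed, person_id, "onset")
  target <- -log1p(-u)

  init <- history$initiation_age
  cess <- history$cessation_age
  cpd <- history$cigarettes_per_day

  h_cap <- onset_cumhaz(cap, init, cess, cpd, nh)
  has_onset <- target < h_cap

  # vectorized bisection on [0, cap]; the cumulative hazard is continuous and
  # strictly increasing wherever the baseline rate is positive
  lo <- rep(0, length(target))
  hi <- rep(cap, length(target))
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    below <- onset_cumhaz(mid, init, cess, cpd, nh) < target
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  ifelse(has_onset, (lo + hi) / 2, NA_real_)
}

#' Assign a histologic type to an onset
#'
#' Categorical draw over adenocarcinoma (including in situ), squamous cell,
#' large cell, small cell and other, from the configured mixture.
#'
#' @param config full configuration (uses `natural_history$histology_probs`)
#' @param master_seed seed
#' @param person_id integer ids of persons with an onset
#' @return character vector of histologies
#' @export
assign_histology <- function(config, master_seed = NULL, person_id) {
  nh <- config$natural_history
  probs <- nh$histology_probs
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("invalid configuration: natural_history$histology_probs must sum to 1",
      call. = FALSE
    )
  }
  seed <- if (is.null(master_seed)) config$population$master_seed else master_seed
  u <- stream_uniform(seed, person_id, "histology")
  HISTOLOGIES[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
}

#' Simulate the preclinical course of a tumor
#'
#' From onset, the tumor enters stage I and progresses I -> II -> III -> IV
#' with exponentially distributed stage sojourns (stage IV is absorbing).
#' Within each stage a stage-specific clinical-detection hazard competes with
#' progression; the first detection event fixes the clinical detection age and
#' stage. Small cell tumors progress faster via a rate multiplier.
#'
#' @param onset_age numeric vector of onset ages
#' @param histology character vector of histologies
#' @param config full configuration
#' @param master_seed seed
#' @param person_id integer ids
#' @return data.frame with `entry_I` .. `entry_IV` (stage entry ages; NA once
#'   unreachable is impossible here, entries are always defined),
#'   `clin_detect_age` (Inf if never clinically detected) and `clin_stage`
#'   (integer 1-4, NA if never detected)
#' @export
sample_preclinical_course <- function(onset_age, histology, config,
                                      master_seed = NULL,
                                      person_id = seq_along(onset_age)) {
  nh <- config$natural_history
  seed <- if (is.null(master_seed)) config$population$master_seed else master_seed
  n <- length(onset_age)
  mult <- ifelse(histology == "small_cell", nh$small_cell_progression_multiplier, 1)
  prog_rate <- cbind(
    mult / nh$sojourn_mean[[1]],
    mult / nh$sojourn_mean[[2]],
    mult / nh$sojourn_mean[[3]],
    0 # stage IV absorbing
  )
  det_rate <- nh$clinical_detection_rate

  entry <- matrix(NA_real_, n, 4)
  entry[, 1] <- onset_age
  detect_age <- rep(Inf, n)
  detect_stage <- rep(NA_integer_, n)
  for (k in 1:4) {
    u_s <- stream_uniform(seed, person_id, "sojourn", counter = k)
    u_d <- stream_uniform(seed, person_id, "clin_detect", counter = k)
    sojourn <- ifelse(prog_rate[, k] > 0, -log1p(-u_s) / prog_rate[, k], Inf)
    t_det <- if (det_rate[[k]] > 0) -log1p(-u_d) / det_rate[[k]] else Inf
    hit <- is.na(detect_stage) & t_det < sojourn
    detect_age[hit] <- entry[hit, k] + t_det[hit]
    detect_stage[hit] <- k
    if (k < 4) entry[, k + 1] <- entry[, k] + sojourn
  }
  out <- as.data.frame(entry)
  names(out) <- paste0("entry_", STAGES)
  out$clin_detect_age <- detect_age
  out$clin_stage <- detect_stage
  out
}

# Preclinical stage occupied at a given age (vectorized); NA if before onset.
stage_at_age <- function(course, age) {
  s <- rep(NA_integer_, nrow(course))
  for (k in 1:4) {
    ek <- course[[paste0("entry_", STAGES[k])]]
    s[!is.na(ek) & ek <= age] <- k
  }
  s
}

#' Lung cancer death age from a cure-mixture survival model
#'
#' Post-diagnosis survival is a mixture of cure (stage-specific probability)
#' and an exponential residual. The death age is the inverse survival function
#' evaluated at a shared per-person quantile:
#' with `S(t) = cure + (1 - cure) * exp(-rate * t)`, the residual time is
#' `-log((1 - q - cure) / (1 - cure)) / rate` when `1 - q > cure`, else the
#' person is cured (no lung cancer death). Because cure fractions are
#' non-increasing and residual rates non-decreasing from stage I to IV, this
#' mapping is comonotone: at a fixed quantile an earlier stage never yields an
#' earlier death — the sole mechanism by which screening confers benefit.
#'
#' @param stage_at_detection integer 1-4 (stage I-IV), vectorized
#' @param histology character vector (small cell has reduced cure and faster
#'   residual mortality)
#' @param detection_age age at diagnosis (years)
#' @param config full configuration
#' @param survival_quantile per-person quantile in `[0, 1)` from the survival
#'   substream
#' @return numeric death age, Inf when cured
#' @export
sample_lc_death_age <- function(stage_at_detection, histology, detection_age,
                                config, survival_quantile) {
  if (any(survival_quantile < 0 | survival_quantile >= 1)) {
    stop("survival_quantile must lie in [0, 1)", call. = FALSE)
  }
  nh <- config$natural_history
  n <- max(
    length(stage_at_detection), length(histology), length(detection_age),
    length(survival_quantile)
  )
  stage_at_detection <- rep_len(stage_at_detection, n)
  histology <- rep_len(histology, n)
  detection_age <- rep_len(detection_age, n)
  survival_quantile <- rep_len(survival_quantile, n)
  cure <- nh$cure_fraction[stage_at_detection]
  rate <- nh$survival_rate[stage_at_detection]
  small <- histology == "small_cell"
  cure <- ifelse(small, cure * nh$small_cell_cure_multiplier, cure)
  rate <- ifelse(small, rate * nh$small_cell_mortality_multiplier, rate)

  surv_target <- 1 - survival_quantile # survival level at which death occurs
  cured <- surv_target <= cure
  resid <- -log(pmax(surv_target - cure, 0) / (1 - cure)) / rate
  ifelse(cured, Inf, detection_age + resid)
}
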