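# CMS low-dose CT screening program: eligibility, fixed per-person adherence,
# and annual exams with stage-dependent sensitivity.

#' CMS screening eligibility
#'
#' True iff `min_age <= age <= max_age` (inclusive on both ends), accumulated
#' pack-years are at least `min_pack_years` (exactly 30 is eligible), and the
#' person is a current smoker or a former smoker strictly fewer than
#' `max_quit_years` years since quitting (exactly 15 quit-years is not
#' eligible). Never smokers are never eligible.
#'
#' @param history data.frame/list with `initiation_age`, `cessation_age`,
#'   `cigarettes_per_day`
#' @param age age in years (vectorized)
#' @param policy `screening` block of the configuration
#' @return logical vector
#' @export
is_eligible <- function(history, age, policy) {
  status <- smoker_status_at(history, age)
  py <- pack_years_at(history, age)
  qy <- quit_years_at(history, age)
  age >= policy$min_age & age <= policy$max_age &
    py >= policy$min_pack_years &
    (status == "current" | (status == "former" & qy < policy$max_quit_years))
}

#' Adherence assignment by threshold coupling
#'
#' A person is adherent iff their fixed `adherence_uniform` draw is below the
#' policy adherence rate. Thresholding one per-person uniform makes adherent
#' sets nested across rates: everyone adherent at 25\% is also adherent at
#' 45\%, which is what makes the adherence sweep monotone on one population.
#'
#' @param persons data.frame with `adherence_uniform`
#' @param policy `screening` block (uses `adherence_rate`)
#' @return logical vector
#' @export
assign_adherent <- function(persons, policy) {
  persons$adherence_uniform < policy$adherence_rate
}

# Vectorized annual screening pass over a whole population.
#
# For each calendar year in [max(policy$start_year, start_year), end_year] an
# adherent, alive, eligible, not-yet-diagnosed person receives one CT exam at
# the start of the year (before that year's clinical detection and deaths). If
# a tumor is in its preclinical phase the exam detects it with the
# stage-specific sensitivity, using the person's screen-detection substream
# indexed by year. Returns per-person exam counts, exam-year bitmaps and the
# first screen-detection event.
#
# `alive_age`: age before which the person is alive for exam purposes (other
# cause death; lung-cancer death cannot precede diagnosis).
run_screens <- function(persons, course, policy, config, master_seed,
                        adherent = NULL) {
  n <- nrow(persons)
  p <- config$population
  seed <- master_seed
  if (is.null(adherent)) adherent <- assign_adherent(persons, policy)
  years <- seq.int(max(policy$start_year, p$start_year), p$end_year)

  exams <- integer(n)
  exam_years <- matrix(FALSE, n, length(years))
  det_age <- rep(Inf, n)
  det_stage <- rep(NA_integer_, n)
  onset <- course$entry_I
  clin_det <- course$clin_detect_age
  oc_death <- persons$oc_death_age

  hist <- persons[c("initiation_age", "cessation_age", "cigarettes_per_day")]
  for (j in seq_along(years)) {
    y <- years[j]
    age <- y - persons$birth_year
    open <- adherent &
      age < oc_death & # alive at the start-of-year exam date
      clin_det > age & # not already clinically diagnosed
      !is.finite(det_age) & # not already screen-detected
      is_eligible(hist, age, policy)
    if (!any(open)) next
    exams[open] <- exams[open] + 1L
    exam_years[open, j] <- TRUE

    present <- open & !is.na(onset) & onset <= age
    if (any(present)) {
      stage <- stage_at_age(course, age)
      u <- stream_uniform(seed, persons$person_id, "screen_detect", counter = j)
      hit <- present & u < policy$sensitivity[ifelse(is.na(stage), 1L, stage)]
      det_age[hit] <- age[hit]
      det_stage[hit] <- stage[hit]
    }
  }
  list(
    exams = exams, exam_years = exam_years, years = years,
    screen_detect_age = det_age, screen_detect_stage = det_stage
  )
}

#' Run the annual screening schedule for one person
#'
#' Thin per-person wrapper over the vectorized screening pass: one exam per
#' calendar year while the person is adherent, alive, eligible under the CMS
#' criteria and not yet diagnosed; detection succeeds with the stage-specific
#' sensitivity. Nonadherent persons receive no exams.
#'
#' @param person one-row data.frame with `person_id`, `birth_year`,
#'   `initiation_age`, `cessation_age`, `cigarettes_per_day`,
#'   `adherence_uniform`, `oc_death_age`
#' @param course one-row preclinical course from [sample_preclinical_course()]
#'   or NULL if the person never develops a tumor
#' @param policy `screening` block
#' @param config full configuration
#' @param master_seed seed
#' @return data.frame of exams (`year`, `age`, `result`, `stage`); zero rows
#'   if never screened
#' @export
run_screens_for_person <- function(person, course, policy, config,
                                   master_seed = NULL) {
  seed <- if (is.null(master_seed)) config$population$master_seed else master_seed
  if (is.null(course)) {
    course <- data.frame(
      entry_I = NA_real_, entry_II = NA_real_, entry_III = NA_real_,
      entry_IV = NA_real_, clin_detect_age = Inf, clin_stage = NA_integer_
    )
  }
  res <- run_screens(person, course, policy, config, seed)
  j <- which(res$exam_years[1, ])
  if (length(j) == 0) {
    return(data.frame(
      year = integer(), age = numeric(), result = character(),
      stage = character(), stringsAsFactors = FALSE
    ))
  }
  yrs <- res$years[j]
  ages <- yrs - person$birth_year
  detected <- is.finite(res$screen_detect_age[1]) & ages == res$screen_detect_age[1]
  data.frame(
    year = yrs,
    age = ages,
    result = ifelse(detected, "screen-detected cancer", "negative"),
    stage = ifelse(detected, STAGES[res$screen_detect_stage[1]], NA_character_),
    stringsAsFactors = FALSE
  )
}
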