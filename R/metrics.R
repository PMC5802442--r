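# Outcome metrics, each implemented exactly as defined for population
# screening evaluation: mortality reduction, deaths avoided, life-years
# gained, overdiagnosis (counterfactual cause-of-death definition and the
# Patz excess-diagnosis rate), stratum shares and percent declines.
# Percentages are reported to 2 decimals, rounding half away from zero.

#' Round half away from zero
#'
#' @param x numeric vector
#' @param digits decimal places (default 2)
#' @return rounded vector
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Lung cancer mortality reduction
#'
#' The difference in lung cancer deaths between the no-screening and
#' screening scenarios (deaths avoided), divided by the deaths in the
#' no-screening scenario, as a percentage to 2 decimals.
#'
#' @param deaths_avoided lung cancer deaths avoided by screening
#' @param deaths_no_screen lung cancer deaths in the no-screening scenario
#'   (must be > 0)
#' @return percent, rounded to 2 decimals
#' @export
mortality_reduction <- function(deaths_avoided, deaths_no_screen) {
  if (any(deaths_no_screen <= 0)) {
    stop("mortality reduction undefined: no-screening deaths must be > 0",
      call. = FALSE
    )
  }
  round_half_up(100 * deaths_avoided / deaths_no_screen, 2)
}

#' Mortality reduction within the screened population
#'
#' Restricted to persons screened at least once in the screening scenario
#' (identified by the common-random-numbers pairing): numerator is the deaths
#' avoided among them, denominator their no-screening-scenario lung cancer
#' deaths within the horizon.
#'
#' @param pairs paired person-level log from [simulate_pairs()] /
#'   `run_replication()$pairs`
#' @param config the configuration the log was produced under
#' @return percent, rounded to 2 decimals
#' @export
screened_population_mortality_reduction <- function(pairs, config) {
  screened <- pairs$s_exams > 0
  if (!any(screened)) {
    stop("screened-population mortality reduction undefined: nobody was screened",
      call. = FALSE
    )
  }
  p <- config$population
  w <- pairs$weight
  in_h <- function(death_age, cause) {
    dy <- floor(pairs$birth_year + death_age)
    screened & cause == "lung_cancer" & dy >= p$start_year & dy <= p$end_year
  }
  d_ns <- sum(w[in_h(pairs$ns_death_age, pairs$ns_death_cause)])
  d_s <- sum(w[in_h(pairs$s_death_age, pairs$s_death_cause)])
  if (d_ns <= 0) {
    stop("screened-population mortality reduction undefined: no lung cancer deaths",
      call. = FALSE
    )
  }
  round_half_up(100 * (d_ns - d_s) / d_ns, 2)
}

#' Life-years gained by screening through the horizon
#'
#' Weighted sum over persons of the difference in life-years lived within the
#' observation window between the screening and no-screening scenarios.
#' Non-negative per person under the comonotone survival coupling.
#'
#' @inheritParams screened_population_mortality_reduction
#' @return life-years (numeric)
#' @export
life_years_gained <- function(pairs, config) {
  sum(pairs$weight * (pairs$s_life_years - pairs$ns_life_years))
}

#' Overdiagnosis count (counterfactual cause-of-death definition)
#'
#' An overdiagnosed case is a person who is screened, subsequently diagnosed
#' with lung cancer via screening, and eventually dies of causes other than
#' lung cancer (follow-up extends to death, past the reporting horizon).
#'
#' @inheritParams screened_population_mortality_reduction
#' @return list with `count`, `screen_detected`, `deaths_avoided`,
#'   `per_100_deaths_avoided` and `rate_pct` (percent of screen-detected
#'   diagnoses), rates rounded to 2 decimals
#' @export
overdiagnosis_def1 <- function(pairs, config) {
  w <- pairs$weight
  count <- sum(w[pairs$s_diag_mode %in% "screen" & pairs$s_death_cause == "other"])
  screen_detected <- sum(w[pairs$s_diag_mode %in% "screen"])
  p <- config$population
  lung_in_h <- function(death_age, cause) {
    dy <- floor(pairs$birth_year + death_age)
    cause == "lung_cancer" & dy >= p$start_year & dy <= p$end_year
  }
  avoided <- sum(w[lung_in_h(pairs$ns_death_age, pairs$ns_death_cause)]) -
    sum(w[lung_in_h(pairs$s_death_age, pairs$s_death_cause)])
  c(
    list(count = count, screen_detected = screen_detected, deaths_avoided = avoided),
    overdiagnosis_rates(count, avoided, screen_detected)
  )
}

#' Overdiagnosis rates from aggregate counts
#'
#' @param overdiagnoses overdiagnosed case count
#' @param deaths_avoided total deaths avoided
#' @param screen_detected total screen-detected diagnoses
#' @return list with `per_100_deaths_avoided` and `rate_pct`, each to 2
#'   decimals (NA where the denominator is 0)
#' @export
overdiagnosis_rates <- function(overdiagnoses, deaths_avoided, screen_detected) {
  list(
    per_100_deaths_avoided = if (deaths_avoided > 0) {
      round_half_up(100 * overdiagnoses / deaths_avoided, 2)
    } else {
      NA_real_
    },
    rate_pct = if (screen_detected > 0) {
      round_half_up(100 * overdiagnoses / screen_detected, 2)
    } else {
      NA_real_
    }
  )
}

#' Excess diagnosis rate (screening-arm excess over control)
#'
#' Difference in lung cancer cases between the screening arm and the control
#' arm, divided by total diagnoses in the screening arm, as a percentage.
#' Here the control arm is the no-screening scenario.
#'
#' @param screen_cases lung cancer cases in the screening arm
#' @param control_cases lung cancer cases in the control arm
#' @param screen_total_diagnoses total lung cancer diagnoses in the screening
#'   arm (must be > 0)
#' @return percent, rounded to 2 decimals
#' @export
excess_diagnosis_rate <- function(screen_cases, control_cases,
                                  screen_total_diagnoses) {
  if (any(screen_total_diagnoses <= 0)) {
    stop("excess diagnosis rate undefined: screening-arm diagnoses must be > 0",
      call. = FALSE
    )
  }
  round_half_up(100 * (screen_cases - control_cases) / screen_total_diagnoses, 2)
}

#' Percent shares of strata in a total
#'
#' `100 * count / total` to 2 decimals; shares of a partition sum to 100 up
#' to rounding.
#'
#' @param counts named numeric vector of stratum counts
#' @param total denominator (default `sum(counts)`, must be > 0)
#' @return numeric vector of percents
#' @export
share_decomposition <- function(counts, total = sum(counts)) {
  if (total <= 0) stop("share undefined: total must be > 0", call. = FALSE)
  round_half_up(100 * counts / total, 2)
}

#' Percent decline from a first to a last value
#'
#' `100 * (first - last) / first` to 2 decimals.
#'
#' @param first initial value (must be > 0)
#' @param last final value
#' @return percent decline (negative if the series grew)
#' @export
percent_change <- function(first, last) {
  if (any(first <= 0)) {
    stop("percent change undefined: first value must be > 0", call. = FALSE)
  }
  round_half_up(100 * (first - last) / first, 2)
}
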