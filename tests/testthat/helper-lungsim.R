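# Shared fixtures: all test inputs are built in code.

small_config <- function(n = 2000L, seed = 11L) {
  cfg <- default_config()
  cfg$population$n_persons <- as.integer(n)
  cfg$population$master_seed <- as.integer(seed)
  cfg
}

# a bare smoking history (vectors recycle)
hist_df <- function(init = NA_real_, cess = NA_real_, cpd = NA_real_) {
  data.frame(
    initiation_age = init, cessation_age = cess, cigarettes_per_day = cpd
  )
}

# a fully specified person row bypassing the population generator
person_row <- function(person_id = 1L, sex = "male", birth_year = 1955L,
                       init = 18, cess = NA_real_, cpd = 20,
                       adherence_uniform = 0, oc_death_age = 100,
                       weight = 1) {
  data.frame(
    person_id = as.integer(person_id), sex = sex,
    birth_year = as.integer(birth_year),
    initiation_age = init, cessation_age = cess, cigarettes_per_day = cpd,
    adherence_uniform = adherence_uniform, weight = weight,
    oc_death_age = oc_death_age, stringsAsFactors = FALSE
  )
}

# deterministic preclinical course row for screening tests
course_row <- function(entry = c(60, 62, 63, 64), clin_detect = 66,
                       clin_stage = 4L) {
  data.frame(
    entry_I = entry[1], entry_II = entry[2], entry_III = entry[3],
    entry_IV = entry[4], clin_detect_age = clin_detect,
    clin_stage = as.integer(clin_stage)
  )
}
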