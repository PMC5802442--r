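#' @useDynLib lungsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Named random substreams. Each person's draw for a given (stream, counter) is
# a pure function of (master_seed, person_id, stream, counter), so the tumor
# process, competing mortality and survival quantile are identical across
# scenarios (common random numbers) and nested-adherence sweeps reuse the same
# adherence draw.
STREAMS <- c(
  birth_year = 1L,
  sex = 2L,
  smoke_init = 3L,
  smoke_init_age = 4L,
  smoke_cpd = 5L,
  smoke_cess = 6L,
  adherence = 7L,
  oc_death = 8L,
  onset = 9L,
  histology = 10L,
  sojourn = 11L, # counter = stage
  clin_detect = 12L, # counter = stage
  survival = 13L,
  screen_detect = 14L # counter = screening-year index
)

#' Uniform draws from a person's named random substream
#'
#' Deterministic keyed uniforms underlying every stochastic component.
#' Substreams are indexed by name; repeated draws within a substream (stages,
#' screening years) use `counter`.
#'
#' @param master_seed non-negative integer seed
#' @param person_id integer vector of person ids
#' @param stream substream name (one of `names(lungsim:::STREAMS)`)
#' @param counter integer draw index within the substream (scalar or vector)
#' @return numeric vector of uniforms in `[0, 1)`
#' @examples
#' stream_uniform(1, 1:3, "onset")
#' @export
stream_uniform <- function(master_seed, person_id, stream, counter = 1L) {
  code <- STREAMS[[stream]]
  if (is.null(code)) stop("unknown substream: ", stream, call. = FALSE)
  substream_uniform(
    as.double(master_seed), as.integer(person_id), code, as.integer(counter)
  )
}
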