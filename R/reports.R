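# Report writing: CSV tables mirroring the standard reporting surfaces
# (annual screens by smoker type, annual/cumulative mortality reduction,
# deaths avoided by 5-year period, overdiagnosis panel), a JSON metrics
# summary and a run manifest.

#' Write simulation reports to a directory
#'
#' Writes, from a completed [run_simulation()] result:
#' \itemize{
#'   \item `annual_aggregates.csv` — per-year, per-scenario means (and CI
#'     bounds) of all annual aggregates;
#'   \item `screens_by_smoker_type.csv` — annual screens, split current/former;
#'   \item `mortality_reduction.csv` — annual and cumulative mortality
#'     reduction series;
#'   \item `deaths_avoided_periods.csv` — deaths avoided by 5-year period
#'     (periods partition the horizon; columns sum to the cumulative total);
#'   \item `overdiagnosis.csv` — overdiagnosis panel;
#'   \item `summary.json` — scalar metrics with means and CIs;
#'   \item `manifest.json` — config hash, seeds, package version, inventory.
#' }
#' Reruns with the same configuration and seed are byte-identical apart from
#' the manifest timestamp field.
#'
#' @param sim `lungsim_simulation` object
#' @param out_dir output directory (created if needed)
#' @return invisible character vector of files written
#' @export
write_reports <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  files <- character()
  summ <- sim$summary
  if (is.null(summ)) summ <- list(annual = sim$replications[[1]]$annual)
  ann <- summ$annual

  path <- function(f) file.path(out_dir, f)
  wcsv <- function(df, f) {
    utils::write.csv(df, path(f), row.names = FALSE)
    files <<- c(files, f)
  }

  wcsv(ann, "annual_aggregates.csv")

  sc <- ann[ann$scenario == "screen", ]
  ns <- ann[ann$scenario == "no_screen", ]
  wcsv(data.frame(
    year = sc$year,
    screens_total = sc$screens,
    screens_current = sc$screens_current,
    screens_former = sc$screens_former
  ), "screens_by_smoker_type.csv")

  cum_ns <- cumsum(ns$lc_deaths)
  cum_s <- cumsum(sc$lc_deaths)
  wcsv(data.frame(
    year = sc$year,
    lc_deaths_no_screen = ns$lc_deaths,
    lc_deaths_screen = sc$lc_deaths,
    annual_mr_pct = ifelse(ns$lc_deaths > 0,
      round_half_up(100 * (ns$lc_deaths - sc$lc_deaths) / ns$lc_deaths, 2), 0
    ),
    cumulative_mr_pct = ifelse(cum_ns > 0,
      round_half_up(100 * (cum_ns - cum_s) / cum_ns, 2), 0
    )
  ), "mortality_reduction.csv")

  # deaths avoided by period: partition the horizon into up to 3 equal spans
  years <- sc$year
  n_per <- if (length(years) %% 3 == 0) 3 else 1
  per_id <- rep(seq_len(n_per), each = length(years) / n_per)
  avoided_y <- ns$lc_deaths - sc$lc_deaths
  periods <- vapply(
    split(avoided_y, per_id), sum, numeric(1)
  )
  labels <- vapply(split(years, per_id), function(y) {
    paste0(min(y), "-", max(y))
  }, character(1))
  wcsv(data.frame(
    period = c(labels, "cumulative"),
    deaths_avoided = c(periods, sum(periods))
  ), "deaths_avoided_periods.csv")

  m <- summ$metrics
  pick <- function(name, col = "mean") m[m$metric == name, col]
  wcsv(data.frame(
    overdiagnoses = pick("overdiagnoses"),
    screen_detected = pick("screen_detected"),
    deaths_avoided = pick("deaths_avoided"),
    per_100_deaths_avoided = round_half_up(
      100 * pick("overdiagnoses") / pick("deaths_avoided"), 2
    ),
    rate_pct = round_half_up(
      100 * pick("overdiagnoses") / pick("screen_detected"), 2
    )
  ), "overdiagnosis.csv")

  jsonlite::write_json(
    summ$metrics, path("summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  files <- c(files, "summary.json")

  cfg_file <- path("config.yaml")
  write_config(sim$config, cfg_file)
  files <- c(files, "config.yaml")
  manifest <- list(
    package_version = as.character(utils::packageVersion("lungsim")),
    master_seed = sim$master_seed,
    replication_seeds = vapply(sim$replications, function(r) r$seed, numeric(1)),
    config_hash = unname(tools::md5sum(cfg_file)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = files
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  files <- c(files, "manifest.json")
  invisible(file.path(out_dir, files))
}
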