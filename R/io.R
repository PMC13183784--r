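# Tidy CSV persistence for experiment logs, plus a machine-readable run
# manifest.

#' Write experiment logs to tidy CSV tables
#'
#' Writes \code{census.csv}, \code{deaths.csv}, \code{harvests.csv},
#' \code{cohorts.csv}, \code{popsize.csv} and a JSON run manifest
#' (\code{manifest.json}: configuration echo, plan, seeds, package version)
#' into \code{dir}.
#'
#' @param logs an \code{experiment_logs} object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_experiment_csv <- function(logs, dir) {
  stopifnot(inherits(logs, "experiment_logs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in c("census", "deaths", "harvests", "cohorts", "popsize")) {
    utils::write.csv(logs[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "harvestlab",
    version = as.character(utils::packageVersion("harvestlab")),
    master_seed = logs$plan$master_seed,
    replicates = logs$plan$replicates,
    phases = logs$plan$phases,
    config = unclass(logs$config),
    populations = logs$populations)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read experiment logs back from CSV tables
#'
#' Reconstructs an \code{experiment_logs} object from a directory written by
#' \code{\link{write_experiment_csv}} (or any directory of schema-compatible
#' tidy tables). Summaries of the reloaded object equal summaries of the
#' in-memory one.
#'
#' @param dir directory containing the CSV tables and manifest.
#' @return an \code{experiment_logs} object.
#' @export
read_experiment_csv <- function(dir) {
  read1 <- function(name, required = TRUE) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) {
      if (required) stop("missing table: ", f, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  out <- list(
    census = read1("census"),
    deaths = read1("deaths"),
    harvests = read1("harvests"),
    cohorts = read1("cohorts"),
    popsize = read1("popsize"))
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    cfg <- manifest$config
    out$config <- tryCatch(
      sim_config(regime = cfg$regime,
                 harvest_proportion_P = cfg$harvest_proportion_P,
                 size_threshold_mm = cfg$size_threshold_mm,
                 cycle_weeks = cfg$cycle_weeks,
                 census_fraction = cfg$census_fraction,
                 n_initial = cfg$n_initial,
                 mu_nat_week = cfg$mu_nat_week,
                 growth_params = as.list(cfg$growth_params),
                 maturation_params = as.list(cfg$maturation_params),
                 fecundity_params = as.list(cfg$fecundity_params),
                 newborn_length_mm = cfg$newborn_length_mm,
                 food_ration = cfg$food_ration,
                 gamma_growth = cfg$gamma_growth,
                 gamma_mort = cfg$gamma_mort,
                 food_factor_max = cfg$food_factor_max,
                 init_age_max_weeks = cfg$init_age_max_weeks,
                 seed = cfg$seed),
      error = function(e) sim_config())
    out$plan <- experiment_plan(replicates = manifest$replicates,
                                master_seed = manifest$master_seed,
                                phases = manifest$phases)
    out$populations <- manifest$populations
  } else {
    out$config <- sim_config()
  }
  structure(out, class = "experiment_logs")
}

#' Write summary tables to CSV
#'
#' One CSV per metric table, named \code{<metric>.csv}.
#'
#' @param summary an \code{experiment_summary}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_summary_csv <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(summary)) {
    tab <- summary[[nm]]
    if (is.data.frame(tab) && nrow(tab) > 0L) {
      utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
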