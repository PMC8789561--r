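#' File interchange and run configuration
#'
#' All pipeline artifacts are plain CSV. Rates are always stored per 1000
#' livebirths; observation reference dates are decimal mid-year values
#' (e.g. 1990.5), while estimate and death tables use integer calendar
#' years.
#'
#' @name interface
NULL

.SOURCE_TYPES <- c("VR", "SRS", "survey_FBH", "census_SBH")
.OBS_COLUMNS <- c("country", "year", "indicator", "value", "se_log",
                  "series_id", "source_type")

#' Read and validate an observation CSV
#'
#' Expects columns country, year (decimal reference date), indicator
#' ("U5MR" or "NMR"), value (rate per 1000), se_log (log-scale standard
#' error), series_id, source_type. Malformed rows are reported with their
#' line numbers.
#'
#' @param path CSV file path.
#' @return validated data frame of observation records.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.OBS_COLUMNS, names(df))
  if (length(missing)) {
    stop("observation file ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(df$value) | df$value <= 0 |
                 !is.finite(df$se_log) | df$se_log < 0 |
                 !df$indicator %in% c("U5MR", "NMR") |
                 !df$source_type %in% .SOURCE_TYPES |
                 !is.finite(df$year) | df$year < 1900 | df$year > 2100)
  if (length(bad)) {
    stop("malformed observation rows (file lines ",
         paste(bad + 1L, collapse = ", "),
         "): values must be positive rates, se_log >= 0, indicator ",
         "U5MR/NMR, source_type one of ",
         paste(.SOURCE_TYPES, collapse = "/"))
  }
  df[.OBS_COLUMNS]
}

#' @rdname read_observations
#' @param observations observation data frame to write. Values are stored
#'   at 4-decimal precision (1e-4 deaths per 1000), far below any sampling
#'   error scale.
#' @export
write_observations <- function(observations, path) {
  stopifnot(all(.OBS_COLUMNS %in% names(observations)))
  out <- observations[.OBS_COLUMNS]
  out$value <- round(out$value, 4)
  out$se_log <- round(out$se_log, 5)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a livebirths CSV (country, year, births)
#' @param path CSV file path.
#' @export
read_livebirths <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "year", "births")
  if (!all(need %in% names(df))) {
    stop("livebirths file must have columns ", paste(need, collapse = ", "))
  }
  if (any(df$births <= 0)) stop("births must be positive")
  df[need]
}

#' @rdname read_livebirths
#' @param livebirths data frame to write.
#' @export
write_livebirths <- function(livebirths, path) {
  utils::write.csv(livebirths[c("country", "year", "births")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read or write an estimates CSV
#'
#' Schema: country, year, median, lower90, upper90 (rates per 1000).
#'
#' @param path CSV file path.
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "year", "median", "lower90", "upper90")
  if (!all(need %in% names(df))) {
    stop("estimates file must have columns ", paste(need, collapse = ", "))
  }
  out <- data.frame(country = df$country, year = df$year,
                    median = df$median, lower = df$lower90,
                    upper = df$upper90)
  attr(out, "level") <- 0.90
  class(out) <- c("estimate_series", "data.frame")
  out
}

#' @rdname read_estimates
#' @param estimates an \code{estimate_series} (or compatible data frame
#'   with columns country, year, median, lower, upper).
#' @export
write_estimates <- function(estimates, path) {
  need <- c("country", "year", "median", "lower", "upper")
  stopifnot(all(need %in% names(estimates)))
  out <- data.frame(country = estimates$country, year = estimates$year,
                    median = round(estimates$median, 4),
                    lower90 = round(estimates$lower, 4),
                    upper90 = round(estimates$upper, 4))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Round rates for display
#'
#' Estimates are kept at full precision internally; tables round rates to
#' one decimal (and counts to integers) only at the reporting layer.
#'
#' @param x numeric values.
#' @param digits decimal places (default 1).
#' @export
report_round <- function(x, digits = 1) round(x, digits)

#' Run configuration
#'
#' A serialisable list of everything a pipeline run needs: seed, paths,
#' MCMC settings, scenario constants and reporting precision. Round-trips
#' losslessly through YAML.
#'
#' @param seed master seed recorded in every output's metadata.
#' @param paths named list of input/output paths.
#' @param mcmc an [mcmc_config()] list.
#' @param scenario_defaults list of scenario constants (see
#'   [scenario_config()]).
#' @param level reporting interval probability.
#' @param digits display rounding for rates.
#' @export
run_config <- function(seed = 1, paths = list(), mcmc = mcmc_config(),
                       scenario_defaults = list(), level = 0.90, digits = 1) {
  structure(list(seed = as.integer(seed), paths = paths, mcmc = mcmc,
                 scenario_defaults = scenario_defaults, level = level,
                 digits = digits),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "run_config")
}

#' Write a synthetic world to a directory of CSVs
#'
#' Emits observations.csv, livebirths.csv, truth.csv and groups.csv in the
#' schemas the downstream stages read.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_observations(world$observations, file.path(dir, "observations.csv"))
  write_livebirths(world$livebirths, file.path(dir, "livebirths.csv"))
  tru <- world$truth
  tru$u5mr_true <- round(tru$u5mr_true, 4)
  tru$nmr_true <- round(tru$nmr_true, 4)
  utils::write.csv(tru, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(world$groups, file.path(dir, "groups.csv"),
                   row.names = FALSE)
  invisible(dir)
}
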