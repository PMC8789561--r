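#' Synthetic multi-country mortality worlds
#'
#' The functions in this file generate a synthetic "world": true U5MR/NMR
#' schedules per country, annual livebirths, and noisy multi-source
#' observations with the statistical structure the estimation model assumes
#' (multiplicative source-type biases, sampling and non-sampling error on the
#' log scale, overlapping series with gaps). They make the full estimation
#' and projection pipeline testable without any external database.
#'
#' @name synthetic_world
NULL

#' Default parameters for one synthetic country
#'
#' @param country country identifier.
#' @param level true U5MR (deaths per 1000 livebirths) at the first year.
#' @param arr annual rate of reduction of the mean U5MR path (per year;
#'   0.03 means a 3 percent exponential decline per year).
#' @param wiggle_sd SD of random-walk increments of the spline wiggle added
#'   to the log-linear mean path (log scale, per 2.5-year knot step). 0 gives
#'   an exact exponential trajectory.
#' @param ratio_coefs coefficients (b0, b1, b2) of the global relation
#'   log R = b0 + b1 log(u5mr) + b2 log(u5mr)^2, where R = NMR/(U5MR-NMR).
#'   The default slope is negative: the neonatal share of under-5 deaths
#'   rises as U5MR falls.
#' @param p_level_sd SD of the country ratio-multiplier level log P(t0).
#' @param p_wiggle_sd SD of random-walk increments of log P over knot steps.
#' @export
country_params <- function(country = "C01", level = 100, arr = 0.03,
                           wiggle_sd = 0.05,
                           ratio_coefs = c(2.0, -0.6, 0),
                           p_level_sd = 0.10, p_wiggle_sd = 0.03) {
  stopifnot(level > 0, wiggle_sd >= 0, p_level_sd >= 0, p_wiggle_sd >= 0)
  list(country = country, level = level, arr = arr, wiggle_sd = wiggle_sd,
       ratio_coefs = ratio_coefs, p_level_sd = p_level_sd,
       p_wiggle_sd = p_wiggle_sd)
}

#' Evaluate the synthetic global NMR/U5MR ratio relation
#'
#' @param u5mr rate per 1000 livebirths.
#' @param coefs coefficients (b0, b1, b2) on the log-log scale.
#' @return the expected ratio R = NMR/(U5MR - NMR), dimensionless.
#' @export
true_ratio_relation <- function(u5mr, coefs = c(2.0, -0.6, 0)) {
  lu <- log(u5mr)
  exp(coefs[1] + coefs[2] * lu + coefs[3] * lu^2)
}

# spline wiggle with RW coefficients starting at zero; returns values at years
.rw_spline <- function(years, sd_step, knot_spacing = 2.5) {
  basis <- build_spline_basis(range(years), knot_spacing = knot_spacing)
  coefs <- cumsum(c(0, stats::rnorm(basis$n_basis - 1L, 0, sd_step)))
  drop(basis_matrix(basis, years) %*% coefs)
}

#' Generate a true mortality schedule for one country
#'
#' The mean path is an exact exponential decline at the country's annual rate
#' of reduction; a smooth zero-mean spline wiggle (random-walk coefficients on
#' a 2.5-year knot grid, the same family the trend model fits) is added on the
#' log scale. True NMR is derived as U5MR * R/(1+R) with
#' R = W(U5MR) * P(t), which makes NMR < U5MR at every year by construction.
#'
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @param params a [country_params()] list.
#' @param years decimal (mid-year) years, spanning at least 10 years so the
#'   cubic spline wiggle is supported; 20+ years is typical.
#' @return data frame of class \code{true_schedule} with columns
#'   \code{country}, \code{year}, \code{u5mr_true}, \code{nmr_true}.
#' @export
generate_true_trajectory <- function(seed, params = country_params(),
                                     years = seq(1985.5, 2019.5, by = 1)) {
  stopifnot(length(years) >= 2)
  set.seed(as.integer(seed))
  t0 <- min(years)
  log_u5mr <- log(params$level) - params$arr * (years - t0)
  if (params$wiggle_sd > 0) {
    log_u5mr <- log_u5mr + .rw_spline(years, params$wiggle_sd)
  }
  u5mr <- exp(log_u5mr)
  log_p <- stats::rnorm(1, 0, params$p_level_sd)
  if (params$p_wiggle_sd > 0) {
    log_p <- log_p + .rw_spline(years, params$p_wiggle_sd)
  }
  r <- true_ratio_relation(u5mr, params$ratio_coefs) * exp(log_p)
  nmr <- u5mr * r / (1 + r)
  structure(
    data.frame(country = params$country, year = years,
               u5mr_true = u5mr, nmr_true = nmr),
    class = c("true_schedule", "data.frame")
  )
}

#' Specification of one observation series
#'
#' Describes the error signature of a data series: a fixed multiplicative
#' bias, a per-observation sampling SD, and an additional non-sampling SD,
#' all on the log scale. Vital registration (VR) is the unbiased anchor and
#' must have \code{bias_multiplier = 1}.
#'
#' @param series_id series identifier, unique within a country.
#' @param source_type one of \code{"VR"}, \code{"SRS"}, \code{"survey_FBH"},
#'   \code{"census_SBH"}.
#' @param bias_multiplier multiplicative bias (observed = truth x bias x
#'   noise); must be positive, and exactly 1 for VR.
#' @param sampling_sd_log per-observation sampling SD on the log scale;
#'   reported to the fitting stage as the observation's standard error.
#' @param extra_sd_log additional non-sampling SD on the log scale, not
#'   reported to the fitting stage (the model estimates it).
#' @param coverage_years decimal years at which the series reports.
#' @param indicators which indicators the series observes; summary birth
#'   histories cannot yield NMR, so \code{census_SBH} defaults to U5MR only.
#' @export
source_spec <- function(series_id, source_type, bias_multiplier = 1,
                        sampling_sd_log = 0.05, extra_sd_log = 0,
                        coverage_years = seq(1985.5, 2019.5, by = 1),
                        indicators = if (source_type == "census_SBH") "U5MR"
                                     else c("U5MR", "NMR")) {
  source_type <- match.arg(source_type, c("VR", "SRS", "survey_FBH", "census_SBH"))
  stopifnot(bias_multiplier > 0, sampling_sd_log >= 0, extra_sd_log >= 0,
            length(coverage_years) >= 1)
  if (source_type == "VR" && abs(bias_multiplier - 1) > 1e-12) {
    stop("VR series are the unbiased anchor: bias_multiplier must be 1")
  }
  list(series_id = series_id, source_type = source_type,
       bias_multiplier = bias_multiplier,
       sampling_sd_log = sampling_sd_log, extra_sd_log = extra_sd_log,
       coverage_years = coverage_years, indicators = indicators)
}

#' Generate noisy observations from a true schedule
#'
#' Each observation is the true rate multiplied by the series' bias
#' multiplier and a lognormal error whose log-SD combines the sampling and
#' non-sampling components: observed = truth x bias x exp(e),
#' e ~ Normal(0, sampling_sd^2 + extra_sd^2). The reported standard error
#' (\code{se_log}) carries only the sampling component, as in real survey
#' series where non-sampling error is unquantified.
#'
#' @param schedule a \code{true_schedule} from [generate_true_trajectory()].
#' @param specs non-empty list of [source_spec()] objects.
#' @param seed integer seed.
#' @return data frame of observation records with columns \code{country},
#'   \code{year}, \code{indicator}, \code{value}, \code{se_log},
#'   \code{series_id}, \code{source_type}.
#' @export
generate_observations <- function(schedule, specs, seed) {
  stopifnot(inherits(schedule, "data.frame"), length(specs) >= 1)
  set.seed(as.integer(seed))
  out <- list()
  for (sp in specs) {
    yrs <- sp$coverage_years[sp$coverage_years >= min(schedule$year) &
                             sp$coverage_years <= max(schedule$year)]
    if (length(yrs) == 0) next
    idx <- match(yrs, schedule$year)
    if (anyNA(idx)) stop("coverage years not on the schedule grid for series ",
                         sp$series_id)
    total_sd <- sqrt(sp$sampling_sd_log^2 + sp$extra_sd_log^2)
    for (ind in sp$indicators) {
      truth <- if (ind == "U5MR") schedule$u5mr_true[idx] else schedule$nmr_true[idx]
      eps <- if (total_sd > 0) stats::rnorm(length(yrs), 0, total_sd) else 0
      out[[length(out) + 1L]] <- data.frame(
        country = schedule$country[idx],
        year = yrs,
        indicator = ind,
        value = truth * sp$bias_multiplier * exp(eps),
        se_log = sp$sampling_sd_log,
        series_id = sp$series_id,
        source_type = sp$source_type
      )
    }
  }
  if (length(out) == 0) stop("no observations generated: empty coverage")
  do.call(rbind, out)
}

#' Generate an annual livebirths series
#'
#' Births follow smooth compound growth with optional lognormal year-to-year
#' perturbations, rounded to whole counts.
#'
#' @param seed integer seed.
#' @param params list with \code{country}, \code{births0} (level in the first
#'   year), \code{growth} (per-year compound growth rate: 0.01 grows births
#'   by 1 percent per year) and \code{noise_sd} (SD of random-walk log
#'   perturbations; 0 gives exact compound growth).
#' @param years integer calendar years.
#' @return data frame with columns \code{country}, \code{year}, \code{births}.
#' @export
generate_livebirths <- function(seed,
                                params = list(country = "C01", births0 = 1e5,
                                              growth = 0.01, noise_sd = 0),
                                years = 1985:2030) {
  stopifnot(params$births0 > 0, params$growth > -1)
  set.seed(as.integer(seed))
  drift <- (years - years[1]) * log1p(params$growth)
  noise <- if (params$noise_sd > 0) {
    cumsum(c(0, stats::rnorm(length(years) - 1L, 0, params$noise_sd)))
  } else 0
  births <- round(params$births0 * exp(drift + noise))
  data.frame(country = params$country, year = years, births = pmax(births, 1))
}

#' Generate a complete synthetic world
#'
#' Draws per-country levels, trends, series layouts, biases and livebirths,
#' producing everything downstream stages consume. Countries differ in their
#' data environment: about 40 percent have a vital-registration series
#' covering the whole period; the rest rely on full-birth-history surveys
#' (periodic, ending a few years before the estimation endpoint) and
#' summary-birth-history censuses with larger, possibly biased errors.
#'
#' @param n_countries number of countries (default 25).
#' @param seed integer master seed; the whole world is deterministic given it.
#' @param years decimal mid-year grid of the estimation period.
#' @param birth_years calendar years for livebirths (should extend past the
#'   estimation period to cover projection horizons).
#' @param level_range,arr_range ranges from which country U5MR starting
#'   levels and annual rates of reduction are drawn uniformly.
#' @param wiggle_sd passed to [country_params()].
#' @param type_biases named vector of source-type bias multipliers: every
#'   series of a type shares its characteristic bias (surveys and summary
#'   birth histories tend to under-report), the structure the estimation
#'   model's per-type mean bias adjusts for.
#' @param series_bias_sd log-scale SD of additional per-series bias scatter
#'   around the type bias (series-level divergence).
#' @param n_regions,n_income_groups synthetic grouping sizes.
#' @return list of class \code{synthetic_world} with elements \code{truth},
#'   \code{observations}, \code{livebirths} (data frames), \code{groups}
#'   (country to region/income map), \code{specs} (per-country list of
#'   series specs) and \code{years}.
#' @export
generate_world <- function(n_countries = 25, seed = 1,
                           years = seq(1985.5, 2019.5, by = 1),
                           birth_years = 1985:2030,
                           level_range = c(20, 200),
                           arr_range = c(0.005, 0.05),
                           wiggle_sd = 0.05,
                           type_biases = c(VR = 1, SRS = 1,
                                           survey_FBH = 0.95,
                                           census_SBH = 0.90),
                           series_bias_sd = 0.03,
                           n_regions = 5, n_income_groups = 4) {
  stopifnot(n_countries >= 1)
  set.seed(as.integer(seed))
  ids <- sprintf("C%02d", seq_len(n_countries))
  levels <- stats::runif(n_countries, level_range[1], level_range[2])
  arrs <- stats::runif(n_countries, arr_range[1], arr_range[2])
  has_vr <- stats::runif(n_countries) < 0.4
  country_seeds <- sample.int(.Machine$integer.max, 3 * n_countries)

  truth <- list(); obs <- list(); births <- list(); specs <- list()
  for (i in seq_len(n_countries)) {
    par <- country_params(country = ids[i], level = levels[i], arr = arrs[i],
                          wiggle_sd = wiggle_sd)
    sched <- generate_true_trajectory(country_seeds[i], par, years)
    specs_i <- .draw_series_layout(ids[i], has_vr[i], years,
                                   type_biases, series_bias_sd)
    truth[[i]] <- sched
    obs[[i]] <- generate_observations(sched, specs_i,
                                      country_seeds[n_countries + i])
    births[[i]] <- generate_livebirths(
      country_seeds[2 * n_countries + i],
      params = list(country = ids[i],
                    births0 = stats::runif(1, 5e4, 2e6),
                    growth = stats::runif(1, -0.005, 0.02),
                    noise_sd = 0.005),
      years = birth_years)
    specs[[ids[i]]] <- specs_i
  }
  groups <- data.frame(
    country = ids,
    region = sprintf("R%d", (seq_len(n_countries) - 1L) %% n_regions + 1L),
    income_group = sprintf("I%d",
      as.integer(cut(rank(levels, ties.method = "first"), n_income_groups)))
  )
  structure(
    list(truth = do.call(rbind, truth),
         observations = do.call(rbind, obs),
         livebirths = do.call(rbind, births),
         groups = groups, specs = specs, years = years, seed = seed),
    class = "synthetic_world"
  )
}

# series layout for one country: VR countries get a continuous VR series plus
# an occasional survey; others get 2-3 surveys and possibly an SBH census,
# with survey coverage ending a few years before the endpoint. Series biases
# are the source-type bias times a small lognormal per-series scatter.
.draw_series_layout <- function(country, has_vr, years, type_biases,
                                series_bias_sd) {
  hi <- max(years)
  ser_bias <- function(type) {
    unname(type_biases[type]) * exp(stats::rnorm(1, 0, series_bias_sd))
  }
  specs <- list()
  if (has_vr) {
    specs[[1]] <- source_spec(paste0(country, "-VR"), "VR",
                              bias_multiplier = 1,
                              sampling_sd_log = 0.025, extra_sd_log = 0.01,
                              coverage_years = years)
    n_extra <- sample(0:1, 1)
  } else {
    n_extra <- sample(2:3, 1)
  }
  for (k in seq_len(n_extra)) {
    is_sbh <- !has_vr && k == n_extra && stats::runif(1) < 0.5
    end_gap <- stats::runif(1, 0.5, 5.5)   # years between last datapoint and endpoint
    last <- hi - floor(end_gap)
    if (is_sbh) {
      cov <- seq(last, by = -5, length.out = 4)
      specs[[length(specs) + 1L]] <- source_spec(
        sprintf("%s-SBH%d", country, k), "census_SBH",
        bias_multiplier = ser_bias("census_SBH"),
        sampling_sd_log = 0.10, extra_sd_log = 0.05,
        coverage_years = rev(cov))
    } else {
      span <- sample(10:25, 1)
      cov <- seq(max(min(years), last - span), last, by = 1)
      specs[[length(specs) + 1L]] <- source_spec(
        sprintf("%s-FBH%d", country, k), "survey_FBH",
        bias_multiplier = ser_bias("survey_FBH"),
        sampling_sd_log = 0.07, extra_sd_log = 0.03,
        coverage_years = cov)
    }
  }
  specs
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic world:", length(unique(x$truth$country)), "countries,",
      "years", min(x$years), "-", max(x$years), ",",
      nrow(x$observations), "observations\n")
  invisible(x)
}
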