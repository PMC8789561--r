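#' Scenario configuration for 2020-2030 projections
#'
#' Holds the floors, caps, targets and ARR window of the four projection
#' scenarios. Defaults are the published constants: lowest observed U5MR
#' 1.7 and NMR 0.85 deaths per 1000 livebirths (floors); highest observed
#' NMR/U5MR ratio in a country with good vital registration 0.79 (cap);
#' SDG 3.2 targets U5MR 25 and NMR 12; 2019 high-income-country averages
#' U5MR 5.0 and NMR 2.9.
#'
#' @param name one of \code{"constant_2019"}, \code{"current_trends"},
#'   \code{"achieve_sdg"}, \code{"achieve_hic"}.
#' @param arr_window years over which the current ARR is measured.
#' @param u5mr_floor,nmr_floor lowest attainable rates (per 1000).
#' @param ratio_cap maximum allowed NMR/U5MR ratio.
#' @param sdg_u5mr,sdg_nmr SDG targets (per 1000).
#' @param hic_u5mr,hic_nmr high-income-country 2019 averages (per 1000).
#' @param horizon first and last projected year.
#' @export
scenario_config <- function(name = c("constant_2019", "current_trends",
                                     "achieve_sdg", "achieve_hic"),
                            arr_window = c(2010, 2019),
                            u5mr_floor = 1.7, nmr_floor = 0.85,
                            ratio_cap = 0.79,
                            sdg_u5mr = 25, sdg_nmr = 12,
                            hic_u5mr = 5.0, hic_nmr = 2.9,
                            horizon = c(2020, 2030)) {
  name <- match.arg(name)
  stopifnot(u5mr_floor < sdg_u5mr, nmr_floor < sdg_nmr,
            ratio_cap > 0, ratio_cap < 1, horizon[1] <= horizon[2])
  structure(list(name = name, arr_window = arr_window,
                 u5mr_floor = u5mr_floor, nmr_floor = nmr_floor,
                 ratio_cap = ratio_cap, sdg_u5mr = sdg_u5mr,
                 sdg_nmr = sdg_nmr, hic_u5mr = hic_u5mr, hic_nmr = hic_nmr,
                 horizon = horizon),
            class = "scenario_config")
}

#' Annual rate of reduction between two years
#'
#' ARR = ln(rate_t1 / rate_t2) / (t2 - t1): the instantaneous exponential
#' rate of decline, positive when mortality is falling.
#'
#' @param rate_t1,rate_t2 rates (per 1000) at the earlier year t1 and the
#'   later year t2; must be positive.
#' @param t1,t2 years with t1 < t2.
#' @return per-year reduction rate (e.g. 0.031 for 3.1 percent per year).
#' @export
compute_arr <- function(rate_t1, rate_t2, t1, t2) {
  if (any(rate_t1 <= 0) || any(rate_t2 <= 0)) {
    stop("rates must be positive to compute an ARR")
  }
  stopifnot(all(t1 < t2))
  log(rate_t1 / rate_t2) / (t2 - t1)
}

#' ARR required to reach a target by 2030
#'
#' @param rate_2019 rate (per 1000) at the projection base year.
#' @param target target rate at 2030.
#' @param base_year base year (default 2019, giving an 11-year span).
#' @param target_year target year (default 2030).
#' @return required per-year reduction rate; 0 if the target is already met.
#' @export
required_arr <- function(rate_2019, target, base_year = 2019,
                         target_year = 2030) {
  stopifnot(all(rate_2019 > 0), all(target > 0))
  pmax(log(rate_2019 / target) / (target_year - base_year), 0)
}

# shared projection engine: exponential path at a scenario-determined ARR
# with a floor; negative current trends are held flat at the 2019 level.
.project_rate <- function(est_2019, arr_current, scenario, target, floor,
                          horizon) {
  yrs <- seq(horizon[1], horizon[2])
  k <- yrs - (horizon[1] - 1)   # years since 2019
  path_current <- est_2019 * exp(-max(arr_current, 0) * k)
  path <- switch(scenario,
    constant_2019 = rep(est_2019, length(yrs)),
    current_trends = path_current,
    {  # achieve_sdg / achieve_hic
      on_track <- est_2019 <= target ||
        path_current[length(path_current)] <= target
      if (on_track) {
        path_current
      } else {
        est_2019 * exp(-required_arr(est_2019, target,
                                     horizon[1] - 1, horizon[2]) * k)
      }
    })
  setNames(pmax(path, floor), yrs)
}

#' Project U5MR for 2020-2030 under a scenario
#'
#' Scenario rules: \code{constant_2019} holds the 2019 level flat;
#' \code{current_trends} continues the 2010-19 ARR (held flat if the ARR is
#' negative) with the 1.7 floor; \code{achieve_sdg} and \code{achieve_hic}
#' send countries that are neither achieved nor on track along the constant
#' required-ARR path hitting the target exactly at 2030, and keep the
#' current-trends path otherwise.
#'
#' @param est_2019 2019 U5MR estimate (per 1000).
#' @param arr_2010_19 current ARR (per year), typically from
#'   posterior-median estimates over 2010-2019.
#' @param config a [scenario_config()].
#' @return named vector of yearly rates over the horizon.
#' @export
project_u5mr <- function(est_2019, arr_2010_19, config) {
  stopifnot(inherits(config, "scenario_config"), est_2019 > 0)
  target <- switch(config$name, achieve_sdg = config$sdg_u5mr,
                   achieve_hic = config$hic_u5mr, NA_real_)
  .project_rate(est_2019, arr_2010_19, config$name, target,
                config$u5mr_floor, config$horizon)
}

#' Project NMR for 2020-2030 under a scenario
#'
#' Applies the same scenario rules as [project_u5mr()] with the NMR floor
#' (0.85) and targets (12.0 SDG / 2.9 HIC), then caps the path at
#' \code{ratio_cap} times the projected U5MR year by year.
#'
#' @param est_2019 2019 NMR estimate (per 1000).
#' @param arr_2010_19 current NMR ARR (per year).
#' @param u5mr_projection yearly U5MR rates from [project_u5mr()] over the
#'   same horizon.
#' @param config a [scenario_config()].
#' @return named vector of yearly NMR rates over the horizon.
#' @export
project_nmr <- function(est_2019, arr_2010_19, u5mr_projection, config) {
  stopifnot(inherits(config, "scenario_config"), est_2019 > 0,
            length(u5mr_projection) == diff(config$horizon) + 1)
  target <- switch(config$name, achieve_sdg = config$sdg_nmr,
                   achieve_hic = config$hic_nmr, NA_real_)
  path <- .project_rate(est_2019, arr_2010_19, config$name, target,
                        config$nmr_floor, config$horizon)
  pmin(path, config$ratio_cap * u5mr_projection)
}

#' Project deaths for a set of countries under one scenario
#'
#' Runs the birth-week cohort method on projected rates. Cohorts born
#' before the projection horizon are exposed to the supplied historical
#' rates, so deaths in 2020 correctly include mortality of children born
#' 2015-2019. Livebirths are shared across scenarios by construction.
#'
#' @param rates data frame with columns \code{country}, \code{year},
#'   \code{u5mr}, \code{nmr}, covering at least \code{min(years)-5} through
#'   \code{max(years)} per country (earlier years are clamped).
#' @param livebirths data frame with \code{country}, \code{year},
#'   \code{births} covering the same span.
#' @param years projection reporting years (default 2020:2030).
#' @return list with \code{by_country} (data frame country x year x age
#'   deaths), \code{total} (data frame year, deaths_neonatal,
#'   deaths_1_59m, deaths_under5 summed over countries), and
#'   \code{cumulative} (named totals over the horizon).
#' @export
project_deaths <- function(rates, livebirths, years = 2020:2030) {
  countries <- sort(unique(rates$country))
  if (!setequal(countries, unique(livebirths$country))) {
    stop("country sets of rates and livebirths differ")
  }
  per <- list()
  for (cn in countries) {
    rc <- rates[rates$country == cn, , drop = FALSE]
    sched <- build_mortality_schedule(rc$u5mr, rc$nmr, year = rc$year)
    dt <- compute_cohort_deaths(livebirths[livebirths$country == cn, ],
                                sched, years)
    per[[cn]] <- cbind(country = cn, as.data.frame(dt))
  }
  by_country <- do.call(rbind, c(per, make.row.names = FALSE))
  total <- stats::aggregate(
    by_country[c("deaths_neonatal", "deaths_1_59m", "deaths_under5")],
    by = list(year = by_country$year), FUN = sum)
  list(by_country = by_country, total = total,
       cumulative = c(deaths_neonatal = sum(total$deaths_neonatal),
                      deaths_1_59m = sum(total$deaths_1_59m),
                      deaths_under5 = sum(total$deaths_under5)))
}

#' Deaths averted between two scenarios
#'
#' @param deaths_baseline,deaths_alternative results of [project_deaths()].
#' @return named vector: cumulative under-5, neonatal and 1-59m deaths of
#'   the baseline minus the alternative (positive when the alternative
#'   scenario saves lives).
#' @export
averted_deaths <- function(deaths_baseline, deaths_alternative) {
  deaths_baseline$cumulative - deaths_alternative$cumulative
}
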