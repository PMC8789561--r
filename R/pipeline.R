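#' End-to-end estimation pipeline
#'
#' Convenience drivers that chain the stages: B3 trend fit for U5MR (with
#' trend-blended extrapolation over data-free tail years), the global ratio
#' relation and country multipliers for NMR, death counts, and recovery
#' metrics against a synthetic world's truth.
#'
#' @name pipeline
NULL

#' Fit U5MR and NMR for a whole world of observations
#'
#' Fits the B3 model jointly to all U5MR observations (pooling source-type
#' bias parameters across countries), extrapolates each country's
#' trajectory beyond its last observation year by blending its own recent
#' trend with the global ARR, then fits the NMR ratio model (global W
#' relation from pooled observed ratios, spline country multiplier P) and
#' derives NMR draws.
#'
#' @param observations observation records (both indicators).
#' @param years annual mid-year estimation grid.
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed.
#' @param knot_spacing spline knot spacing in years.
#' @param extrap_rho,extrap_innovation_sd extrapolation blend parameters,
#'   see [extrapolate()].
#' @return list with \code{u5mr} (rate_posterior), \code{nmr}
#'   (rate_posterior), \code{w} (global relation), \code{ratio} (list of
#'   ratio posteriors), \code{u5mr_est}/\code{nmr_est} (estimate_series),
#'   \code{global_arr}, \code{last_obs_year}.
#' @export
fit_world <- function(observations, years = seq(1985.5, 2019.5, by = 1),
                      mcmc = mcmc_config(), seed = 1, knot_spacing = 2.5,
                      extrap_rho = 0.9, extrap_innovation_sd = 0.03) {
  obs_u5 <- observations[observations$indicator == "U5MR", , drop = FALSE]
  obs_nm <- observations[observations$indicator == "NMR", , drop = FALSE]
  if (nrow(obs_u5) == 0) stop("no U5MR observations")
  missing_u5 <- setdiff(unique(observations$country), unique(obs_u5$country))
  if (length(missing_u5)) {
    stop("no U5MR observations for country: ",
         paste(missing_u5, collapse = ", "))
  }
  basis <- build_spline_basis(years, knot_spacing = knot_spacing)
  fit <- .with_retry(function(m, s) {
    fit_b3(obs_u5, basis, mcmc = m, seed = s, years = years)
  }, mcmc, seed)

  last_obs <- tapply(obs_u5$year, obs_u5$country, max)[fit$countries]
  # global ARR over the last decade of the fitted medians (countries with
  # near-complete data only, to avoid circularity with extrapolation)
  complete <- names(last_obs)[last_obs >= max(years) - 1]
  arr10 <- posterior_arr(fit, max(years) - 10, max(years))
  global_arr <- if (length(complete) >= 3) {
    stats::median(arr10[complete])
  } else stats::median(arr10)
  u5_post <- extrapolate(fit, global_arr = global_arr,
                         horizon_end = max(years),
                         from = setNames(as.numeric(last_obs),
                                         names(last_obs)),
                         rho = extrap_rho,
                         innovation_sd = extrap_innovation_sd,
                         seed = seed + 1000L)
  # backcast before each country's first datapoint with the same blend
  first_obs <- tapply(obs_u5$year, obs_u5$country, min)[fit$countries]
  u5_post <- extrapolate(u5_post, global_arr = global_arr,
                         horizon_end = min(years),
                         from = setNames(as.numeric(first_obs),
                                         names(first_obs)),
                         rho = extrap_rho,
                         innovation_sd = extrap_innovation_sd,
                         seed = seed + 2000L, direction = "backward")
  u5_est <- summarize_posterior(u5_post)

  # global ratio relation from pooled observed ratios vs estimated U5MR
  pairs <- .ratio_pairs(debias_observations(obs_nm, fit$bias), u5_est)
  w <- fit_global_relation(pairs)
  # the country-multiplier model is small; run longer chains for robust
  # mixing of its variance parameters at negligible cost
  mcmc_p <- mcmc
  mcmc_p$n_burnin <- 2 * mcmc$n_burnin
  mcmc_p$n_iter <- 2 * mcmc$n_iter
  mcmc_p$thin <- 2 * mcmc$thin
  ratio <- list()
  nmr_draws <- array(NA_real_, dim(u5_post$draws),
                     dimnames = dimnames(u5_post$draws))
  for (i in seq_along(u5_post$countries)) {
    cn <- u5_post$countries[i]
    rp <- .with_retry(function(m, s) {
      fit_country_multiplier(
        obs_nm[obs_nm$country == cn, , drop = FALSE],
        u5_est[u5_est$country == cn, , drop = FALSE],
        w, basis, bias = fit$bias, mcmc = m, seed = s, years = years)
    }, mcmc_p, seed + i)
    nm <- derive_nmr(rp, country_draws(u5_post, cn))
    nd <- dim(nm$draws)[1]
    nmr_draws[seq_len(nd), , i] <- nm$draws[, , 1]
    if (nd < dim(nmr_draws)[1]) {
      nmr_draws[(nd + 1):dim(nmr_draws)[1], , i] <-
        nm$draws[sample.int(nd, dim(nmr_draws)[1] - nd, replace = TRUE), , 1]
    }
    ratio[[cn]] <- rp
  }
  nmr_post <- rate_posterior(nmr_draws, years, u5_post$countries)
  list(u5mr = u5_post, nmr = nmr_post, w = w, ratio = ratio,
       u5mr_est = u5_est, nmr_est = summarize_posterior(nmr_post),
       global_arr = global_arr, last_obs_year = last_obs,
       basis = basis, seed = seed)
}

# retry a fit once with 4x longer chains on a convergence failure; any
# other error (or a second failure) propagates
.with_retry <- function(fit_fn, mcmc, seed) {
  tryCatch(fit_fn(mcmc, seed), error = function(e) {
    if (!grepl("converge", conditionMessage(e))) stop(e)
    mcmc$n_burnin <- 4 * mcmc$n_burnin
    mcmc$n_iter <- 4 * mcmc$n_iter
    mcmc$thin <- 4 * mcmc$thin
    fit_fn(mcmc, seed + 10000L)
  })
}

.ratio_pairs <- function(obs_nm, u5_est) {
  if (nrow(obs_nm) == 0) stop("no NMR observations to fit the global relation")
  key_obs <- paste(obs_nm$country, round(obs_nm$year, 3))
  key_est <- paste(u5_est$country, round(u5_est$year, 3))
  u5 <- u5_est$median[match(key_obs, key_est)]
  ok <- !is.na(u5) & obs_nm$value < u5
  data.frame(ratio = ratio_from_rates(obs_nm$value[ok], u5[ok]),
             u5mr = u5[ok])
}

#' Recovery metrics of a fit against synthetic truth
#'
#' @param fit a [fit_world()] result (or a \code{rate_posterior} for
#'   \code{indicator = "U5MR"} only).
#' @param truth the \code{truth} data frame of a [generate_world()] world.
#' @param indicator "U5MR" or "NMR".
#' @param level interval probability of the coverage check.
#' @return list with \code{rmse_log} (RMSE of posterior median log rate vs
#'   true log rate over all country-years), \code{coverage} (share of
#'   country-years whose interval contains the truth) and \code{n}.
#' @export
recovery_metrics <- function(fit, truth, indicator = "U5MR", level = 0.90) {
  post <- if (inherits(fit, "rate_posterior")) fit
          else if (indicator == "U5MR") fit$u5mr else fit$nmr
  est <- summarize_posterior(post, level = level)
  tru_col <- if (indicator == "U5MR") "u5mr_true" else "nmr_true"
  key_est <- paste(est$country, round(est$year, 3))
  key_tru <- paste(truth$country, round(truth$year, 3))
  m <- match(key_est, key_tru)
  ok <- !is.na(m)
  tv <- truth[[tru_col]][m[ok]]
  e <- est[ok, ]
  list(rmse_log = sqrt(mean((log(e$median) - log(tv))^2)),
       coverage = mean(tv >= e$lower & tv <= e$upper),
       n = sum(ok))
}

#' Deaths with uncertainty for every country of a fitted world
#'
#' @param fit a [fit_world()] result.
#' @param livebirths data frame country, year, births.
#' @param years reporting calendar years.
#' @param max_draws cap on draws run through the cohort method per country.
#' @return named list (by country) of \code{deaths_posterior} objects.
#' @export
world_deaths <- function(fit, livebirths, years, max_draws = 200) {
  rate_years <- floor(fit$u5mr$years)
  out <- list()
  for (cn in fit$u5mr$countries) {
    out[[cn]] <- deaths_uncertainty(
      country_draws(fit$u5mr, cn), country_draws(fit$nmr, cn),
      rate_years, livebirths[livebirths$country == cn, , drop = FALSE],
      years = years, max_draws = max_draws)
  }
  out
}

#' Scenario projections for every country of a fitted world
#'
#' Computes per-country 2010-19 ARRs from posterior medians, projects U5MR
#' and NMR under a scenario, and prepends the 2015-2019 estimated rates so
#' the cohort method can expose earlier birth cohorts.
#'
#' @param fit a [fit_world()] result.
#' @param scenario scenario name (see [scenario_config()]).
#' @param config optional full [scenario_config()]; overrides
#'   \code{scenario}.
#' @param crisis_adjust optional data frame (country, year, u5mr_adj,
#'   nmr_adj) of rate adjustments subtracted before the ARR window
#'   computation (crisis deaths removal); rarely used with synthetic data.
#' @return data frame country, year (2015-2030), u5mr, nmr.
#' @export
project_world <- function(fit, scenario = "current_trends", config = NULL,
                          crisis_adjust = NULL) {
  if (is.null(config)) config <- scenario_config(scenario)
  u5_med <- summarize_posterior(fit$u5mr)
  nm_med <- summarize_posterior(fit$nmr)
  yr_grid <- floor(fit$u5mr$years)
  w <- config$arr_window
  out <- list()
  for (cn in fit$u5mr$countries) {
    u5c <- u5_med[u5_med$country == cn, ]
    nmc <- nm_med[nm_med$country == cn, ]
    rate_at <- function(df, y) df$median[which.min(abs(yr_grid - y))]
    u5_w <- c(rate_at(u5c, w[1]), rate_at(u5c, w[2]))
    nm_w <- c(rate_at(nmc, w[1]), rate_at(nmc, w[2]))
    if (!is.null(crisis_adjust)) {
      ca <- crisis_adjust[crisis_adjust$country == cn, , drop = FALSE]
      adj <- function(v, y, col) {
        i <- match(y, ca$year)
        v - ifelse(is.na(i), 0, ca[[col]][i])
      }
      u5_w <- adj(u5_w, w, "u5mr_adj")
      nm_w <- adj(nm_w, w, "nmr_adj")
    }
    arr_u5 <- compute_arr(u5_w[1], u5_w[2], w[1], w[2])
    arr_nm <- compute_arr(nm_w[1], nm_w[2], w[1], w[2])
    est_u5 <- rate_at(u5c, 2019)
    est_nm <- rate_at(nmc, 2019)
    p_u5 <- project_u5mr(est_u5, arr_u5, config)
    p_nm <- project_nmr(est_nm, arr_nm, p_u5, config)
    hist_years <- 2015:2019
    hi <- vapply(hist_years, function(y) which.min(abs(yr_grid - y)), 1L)
    out[[cn]] <- data.frame(
      country = cn,
      year = c(hist_years, as.integer(names(p_u5))),
      u5mr = c(u5c$median[hi], unname(p_u5)),
      nmr = c(pmin(nmc$median[hi], 0.999 * u5c$median[hi]), unname(p_nm)))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
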