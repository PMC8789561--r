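make_obs <- function(country, years, values, se_log, series_id, source_type) {
  data.frame(country = country, year = years, indicator = "U5MR",
             value = values, se_log = se_log, series_id = series_id,
             source_type = source_type)
}

test_that("a single observation is contained in its 90 percent interval", {
  obs <- make_obs("A", 2005.5, 50, 0.05, "A-VR", "VR")
  basis <- build_spline_basis(c(1995.5, 2015.5))
  post <- fit_b3(obs, basis, mcmc = test_mcmc(), seed = 2,
                 check_convergence = FALSE)
  est <- summarize_posterior(post)
  at <- est[est$year == 2005.5, ]
  expect_gt(50, at$lower)
  expect_lt(50, at$upper)
})

test_that("dense unbiased low-noise data recover the truth closely", {
  par <- country_params(country = "A", level = 90, arr = 0.03,
                        wiggle_sd = 0.03)
  years <- seq(1995.5, 2019.5)
  sch <- generate_true_trajectory(21, par, years)
  sp <- source_spec("A-VR", "VR", sampling_sd_log = 0.01,
                    extra_sd_log = 0, coverage_years = years,
                    indicators = "U5MR")
  obs <- generate_observations(sch, list(sp), seed = 22)
  basis <- build_spline_basis(years)
  post <- fit_b3(obs, basis, mcmc = test_mcmc(), seed = 23, years = years,
                 check_convergence = FALSE)
  med <- apply(country_draws(post, "A"), 2, median)
  expect_lt(max(abs(med - log(sch$u5mr_true))), 0.05)
  # posterior median at observation years approaches the observation
  est <- summarize_posterior(post)
  psd <- apply(country_draws(post, "A"), 2, sd)
  i <- match(obs$year, est$year)
  expect_true(all(abs(log(est$median[i]) - log(obs$value)) < 2 * psd[i] + 0.02))
})

test_that("a biased source is detected against a VR anchor", {
  par <- country_params(country = "A", level = 80, arr = 0.02,
                        wiggle_sd = 0.03)
  years <- seq(1995.5, 2019.5)
  sch <- generate_true_trajectory(31, par, years)
  specs <- list(
    source_spec("A-VR", "VR", sampling_sd_log = 0.025,
                coverage_years = years, indicators = "U5MR"),
    source_spec("A-S", "survey_FBH", bias_multiplier = 0.8,
                sampling_sd_log = 0.05, coverage_years = years,
                indicators = "U5MR"))
  obs <- generate_observations(sch, specs, seed = 32)
  basis <- build_spline_basis(years)
  post <- fit_b3(obs, basis, mcmc = test_mcmc(), seed = 33)
  b <- post$bias
  est_bias <- b$mean_bias_log[b$source_type == "survey_FBH"]
  expect_lt(est_bias, 0)
  expect_lt(abs(est_bias - log(0.8)), 0.5 * abs(log(0.8)))
})

test_that("scaling all observations by k shifts the posterior by log k", {
  obs <- make_obs("A", seq(2000.5, 2014.5), 60 * exp(-0.02 * 0:14), 0.03,
                  "A-VR", "VR")
  basis <- build_spline_basis(c(2000.5, 2014.5))
  p1 <- fit_b3(obs, basis, mcmc = test_mcmc(), seed = 4,
               check_convergence = FALSE)
  obs2 <- obs
  obs2$value <- obs2$value * 2
  p2 <- fit_b3(obs2, basis, mcmc = test_mcmc(), seed = 4,
               check_convergence = FALSE)
  m1 <- apply(country_draws(p1, "A"), 2, median)
  m2 <- apply(country_draws(p2, "A"), 2, median)
  expect_equal(m2 - m1, rep(log(2), length(m1)), tolerance = 0.02)
})

test_that("posterior summaries match closed-form lognormal quantiles", {
  mu <- log(40); sigma <- 0.1
  set.seed(99)
  draws <- matrix(rnorm(40000, mu, sigma), ncol = 1)
  post <- rate_posterior(draws, years = 2000, countries = "A")
  est <- summarize_posterior(post, level = 0.90)
  expect_equal(est$median, exp(mu), tolerance = 0.005)
  expect_equal(est$lower, exp(mu - 1.6449 * sigma), tolerance = 0.005)
  expect_equal(est$upper, exp(mu + 1.6449 * sigma), tolerance = 0.005)
  # degenerate posterior collapses to a point
  d0 <- rate_posterior(matrix(log(25), 100, 1), 2000, "A")
  e0 <- summarize_posterior(d0)
  expect_equal(c(e0$median, e0$lower, e0$upper), rep(25, 3))
  # a 50 percent interval nests inside the 90 percent interval
  e50 <- summarize_posterior(post, level = 0.5)
  expect_gt(e50$lower, est$lower)
  expect_lt(e50$upper, est$upper)
})

test_that("extrapolation blends country and global trends as configured", {
  # all draws decline at exactly 2 percent per year
  years <- seq(2000.5, 2019.5)
  f <- log(50) - 0.02 * (years - 2000.5)
  draws <- matrix(rep(f, each = 50), nrow = 50)
  post <- rate_posterior(draws, years, "A")
  # full weight on the country trend: exact exponential continuation
  e1 <- extrapolate(post, global_arr = 0.10, horizon_end = 2030.5,
                    rho = 1, innovation_sd = 0)
  ext <- e1$draws[1, e1$years > 2019.5, 1]
  expect_equal(ext, log(50) - 0.02 * (seq(2020.5, 2030.5) - 2000.5),
               tolerance = 1e-10)
  # full weight on the global trend: continuation at global_arr
  e0 <- extrapolate(post, global_arr = 0.10, horizon_end = 2030.5,
                    rho = 0, innovation_sd = 0)
  ext0 <- e0$draws[1, e0$years > 2019.5, 1]
  expect_equal(diff(ext0), rep(-0.10, 10), tolerance = 1e-10)
})

test_that("interval width grows over the extrapolation horizon", {
  set.seed(12)
  years <- seq(2000.5, 2019.5)
  # draws with heterogeneous trends
  n <- 400
  lev <- rnorm(n, log(60), 0.05)
  tr <- rnorm(n, 0.025, 0.01)
  draws <- outer(lev, rep(1, length(years))) -
    outer(tr, years - 2000.5)
  post <- rate_posterior(draws, years, "A")
  for (seed in 1:5) {
    e <- extrapolate(post, global_arr = 0.02, horizon_end = 2030.5,
                     seed = seed)
    width <- function(j) diff(quantile(e$draws[, j, 1], c(0.05, 0.95)))
    expect_gte(width(length(e$years)), width(length(years)))
  }
})

test_that("backward extrapolation rebuilds the pre-data trend", {
  years <- seq(2000.5, 2019.5)
  f <- log(50) - 0.02 * (years - 2000.5)
  draws <- matrix(rep(f, each = 20), nrow = 20)
  post <- rate_posterior(draws, years, "A")
  e <- extrapolate(post, global_arr = 0.02, horizon_end = 1990.5,
                   from = c(A = 2000.5), rho = 1, innovation_sd = 0,
                   direction = "backward")
  back <- e$draws[1, e$years < 2000.5, 1]
  expect_equal(back, log(50) - 0.02 * (seq(1990.5, 1999.5) - 2000.5),
               tolerance = 1e-10)
  # original fitted years untouched
  expect_equal(e$draws[1, match(years, e$years), 1], f)
})

test_that("non-convergent chains raise rather than return silently", {
  obs <- make_obs("A", seq(2000.5, 2014.5), 60 * exp(-0.02 * 0:14), 0.03,
                  "A-VR", "VR")
  basis <- build_spline_basis(c(2000.5, 2014.5))
  strict <- test_mcmc(rhat_max = 0.999)   # unattainable threshold
  expect_error(fit_b3(obs, basis, mcmc = strict, seed = 4), "R-hat")
})
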