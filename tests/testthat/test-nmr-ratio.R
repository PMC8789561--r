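test_that("the global relation is recovered exactly from noise-free pairs", {
  u <- exp(seq(log(5), log(200), length.out = 60))
  pairs <- data.frame(u5mr = u, ratio = exp(0.5 - 0.4 * log(u)))
  w <- fit_global_relation(pairs)
  expect_equal(unname(w$coefs[1]), 0.5, tolerance = 0.005)
  expect_equal(unname(w$coefs[2]), -0.4, tolerance = 0.004)
  expect_equal(unname(w$coefs[3]), 0, tolerance = 1e-6)
  # neonatal share rises as U5MR falls: W larger at 20 than at 100
  expect_gt(w_eval(w, 20), w_eval(w, 100))
  expect_true(all(w_eval(w, c(0.5, 5, 50, 500)) > 0))
})

test_that("a constant-U5MR input leaves the relation unidentifiable", {
  pairs <- data.frame(u5mr = rep(50, 30), ratio = runif(30, 0.3, 0.5))
  expect_error(fit_global_relation(pairs), "degenerate")
})

test_that("the ratio transform round-trips the printed global 2019 rates", {
  u5 <- 37.7; nm <- 17.5
  r <- ratio_from_rates(nm, u5)
  expect_equal(r, 17.5 / (37.7 - 17.5), tolerance = 1e-12)
  # derive_nmr inverts the transform exactly
  w <- structure(list(coefs = c(log(r), 0, 0), degree = 2, n = 1,
                      sigma = 0), class = "w_function")
  rp <- structure(list(years = 2019, log_p_draws = matrix(0, 10, 1),
                       w = w, country = "World",
                       diagnostics = list(max_rhat = NA_real_)),
                  class = "ratio_posterior")
  nm_post <- derive_nmr(rp, matrix(log(u5), 10, 1))
  expect_equal(unname(exp(nm_post$draws[1, 1, 1])), nm, tolerance = 1e-12)
})

test_that("algebraic limits of the ratio transform hold", {
  w1 <- structure(list(coefs = c(0, 0, 0), degree = 2, n = 1, sigma = 0),
                  class = "w_function")   # W = 1
  rp <- structure(list(years = 2000, log_p_draws = matrix(0, 5, 1),
                       w = w1, country = "A",
                       diagnostics = list(max_rhat = NA_real_)),
                  class = "ratio_posterior")
  # R = 1 gives NMR = U5MR / 2
  nm <- derive_nmr(rp, matrix(log(40), 5, 1))
  expect_equal(exp(nm$draws[, 1, 1]), rep(20, 5))
  # R -> 0 gives NMR -> 0
  w0 <- structure(list(coefs = c(-20, 0, 0), degree = 2, n = 1, sigma = 0),
                  class = "w_function")
  rp0 <- structure(list(years = 2000, log_p_draws = matrix(0, 5, 1),
                        w = w0, country = "A",
                        diagnostics = list(max_rhat = NA_real_)),
                   class = "ratio_posterior")
  nm0 <- derive_nmr(rp0, matrix(log(40), 5, 1))
  expect_lt(max(exp(nm0$draws)), 1e-6)
  # monotonicity: holding R fixed, NMR increases with U5MR
  nm_small <- derive_nmr(rp, matrix(log(20), 5, 1))
  expect_true(all(nm$draws[, 1, 1] > nm_small$draws[, 1, 1]))
})

test_that("country multiplier near 1 is recovered and NMR stays below U5MR", {
  years <- seq(2000.5, 2019.5)
  u5_true <- 80 * exp(-0.03 * (years - 2000.5))
  w_true <- c(2.0, -0.6, 0)
  r_true <- true_ratio_relation(u5_true, w_true)   # P = 1
  nmr_true <- u5_true * r_true / (1 + r_true)
  set.seed(5)
  obs <- data.frame(country = "A", year = years, indicator = "NMR",
                    value = nmr_true * exp(rnorm(length(years), 0, 0.03)),
                    se_log = 0.03, series_id = "A-S", source_type = "survey_FBH")
  u5_est <- data.frame(country = "A", year = years, median = u5_true,
                       lower = u5_true * 0.95, upper = u5_true * 1.05)
  w <- structure(list(coefs = w_true, degree = 2, n = 100, sigma = 0.05),
                 class = "w_function")
  basis <- build_spline_basis(years)
  rp <- fit_country_multiplier(obs, u5_est, w, basis, mcmc = test_mcmc(),
                               seed = 6, check_convergence = FALSE)
  p_med <- apply(exp(rp$log_p_draws), 2, median)
  expect_true(all(p_med > 0.9 & p_med < 1.1))
  nm_post <- derive_nmr(rp, matrix(log(u5_true), nrow(rp$log_p_draws),
                                   length(years), byrow = TRUE))
  expect_true(all(exp(nm_post$draws[, , 1]) <
                    matrix(u5_true, nrow(nm_post$draws), length(years),
                           byrow = TRUE)))
})

test_that("an elevated country multiplier is detected", {
  years <- seq(2000.5, 2019.5)
  u5_true <- 60 * exp(-0.02 * (years - 2000.5))
  w_true <- c(2.0, -0.6, 0)
  r_true <- true_ratio_relation(u5_true, w_true) * 1.3   # P = 1.3
  nmr_true <- u5_true * r_true / (1 + r_true)
  set.seed(15)
  obs <- data.frame(country = "A", year = years, indicator = "NMR",
                    value = nmr_true * exp(rnorm(length(years), 0, 0.03)),
                    se_log = 0.03, series_id = "A-S", source_type = "survey_FBH")
  u5_est <- data.frame(country = "A", year = years, median = u5_true,
                       lower = u5_true, upper = u5_true)
  w <- structure(list(coefs = w_true, degree = 2, n = 100, sigma = 0.05),
                 class = "w_function")
  rp <- fit_country_multiplier(obs, u5_est, w, build_spline_basis(years),
                               mcmc = test_mcmc(), seed = 16,
                               check_convergence = FALSE)
  p_med <- apply(exp(rp$log_p_draws), 2, median)
  expect_true(all(p_med > 1))
})

test_that("with no NMR data the estimate follows the global relation", {
  years <- seq(2000.5, 2019.5)
  u5_true <- 50 * exp(-0.02 * (years - 2000.5))
  w <- structure(list(coefs = c(2.0, -0.6, 0), degree = 2, n = 100,
                      sigma = 0.08), class = "w_function")
  obs0 <- data.frame(country = character(), year = numeric(),
                     indicator = character(), value = numeric(),
                     se_log = numeric(), series_id = character(),
                     source_type = character())
  u5_est <- data.frame(country = "A", year = years, median = u5_true,
                       lower = u5_true, upper = u5_true)
  rp <- fit_country_multiplier(obs0, u5_est, w, build_spline_basis(years),
                               mcmc = test_mcmc(), seed = 8)
  nm <- derive_nmr(rp, matrix(log(u5_true), nrow(rp$log_p_draws),
                              length(years), byrow = TRUE))
  est <- summarize_posterior(nm)
  r_w <- w_eval(w, u5_true)
  nmr_w <- u5_true * r_w / (1 + r_w)
  expect_equal(log(est$median), log(nmr_w), tolerance = 0.02)
  # prior spread is carried through, not collapsed
  expect_true(all(est$upper > est$lower))
})

test_that("debiasing corrects values and inflates standard errors", {
  bias <- data.frame(source_type = c("survey_FBH", "VR"),
                     anchored = c(FALSE, TRUE),
                     mean_bias_log = c(-0.05, 0),
                     extra_sd_log = c(0.03, 0.005),
                     series_sd_log = c(0.04, NA))
  obs <- data.frame(country = "A", year = 2000.5, indicator = "NMR",
                    value = c(20, 20), se_log = c(0.05, 0.05),
                    series_id = c("S", "V"),
                    source_type = c("survey_FBH", "VR"))
  adj <- debias_observations(obs, bias)
  expect_equal(adj$value[1], 20 * exp(0.05))
  expect_equal(adj$value[2], 20)
  expect_equal(adj$se_log[1], sqrt(0.05^2 + 0.03^2 + 0.04^2))
  expect_equal(adj$se_log[2], sqrt(0.05^2 + 0.005^2))
})
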