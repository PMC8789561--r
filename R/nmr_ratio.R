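#' NMR from the ratio model
#'
#' NMR is not modelled directly. Instead the ratio
#' \deqn{R(c,t) = NMR(c,t) / (U5MR(c,t) - NMR(c,t))}
#' is modelled as R = W x P, where W is the expected ratio given the
#' country-year's U5MR (a global relation: the neonatal share of under-5
#' deaths rises as U5MR falls) and P is a smooth country-specific
#' multiplier. Transforming back via NMR = U5MR x R/(1+R) guarantees
#' NMR < U5MR for every posterior draw and lets countries with sparse or no
#' NMR data borrow the global relation (P = 1).
#'
#' @name nmr_ratio
NULL

#' Ratio of NMR to the non-neonatal remainder of U5MR
#'
#' @param nmr,u5mr rates per 1000 livebirths, with nmr < u5mr.
#' @return dimensionless ratio R = nmr/(u5mr - nmr).
#' @export
ratio_from_rates <- function(nmr, u5mr) {
  stopifnot(all(nmr > 0), all(u5mr > nmr))
  nmr / (u5mr - nmr)
}

#' Fit the global relation W between the ratio and U5MR
#'
#' Least-squares fit of log R on log U5MR (quadratic by default) across
#' pooled country-year pairs, giving the expected ratio W(u5mr) used as the
#' baseline of the NMR model.
#'
#' @param pairs data frame with columns \code{ratio} (observed R) and
#'   \code{u5mr}; at least a handful of pairs spanning a wide U5MR range
#'   (20+ recommended).
#' @param degree 1 for log-linear, 2 for log-quadratic (default).
#' @return object of class \code{w_function} with the fitted coefficients.
#' @export
fit_global_relation <- function(pairs, degree = 2) {
  stopifnot(all(c("ratio", "u5mr") %in% names(pairs)),
            all(pairs$ratio > 0), all(pairs$u5mr > 0))
  lu <- log(pairs$u5mr)
  if (stats::sd(lu) < 1e-8) {
    stop("degenerate input: U5MR values are constant, W is unidentifiable")
  }
  df <- data.frame(lr = log(pairs$ratio), lu = lu)
  fit <- if (degree >= 2) {
    stats::lm(lr ~ lu + I(lu^2), data = df)
  } else {
    stats::lm(lr ~ lu, data = df)
  }
  co <- stats::coef(fit)
  structure(list(coefs = c(co, rep(0, 3 - length(co))), degree = degree,
                 n = nrow(pairs), sigma = stats::sigma(fit)),
            class = "w_function")
}

#' Evaluate a fitted global relation
#'
#' @param w a \code{w_function}.
#' @param u5mr rates per 1000 livebirths.
#' @return expected ratio W(u5mr), strictly positive.
#' @export
w_eval <- function(w, u5mr) {
  stopifnot(inherits(w, "w_function"), all(u5mr > 0))
  lu <- log(u5mr)
  exp(w$coefs[1] + w$coefs[2] * lu + w$coefs[3] * lu^2)
}

#' @export
print.w_function <- function(x, ...) {
  cat("global NMR/U5MR ratio relation: log W =",
      paste(round(x$coefs, 4), collapse = " , "),
      "(intercept, log u5mr, squared); n =", x$n, "\n")
  invisible(x)
}

#' Apply a fitted source-type error model to observations
#'
#' Divides observed values by the estimated mean bias multiplier of their
#' source type and inflates the reported standard error by the estimated
#' non-sampling and series-divergence SDs (all on the log scale). Source
#' types absent from the bias table pass through unchanged.
#'
#' @param observations observation records.
#' @param bias the \code{bias} element of a [fit_b3()] result (or NULL for
#'   a no-op).
#' @return the observations with adjusted \code{value} and \code{se_log}.
#' @export
debias_observations <- function(observations, bias = NULL) {
  if (is.null(bias) || nrow(observations) == 0) return(observations)
  i <- match(observations$source_type, bias$source_type)
  pick <- function(col) {
    v <- ifelse(is.na(i), 0, bias[[col]][i])
    ifelse(is.na(v), 0, v)
  }
  observations$value <- observations$value * exp(-pick("mean_bias_log"))
  observations$se_log <- sqrt(observations$se_log^2 +
                                pick("extra_sd_log")^2 +
                                pick("series_sd_log")^2)
  observations
}

.p_jags_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(inprod(B[i, ], alpha[]), 1 / (se2[i] + pow(sd_extra, 2)))
  }
  alpha[1] ~ dnorm(0, prec_p0)
  for (k in 2:K) {
    alpha[k] ~ dnorm(alpha[k - 1], tau_alpha)
  }
  tau_alpha ~ dgamma(1.5, 0.015)
  sigma_alpha <- 1 / sqrt(tau_alpha)
  sd_extra ~ dunif(0, 0.5)
}
"

#' Fit the country multiplier P of the ratio model
#'
#' Bayesian B-spline fit of log P(t) for one country. Observed ratios are
#' formed from the country's NMR observations and the posterior-median U5MR
#' at the observation year; the residual log R - log W(U5MR) is smoothed
#' with a random-walk spline centred at zero (prior mean P = 1). With no
#' NMR observations the prior is returned degenerate at P = 1, so the NMR
#' estimate follows the global relation exactly.
#'
#' @param nmr_observations observation records with indicator NMR for one
#'   country (may have zero rows).
#' @param u5mr_estimates \code{estimate_series} rows for the same country,
#'   covering all observation years.
#' @param w a fitted [fit_global_relation()] object.
#' @param basis [build_spline_basis()] spanning the estimation years.
#' @param bias optional source-type bias summary (the \code{bias} element
#'   of a [fit_b3()] result): NMR observations are corrected by the
#'   per-type mean log-bias and their error variance inflated by the
#'   estimated non-sampling and series-divergence components, mirroring
#'   the U5MR error model.
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed.
#' @param years year grid for the returned P draws (default annual over the
#'   basis span).
#' @param check_convergence raise on R-hat above \code{mcmc$rhat_max}.
#' @return list of class \code{ratio_posterior}: \code{years},
#'   \code{log_p_draws} (draws x years), \code{w}, \code{country}.
#' @export
fit_country_multiplier <- function(nmr_observations, u5mr_estimates, w, basis,
                                   bias = NULL, mcmc = mcmc_config(),
                                   seed = 1, years = NULL,
                                   check_convergence = TRUE) {
  stopifnot(inherits(w, "w_function"))
  if (is.null(years)) {
    years <- seq(basis$boundary[1], basis$boundary[2], by = 1)
  }
  country <- if (nrow(nmr_observations) > 0) nmr_observations$country[1]
             else unique(u5mr_estimates$country)[1]
  obs <- debias_observations(nmr_observations, bias)
  if (nrow(obs) > 0) {
    iu <- match(obs$year, u5mr_estimates$year)
    if (anyNA(iu)) stop("U5MR estimates do not cover all NMR observation years")
    u5 <- u5mr_estimates$median[iu]
    ok <- obs$value < u5
    if (!all(ok)) {
      warning(sum(!ok), " NMR observation(s) at or above the U5MR estimate ",
              "dropped for country ", country)
      obs <- obs[ok, , drop = FALSE]
      u5 <- u5[ok]
    }
  }
  n_draws_target <- with(mcmc, n_chains * (n_iter %/% thin))
  if (nrow(obs) == 0) {
    # prior-dominated: P centred at 1, with the cross-country spread of the
    # global relation's residuals as the honest level uncertainty
    set.seed(as.integer(seed))
    log_p <- matrix(rnorm(n_draws_target, 0, w$sigma),
                    n_draws_target, length(years))
    return(structure(list(years = years, log_p_draws = log_p, w = w,
                          country = country,
                          diagnostics = list(max_rhat = NA_real_)),
                     class = "ratio_posterior"))
  }
  r_obs <- ratio_from_rates(obs$value, u5)
  y <- log(r_obs) - log(w_eval(w, u5))
  # delta method: d log R / d log NMR = 1 + R
  se_logr <- (1 + r_obs) * obs$se_log
  B <- basis_matrix(basis, obs$year)
  data <- list(y = y, B = B, se2 = se_logr^2, N = length(y),
               K = basis$n_basis, prec_p0 = 1 / 0.25^2)
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(.p_jags_model), data = data,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = TRUE)
  stats::update(jm, mcmc$n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("alpha", "sigma_alpha", "sd_extra"),
                              n.iter = mcmc$n_iter, thin = mcmc$thin,
                              progress.bar = "none")
  diag <- .convergence_diagnostics(samp)
  if (check_convergence && mcmc$n_chains >= 2 &&
      is.finite(diag$max_rhat) && diag$max_rhat > mcmc$rhat_max) {
    stop("ratio-model MCMC did not converge for ", country,
         ": max R-hat ", round(diag$max_rhat, 3))
  }
  m <- as.matrix(samp)
  acols <- sprintf("alpha[%d]", seq_len(basis$n_basis))
  log_p <- m[, acols, drop = FALSE] %*% t(basis_matrix(basis, years))
  structure(list(years = years, log_p_draws = log_p, w = w, country = country,
                 diagnostics = diag),
            class = "ratio_posterior")
}

#' Derive NMR draws from ratio and U5MR draws
#'
#' Applies NMR = U5MR x R/(1+R) draw by draw, where
#' R = W(U5MR) x P. Because R/(1+R) < 1 for any positive R, every NMR draw
#' is strictly below its paired U5MR draw.
#'
#' @param ratio_posterior a [fit_country_multiplier()] result.
#' @param u5mr_draws matrix (draws x years) of log U5MR draws for the same
#'   country and year grid (see [country_draws()]). Draw counts are aligned
#'   by truncation to the smaller of the two.
#' @return \code{rate_posterior} (single country) of log NMR draws.
#' @export
derive_nmr <- function(ratio_posterior, u5mr_draws) {
  stopifnot(inherits(ratio_posterior, "ratio_posterior"))
  if (ncol(u5mr_draws) != length(ratio_posterior$years)) {
    stop("year grids of ratio and U5MR draws differ")
  }
  nd <- min(nrow(u5mr_draws), nrow(ratio_posterior$log_p_draws))
  u5 <- exp(u5mr_draws[seq_len(nd), , drop = FALSE])
  r <- w_eval(ratio_posterior$w, u5) *
    exp(ratio_posterior$log_p_draws[seq_len(nd), , drop = FALSE])
  nmr <- u5 * r / (1 + r)
  rate_posterior(log(nmr), ratio_posterior$years, ratio_posterior$country)
}
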