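#' @importFrom stats quantile median rnorm runif setNames update
NULL

#' MCMC settings for the Bayesian trend models
#'
#' @param n_chains number of parallel chains (at least 2 for convergence
#'   diagnostics; default 4).
#' @param n_adapt adaptation iterations.
#' @param n_burnin burn-in iterations discarded before sampling.
#' @param n_iter sampling iterations per chain.
#' @param thin thinning interval.
#' @param rhat_max largest acceptable potential scale reduction factor
#'   (Gelman-Rubin R-hat); the fit raises an error above this.
#' @export
mcmc_config <- function(n_chains = 4, n_adapt = 500, n_burnin = 2000,
                        n_iter = 2000, thin = 4, rhat_max = 1.05) {
  stopifnot(n_chains >= 1, n_iter >= 10)
  list(n_chains = n_chains, n_adapt = n_adapt, n_burnin = n_burnin,
       n_iter = n_iter, thin = thin, rhat_max = rhat_max)
}

#' Priors for the source-type bias model
#'
#' Observed log-rates are modelled as true log-rate + mean_bias_log[source]
#' + noise, with noise variance se_log^2 + extra_var[source]. One source
#' type (vital registration by default) is anchored at zero log-bias for
#' identifiability; the others get a normal prior centred at zero. The
#' non-sampling SDs get a uniform prior on [0, extra_sd_max].
#'
#' @param bias_sd prior SD of the per-source-type mean log-bias.
#' @param extra_sd_max upper bound of the uniform prior on the per-source
#'   non-sampling SD (log scale).
#' @param series_tau_shape,series_tau_rate gamma prior (conjugate) on the
#'   precision of the per-series random offsets (a series' common
#'   divergence from the truth), pooled by source type; the defaults put
#'   the offset SD loosely around 0.05-0.2 on the log scale. The anchor
#'   type has no series offsets.
#' @param anchor source type whose mean log-bias is fixed to zero.
#' @export
bias_prior <- function(bias_sd = 0.2, extra_sd_max = 0.5,
                       series_tau_shape = 1.5, series_tau_rate = 0.015,
                       anchor = "VR") {
  stopifnot(bias_sd > 0, extra_sd_max > 0, series_tau_shape > 0,
            series_tau_rate > 0)
  list(bias_sd = bias_sd, extra_sd_max = extra_sd_max,
       series_tau_shape = series_tau_shape,
       series_tau_rate = series_tau_rate, anchor = anchor)
}

.b3_jags_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], prec[i])
    mu[i] <- inprod(B[i, ], alpha[cid[i], ]) + beta[sid[i]] + u[serid[i]]
    prec[i] <- 1 / (se2[i] + pow(sd_extra[sid[i]], 2))
  }
  # series-level random offsets: a whole data series can sit above or below
  # the truth by a common factor; pooled by source type across countries.
  # The anchor source type (VR) has none: it defines the level.
  for (j in 1:J) {
    u[j] <- (1 - ser_anch[j]) * u_free[j]
    u_free[j] ~ dnorm(0, tau_series[ser_type[j]])
  }
  for (c in 1:C) {
    alpha[c, 1] ~ dnorm(a0[c], 0.25)
    for (k in 2:K) {
      alpha[c, k] ~ dnorm(alpha[c, k - 1], tau_alpha)
    }
  }
  tau_alpha ~ dgamma(1.5, 0.015)
  sigma_alpha <- 1 / sqrt(tau_alpha)
  for (s in 1:S) {
    beta[s] <- (1 - anchored[s]) * beta_free[s]
    beta_free[s] ~ dnorm(0, prec_beta)
    sd_extra[s] ~ dunif(0, extra_sd_max)
    tau_series[s] ~ dgamma(series_tau_shape, series_tau_rate)
    sigma_series[s] <- 1 / sqrt(tau_series[s])
  }
}
"

#' Fit the Bayesian B-spline bias-adjusted trend model
#'
#' Fits, jointly across the countries present in \code{observations}, a
#' penalised B-spline regression of log U5MR (or log NMR) with a
#' multiplicative observation error model. On the log scale,
#' \deqn{log(observed) = log(true) + bias[source] + \epsilon,\quad
#'       Var(\epsilon) = se_{log}^2 + extra\_var[source],}
#' where the true log-rate for each country is a spline with a first-order
#' random-walk prior on its coefficients (smoothing), the per-source-type
#' mean log-biases are pooled across all countries in the call, and the
#' anchor source type (VR) is fixed at zero bias. Sampling is by Gibbs/slice
#' MCMC via JAGS.
#'
#' @param observations data frame of observation records (see
#'   [read_observations()]); all rows are used, so filter to one indicator
#'   before calling.
#' @param basis a [build_spline_basis()] object spanning all observation
#'   years plus the years to be estimated.
#' @param prior a [bias_prior()].
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed; chains get distinct deterministic RNG streams.
#' @param years year grid at which posterior trajectories are evaluated
#'   (default: annual mid-year grid over the basis span).
#' @param check_convergence raise an error if max R-hat exceeds
#'   \code{mcmc$rhat_max} (default TRUE; requires at least 2 chains).
#' @return object of class \code{rate_posterior}: list with \code{years},
#'   \code{countries}, \code{draws} (array draws x years x countries of
#'   posterior log-rate samples), \code{bias} (posterior summary of
#'   source-type biases and non-sampling SDs), \code{diagnostics} and
#'   \code{seed}.
#' @export
fit_b3 <- function(observations, basis, prior = bias_prior(),
                   mcmc = mcmc_config(), seed = 1, years = NULL,
                   check_convergence = TRUE) {
  obs <- observations
  stopifnot(nrow(obs) >= 1, all(obs$value > 0), all(is.finite(obs$se_log)))
  if (is.null(years)) {
    years <- seq(basis$boundary[1], basis$boundary[2], by = 1)
  }
  countries <- sort(unique(obs$country))
  sources <- sort(unique(obs$source_type))
  cid <- match(obs$country, countries)
  sid <- match(obs$source_type, sources)
  anchored <- as.numeric(sources == prior$anchor)
  if (!any(anchored == 1) && length(sources) > 1) {
    # no anchor present in the data: anchor the first source type instead
    anchored[1] <- 1
  }
  if (length(sources) == 1) anchored[1] <- 1
  B <- basis_matrix(basis, obs$year)
  y <- log(obs$value)
  a0 <- as.numeric(tapply(y, cid, mean))[seq_along(countries)]
  series <- unique(data.frame(series_id = obs$series_id,
                              source_type = obs$source_type))
  serid <- match(obs$series_id, series$series_id)
  ser_type <- match(series$source_type, sources)
  ser_anch <- anchored[ser_type]

  data <- list(y = y, B = B, cid = cid, sid = sid, a0 = a0,
               serid = serid, ser_type = ser_type, ser_anch = ser_anch,
               J = nrow(series),
               se2 = obs$se_log^2,
               N = nrow(obs), C = length(countries), K = basis$n_basis,
               S = length(sources), anchored = anchored,
               prec_beta = 1 / prior$bias_sd^2,
               extra_sd_max = prior$extra_sd_max,
               series_tau_shape = prior$series_tau_shape,
               series_tau_rate = prior$series_tau_rate)
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  # block updating of the conjugate normal sub-graph (spline coefficients
  # and biases are strongly correlated; single-site Gibbs mixes poorly)
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(.b3_jags_model), data = data,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = TRUE)
  stats::update(jm, mcmc$n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(
    jm, c("alpha", "beta", "sd_extra", "sigma_series", "sigma_alpha"),
    n.iter = mcmc$n_iter, thin = mcmc$thin, progress.bar = "none")

  anchor_idx <- which(anchored == 1)
  diag <- .convergence_diagnostics(
    samp, skip_names = c(sprintf("beta[%d]", anchor_idx),
                         sprintf("sigma_series[%d]", anchor_idx)))
  if (check_convergence && mcmc$n_chains >= 2 &&
      is.finite(diag$max_rhat) && diag$max_rhat > mcmc$rhat_max) {
    stop("MCMC did not converge: max R-hat ", round(diag$max_rhat, 3),
         " exceeds ", mcmc$rhat_max)
  }

  m <- as.matrix(samp)
  Bg <- basis_matrix(basis, years)
  n_draws <- nrow(m)
  draws <- array(NA_real_, c(n_draws, length(years), length(countries)),
                 dimnames = list(NULL, NULL, countries))
  for (c in seq_along(countries)) {
    acols <- sprintf("alpha[%d,%d]", c, seq_len(basis$n_basis))
    draws[, , c] <- m[, acols, drop = FALSE] %*% t(Bg)
  }
  # JAGS omits monitored nodes it treats as constants (the anchored bias
  # in a single-source fit); default those to their fixed value
  col_mean <- function(fmt, default = 0) {
    vapply(seq_along(sources), function(s) {
      cl <- sprintf(fmt, s)
      if (cl %in% colnames(m)) mean(m[, cl]) else default
    }, numeric(1))
  }
  bias <- data.frame(
    source_type = sources,
    anchored = anchored == 1,
    mean_bias_log = col_mean("beta[%d]"),
    extra_sd_log = col_mean("sd_extra[%d]", NA_real_),
    series_sd_log = ifelse(anchored == 1, NA_real_,
                           col_mean("sigma_series[%d]", NA_real_)),
    row.names = NULL
  )
  structure(
    list(years = years, countries = countries, draws = draws, bias = bias,
         diagnostics = diag, seed = seed, mcmc = mcmc, basis = basis),
    class = "rate_posterior"
  )
}

# max R-hat over monitored scalars; anchored beta nodes are constants (and
# the anchor's series SD is prior-only), so they are excluded.
.convergence_diagnostics <- function(samp, skip_names = character()) {
  if (coda::nchain(samp) < 2) {
    return(list(max_rhat = NA_real_, n_eff_min = NA_real_))
  }
  keep <- setdiff(coda::varnames(samp), skip_names)
  sub <- samp[, keep, drop = FALSE]
  g <- try(coda::gelman.diag(sub, multivariate = FALSE, autoburnin = FALSE),
           silent = TRUE)
  if (inherits(g, "try-error")) return(list(max_rhat = NA_real_))
  list(max_rhat = max(g$psrf[, 1], na.rm = TRUE))
}

#' Extract the draw matrix for one country
#'
#' @param posterior a \code{rate_posterior}.
#' @param country country identifier.
#' @return matrix (draws x years) of posterior log-rate samples.
#' @export
country_draws <- function(posterior, country) {
  stopifnot(inherits(posterior, "rate_posterior"))
  i <- match(country, posterior$countries)
  if (is.na(i)) stop("no posterior for country ", country)
  posterior$draws[, , i]
}

#' Assemble a rate_posterior from a draw array
#'
#' Utility for downstream stages (ratio model, projections) that construct
#' posterior trajectories outside of an MCMC fit.
#'
#' @param draws array (draws x years x countries) of log-rate samples, or a
#'   matrix (draws x years) for a single country.
#' @param years year grid.
#' @param countries country identifiers.
#' @export
rate_posterior <- function(draws, years, countries) {
  if (is.matrix(draws)) {
    draws <- array(draws, c(nrow(draws), ncol(draws), 1),
                   dimnames = list(NULL, NULL, countries))
  }
  stopifnot(dim(draws)[2] == length(years), dim(draws)[3] == length(countries))
  structure(list(years = years, countries = countries, draws = draws,
                 diagnostics = list(max_rhat = NA_real_)),
            class = "rate_posterior")
}

#' @export
print.rate_posterior <- function(x, ...) {
  cat("rate posterior:", length(x$countries), "countries,",
      dim(x$draws)[1], "draws over years", min(x$years), "-", max(x$years), "\n")
  if (!is.null(x$diagnostics$max_rhat) && is.finite(x$diagnostics$max_rhat)) {
    cat("  max R-hat:", round(x$diagnostics$max_rhat, 3), "\n")
  }
  invisible(x)
}

#' Summarise a posterior into median and equal-tailed interval
#'
#' Returns, per country-year, the posterior median rate and the equal-tailed
#' uncertainty interval at the given level (5th/95th percentiles for the
#' default 90 percent level), on the rate (per 1000 livebirths) scale.
#'
#' @param posterior a \code{rate_posterior} (draws on the log scale).
#' @param level interval probability (default 0.90).
#' @return data frame of class \code{estimate_series} with columns
#'   \code{country}, \code{year}, \code{median}, \code{lower}, \code{upper}
#'   and attribute \code{level}.
#' @export
summarize_posterior <- function(posterior, level = 0.90) {
  stopifnot(inherits(posterior, "rate_posterior"), level > 0, level < 1)
  p <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  out <- list()
  for (c in seq_along(posterior$countries)) {
    q <- apply(exp(posterior$draws[, , c, drop = FALSE]), 2, quantile,
               probs = p, names = FALSE)
    out[[c]] <- data.frame(country = posterior$countries[c],
                           year = posterior$years,
                           median = q[2, ], lower = q[1, ], upper = q[3, ])
  }
  res <- do.call(rbind, out)
  attr(res, "level") <- level
  class(res) <- c("estimate_series", "data.frame")
  res
}

#' Extrapolate posterior trajectories beyond the data period
#'
#' Extends each posterior draw to \code{horizon_end} with a per-year log
#' decrement blending the draw's own recent trend with a global annual rate
#' of reduction. For extrapolated year k the decrement is
#' \deqn{\rho^k a_{draw} + (1-\rho^k)\, a_{global},}
#' so the country's own trend dominates early and the global trend
#' increasingly takes over. A small random-walk innovation (default SD
#' 0.03 per year on the log scale, matching the per-year diffusion of the
#' fitted trend family) widens the intervals with extrapolation length.
#'
#' @param posterior a \code{rate_posterior}.
#' @param global_arr global annual rate of reduction (positive = decline).
#' @param horizon_end last year of the extended grid.
#' @param from named vector of per-country years after which to extrapolate
#'   (default: the posterior's last year for every country). Years after
#'   \code{from} are overwritten; use this to replace data-free tail years
#'   with trend-blended extrapolation.
#' @param rho per-year weight retention on the country trend (default 0.9).
#' @param window number of trailing years used for the draw's own trend.
#' @param innovation_sd SD of the per-year log-scale random-walk innovation
#'   (0 gives deterministic continuation of each draw).
#' @param seed integer seed for the innovations.
#' @param direction \code{"forward"} extends/overwrites years after
#'   \code{from}; \code{"backward"} overwrites years before \code{from}
#'   (backcasting before a country's first datapoint with the same blend).
#' @return a new \code{rate_posterior} on the extended year grid.
#' @export
extrapolate <- function(posterior, global_arr, horizon_end = NULL,
                        from = NULL, rho = 0.9, window = 10,
                        innovation_sd = 0.03, seed = 1,
                        direction = c("forward", "backward")) {
  stopifnot(inherits(posterior, "rate_posterior"))
  direction <- match.arg(direction)
  fwd <- direction == "forward"
  years <- posterior$years
  step <- years[2] - years[1]
  if (is.null(horizon_end)) horizon_end <- if (fwd) max(years) else min(years)
  if (is.null(from)) {
    from <- setNames(rep(if (fwd) max(years) else min(years),
                         length(posterior$countries)),
                     posterior$countries)
  }
  new_years <- if (fwd) seq(min(years), horizon_end, by = step)
               else seq(horizon_end, max(years), by = step)
  old_idx <- match(round(years, 6), round(new_years, 6))
  nd <- dim(posterior$draws)[1]
  set.seed(as.integer(seed))
  draws <- array(NA_real_, c(nd, length(new_years), length(posterior$countries)),
                 dimnames = list(NULL, NULL, posterior$countries))
  draws[, old_idx, ] <- posterior$draws
  for (c in seq_along(posterior$countries)) {
    f_c <- from[[posterior$countries[c]]]
    if (is.null(f_c) || is.na(f_c)) f_c <- if (fwd) max(years) else min(years)
    i_from <- if (fwd) max(which(years <= f_c + 1e-9))
              else min(which(years >= f_c - 1e-9))
    # per-draw recent trend: average per-year log decline over the window
    # of fitted years adjacent to the jump-off point
    i_win <- if (fwd) max(1L, i_from - as.integer(round(window / step)))
             else min(length(years), i_from + as.integer(round(window / step)))
    span <- abs(i_from - i_win) * step
    a_draw <- if (span > 0) {
      if (fwd) (posterior$draws[, i_win, c] - posterior$draws[, i_from, c]) / span
      else (posterior$draws[, i_from, c] - posterior$draws[, i_win, c]) / span
    } else rep(global_arr, nd)
    level <- posterior$draws[, i_from, c]
    ext_idx <- if (fwd) which(new_years > years[i_from] + 1e-9)
               else rev(which(new_years < years[i_from] - 1e-9))
    for (j in seq_along(ext_idx)) {
      k <- j * step
      w <- rho^k
      decr <- (w * a_draw + (1 - w) * global_arr) * step
      eps <- if (innovation_sd > 0) rnorm(nd, 0, innovation_sd * sqrt(step)) else 0
      # rates fall forward in time, rise backward
      level <- level + (if (fwd) -decr else decr) + eps
      draws[, ext_idx[j], c] <- level
    }
  }
  structure(
    list(years = new_years, countries = posterior$countries, draws = draws,
         bias = posterior$bias, diagnostics = posterior$diagnostics,
         seed = posterior$seed, mcmc = posterior$mcmc),
    class = "rate_posterior"
  )
}

#' Posterior-median annual rate of reduction per country
#'
#' Convenience for extrapolation and projection stages: computes the ARR of
#' the posterior median trajectory between two years for every country.
#'
#' @param posterior a \code{rate_posterior}.
#' @param t1,t2 start and end year (matched to the nearest grid year).
#' @return named numeric vector of per-year reduction rates.
#' @export
posterior_arr <- function(posterior, t1, t2) {
  i1 <- which.min(abs(posterior$years - t1))
  i2 <- which.min(abs(posterior$years - t2))
  stopifnot(i1 < i2)
  med <- apply(posterior$draws, c(2, 3), median)
  out <- (med[i1, ] - med[i2, ]) / (posterior$years[i2] - posterior$years[i1])
  setNames(as.numeric(out), posterior$countries)
}
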