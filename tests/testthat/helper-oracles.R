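# Independent oracles used by the tests. These deliberately re-derive the
# quantities with different algorithms (textbook recursion, brute-force
# microsimulation) so the package code is checked against something it does
# not share.

# Cox-de Boor recursive B-spline evaluation (textbook form, zero-width
# intervals handled by the 0/0 := 0 convention).
cox_de_boor <- function(knots, i, k, x) {
  if (k == 0) {
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  }
  d1 <- knots[i + k] - knots[i]
  d2 <- knots[i + k + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * cox_de_boor(knots, i, k - 1, x) else 0
  t2 <- if (d2 > 0) (knots[i + k + 1] - x) / d2 *
          cox_de_boor(knots, i + 1, k - 1, x) else 0
  t1 + t2
}

# Daily-resolution microsimulation of the birth-week cohort method: 1/365
# year steps, explicit splitting at the neonatal age boundary. Slow but
# direct.
daily_microsim <- function(livebirths, schedules, years, step = 1 / 365) {
  a1 <- 28 / 365.25
  by_range <- (min(years) - 5):max(years)
  res <- matrix(0, length(years), 2)
  lbv <- stats::setNames(livebirths$births, livebirths$year)
  schy <- schedules$year
  for (by in by_range) {
    b <- lbv[as.character(by)]
    if (is.na(b)) b <- if (by < min(schy)) lbv[[1]] else lbv[[length(lbv)]]
    for (w in 1:52) {
      t0 <- by + (w - 0.5) / 52
      S <- b / 52
      t <- t0
      while (t < t0 + 5 - 1e-12) {
        dt <- min(step, t0 + 5 - t)
        age <- t - t0
        yr <- floor(t + dt / 2)
        i <- which.min(abs(schy - min(max(yr, min(schy)), max(schy))))
        if (age < a1 && age + dt > a1) {
          d1 <- S * (1 - exp(-schedules$hazard_neonatal[i] * (a1 - age)))
          d2 <- (S - d1) *
            (1 - exp(-schedules$hazard_postneonatal[i] * (age + dt - a1)))
          dn <- d1
          d <- d1 + d2
        } else {
          h <- if (age < a1) schedules$hazard_neonatal[i]
               else schedules$hazard_postneonatal[i]
          d <- S * (1 - exp(-h * dt))
          dn <- if (age < a1) d else 0
        }
        S <- S - d
        yi <- match(yr, years)
        if (!is.na(yi)) {
          res[yi, 1] <- res[yi, 1] + dn
          res[yi, 2] <- res[yi, 2] + (d - dn)
        }
        t <- t + dt
      }
    }
  }
  data.frame(year = years, deaths_neonatal = res[, 1],
             deaths_1_59m = res[, 2],
             deaths_under5 = res[, 1] + res[, 2])
}

# light MCMC settings for unit tests (acceptance tests use heavier ones)
test_mcmc <- function(...) {
  mcmc_config(n_adapt = 300, n_burnin = 800, n_iter = 800, thin = 2, ...)
}
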