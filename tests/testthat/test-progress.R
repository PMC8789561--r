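test_that("countries are classified against the SDG target correctly", {
  # at or below target: achieved regardless of trend
  p <- classify_progress(20, -0.05, 25)
  expect_equal(p$status, "achieved")
  # slow decline from 50: needs more than triple the current pace
  p2 <- classify_progress(50, 0.02, 25)
  expect_equal(p2$status, "acceleration_needed")
  expect_equal(p2$acceleration_factor, (log(2) / 11) / 0.02, tolerance = 1e-12)
  expect_equal(p2$band, ">=3")
  # 30 falling at 5 percent per year reaches ~17.3 by 2030: on track
  p3 <- classify_progress(30, 0.05, 25)
  expect_equal(p3$status, "on_track")
})

test_that("achievement years follow the current-trends crossing time", {
  p <- classify_progress(50, 0.05, 25)
  expect_equal(p$achievement_year, 2019 + ceiling(log(2) / 0.05))
  # stagnating or rising mortality never achieves
  p0 <- classify_progress(50, 0, 25)
  expect_equal(p0$achievement_label, ">2099")
  expect_equal(p0$band, ">=3")
  pn <- classify_progress(50, -0.03, 25)
  expect_equal(pn$achievement_label, ">2099")
  # a crossing after 2099 is reported the same way
  pslow <- classify_progress(50, 0.005, 25)
  expect_equal(pslow$achievement_label, ">2099")
})

test_that("every country receives exactly one status", {
  set.seed(42)
  est <- runif(200, 2, 150)
  arr <- runif(200, -0.02, 0.08)
  p <- classify_progress(est, arr, 25)
  expect_equal(nrow(p), 200)
  counts <- table(factor(p$status, c("achieved", "on_track",
                                     "acceleration_needed")))
  expect_equal(sum(counts), 200L)
  expect_true(all(p$acceleration_factor >= 0))
  expect_true(all((p$est_2019 <= 25) == (p$status == "achieved")))
})

test_that("percent decline matches the published summary figures", {
  expect_equal(percent_decline(93.0, 37.7), 59)
  expect_equal(percent_decline(12494, 5189), 58)
  expect_equal(percent_decline(36.6, 17.5), 52)
  expect_equal(percent_decline(40, 40), 0)
  # exact round trip for integer percents
  for (p in c(0L, 13L, 50L, 99L, 100L)) {
    expect_equal(percent_decline(80, 80 * (1 - p / 100)), p)
  }
})

test_that("share, one-in-N and fold indicators match the published values", {
  expect_equal(percent_share(2440, 5189), 47)   # neonatal share of deaths
  expect_equal(one_in_n(75.8), 13)              # highest-burden region
  expect_equal(fold_ratio(94.7, 5.0), 19)       # vs high-income average
})

fake_deaths_posterior <- function(draws_u5, years) {
  nd <- nrow(draws_u5)
  arr <- array(0, c(nd, length(years), 3),
               dimnames = list(NULL, NULL, c("neonatal", "m1_59", "under5")))
  arr[, , 1] <- draws_u5 * 0.4
  arr[, , 2] <- draws_u5 * 0.6
  arr[, , 3] <- draws_u5
  p <- c(0.05, 0.5, 0.95)
  qs <- apply(arr, c(2, 3), quantile, probs = p, names = FALSE)
  summary <- data.frame(year = years,
                        deaths_neonatal = qs[2, , 1],
                        neonatal_lower = qs[1, , 1], neonatal_upper = qs[3, , 1],
                        deaths_1_59m = qs[2, , 2],
                        m1_59_lower = qs[1, , 2], m1_59_upper = qs[3, , 2],
                        deaths_under5 = qs[2, , 3],
                        under5_lower = qs[1, , 3], under5_upper = qs[3, , 3])
  structure(list(years = years, draws = arr, summary = summary, level = 0.9),
            class = "deaths_posterior")
}

test_that("group aggregation sums draws before taking quantiles", {
  set.seed(9)
  years <- 2019:2021
  cd <- list(
    A = fake_deaths_posterior(matrix(rlnorm(300, log(1000), 0.2), 100), years),
    B = fake_deaths_posterior(matrix(rlnorm(300, log(500), 0.3), 100), years),
    C = fake_deaths_posterior(matrix(rlnorm(300, log(200), 0.1), 100), years))
  groups <- data.frame(country = c("A", "B", "C"),
                       region = c("R1", "R1", "R2"),
                       income_group = c("I1", "I2", "I2"))
  agg <- aggregate_deaths(cd, groups, by = "region")
  expect_setequal(names(agg), c("R1", "R2"))
  # one-country group equals that country
  expect_equal(agg$R2$summary$deaths_under5, cd$C$summary$deaths_under5)
  # draw-level conservation: world draws equal the sum of region draws
  world <- aggregate_deaths(cd, groups, by = "world")$World
  expect_equal(world$draws, agg$R1$draws + agg$R2$draws)
  # the median of a sum need not equal the sum of medians, but the 5th
  # percentile of the sum dominates the sum of 5th percentiles
  expect_true(all(world$summary$under5_lower >=
                    cd$A$summary$under5_lower + cd$B$summary$under5_lower +
                    cd$C$summary$under5_lower - 1e-9))
  # unmapped countries are an error
  expect_error(aggregate_deaths(cd, groups[1:2, ], by = "region"),
               "not in the grouping")
})

test_that("group rates are births-weighted means of member rates", {
  years <- 2018:2020
  draws <- list(A = matrix(log(20), 50, 3), B = matrix(log(40), 50, 3))
  births <- list(A = rep(1e5, 3), B = rep(1e5, 3))
  g <- aggregate_rate(draws, births, years)
  expect_equal(g$summary$median, rep(30, 3))
  # identical member rates pass through unchanged
  g2 <- aggregate_rate(list(A = matrix(log(20), 50, 3),
                            B = matrix(log(20), 50, 3)), births, years)
  expect_equal(g2$summary$median, rep(20, 3))
  # convexity: group rate lies between member extremes
  births3 <- list(A = rep(2e5, 3), B = rep(5e4, 3))
  g3 <- aggregate_rate(draws, births3, years)
  expect_true(all(g3$summary$median > 20 & g3$summary$median < 40))
})
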