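test_that("ARR reproduces the published global rates of decline", {
  # global U5MR fell from 93.0 to 37.7 over 1990-2019: 3.1 percent per year
  expect_equal(round(100 * compute_arr(93.0, 37.7, 1990, 2019), 1), 3.1)
  # global NMR fell from 36.6 to 17.5: 2.5 percent per year
  expect_equal(round(100 * compute_arr(36.6, 17.5, 1990, 2019), 1), 2.5)
  expect_equal(compute_arr(40, 40, 2000, 2010), 0)
  expect_error(compute_arr(-1, 5, 2000, 2010), "positive")
})

test_that("required ARR is the constant rate hitting the target at 2030", {
  expect_equal(required_arr(25, 25), 0)
  expect_equal(required_arr(50, 25), log(2) / 11)
  expect_equal(required_arr(20, 25), 0)  # already achieved: clamped
})

test_that("ARR round-trips through an exponential projection exactly", {
  for (a in c(0.005, 0.031, 0.09)) {
    cfg <- scenario_config("current_trends")
    path <- project_u5mr(60, a, cfg)
    expect_equal(compute_arr(path[["2020"]], path[["2030"]], 2020, 2030), a,
                 tolerance = 1e-12)
  }
})

test_that("scenario paths obey their defining rules", {
  cfg_const <- scenario_config("constant_2019")
  expect_equal(unname(project_u5mr(40, 0.05, cfg_const)), rep(40, 11))
  # negative current ARR: held flat at the 2019 level
  cfg_cur <- scenario_config("current_trends")
  expect_equal(unname(project_u5mr(40, -0.02, cfg_cur)), rep(40, 11))
  # floor activation: fast decline from a low level clamps at 1.7
  p <- project_u5mr(2.0, 0.10, cfg_cur)
  expect_true(any(p == 1.7))
  expect_true(all(diff(p) <= 0))
  expect_equal(unname(p[["2030"]]), 1.7)
  # SDG scenario endpoint exactness for a non-on-track country
  cfg_sdg <- scenario_config("achieve_sdg")
  p_sdg <- project_u5mr(50, 0.01, cfg_sdg)
  expect_equal(unname(p_sdg[["2030"]]), 25)
  # on-track country keeps its current-trends path
  p_ot <- project_u5mr(30, 0.05, cfg_sdg)
  expect_equal(p_ot, project_u5mr(30, 0.05, cfg_cur))
  # HIC scenario endpoint
  cfg_hic <- scenario_config("achieve_hic")
  expect_equal(unname(project_u5mr(50, 0.01, cfg_hic)[["2030"]]), 5.0)
})

test_that("NMR projection applies its own floor, targets and the ratio cap", {
  cfg_cur <- scenario_config("current_trends")
  u5 <- project_u5mr(40, 0.02, cfg_cur)
  # cap inactive: flat constant scenario below 0.79 x U5MR
  cfg_const <- scenario_config("constant_2019")
  u5c <- project_u5mr(40, 0, cfg_const)
  expect_equal(unname(project_nmr(10, 0.02, u5c, cfg_const)), rep(10, 11))
  # cap active: an NMR path exceeding 0.79 x U5MR is clipped to it
  u5_low <- project_u5mr(10, 0.15, cfg_cur)
  nm <- project_nmr(9.5, 0, u5_low, cfg_cur)
  expect_true(all(nm <= 0.79 * u5_low + 1e-12))
  expect_true(any(abs(nm - 0.79 * u5_low) < 1e-12))
  # SDG endpoint before capping
  cfg_sdg <- scenario_config("achieve_sdg")
  u5_big <- project_u5mr(90, 0.01, cfg_sdg)
  nm_sdg <- project_nmr(30, 0.01, u5_big, cfg_sdg)
  expect_equal(unname(nm_sdg[["2030"]]), 12)
  # NMR floor
  nm_floor <- project_nmr(1.0, 0.2, project_u5mr(5, 0.0, cfg_cur), cfg_cur)
  expect_equal(unname(nm_floor[["2030"]]), 0.85)
})

test_that("scenario rates are ordered hic <= sdg <= current <= constant", {
  for (est in c(30, 60, 120)) {
    for (arr in c(0, 0.01, 0.04)) {
      p_const <- project_u5mr(est, arr, scenario_config("constant_2019"))
      p_cur <- project_u5mr(est, arr, scenario_config("current_trends"))
      p_sdg <- project_u5mr(est, arr, scenario_config("achieve_sdg"))
      p_hic <- project_u5mr(est, arr, scenario_config("achieve_hic"))
      expect_true(all(p_hic <= p_sdg + 1e-12))
      expect_true(all(p_sdg <= p_cur + 1e-12))
      expect_true(all(p_cur <= p_const + 1e-12))
    }
  }
})

test_that("projected deaths match the steady-state closed form", {
  # one country, constant births and rates: 11 years x births x U5MR/1000
  years_all <- 2015:2030
  rates <- data.frame(country = "A", year = years_all, u5mr = 50, nmr = 20)
  lb <- data.frame(country = "A", year = 2010:2030, births = 1e5)
  pd <- project_deaths(rates, lb, years = 2020:2030)
  expect_equal(unname(pd$cumulative[["deaths_under5"]]), 11 * 5000,
               tolerance = 0.01)
  # identical scenarios avert nothing
  expect_equal(unname(averted_deaths(pd, pd)), rep(0, 3))
  # mismatched country sets are rejected
  lb_bad <- data.frame(country = "B", year = 2010:2030, births = 1e5)
  expect_error(project_deaths(rates, lb_bad, years = 2020:2030),
               "country sets")
})

test_that("slower decline never produces fewer deaths", {
  years_all <- 2015:2030
  lb <- data.frame(country = "A", year = 2010:2030, births = 1e5)
  base <- data.frame(country = "A", year = years_all,
                     u5mr = 60 * exp(-0.00 * (years_all - 2019)))
  fast <- data.frame(country = "A", year = years_all,
                     u5mr = 60 * exp(-0.03 * pmax(years_all - 2019, 0)))
  base$nmr <- base$u5mr * 0.4
  fast$nmr <- fast$u5mr * 0.4
  d_const <- project_deaths(base, lb, years = 2020:2030)
  d_cur <- project_deaths(fast, lb, years = 2020:2030)
  expect_gte(d_const$cumulative[["deaths_under5"]],
             d_cur$cumulative[["deaths_under5"]])
})
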