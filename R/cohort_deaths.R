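#' Birth-week cohort death counts
#'
#' Converts annual U5MR/NMR schedules and livebirths into annual death
#' counts by age at death (neonatal: first 28 days; 1-59 months: the
#' remainder of the first 5 years). Each annual birth cohort is split into
#' 52 equal birth-week cohorts seeded at week midpoints; every cohort is
#' exposed through its first 5 years of life to piecewise-constant,
#' calendar-year- and age-specific hazards, and deaths are allocated to the
#' calendar year in which they occur.
#'
#' @name cohort_deaths
NULL

.AGE_NEONATAL <- 28 / 365.25

#' Convert U5MR and NMR into a two-segment hazard schedule
#'
#' Piecewise-constant hazards such that, under a constant schedule, a birth
#' cohort dies with probability nmr/1000 by day 28 and u5mr/1000 by exact
#' age 5:
#' \deqn{h_{neo} = -\log(1 - NMR/1000) / (28/365.25)}
#' \deqn{h_{post} = -\log\{(1 - U5MR/1000)/(1 - NMR/1000)\} / (5 - 28/365.25)}
#'
#' @param u5mr,nmr rates per 1000 livebirths (vectors allowed), with
#'   0 < nmr < u5mr < 1000.
#' @param year optional calendar years to attach.
#' @return data frame of class \code{age_schedule} with columns \code{year}
#'   (if given), \code{hazard_neonatal}, \code{hazard_postneonatal}
#'   (per-year hazards).
#' @export
build_mortality_schedule <- function(u5mr, nmr, year = NULL) {
  if (any(nmr <= 0) || any(u5mr >= 1000)) {
    stop("rates must satisfy 0 < nmr < u5mr < 1000")
  }
  if (any(nmr >= u5mr)) stop("nmr must be strictly below u5mr")
  h_neo <- -log(1 - nmr / 1000) / .AGE_NEONATAL
  h_post <- -log((1 - u5mr / 1000) / (1 - nmr / 1000)) / (5 - .AGE_NEONATAL)
  out <- data.frame(hazard_neonatal = h_neo, hazard_postneonatal = h_post)
  if (!is.null(year)) out <- cbind(year = year, out)
  class(out) <- c("age_schedule", "data.frame")
  out
}

# Precomputed exposure layout for the 52 weekly cohorts: for cohort w (born
# at age offset frac = (w-0.5)/52 within its birth year), the first 5 years
# of life split into at most 7 intervals at the neonatal age boundary and
# the 5 calendar-year boundaries. Because hazards are constant within each
# (calendar year, age segment) cell, integrating interval by interval is
# exact. Rows: cohorts; columns: intervals.
.cohort_layout <- function() {
  frac <- (seq_len(52) - 0.5) / 52
  nint <- 7L
  AGE0 <- DT <- NEO <- YOFF <- matrix(NA_real_, 52, nint)
  for (w in 1:52) {
    brk <- sort(unique(c(0, .AGE_NEONATAL, 5, seq_len(5) - frac[w])))
    a0 <- brk[-length(brk)]
    dt <- diff(brk)
    # degenerate case: a boundary collision leaves 6 intervals; pad with 0
    if (length(a0) < nint) {
      a0 <- c(a0, rep(4.999, nint - length(a0)))
      dt <- c(dt, rep(0, nint - length(dt)))
    }
    AGE0[w, ] <- a0
    DT[w, ] <- dt
    NEO[w, ] <- as.numeric(a0 < .AGE_NEONATAL - 1e-12)
    YOFF[w, ] <- floor(frac[w] + a0 + 1e-9)
  }
  list(AGE0 = AGE0, DT = DT, NEO = NEO, YOFF = YOFF, n_int = nint)
}

.layout_cache <- new.env(parent = emptyenv())

.cohort_layout_cached <- function() {
  if (is.null(.layout_cache$lay)) .layout_cache$lay <- .cohort_layout()
  .layout_cache$lay
}

#' Compute annual death counts with the birth-week cohort method
#'
#' @param livebirths data frame with columns \code{year}, \code{births}
#'   covering at least the reporting years; cohorts born before the first
#'   available year reuse its births (and analogously for hazards, see
#'   below).
#' @param schedules an \code{age_schedule} with a \code{year} column. Years
#'   outside the available range are exposed to the nearest available
#'   year's schedule (in particular, cohorts born within 5 years of the
#'   reporting end keep the last year's schedule).
#' @param years integer reporting calendar years.
#' @return data frame of class \code{deaths_table} with columns \code{year},
#'   \code{deaths_neonatal}, \code{deaths_1_59m}, \code{deaths_under5}.
#'   Attribute \code{cohorts} holds per-birth-cohort bookkeeping
#'   (\code{births}, \code{deaths}, \code{survivors_age5}) over the full
#'   internal range, for conservation checks.
#' @export
compute_cohort_deaths <- function(livebirths, schedules, years) {
  stopifnot(all(c("year", "births") %in% names(livebirths)),
            all(c("year", "hazard_neonatal", "hazard_postneonatal") %in%
                  names(schedules)))
  years <- sort(as.integer(years))
  lay <- .cohort_layout_cached()
  birth_years <- (min(years) - 5L):max(years)
  nby <- length(birth_years)

  # clamped lookups: years outside the provided ranges reuse the nearest
  # available year (first for earlier, last for later)
  lb <- livebirths[order(livebirths$year), , drop = FALSE]
  births <- lb$births[pmax(findInterval(birth_years, lb$year), 1L)]
  sch <- schedules[order(schedules$year), , drop = FALSE]

  n_int <- lay$n_int
  ncoh <- 52L * nby
  by_vec <- rep(birth_years, each = 52L)
  size <- rep(births / 52, each = 52L)
  w_vec <- rep(seq_len(52L), times = nby)

  out_years <- seq(min(years) - 5L, max(years) + 5L)
  ny_out <- length(out_years)
  deaths <- matrix(0, ny_out, 2)  # cols: neonatal, post-neonatal
  S <- rep(1, ncoh)
  total_dead <- rep(0, ncoh)
  for (m in seq_len(n_int)) {
    dt <- lay$DT[w_vec, m]
    yr <- by_vec + lay$YOFF[w_vec, m]
    neo <- lay$NEO[w_vec, m]
    hi <- pmax(findInterval(yr, sch$year), 1L)
    h <- ifelse(neo == 1, sch$hazard_neonatal[hi], sch$hazard_postneonatal[hi])
    d <- S * (1 - exp(-h * dt))
    S <- S - d
    total_dead <- total_dead + d * size
    yo <- match(yr, out_years)
    keep <- which(!is.na(yo) & d > 0)
    if (length(keep)) {
      li <- yo[keep] + ifelse(neo[keep] == 1, 0L, ny_out)  # linear index
      acc <- rowsum(d[keep] * size[keep], li)
      ii <- as.integer(rownames(acc))
      deaths[ii] <- deaths[ii] + acc[, 1]
    }
  }
  cohorts <- data.frame(
    birth_year = birth_years,
    births = births,
    deaths = as.numeric(rowsum(total_dead, by_vec)),
    survivors_age5 = as.numeric(rowsum(S * size, by_vec))
  )
  keep <- match(years, out_years)
  res <- data.frame(
    year = years,
    deaths_neonatal = deaths[keep, 1],
    deaths_1_59m = deaths[keep, 2],
    deaths_under5 = deaths[keep, 1] + deaths[keep, 2]
  )
  attr(res, "cohorts") <- cohorts
  attr(res, "full") <- data.frame(year = out_years,
                                  deaths_neonatal = deaths[, 1],
                                  deaths_1_59m = deaths[, 2])
  class(res) <- c("deaths_table", "data.frame")
  res
}

#' Death counts with uncertainty from posterior rate draws
#'
#' Applies [compute_cohort_deaths()] to each paired posterior draw of U5MR
#' and NMR, holding livebirths fixed, and summarises each (year, age group)
#' cell by its median and equal-tailed interval. Livebirths are treated as
#' known: the intervals reflect only rate uncertainty.
#'
#' @param u5mr_draws,nmr_draws matrices (draws x years) of log-rate draws
#'   for one country, on the same integer-year grid \code{rate_years};
#'   draws are paired row by row.
#' @param rate_years integer calendar years of the draw columns.
#' @param livebirths data frame with \code{year}, \code{births}.
#' @param years reporting years (default \code{rate_years}).
#' @param level interval probability (default 0.90).
#' @param max_draws cap on the number of draws run through the cohort
#'   method (thinned evenly; default 250).
#' @return list of class \code{deaths_posterior} with \code{years},
#'   \code{draws} (array draws x years x 3 for neonatal, 1-59m, under-5)
#'   and \code{summary} (a \code{deaths_table} with lower/median/upper per
#'   cell).
#' @export
deaths_uncertainty <- function(u5mr_draws, nmr_draws, rate_years, livebirths,
                               years = rate_years, level = 0.90,
                               max_draws = 250) {
  stopifnot(nrow(u5mr_draws) == nrow(nmr_draws),
            ncol(u5mr_draws) == length(rate_years))
  nd_all <- nrow(u5mr_draws)
  take <- if (nd_all > max_draws) {
    unique(round(seq(1, nd_all, length.out = max_draws)))
  } else seq_len(nd_all)
  draws <- array(NA_real_, c(length(take), length(years), 3),
                 dimnames = list(NULL, NULL,
                                 c("neonatal", "m1_59", "under5")))
  for (j in seq_along(take)) {
    u5 <- exp(u5mr_draws[take[j], ])
    nm <- exp(nmr_draws[take[j], ])
    nm <- pmin(nm, u5 * 0.999)  # numerical guard; ratio model keeps nm < u5
    sched <- build_mortality_schedule(u5, nm, year = rate_years)
    dt <- compute_cohort_deaths(livebirths, sched, years)
    draws[j, , 1] <- dt$deaths_neonatal
    draws[j, , 2] <- dt$deaths_1_59m
    draws[j, , 3] <- dt$deaths_under5
  }
  p <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  qs <- apply(draws, c(2, 3), quantile, probs = p, names = FALSE)
  summary <- data.frame(
    year = years,
    deaths_neonatal = qs[2, , 1], neonatal_lower = qs[1, , 1],
    neonatal_upper = qs[3, , 1],
    deaths_1_59m = qs[2, , 2], m1_59_lower = qs[1, , 2],
    m1_59_upper = qs[3, , 2],
    deaths_under5 = qs[2, , 3], under5_lower = qs[1, , 3],
    under5_upper = qs[3, , 3]
  )
  class(summary) <- c("deaths_table", "data.frame")
  structure(list(years = years, draws = draws, summary = summary,
                 level = level),
            class = "deaths_posterior")
}
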