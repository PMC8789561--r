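#' SDG progress classification and aggregation
#'
#' Country-level classification of progress toward the SDG 3.2 child
#' survival targets, and aggregation of country results to regional, income
#' group and global rates and death counts.
#'
#' @name progress_aggregate
NULL

#' Classify a country's progress toward a mortality target
#'
#' A country has \emph{achieved} the target if its 2019 estimate is at or
#' below it; it is \emph{on track} if the current-trends path reaches the
#' target by 2030; otherwise \emph{acceleration needed}, with the
#' acceleration factor required_arr / current_arr (current ARR floored at a
#' small epsilon so stagnating countries get a finite, large factor and the
#' "at least triple" band). The achievement year is the first year the
#' current-trends path meets the target, \code{Inf} (reported as ">2099")
#' if the ARR is non-positive or the year falls after 2099.
#'
#' @param est_2019 vector of 2019 estimates (per 1000).
#' @param arr_2010_19 vector of current ARRs (per year).
#' @param target target rate (per 1000), e.g. 25 for U5MR or 12 for NMR.
#' @param country optional country identifiers.
#' @param eps floor applied to the current ARR in the factor denominator.
#' @return data frame of class \code{progress_status} with columns
#'   \code{country}, \code{est_2019}, \code{arr_2010_19}, \code{status}
#'   (achieved / on_track / acceleration_needed),
#'   \code{acceleration_factor}, \code{band} ("<2", ">=2", ">=3"),
#'   \code{achievement_year} (numeric, possibly Inf) and
#'   \code{achievement_label} (">2099" when past the century).
#' @export
classify_progress <- function(est_2019, arr_2010_19, target,
                              country = NULL, eps = 1e-6) {
  stopifnot(all(is.finite(est_2019)), all(is.finite(arr_2010_19)), target > 0)
  n <- length(est_2019)
  if (is.null(country)) country <- sprintf("C%02d", seq_len(n))
  req <- required_arr(pmax(est_2019, 1e-12), target)
  path_2030 <- est_2019 * exp(-pmax(arr_2010_19, 0) * 11)
  achieved <- est_2019 <= target
  on_track <- !achieved & path_2030 <= target
  status <- ifelse(achieved, "achieved",
                   ifelse(on_track, "on_track", "acceleration_needed"))
  factor <- req / pmax(arr_2010_19, eps)
  band <- ifelse(factor >= 3, ">=3", ifelse(factor >= 2, ">=2", "<2"))
  ach_year <- ifelse(achieved, 2019,
                     ifelse(arr_2010_19 <= 0, Inf,
                            2019 + ceiling(log(est_2019 / target) /
                                             pmax(arr_2010_19, eps))))
  ach_year[ach_year > 2099] <- Inf
  structure(
    data.frame(country = country, est_2019 = est_2019,
               arr_2010_19 = arr_2010_19,
               status = status, acceleration_factor = factor, band = band,
               achievement_year = ach_year,
               achievement_label = ifelse(is.infinite(ach_year), ">2099",
                                          as.character(ach_year))),
    class = c("progress_status", "data.frame")
  )
}

#' Aggregate country death draws to groups
#'
#' Sums posterior death draws cell-wise across the countries of each group
#' and only then takes quantiles (sums of quantiles are not quantiles of
#' sums), as required for coherent regional and global intervals.
#'
#' @param country_deaths named list (by country) of \code{deaths_posterior}
#'   objects on a common year grid and draw count.
#' @param groups data frame mapping \code{country} to a grouping column.
#' @param by name of the grouping column (default \code{"region"}); use
#'   \code{"world"} to aggregate everything into one group.
#' @param level interval probability (default 0.90).
#' @return named list (by group) of \code{deaths_posterior} objects.
#' @export
aggregate_deaths <- function(country_deaths, groups, by = "region",
                             level = 0.90) {
  countries <- names(country_deaths)
  if (by == "world") {
    membership <- setNames(rep("World", length(countries)), countries)
  } else {
    stopifnot(by %in% names(groups))
    membership <- setNames(as.character(groups[[by]]), groups$country)
    unmapped <- setdiff(countries, names(membership))
    if (length(unmapped)) {
      stop("countries not in the grouping table: ",
           paste(unmapped, collapse = ", "))
    }
    membership <- membership[countries]
  }
  out <- list()
  for (g in unique(membership)) {
    members <- countries[membership == g]
    agg <- country_deaths[[members[1]]]$draws
    if (length(members) > 1) {
      for (cn in members[-1]) agg <- agg + country_deaths[[cn]]$draws
    }
    years <- country_deaths[[members[1]]]$years
    p <- c((1 - level) / 2, 0.5, (1 + level) / 2)
    qs <- apply(agg, c(2, 3), quantile, probs = p, names = FALSE)
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
    out[[g]] <- structure(list(years = years, draws = agg, summary = summary,
                               level = level),
                          class = "deaths_posterior")
  }
  out
}

#' Births-weighted aggregation of rate draws to a group
#'
#' Group rates are aggregated as the births-weighted mean of country rates
#' per draw and year. This approximates the rate that would reproduce the
#' group's cohort deaths from the group's births; the approximation error is
#' second order in the spread of member rates (exact when members share one
#' rate) and small relative to reported precision for realistic
#' heterogeneity.
#'
#' @param rate_draws named list (by country) of matrices (draws x years) of
#'   log-rate draws on a common year grid.
#' @param births named list or data frame of per-country births aligned to
#'   the same years (vectors of length n_years).
#' @param years year grid.
#' @param level interval probability.
#' @param group_name label for the aggregated series.
#' @return list with \code{draws} (draws x years matrix of group log rates)
#'   and \code{summary} (an \code{estimate_series} for the group).
#' @export
aggregate_rate <- function(rate_draws, births, years, level = 0.90,
                           group_name = "Group") {
  countries <- names(rate_draws)
  stopifnot(length(countries) >= 1, all(countries %in% names(births)))
  nd <- nrow(rate_draws[[1]])
  num <- matrix(0, nd, length(years))
  den <- rep(0, length(years))
  for (cn in countries) {
    b <- births[[cn]]
    stopifnot(length(b) == length(years))
    num <- num + exp(rate_draws[[cn]]) * matrix(b, nd, length(years),
                                                byrow = TRUE)
    den <- den + b
  }
  grate <- num / matrix(den, nd, length(years), byrow = TRUE)
  post <- rate_posterior(log(grate), years, group_name)
  list(draws = log(grate), summary = summarize_posterior(post, level))
}

#' Percent decline between two values
#'
#' @param v_start,v_end values with \code{v_start > 0}.
#' @return integer percent decline, rounded to the nearest percent.
#' @export
percent_decline <- function(v_start, v_end) {
  stopifnot(all(v_start > 0))
  round(100 * (1 - v_end / v_start))
}

#' Share, one-in-N and fold-ratio display indicators
#'
#' @param part,total counts with \code{total > 0}.
#' @return integer percent share.
#' @export
percent_share <- function(part, total) {
  stopifnot(all(total > 0))
  round(100 * part / total)
}

#' @rdname percent_share
#' @param rate rate per 1000 livebirths; returns N such that the rate is
#'   "one in N" children.
#' @export
one_in_n <- function(rate) {
  stopifnot(all(rate > 0))
  round(1000 / rate)
}

#' @rdname percent_share
#' @param rate_a,rate_b rates; returns the rounded fold ratio a/b.
#' @export
fold_ratio <- function(rate_a, rate_b) {
  stopifnot(all(rate_b > 0))
  round(rate_a / rate_b)
}
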