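#' B-spline basis over a span of years
#'
#' Builds a clamped (open-uniform) B-spline basis covering a year range, used
#' as the trend family for log-mortality in the Bayesian trend models. Knots
#' are placed every \code{knot_spacing} years; boundary knots are repeated
#' \code{degree + 1} times so the basis is a partition of unity on the whole
#' span (weights at any year are non-negative and sum to one).
#'
#' @param years numeric vector; the basis is built over \code{range(years)}.
#'   Must cover the observation years plus any extrapolation horizon.
#' @param knot_spacing spacing between knots in years (default 2.5).
#' @param degree polynomial degree of the spline pieces (default 3, cubic).
#' @return an object of class \code{spline_basis} with elements
#'   \code{boundary} (span), \code{interior} (interior knots), \code{knots}
#'   (full clamped knot vector), \code{degree} and \code{n_basis}.
#' @seealso [basis_matrix()] to evaluate the basis at years.
#' @export
build_spline_basis <- function(years, knot_spacing = 2.5, degree = 3L) {
  stopifnot(is.numeric(years), length(years) >= 2, knot_spacing > 0, degree >= 0)
  lo <- min(years)
  hi <- max(years)
  grid <- seq(lo, hi, by = knot_spacing)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  n_intervals <- length(grid) - 1L
  if (n_intervals < degree + 1L) {
    stop("year range supports only ", n_intervals, " knot intervals; ",
         "need at least degree + 1 = ", degree + 1L)
  }
  interior <- grid[-c(1L, length(grid))]
  knots <- c(rep(lo, degree + 1L), interior, rep(hi, degree + 1L))
  structure(
    list(boundary = c(lo, hi), interior = interior, knots = knots,
         degree = as.integer(degree),
         n_basis = length(interior) + degree + 1L),
    class = "spline_basis"
  )
}

#' Evaluate a spline basis at given years
#'
#' @param basis a \code{spline_basis} from [build_spline_basis()].
#' @param years numeric vector of years within the basis span.
#' @return matrix with \code{length(years)} rows and \code{basis$n_basis}
#'   columns; each row is non-negative and sums to 1.
#' @export
basis_matrix <- function(basis, years) {
  stopifnot(inherits(basis, "spline_basis"))
  lo <- basis$boundary[1]
  hi <- basis$boundary[2]
  if (any(years < lo - 1e-9) || any(years > hi + 1e-9)) {
    stop("years outside basis span [", lo, ", ", hi, "]")
  }
  # splineDesign assigns the right boundary to a zero-width support; nudge
  # boundary evaluations inward so the partition of unity holds at hi too.
  eps <- (hi - lo) * 1e-10
  x <- pmin(pmax(years, lo), hi - eps)
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L)
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("B-spline basis: degree", x$degree, "with", x$n_basis,
      "basis functions over [", x$boundary[1], ",", x$boundary[2], "]\n")
  invisible(x)
}
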