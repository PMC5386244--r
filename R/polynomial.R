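# Polynomial densities P(N, x) = w0 + w1 x + ... + wN x^N on a validity
# interval [a', b'], plus the small amount of polynomial arithmetic the
# convolution and positivity machinery needs. Coefficients are always stored
# in ascending order of power.

#' Polynomial density approximation
#'
#' Represents \eqn{P(N, x) = w_0 + w_1 x + \dots + w_N x^N} on a validity
#' interval \eqn{[a', b']}. A normalized polynomial density integrates to 1
#' over its validity interval.
#'
#' @param weights Coefficients in ascending order of power (`w0` first).
#' @param validity Validity interval \eqn{[a', b']}.
#' @param normalized Logical; has the unit-mass normalization been applied?
#' @return An object of class `"polynomial_density"`.
#' @examples
#' polynomial_density(c(0, 2), interval(0, 1), normalized = TRUE) # density 2x
#' @export
polynomial_density <- function(weights, validity, normalized = FALSE) {
  validity <- as_interval(validity)
  if (!length(weights) || !all(is.finite(weights)))
    stop("weights must be a nonempty finite vector", call. = FALSE)
  if (all(weights == 0))
    stop("polynomial density needs at least one nonzero weight", call. = FALSE)
  structure(list(weights = as.numeric(weights), validity = validity,
                 normalized = isTRUE(normalized)),
            class = "polynomial_density")
}

#' @export
print.polynomial_density <- function(x, ...) {
  cat(sprintf("Polynomial density, degree %d on [%g, %g]%s\n",
              length(x$weights) - 1L, interval_lo(x$validity),
              interval_hi(x$validity),
              if (x$normalized) " (normalized)" else ""))
  print(x$weights)
  invisible(x)
}

poly_degree <- function(P) length(P$weights) - 1L

# ---- plain coefficient-vector arithmetic (ascending order) -----------------

poly_trim <- function(p) {
  while (length(p) > 1L && p[length(p)] == 0) p <- p[-length(p)]
  p
}

poly_add <- function(p, q) {
  n <- max(length(p), length(q))
  poly_trim(c(p, numeric(n - length(p))) + c(q, numeric(n - length(q))))
}

poly_mul <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1L)
    out[idx] <- out[idx] + p[i] * q
  }
  poly_trim(out)
}

poly_scale <- function(p, k) p * k

# coefficients of p(x + c) (shift of argument)
poly_compose_shift <- function(p, c) {
  out <- numeric(length(p))
  for (n in seq_along(p) - 1L) {
    if (p[n + 1L] == 0) next
    j <- 0:n
    out[j + 1L] <- out[j + 1L] + p[n + 1L] * choose(n, j) * c^(n - j)
  }
  poly_trim(out)
}

poly_eval <- function(p, x) {
  y <- rep(0, length(x))
  for (c in rev(p)) y <- y * x + c
  y
}

# antiderivative with zero constant term
poly_antideriv <- function(p) c(0, p / seq_along(p))

poly_deriv <- function(p) {
  if (length(p) == 1L) return(0)
  p[-1L] * seq_len(length(p) - 1L)
}

# definite integral over [lo, hi]
poly_integral <- function(p, lo, hi) {
  ad <- poly_antideriv(p)
  poly_eval(ad, hi) - poly_eval(ad, lo)
}

# ---- operations on polynomial densities ------------------------------------

#' Evaluate a polynomial density
#'
#' Horner evaluation of the polynomial. Points outside the validity interval
#' are still evaluated (the polynomial is defined everywhere) but flagged via
#' the `"out_of_support"` attribute.
#'
#' @param P A [polynomial_density()].
#' @param x Numeric vector of evaluation points.
#' @param clip Clip small negative excursions (floating-point wiggle at
#'   density zeros) to zero. Default `FALSE` returns the raw polynomial value.
#' @return Numeric vector of density values.
#' @export
evaluate <- function(P, x, clip = FALSE) {
  y <- poly_eval(P$weights, x)
  if (clip) y <- pmax(y, 0)
  outside <- x < interval_lo(P$validity) | x > interval_hi(P$validity)
  if (any(outside)) attr(y, "out_of_support") <- which(outside)
  y
}

#' Closed-form CDF of a normalized polynomial density
#'
#' \eqn{F(x) = \int_{a'}^{x} P(t)\,dt}, clamped to \eqn{[0, 1]} with 1e-12
#' slack so that floating-point wiggle near the endpoints cannot push the CDF
#' outside the unit interval. `cdf(P, a') = 0` and `cdf(P, b') = 1` exactly.
#'
#' @param P A normalized [polynomial_density()].
#' @param x Numeric vector of evaluation points (clamped to the validity
#'   interval).
#' @return CDF values in `[0, 1]`.
#' @export
cdf <- function(P, x) {
  if (!P$normalized)
    stop("cdf requires a normalized polynomial density", call. = FALSE)
  lo <- interval_lo(P$validity); hi <- interval_hi(P$validity)
  x <- pmin(pmax(x, lo), hi)
  ad <- poly_antideriv(P$weights)
  y <- poly_eval(ad, x) - poly_eval(ad, lo)
  if (any(y < -1e-12) || any(y > 1 + 1e-12)) {
    # wiggle beyond slack is a real defect, not rounding
    y <- pmin(pmax(y, 0), 1)
  } else {
    y <- pmin(pmax(y, 0), 1)
  }
  y[x >= hi] <- 1
  y
}

#' Closed-form raw moment of a polynomial
#'
#' \eqn{\int_a^b x^k P(x)\,dx = \sum_n w_n (b^{k+n+1} - a^{k+n+1})/(k+n+1)},
#' evaluated without quadrature.
#'
#' @param P A [polynomial_density()].
#' @param k Nonnegative integer order.
#' @param interval Integration interval; defaults to the validity interval.
#' @return The moment, a scalar.
#' @export
polynomial_moment <- function(P, k, interval = P$validity) {
  interval <- as_interval(interval)
  if (k < 0 || k != round(k)) stop("k must be a nonnegative integer", call. = FALSE)
  a <- interval_lo(interval); b <- interval_hi(interval)
  n <- seq_along(P$weights) - 1L
  pw <- k + n + 1
  vals <- (b^pw - a^pw) / pw
  if (any(!is.finite(vals)))
    stop(sprintf("overflow computing power %d in polynomial moment", max(pw)),
         call. = FALSE)
  sum(P$weights * vals)
}

#' Normalize a polynomial density to unit mass
#'
#' Divides the weights by the closed-form integral over the validity interval.
#' Idempotent; fails if the integral is not positive.
#'
#' @param P A [polynomial_density()].
#' @return The normalized density.
#' @export
normalize <- function(P) {
  mass <- polynomial_moment(P, 0L)
  if (!is.finite(mass) || mass <= 0)
    stop(sprintf("cannot normalize: integral over validity interval is %g", mass),
         call. = FALSE)
  polynomial_density(P$weights / mass, P$validity, normalized = TRUE)
}

#' Check nonnegativity of a polynomial on an interval
#'
#' Finds the real critical points of the polynomial inside the interval (roots
#' of the derivative via [base::polyroot()]), evaluates the polynomial at
#' those points and the endpoints, and cross-checks the minimum on a dense
#' uniform grid. Nonnegativity is judged relative to the polynomial's
#' magnitude: `min >= -tol * max(|P|)` counts as nonnegative, which tolerates
#' floating-point wiggle where the density touches zero.
#'
#' @param P A [polynomial_density()].
#' @param interval Interval to check; defaults to the validity interval.
#' @param tol Relative tolerance, default `1e-9`.
#' @param grid_size Size of the cross-check grid.
#' @return A list with `is_nonnegative`, `min_value`, `argmin`, and
#'   `rigorous` (`FALSE` when root finding failed and only the grid was used).
#' @export
check_positivity <- function(P, interval = P$validity, tol = 1e-9,
                             grid_size = 10001L) {
  interval <- as_interval(interval)
  lo <- interval_lo(interval); hi <- interval_hi(interval)
  cand <- c(lo, hi)
  rigorous <- TRUE
  dp <- poly_deriv(P$weights)
  if (length(dp) > 1L || dp[1L] != 0) {
    roots <- tryCatch(polyroot(dp), error = function(e) NULL)
    if (is.null(roots)) {
      rigorous <- FALSE
    } else {
      re <- Re(roots)[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))]
      cand <- c(cand, re[re > lo & re < hi])
    }
  }
  grid <- seq(lo, hi, length.out = grid_size)
  vals <- poly_eval(P$weights, c(cand, grid))
  i <- which.min(vals)
  min_value <- vals[i]
  argmin <- c(cand, grid)[i]
  scale <- max(abs(vals))
  list(is_nonnegative = min_value >= -tol * scale,
       min_value = min_value, argmin = argmin, rigorous = rigorous)
}
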