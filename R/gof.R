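# Goodness-of-fit and error metrics: the Kolmogorov-Smirnov statistic used
# by the fit procedure's final check, and L1/Linf density distances used to
# quantify convergence with the polynomial degree.

#' Kolmogorov-Smirnov statistic against a polynomial density
#'
#' For a numeric sample, the standard one-sample two-sided statistic
#' \eqn{D = \sup_x |F_n(x) - F(x)|} with the correct left and right limits at
#' the empirical jumps. For an analytic reference density, the sup is taken
#' over a fixed grid of 4097 points on the polynomial's validity interval,
#' with the reference CDF obtained by cumulative trapezoidal integration of
#' the reference density from the interval's lower end (no renormalization:
#' reference mass outside the interval shows up in D).
#'
#' The reported D is descriptive. When the polynomial was fitted to moments
#' of the same sample the classical KS null distribution does not apply, so
#' no p-value is attached.
#'
#' @param reference A numeric sample or a vectorized density evaluator.
#' @param P A normalized [polynomial_density()].
#' @param grid_size Grid size for the analytic branch (default 4097,
#'   a power of two plus one so trapezoid refinements nest).
#' @return The statistic D in `[0, 1]`.
#' @examples
#' U <- polynomial_density(1, interval(0, 1), normalized = TRUE)
#' ks_statistic(0.5, U) # 0.5: single observation at the median
#' @export
ks_statistic <- function(reference, P, grid_size = 4097L) {
  if (!inherits(P, "polynomial_density") || !P$normalized)
    stop("P must be a normalized polynomial density", call. = FALSE)
  if (is.numeric(reference)) {
    if (!length(reference)) stop("empty sample", call. = FALSE)
    x <- sort(reference)
    n <- length(x)
    Fx <- cdf(P, x)
    max(pmax(Fx - (seq_len(n) - 1) / n, seq_len(n) / n - Fx))
  } else if (is.function(reference)) {
    lo <- interval_lo(P$validity); hi <- interval_hi(P$validity)
    g <- seq(lo, hi, length.out = grid_size)
    fref <- reference(g)
    h <- g[2L] - g[1L]
    Fref <- c(0, cumsum((fref[-1L] + fref[-grid_size]) / 2) * h)
    max(abs(Fref - cdf(P, g)))
  } else {
    stop("reference must be a numeric sample or a density evaluator", call. = FALSE)
  }
}

#' L1 and sup-norm distance between a density and a polynomial fit
#'
#' The L1 error is computed by adaptive quadrature of `|f - P|` (falling back
#' to a fine trapezoid rule if the adaptive rule fails on the kinks of the
#' absolute value); the sup-norm error is the maximum over a fixed grid.
#'
#' @param f Reference density evaluator.
#' @param P A [polynomial_density()].
#' @param interval Interval over which to compare.
#' @param grid_size Grid for the sup-norm (default 4097).
#' @return List with elements `l1` and `linf`.
#' @export
density_errors <- function(f, P, interval = P$validity, grid_size = 4097L) {
  interval <- as_interval(interval)
  lo <- interval_lo(interval); hi <- interval_hi(interval)
  diff_abs <- function(x) abs(f(x) - poly_eval(P$weights, x))
  l1 <- tryCatch({
    r <- stats::integrate(diff_abs, lo, hi, rel.tol = 1e-8,
                          subdivisions = 2000L, stop.on.error = FALSE)
    if (r$message %in% c("OK", "maximum number of subdivisions reached")) r$value
    else stop(r$message)
  }, error = function(e) {
    g <- seq(lo, hi, length.out = 32769L)
    d <- diff_abs(g)
    sum((d[-1L] + d[-length(d)]) / 2) * (g[2L] - g[1L])
  })
  g <- seq(lo, hi, length.out = grid_size)
  list(l1 = l1, linf = max(diff_abs(g)))
}

#' Goodness-of-fit report for a polynomial density
#'
#' Bundles the KS statistic (when a reference is supplied) with L1 and
#' sup-norm errors (when the reference is a density evaluator).
#'
#' @param P A normalized [polynomial_density()].
#' @param reference A numeric sample or density evaluator.
#' @param interval Comparison interval for the density errors.
#' @param grid_size Grid size.
#' @return List of class `"gof_report"` with `ks_D`, `l1_error`,
#'   `linf_error`, `grid_size`.
#' @export
gof_report <- function(P, reference, interval = P$validity, grid_size = 4097L) {
  ks <- ks_statistic(reference, P, grid_size = grid_size)
  if (is.function(reference)) {
    de <- density_errors(reference, P, interval, grid_size = grid_size)
    l1 <- de$l1; linf <- de$linf
  } else {
    l1 <- NA_real_; linf <- NA_real_
  }
  structure(list(ks_D = ks, l1_error = l1, linf_error = linf,
                 grid_size = as.integer(grid_size)),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("KS D = %.5g; L1 = %s; Linf = %s (grid %d)\n", x$ks_D,
              format(x$l1_error), format(x$linf_error), x$grid_size))
  invisible(x)
}
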