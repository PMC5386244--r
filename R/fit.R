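# The core fitting algorithm: equate the first N+1 raw moments of a target
# (density, sample, or supplied moment vector) on [a, b] with the closed-form
# moments of an unknown degree-N polynomial, solve the resulting Hankel
# system, require nonnegativity on the validity interval [a', b'], normalize
# to unit mass there, and judge the result with a goodness-of-fit statistic.
# On failure the degree is searched upward first, then downward.

#' Configuration for the polynomial fit
#'
#' @param degree Polynomial degree N to try first.
#' @param moment_interval Interval `[a, b]` on which the moments are taken.
#' @param validity_interval Interval `[a', b']` on which the fitted polynomial
#'   must be a genuine density. Defaults to the moment interval; the two are
#'   deliberately kept distinct because a fit that goes negative near the
#'   edges of `[a, b]` may still be a valid density on an inner interval.
#' @param gof Goodness-of-fit test: `"ks"` (one-sample Kolmogorov-Smirnov
#'   statistic) or `"none"`.
#' @param gof_threshold Pass threshold for the KS statistic. There is no
#'   universally correct value; the default 0.05 is an application choice and
#'   should be set per use case.
#' @param n_max,n_min Bounds for the degree search on failure; upward
#'   (`degree + 1 ... n_max`) is tried before downward (`degree - 1 ... n_min`).
#' @param positivity_tol Relative tolerance for [check_positivity()].
#' @param solver Linear solver, see [solve_weights()].
#' @param rel_tol Quadrature tolerance when moments come from a density
#'   evaluator.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(degree, moment_interval,
                       validity_interval = moment_interval,
                       gof = c("ks", "none"), gof_threshold = 0.05,
                       n_max = degree + 6L, n_min = 2L,
                       positivity_tol = 1e-9,
                       solver = c("factorized", "rescaled_hilbert", "exact_rational"),
                       rel_tol = 1e-10) {
  gof <- match.arg(gof)
  solver <- match.arg(solver)
  if (degree < 0 || degree != round(degree))
    stop("degree must be a nonnegative integer", call. = FALSE)
  n_min <- max(0L, as.integer(n_min))
  if (!(n_min <= degree && degree <= n_max))
    stop("degree search bounds must satisfy n_min <= degree <= n_max", call. = FALSE)
  if (gof_threshold <= 0) stop("gof_threshold must be positive", call. = FALSE)
  if (positivity_tol <= 0) stop("positivity_tol must be positive", call. = FALSE)
  structure(list(degree = as.integer(degree),
                 moment_interval = as_interval(moment_interval),
                 validity_interval = as_interval(validity_interval),
                 gof = gof, gof_threshold = gof_threshold,
                 n_max = as.integer(n_max), n_min = n_min,
                 positivity_tol = positivity_tol, solver = solver,
                 rel_tol = rel_tol),
            class = "fit_config")
}

#' Fit a polynomial density by the method of moments
#'
#' Runs the full adaptive procedure: obtain moments of the target on
#' `[a, b]`, solve the Hankel system for the polynomial weights, check
#' nonnegativity on `[a', b']`, normalize to unit mass there, and evaluate
#' the goodness of fit. If a candidate degree fails (unsolvable system,
#' negativity, or a KS statistic above the threshold) the degrees
#' `N+1, ..., n_max` are tried, then `N-1, ..., n_min`; the first candidate
#' passing every check wins. If none passes, the best nonnegative candidate
#' (smallest KS statistic) is returned with `passed = FALSE`; if no candidate
#' is nonnegative at any degree, the least-negative candidate is returned and
#' the per-degree minima are reported in the trace.
#'
#' @param source The fit target: a [moment_vector()], a density evaluator
#'   (vectorized function of one argument), or a numeric sample.
#' @param config A [fit_config()].
#' @return A `"polyfit_result"`: list with elements `density` (a
#'   [polynomial_density()], normalized when possible), `degree_used`,
#'   `condition_estimate`, `moment_residuals` (per-order residuals of the
#'   solved system), `positivity` (report from [check_positivity()]),
#'   `gof_value` (`NA` when no reference is available), `passed`, and `trace`
#'   (a data frame with one row per degree attempted).
#' @examples
#' E <- moment_vector(1 / (1:4), interval(0, 1))  # exact uniform moments
#' fit <- fit_polynomial_pdf(E, fit_config(3, interval(0, 1), gof = "none"))
#' fit$density$weights  # ~ (1, 0, 0, 0)
#' @export
fit_polynomial_pdf <- function(source, config) {
  stopifnot(inherits(config, "fit_config"))
  miv <- config$moment_interval
  kind <- if (inherits(source, "moment_vector")) "moments"
          else if (is.function(source)) "density"
          else if (is.numeric(source)) "sample"
          else stop("source must be a moment_vector, a density evaluator function, or a numeric sample",
                    call. = FALSE)

  max_deg_possible <- if (kind == "moments") max_order(source) else config$n_max
  if (max_deg_possible < config$degree)
    stop(sprintf("source provides moments only to order %d, below the requested degree %d",
                 max_deg_possible, config$degree), call. = FALSE)

  moments_to <- function(N) {
    switch(kind,
      moments = moment_vector(source$values[1:(N + 1L)], source$interval,
                              source = source$source),
      density = {
        vals <- vapply(0:N, function(k)
          raw_moment_quadrature(source, k, miv, rel_tol = config$rel_tol),
          numeric(1))
        moment_vector(vals, miv, source = "analytic_quadrature")
      },
      sample = sample_moments(source, N, interval = miv))
  }

  degrees <- unique(c(config$degree,
                      seq_len(config$n_max)[seq_len(config$n_max) > config$degree],
                      rev(seq(config$n_min, max(config$n_min, config$degree - 1L)))))
  degrees <- degrees[degrees >= config$n_min & degrees <= min(config$n_max, max_deg_possible)]

  trace <- data.frame(degree = integer(), solvable = logical(),
                      min_value = numeric(), gof = numeric(), passed = logical())
  candidates <- list()

  for (deg in degrees) {
    E <- moments_to(deg)
    M <- build_moment_matrix(deg, if (kind == "moments") source$interval else miv)
    w <- tryCatch(
      withCallingHandlers(
        solve_weights(M, E, solver = config$solver),
        polydens_condition_warning = function(wrn) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(w)) {
      trace <- rbind(trace, data.frame(degree = deg, solvable = FALSE,
                                       min_value = NA_real_, gof = NA_real_,
                                       passed = FALSE))
      next
    }
    P0 <- polynomial_density(w, config$validity_interval)
    pos <- check_positivity(P0, config$validity_interval, tol = config$positivity_tol)
    Pn <- tryCatch(normalize(P0), error = function(e) NULL)
    gof_value <- NA_real_
    if (config$gof == "ks" && !is.null(Pn)) {
      gof_value <- switch(kind,
        density = ks_statistic(source, Pn),
        sample = ks_statistic(source, Pn),
        moments = NA_real_)
    }
    ok <- pos$is_nonnegative && !is.null(Pn) &&
      (is.na(gof_value) || gof_value <= config$gof_threshold)
    trace <- rbind(trace, data.frame(degree = deg, solvable = TRUE,
                                     min_value = pos$min_value,
                                     gof = gof_value, passed = ok))
    resid <- drop(M$entries %*% w - E$values)
    cand <- list(density = if (!is.null(Pn)) Pn else P0,
                 degree_used = deg,
                 condition_estimate = M$condition_estimate,
                 moment_residuals = resid,
                 positivity = pos, gof_value = gof_value, passed = ok)
    candidates[[length(candidates) + 1L]] <- cand
    if (ok) {
      cand$trace <- trace
      return(structure(cand, class = "polyfit_result"))
    }
  }

  if (!length(candidates))
    stop("no candidate degree produced a solvable moment system; see the trace of attempted degrees",
         call. = FALSE)
  nonneg <- Filter(function(cc) cc$positivity$is_nonnegative, candidates)
  pool <- if (length(nonneg)) nonneg else candidates
  scores <- vapply(pool, function(cc) {
    if (!is.na(cc$gof_value)) cc$gof_value
    else if (cc$positivity$is_nonnegative) 0
    else -cc$positivity$min_value  # least negative wins
  }, numeric(1))
  best <- pool[[which.min(scores)]]
  best$passed <- FALSE
  best$trace <- trace
  structure(best, class = "polyfit_result")
}

#' @export
print.polyfit_result <- function(x, ...) {
  cat(sprintf("Polynomial density fit: degree %d, %s\n", x$degree_used,
              if (x$passed) "passed" else "NOT passed"))
  cat(sprintf("  validity interval [%g, %g]; condition ~ %.3g\n",
              interval_lo(x$density$validity), interval_hi(x$density$validity),
              x$condition_estimate))
  cat(sprintf("  positivity: min %.3g at x = %.4g (%snonnegative)\n",
              x$positivity$min_value, x$positivity$argmin,
              if (x$positivity$is_nonnegative) "" else "not "))
  if (!is.na(x$gof_value)) cat(sprintf("  KS statistic: %.4g\n", x$gof_value))
  cat(sprintf("  max moment residual: %.3g\n", max(abs(x$moment_residuals))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a polynomial density fit
#'
#' @param x A `"polyfit_result"`.
#' @param ... Unused.
#' @return A data frame with one row per coefficient: `term`, `power`,
#'   `estimate`, and the per-order moment residual.
#' @method tidy polyfit_result
#' @export
tidy.polyfit_result <- function(x, ...) {
  n <- length(x$density$weights)
  data.frame(term = paste0("x^", 0:(n - 1L)),
             power = 0:(n - 1L),
             estimate = x$density$weights,
             moment_residual = x$moment_residuals)
}

#' One-row summary of a polynomial density fit
#'
#' @param x A `"polyfit_result"`.
#' @param ... Unused.
#' @return A one-row data frame with the fit diagnostics.
#' @method glance polyfit_result
#' @export
glance.polyfit_result <- function(x, ...) {
  data.frame(degree = x$degree_used,
             condition_estimate = x$condition_estimate,
             min_value = x$positivity$min_value,
             is_nonnegative = x$positivity$is_nonnegative,
             ks = x$gof_value,
             max_moment_residual = max(abs(x$moment_residuals)),
             passed = x$passed)
}

#' Plot a fitted polynomial density
#'
#' @param x A `"polyfit_result"`.
#' @param reference Optional reference density evaluator to overlay.
#' @param n Number of grid points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.polyfit_result <- function(x, reference = NULL, n = 513L, ...) {
  lo <- interval_lo(x$density$validity); hi <- interval_hi(x$density$validity)
  g <- seq(lo, hi, length.out = n)
  y <- evaluate(x$density, g, clip = TRUE)
  graphics::plot(g, y, type = "l", xlab = "x", ylab = "density",
                 main = sprintf("Polynomial density fit (N = %d)", x$degree_used), ...)
  if (!is.null(reference)) graphics::lines(g, reference(g), lty = 2)
  invisible(x)
}
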