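#' Ordered raw moments on an interval
#'
#' A `moment_vector` holds the raw moments \eqn{E[X^k]}, \eqn{k = 0, \dots, N},
#' of a density taken over a stated interval. The order-0 entry is the total
#' mass captured by the interval; for sample moments it is exactly 1.
#'
#' @param values Numeric vector of moments, orders `0:(length(values) - 1)`.
#' @param interval The interval `[a, b]` the moments refer to.
#' @param source How the moments were obtained: `"analytic_quadrature"`,
#'   `"sample"` or `"supplied"`.
#' @return An object of class `"moment_vector"`.
#' @export
moment_vector <- function(values, interval,
                          source = c("supplied", "analytic_quadrature", "sample")) {
  source <- match.arg(source)
  interval <- as_interval(interval)
  if (length(values) < 1L || !all(is.finite(values)))
    stop("moments must be a nonempty vector of finite values", call. = FALSE)
  if (values[[1L]] <= 0)
    stop("order-0 moment (total mass) must be positive", call. = FALSE)
  structure(list(values = as.numeric(values), interval = interval, source = source),
            class = "moment_vector")
}

#' @export
print.moment_vector <- function(x, ...) {
  cat(sprintf("Raw moments of order 0..%d on [%g, %g] (%s)\n",
              length(x$values) - 1L, interval_lo(x$interval),
              interval_hi(x$interval), x$source))
  print(x$values)
  invisible(x)
}

max_order <- function(E) length(E$values) - 1L

#' Raw moment of a density by adaptive quadrature
#'
#' Computes \eqn{\int_a^b x^k f(x)\,dx} with [stats::integrate()]. The density
#' is not renormalized to the interval: if `[a, b]` truncates part of its mass,
#' the truncated moments are returned as-is (the fitting step's normalization
#' absorbs the missing mass).
#'
#' @param f Density evaluator, a vectorized function of one argument returning
#'   nonnegative finite values on the interval.
#' @param k Nonnegative integer moment order.
#' @param interval Integration interval `[a, b]`.
#' @param rel_tol Relative quadrature tolerance in (0, 1).
#' @param subdivisions Subdivision cap for the adaptive rule. Hitting the cap
#'   raises a warning rather than degrading silently.
#' @return The moment, a scalar.
#' @examples
#' raw_moment_quadrature(function(x) 2 * x, 1, interval(0, 1)) # 2/3
#' @export
raw_moment_quadrature <- function(f, k, interval, rel_tol = 1e-10,
                                  subdivisions = 500L) {
  interval <- as_interval(interval)
  if (k < 0 || k != round(k)) stop("moment order k must be a nonnegative integer",
                                   call. = FALSE)
  if (rel_tol <= 0 || rel_tol >= 1) stop("rel_tol must lie in (0, 1)", call. = FALSE)
  integrand <- function(x) {
    y <- x^k * f(x)
    if (any(!is.finite(y)))
      stop(sprintf("non-finite integrand near x = %g for moment order %d",
                   x[which(!is.finite(y))[1L]], k), call. = FALSE)
    y
  }
  res <- stats::integrate(integrand, interval_lo(interval), interval_hi(interval),
                          rel.tol = rel_tol, subdivisions = subdivisions,
                          stop.on.error = FALSE)
  if (res$message != "OK") {
    if (grepl("maximum number of subdivisions", res$message)) {
      warning(sprintf("quadrature subdivision cap (%d) reached for order %d on [%g, %g]; estimate may be degraded",
                      subdivisions, k, interval_lo(interval), interval_hi(interval)),
              call. = FALSE)
    } else {
      stop(sprintf("quadrature failed for moment order %d on [%g, %g]: %s",
                   k, interval_lo(interval), interval_hi(interval), res$message),
           call. = FALSE)
    }
  }
  res$value
}

#' Sample raw moments
#'
#' The order-k sample moment is \eqn{M^{-1}\sum_i x_i^k}. The order-0 entry is
#' exactly 1 for any sample.
#'
#' @param data Nonempty numeric vector with finite entries.
#' @param N Highest order to compute.
#' @param interval Optional interval to attach; defaults to the sample range.
#' @return A [moment_vector()] with `source = "sample"`.
#' @examples
#' sample_moments(c(1, 2, 3), 2) # 1, 2, 14/3
#' @export
sample_moments <- function(data, N, interval = NULL) {
  if (length(data) == 0L || !all(is.finite(data)))
    stop("data must be a nonempty vector of finite values", call. = FALSE)
  if (N < 0 || N != round(N)) stop("N must be a nonnegative integer", call. = FALSE)
  vals <- vapply(0:N, function(k) mean(data^k), numeric(1))
  vals[1L] <- 1
  if (is.null(interval)) {
    rng <- range(data)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)  # degenerate constant sample
    interval <- interval(rng[1L], rng[2L])
  } else {
    interval <- as_interval(interval)
    if (interval_lo(interval) > min(data) || interval_hi(interval) < max(data))
      stop("supplied interval must cover the sample range", call. = FALSE)
  }
  moment_vector(vals, interval, source = "sample")
}

# Density functions for the cataloged families; shared with the synthetic
# generators so sampled data and analytic moments always refer to the same law.
family_density <- function(family, params) {
  switch(family,
    normal = {
      mu <- params$mean; sd <- params$sd
      if (!is.numeric(sd) || sd <= 0) stop("normal family needs sd > 0", call. = FALSE)
      function(x) stats::dnorm(x, mu, sd)
    },
    weibull = {
      k <- params$shape; lam <- params$scale
      if (!is.numeric(k) || k <= 0 || !is.numeric(lam) || lam <= 0)
        stop("weibull family needs positive shape and scale", call. = FALSE)
      function(x) stats::dweibull(x, k, lam)
    },
    lognormal = {
      ml <- params$meanlog; sl <- params$sdlog
      if (!is.numeric(sl) || sl <= 0) stop("lognormal family needs sdlog > 0", call. = FALSE)
      function(x) stats::dlnorm(x, ml, sl)
    },
    weibull_mixture = {
      w <- params$weights; k <- params$shapes; lam <- params$scales
      if (length(w) != length(k) || length(w) != length(lam))
        stop("mixture weights, shapes and scales must have equal length", call. = FALSE)
      if (any(w < 0) || abs(sum(w) - 1) > 1e-12)
        stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
      if (any(k <= 0) || any(lam <= 0))
        stop("mixture components need positive shape and scale", call. = FALSE)
      function(x) {
        y <- numeric(length(x))
        for (i in seq_along(w)) y <- y + w[i] * stats::dweibull(x, k[i], lam[i])
        y
      }
    },
    stop(sprintf("unknown distribution family '%s'", family), call. = FALSE)
  )
}

#' Moments of cataloged test distributions
#'
#' Raw moments of a standard density restricted to `[a, b]`, by quadrature of
#' the full-support density over the interval, without renormalizing first.
#' This is the quantity the polynomial fit consumes; the tail mass lost to
#' truncation is recovered by the fit's own normalization step.
#'
#' @param family One of `"normal"`, `"weibull"`, `"lognormal"`,
#'   `"weibull_mixture"`.
#' @param params Named list of family parameters: `mean`/`sd`, `shape`/`scale`,
#'   `meanlog`/`sdlog`, or `weights`/`shapes`/`scales` for the mixture.
#' @param N Highest moment order.
#' @param interval Moment interval `[a, b]`.
#' @param rel_tol Quadrature tolerance.
#' @return A [moment_vector()] with `source = "analytic_quadrature"`.
#' @examples
#' catalog_moments("weibull", list(shape = 3, scale = 2), 4, interval(0, 5))
#' @export
catalog_moments <- function(family, params, N, interval, rel_tol = 1e-10) {
  interval <- as_interval(interval)
  f <- family_density(family, params)
  vals <- vapply(0:N, function(k)
    raw_moment_quadrature(f, k, interval, rel_tol = rel_tol), numeric(1))
  moment_vector(vals, interval, source = "analytic_quadrature")
}

#' Read a one-column numeric sample from CSV/TSV
#'
#' Accepts one numeric value per line (comma- or tab-separated files with a
#' single column; an optional non-numeric header line is skipped). Non-numeric
#' rows abort with their line numbers.
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_sample <- function(path) {
  if (!file.exists(path)) stop(sprintf("sample file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[,\t ;].*$", "", trimws(lines))
  keep <- nzchar(lines)
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  if (length(vals) && is.na(vals[1L]) && length(vals) > 1L) {
    # header line
    idx <- idx[-1L]; vals <- vals[-1L]
  }
  bad <- idx[is.na(vals)]
  if (length(bad))
    stop(sprintf("non-numeric sample rows at line(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!length(vals)) stop("sample file contains no numeric rows", call. = FALSE)
  vals
}

#' Read precomputed moments from a two-column CSV
#'
#' Expects columns `order, value` with consecutive integer orders starting at 0.
#'
#' @param path File path.
#' @param interval Interval the moments refer to.
#' @return A [moment_vector()] with `source = "supplied"`.
#' @export
read_moments <- function(path, interval) {
  if (!file.exists(path)) stop(sprintf("moments file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.csv(path, header = has_header, comment.char = "#")
  if (ncol(tab) != 2L)
    stop("moments file must have exactly two columns: order, value", call. = FALSE)
  names(tab) <- c("order", "value")
  tab$order <- as.numeric(tab$order); tab$value <- as.numeric(tab$value)
  if (any(is.na(tab$order)) || any(is.na(tab$value)))
    stop("moments file must contain numeric 'order,value' rows", call. = FALSE)
  tab <- tab[order(tab$order), , drop = FALSE]
  if (!identical(as.integer(tab$order), seq_len(nrow(tab)) - 1L))
    stop("moment orders must be the consecutive integers 0..N", call. = FALSE)
  moment_vector(tab$value, interval, source = "supplied")
}
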