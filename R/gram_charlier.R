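# Gram-Charlier type A and Edgeworth density approximations, the classical
# Hermite-series competitors to the polynomial moment fit. The probabilists'
# Hermite convention He_n (orthogonal under the standard Gaussian weight) is
# required here: it is what makes the 1/6 and 1/24 factors in the four-term
# expansion correct.

#' Probabilists' Hermite polynomial
#'
#' \eqn{He_n(x)} via the three-term recurrence
#' \eqn{He_{n+1} = x\,He_n - n\,He_{n-1}}, with \eqn{He_0 = 1},
#' \eqn{He_1 = x}.
#'
#' @param n Nonnegative integer order.
#' @param x Numeric vector.
#' @return \eqn{He_n(x)}, vectorized over `x`.
#' @examples
#' hermite(3, 2) # x^3 - 3x at 2 = 2
#' @export
hermite <- function(n, x) {
  if (n < 0 || n != round(n)) stop("n must be a nonnegative integer", call. = FALSE)
  if (n == 0) return(rep(1, length(x)))
  if (n == 1) return(x)
  hm1 <- rep(1, length(x)); h <- x
  for (k in seq_len(n - 1)) {
    tmp <- x * h - k * hm1
    hm1 <- h; h <- tmp
  }
  h
}

#' Skewness and excess kurtosis from central moments
#'
#' \eqn{\gamma_1 = \mu_3/\mu_2^{3/2}} and
#' \eqn{\gamma_2 = \mu_4/\mu_2^2 - 3}.
#'
#' @param mu2,mu3,mu4 Second, third and fourth central moments
#'   (\eqn{\mu_2 > 0}).
#' @return Named vector `c(gamma1, gamma2)`.
#' @examples
#' skew_kurt(1, 2, 9) # Exp(1): gamma1 = 2, gamma2 = 6
#' @export
skew_kurt <- function(mu2, mu3, mu4) {
  if (!is.numeric(mu2) || mu2 <= 0)
    stop("second central moment must be positive", call. = FALSE)
  c(gamma1 = mu3 / mu2^1.5, gamma2 = mu4 / mu2^2 - 3)
}

# central moments mu_0..mu_K from raw probability moments (E0-normalized to
# tolerate slightly truncated mass)
central_from_raw <- function(raw, K) {
  if (length(raw) < K + 1L)
    stop(sprintf("need raw moments to order %d", K), call. = FALSE)
  m <- raw / raw[1L]
  mean <- m[2L]
  mu <- numeric(K + 1L); mu[1L] <- 1
  for (k in seq_len(K)) {
    j <- 0:k
    mu[k + 1L] <- sum(choose(k, j) * (-mean)^(k - j) * m[j + 1L])
  }
  mu
}

#' Gram-Charlier type A density
#'
#' \deqn{g(x) = \frac{1}{\sigma}\,\phi(z)\Big[1 + \sum_{i=3}^{K} c_i He_i(z)\Big],
#'   \quad z = (x - \mu)/\sigma,}
#' with Hermite coefficients \eqn{c_i = E[He_i(Z)]/i!} of the standardized
#' variable. For `n_corrections = 4` this is exactly the familiar four-term
#' form \eqn{1 + (\gamma_1/6) He_3 + (\gamma_2/24) He_4}; `n_corrections = 3`
#' keeps only the skewness term and `n_corrections = 5` adds
#' \eqn{c_5 = (r_5 - 10 r_3)/120} from the fifth standardized moment. The
#' standardize-then-backtransform construction returns a density in the
#' original units.
#'
#' @param x Evaluation points.
#' @param mean,sd Location and scale used for standardization (`sd > 0`).
#' @param moments A [moment_vector()] (raw moments, order 0 up to at least
#'   `n_corrections`) of the target distribution.
#' @param n_corrections Highest Hermite correction: 3, 4 or 5.
#' @return Density values (may be negative: the expansion is not guaranteed
#'   nonnegative).
#' @export
gc_density <- function(x, mean, sd, moments, n_corrections = 4L) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  if (!n_corrections %in% 3:5)
    stop("n_corrections must be 3, 4 or 5", call. = FALSE)
  raw <- if (inherits(moments, "moment_vector")) moments$values else as.numeric(moments)
  if (length(raw) < n_corrections + 1L)
    stop(sprintf("need raw moments to order %d", n_corrections), call. = FALSE)
  # standardized moments r_k = E[Z^k] about the *supplied* mean/sd
  m <- raw / raw[1L]
  r <- vapply(0:n_corrections, function(k) {
    j <- 0:k
    sum(choose(k, j) * (-mean)^(k - j) * m[j + 1L]) / sd^k
  }, numeric(1))
  eHe <- function(k) {
    # E[He_k(Z)] from standardized raw moments r_0..r_k
    he <- hermite_coefficients(k)
    sum(he * r[seq_along(he)])
  }
  z <- (x - mean) / sd
  corr <- rep(1, length(x))
  for (i in 3:n_corrections) {
    ci <- eHe(i) / factorial(i)
    corr <- corr + ci * hermite(i, z)
  }
  stats::dnorm(z) / sd * corr
}

# monomial coefficients (ascending) of He_k
hermite_coefficients <- function(k) {
  if (k == 0) return(1)
  prev <- 1; cur <- c(0, 1)  # He_0, He_1
  if (k == 1) return(cur)
  for (n in seq_len(k - 1)) {
    nxt <- c(0, cur) - n * c(prev, 0, 0)[seq_len(n + 2L)]
    prev <- cur; cur <- poly_trim(nxt)
    cur <- c(cur, numeric(n + 2L - length(cur)))
    prev <- c(prev, numeric(length(cur) - length(prev)))
  }
  cur
}

#' Edgeworth expansion density
#'
#' The four-term Gram-Charlier form plus the extra
#' \eqn{(\gamma_1^2/72) He_6} term:
#' \deqn{\frac{1}{\sigma}\phi(z)\Big[1 + \frac{\gamma_1}{6}He_3(z)
#'   + \frac{\gamma_2}{24}He_4(z) + \frac{\gamma_1^2}{72}He_6(z)\Big].}
#' With \eqn{\gamma_1 = \gamma_2 = 0} this is exactly the Normal density.
#'
#' @param x Evaluation points.
#' @param mean,sd Location and scale (`sd > 0`).
#' @param gamma1,gamma2 Skewness and excess kurtosis.
#' @return Density values (possibly negative).
#' @export
edgeworth_density <- function(x, mean, sd, gamma1, gamma2) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  z <- (x - mean) / sd
  stats::dnorm(z) / sd *
    (1 + gamma1 / 6 * hermite(3, z) + gamma2 / 24 * hermite(4, z) +
       gamma1^2 / 72 * hermite(6, z))
}

#' Gram-Charlier expansion object
#'
#' Convenience constructor capturing the standardization parameters and
#' Hermite coefficients of an expansion fitted to a sample or moment vector,
#' for serialization and curve export.
#'
#' @param moments A [moment_vector()] or numeric sample.
#' @param n_corrections Highest Hermite correction (3, 4 or 5); ignored for
#'   the Edgeworth variant, which uses its fixed three corrections.
#' @param variant `"gram_charlier_A"` or `"edgeworth"`.
#' @return List of class `"gc_expansion"` with `mean`, `sd`, `coefficients`
#'   (`c_0 = 1`, `c_1 = c_2 = 0`, then the corrections), `variant`, and an
#'   evaluator `density(x)`.
#' @export
gc_expansion <- function(moments, n_corrections = 4L,
                         variant = c("gram_charlier_A", "edgeworth")) {
  variant <- match.arg(variant)
  if (is.numeric(moments) && !inherits(moments, "moment_vector"))
    moments <- sample_moments(moments, max(n_corrections, 6L))
  raw <- moments$values
  K <- if (variant == "edgeworth") 4L else n_corrections
  mu <- central_from_raw(raw, K)
  mean <- raw[2L] / raw[1L]; sd <- sqrt(mu[3L])
  gk <- skew_kurt(mu[3L], mu[4L], if (K >= 4) mu[5L] else 3 * mu[3L]^2)
  coefs <- c(1, 0, 0, gk[["gamma1"]] / 6,
             if (K >= 4) gk[["gamma2"]] / 24,
             if (K >= 5) {
               r5 <- mu[6L] / sd^5
               r3 <- mu[4L] / sd^3
               (r5 - 10 * r3) / 120
             })
  dens <- if (variant == "edgeworth")
    function(x) edgeworth_density(x, mean, sd, gk[["gamma1"]], gk[["gamma2"]])
  else
    function(x) gc_density(x, mean, sd, moments, n_corrections = n_corrections)
  structure(list(mean = mean, sd = sd, coefficients = coefs,
                 variant = variant, density = dens),
            class = "gc_expansion")
}

#' @export
print.gc_expansion <- function(x, ...) {
  cat(sprintf("%s expansion: mean %.4g, sd %.4g\n",
              if (x$variant == "edgeworth") "Edgeworth" else "Gram-Charlier A",
              x$mean, x$sd))
  cat("Hermite coefficients:", format(x$coefficients, digits = 5), "\n")
  invisible(x)
}
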