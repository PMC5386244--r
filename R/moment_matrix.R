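# The Hankel moment matrix M with entries (b^{i+j+1} - a^{i+j+1})/(i+j+1)
# and the solvers for M w = E. On [0, 1] the matrix is the Hilbert matrix,
# whose inverse has an explicit integer formula; that exact inverse and a
# fully rational elimination are offered as alternatives to the default
# floating-point factorization because the system's conditioning explodes
# with the degree.

#' Build the Hankel moment matrix
#'
#' Entry \eqn{(i, j)} (0-based) is \eqn{(b^{i+j+1} - a^{i+j+1})/(i+j+1)}, the
#' order-(i+j) moment of the monomial basis on \eqn{[a, b]}. The matrix is
#' symmetric and constant along anti-diagonals; on \eqn{[0, 1]} it is the
#' Hilbert matrix.
#'
#' @param N Polynomial degree; the matrix has order `N + 1`.
#' @param interval Moment interval `[a, b]`.
#' @return A `"moment_matrix"`: list with `entries`, `interval` and
#'   `condition_estimate` (1-norm condition number estimate).
#' @examples
#' build_moment_matrix(2, interval(0, 1)) # the 3x3 Hilbert matrix
#' @export
build_moment_matrix <- function(N, interval) {
  interval <- as_interval(interval)
  if (N < 0 || N != round(N)) stop("N must be a nonnegative integer", call. = FALSE)
  a <- interval_lo(interval); b <- interval_hi(interval)
  pw <- outer(0:N, 0:N, `+`) + 1
  entries <- (b^pw - a^pw) / pw
  if (any(!is.finite(entries))) {
    bad <- which(!is.finite(entries), arr.ind = TRUE)[1L, ]
    stop(sprintf("overflow in moment matrix at power %d for interval [%g, %g]",
                 pw[bad[1L], bad[2L]], a, b), call. = FALSE)
  }
  cond <- tryCatch(kappa(entries, exact = FALSE), error = function(e) Inf)
  structure(list(entries = entries, interval = interval,
                 condition_estimate = cond),
            class = "moment_matrix")
}

#' @export
print.moment_matrix <- function(x, ...) {
  cat(sprintf("Hankel moment matrix of order %d on [%g, %g], condition ~ %.3g\n",
              nrow(x$entries), interval_lo(x$interval), interval_hi(x$interval),
              x$condition_estimate))
  print(x$entries)
  invisible(x)
}

#' Exact inverse of the Hilbert matrix
#'
#' The \eqn{n \times n} Hilbert matrix \eqn{H_{ij} = 1/(i + j - 1)} has an
#' explicit integer inverse,
#' \deqn{(H^{-1})_{ij} = (-1)^{i+j} (i + j - 1)
#'   \binom{n+i-1}{n-j} \binom{n+j-1}{n-i} \binom{i+j-2}{i-1}^2.}
#' Entries are computed in exact big-integer arithmetic (they overflow 64-bit
#' integers well before `n = 13`) and either returned as doubles or, with
#' `exact = TRUE`, as the internal exact representation for downstream exact
#' computation.
#'
#' @param n Matrix order, a positive integer.
#' @param exact Return the exact big-integer entries (a list-of-rows of
#'   internal bigint objects) instead of doubles.
#' @return Numeric matrix, or list-of-rows of exact integers.
#' @examples
#' hilbert_inverse(2) # matrix(c(4, -6, -6, 12), 2)
#' @export
hilbert_inverse <- function(n, exact = FALSE) {
  if (n < 1 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  # Pascal triangle rows 0..2n in exact arithmetic
  ch <- vector("list", 2L * n + 1L)
  ch[[1L]] <- list(bi_one())
  for (r in seq_len(2L * n)) {
    prev <- ch[[r]]
    row <- vector("list", r + 1L)
    row[[1L]] <- bi_one(); row[[r + 1L]] <- bi_one()
    if (r > 1L) for (k in 2:r) row[[k]] <- bi_add(prev[[k - 1L]], prev[[k]])
    ch[[r + 1L]] <- row
  }
  binom <- function(a, b) {
    if (b < 0 || b > a) return(bi_zero())
    ch[[a + 1L]][[b + 1L]]
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    row <- vector("list", n)
    for (j in seq_len(n)) {
      v <- bi_mul_small(binom(n + i - 1L, n - j), i + j - 1L)
      v <- bi_mul(v, binom(n + j - 1L, n - i))
      c2 <- binom(i + j - 2L, i - 1L)
      v <- bi_mul(v, bi_mul(c2, c2))
      if ((i + j) %% 2L == 1L) v <- bi_neg(v)
      row[[j]] <- v
    }
    rows[[i]] <- row
  }
  if (exact) return(rows)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- bi_to_double(rows[[i]][[j]])
  out
}

# Verify H^{-1} H = I exactly: sum_k A[i,k] * L/(k+j-1) must equal L*delta_ij,
# with L = lcm(1..2n-1) (fits a double). Used by the exact-arithmetic tests.
hilbert_inverse_identity_exact <- function(n) {
  Ainv <- hilbert_inverse(n, exact = TRUE)
  denoms <- seq_len(2L * n - 1L)
  L <- Reduce(function(a, b) a * b / gcd_int(a, b), denoms)
  Lbig <- bi(L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- bi_zero()
    for (k in seq_len(n)) {
      term <- bi_mul(Ainv[[i]][[k]], bi(L / (k + j - 1)))
      acc <- bi_add(acc, term)
    }
    target <- if (i == j) Lbig else bi_zero()
    if (!bi_eq(acc, target)) return(FALSE)
  }
  TRUE
}

gcd_int <- function(a, b) { while (b != 0) { t <- a %% b; a <- b; b <- t }; a }

#' Solve the moment system M w = E for the polynomial weights
#'
#' Three strategies are available for the ill-conditioned Hankel system:
#' \describe{
#'   \item{`factorized`}{LU factorization of the Hankel matrix (never an
#'     explicit floating-point inverse). The default.}
#'   \item{`rescaled_hilbert`}{Affine rescale of \eqn{[a, b]} to \eqn{[0, 1]}
#'     (binomial transform of the moments), application of the exact integer
#'     Hilbert inverse, and binomial back-transform of the weights.}
#'   \item{`exact_rational`}{Exact rational Gaussian elimination treating the
#'     (binary-representable) moments and interval endpoints as exact
#'     rationals; the returned doubles are roundings of the exact solution.}
#' }
#' A condition estimate beyond `1e12` raises a warning of class
#' `"polydens_condition_warning"`; a numerically singular system is an error
#' suggesting a different degree or moment interval.
#'
#' @param M A [build_moment_matrix()] result.
#' @param E A [moment_vector()] of matching length and interval.
#' @param solver Strategy, see above.
#' @return Numeric weight vector `w0..wN` with attribute `"residual"`, the
#'   max absolute residual of `M w - E` relative to `max(|E|)`.
#' @export
solve_weights <- function(M, E,
                          solver = c("factorized", "rescaled_hilbert", "exact_rational")) {
  solver <- match.arg(solver)
  n <- nrow(M$entries)
  if (length(E$values) != n)
    stop(sprintf("moment vector length (%d) must equal matrix order (%d)",
                 length(E$values), n), call. = FALSE)
  if (!isTRUE(all.equal(unclass(M$interval), unclass(E$interval), tolerance = 1e-12)))
    stop("moment vector and moment matrix refer to different intervals", call. = FALSE)
  if (is.finite(M$condition_estimate) && M$condition_estimate > 1e12)
    warning(structure(class = c("polydens_condition_warning", "warning", "condition"),
                      list(message = sprintf(
                        "moment system condition estimate %.3g exceeds 1e12; weights may be inaccurate (consider a lower degree, a different interval, or the exact_rational solver)",
                        M$condition_estimate), call = NULL)))
  a <- interval_lo(M$interval); b <- interval_hi(M$interval)
  w <- switch(solver,
    factorized = {
      out <- tryCatch(solve(M$entries, E$values, tol = 0),
                      error = function(e)
                        stop("moment system not solvable (numerically singular); change the degree N or the moment interval [a, b]",
                             call. = FALSE))
      if (any(!is.finite(out)))
        stop("moment system not solvable (non-finite solution); change the degree N or the moment interval [a, b]",
             call. = FALSE)
      out
    },
    rescaled_hilbert = {
      s <- b - a
      k <- 0:(n - 1L)
      # moments of u = (x - a)/s from moments of x
      Eu <- vapply(k, function(kk) {
        j <- 0:kk
        sum(choose(kk, j) * (-a)^(kk - j) * E$values[j + 1L]) / s^kk
      }, numeric(1))
      Hinv <- hilbert_inverse(n)
      wu <- drop(Hinv %*% Eu)
      # P(x) = Pu((x - a)/s)/s, expanded back to the monomial basis in x
      w <- numeric(n)
      for (m in k) {
        j <- 0:m
        w[j + 1L] <- w[j + 1L] + wu[m + 1L] / s^(m + 1) * choose(m, j) * (-a)^(m - j)
      }
      w
    },
    exact_rational = {
      qa <- q_from_double(a); qb <- q_from_double(b)
      pa <- qq(bi_one()); pb <- qq(bi_one())  # running powers a^p, b^p
      ent <- vector("list", 2L * n - 1L)      # anti-diagonal values, power p = s+1
      for (p in seq_len(2L * n - 1L)) {
        pa <- q_mul(pa, qa); pb <- q_mul(pb, qb)
        ent[[p]] <- q_div(q_sub(pb, pa), q_from_double(p))
      }
      A <- lapply(seq_len(n), function(i)
        lapply(seq_len(n), function(j) ent[[i + j - 1L]]))
      bq <- lapply(E$values, q_from_double)
      xs <- q_solve(A, bq)
      vapply(xs, q_to_double, numeric(1))
    })
  resid <- max(abs(M$entries %*% w - E$values)) / max(abs(E$values))
  attr(w, "residual") <- resid
  w
}
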