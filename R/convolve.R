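# Exact convolution of compactly supported polynomial densities. Because the
# integration limits of the convolution integral depend on the evaluation
# point, the density of a sum of two independent polynomial-density variables
# is piecewise polynomial (degree up to N + M + 1), not a single global
# polynomial; the pieces are computed in closed form by term-wise integration.

#' Piecewise polynomial function
#'
#' Breakpoints plus one ascending coefficient vector per piece, in global
#' coordinates; zero outside the outer breakpoints.
#'
#' @param breakpoints Strictly increasing numeric vector (length
#'   `length(pieces) + 1`).
#' @param pieces List of ascending coefficient vectors.
#' @return An object of class `"piecewise_polynomial"`.
#' @export
piecewise_polynomial <- function(breakpoints, pieces) {
  if (length(breakpoints) != length(pieces) + 1L)
    stop("need one more breakpoint than pieces", call. = FALSE)
  if (any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing", call. = FALSE)
  structure(list(breakpoints = as.numeric(breakpoints), pieces = pieces),
            class = "piecewise_polynomial")
}

#' @export
print.piecewise_polynomial <- function(x, ...) {
  cat(sprintf("Piecewise polynomial with %d piece(s) on [%g, %g]\n",
              length(x$pieces), x$breakpoints[1L],
              x$breakpoints[length(x$breakpoints)]))
  for (i in seq_along(x$pieces))
    cat(sprintf("  [%g, %g]: degree %d\n", x$breakpoints[i],
                x$breakpoints[i + 1L], length(x$pieces[[i]]) - 1L))
  invisible(x)
}

#' Evaluate a piecewise polynomial
#'
#' @param pp A [piecewise_polynomial()].
#' @param x Numeric vector; zero outside the support.
#' @return Numeric vector.
#' @export
evaluate_piecewise <- function(pp, x) {
  y <- numeric(length(x))
  bp <- pp$breakpoints
  idx <- findInterval(x, bp, rightmost.closed = TRUE)
  inside <- idx >= 1L & idx <= length(pp$pieces)
  for (i in unique(idx[inside]))
    y[idx == i] <- poly_eval(pp$pieces[[i]], x[idx == i])
  y
}

#' Integral of a piecewise polynomial over its support
#'
#' @param pp A [piecewise_polynomial()].
#' @return Closed-form integral.
#' @export
integrate_piecewise <- function(pp) {
  bp <- pp$breakpoints
  sum(vapply(seq_along(pp$pieces), function(i)
    poly_integral(pp$pieces[[i]], bp[i], bp[i + 1L]), numeric(1)))
}

#' Exact convolution of two polynomial densities
#'
#' Computes the density of \eqn{X + Y} for independent variables with
#' normalized polynomial densities `P` on \eqn{[a_1, b_1]} and `Q` on
#' \eqn{[a_2, b_2]}:
#' \deqn{(P * Q)(t) = \int_{\max(a_1, t - b_2)}^{\min(b_1, t - a_2)}
#'   P(x)\,Q(t - x)\,dx,}
#' expanded term-wise so every piece is an exact polynomial in `t`. The
#' support is \eqn{[a_1 + a_2, b_1 + b_2]}; interior breakpoints occur where
#' an integration limit changes branch. Total mass 1 is preserved exactly
#' (up to rounding).
#'
#' Optionally a single global polynomial is re-fitted to the exact result via
#' the moments of the sum ([moments_of_sum()]) and [fit_polynomial_pdf()],
#' mirroring the single-polynomial representation of the method; the exact
#' answer remains the piecewise one.
#'
#' @param P,Q Normalized [polynomial_density()] objects.
#' @param refit_degree If non-`NULL`, also return a degree-`refit_degree`
#'   single-polynomial re-fit as attribute `"refit"`.
#' @return A [piecewise_polynomial()].
#' @examples
#' U <- polynomial_density(1, interval(0, 1), normalized = TRUE)
#' tri <- convolve_polynomial_densities(U, U)  # triangular on [0, 2]
#' evaluate_piecewise(tri, 1) # peak value 1
#' @export
convolve_polynomial_densities <- function(P, Q, refit_degree = NULL) {
  for (D in list(P, Q))
    if (!inherits(D, "polynomial_density") || !D$normalized)
      stop("both inputs must be normalized polynomial densities", call. = FALSE)
  a1 <- interval_lo(P$validity); b1 <- interval_hi(P$validity)
  a2 <- interval_lo(Q$validity); b2 <- interval_hi(Q$validity)
  w <- P$weights; z <- Q$weights
  bp <- sort(unique(c(a1 + a2, a1 + b2, b1 + a2, b1 + b2)))
  # drop numerically coincident breakpoints
  bp <- bp[c(TRUE, diff(bp) > 1e-12 * max(abs(bp), 1))]

  # antiderivative (in x) of P(x) Q(t - x): coefficients on x^{m+1} t^l
  # term (i, j, l): w_i z_j C(j, l) (-1)^{j-l} x^{i+j-l} t^l
  terms <- list()
  for (i in seq_along(w) - 1L) {
    if (w[i + 1L] == 0) next
    for (j in seq_along(z) - 1L) {
      if (z[j + 1L] == 0) next
      for (l in 0:j) {
        cf <- w[i + 1L] * z[j + 1L] * choose(j, l) * (-1)^(j - l)
        m <- i + j - l
        terms[[length(terms) + 1L]] <- c(cf = cf, m = m, l = l)
      }
    }
  }

  # polynomial in t for x0^{m+1}, where x0 is const c or t + d
  bound_power <- function(kind, val, mp1) {
    if (kind == "const") return(val^mp1)        # degree-0 polynomial
    j <- 0:mp1                                   # (t + d)^{m+1}
    cf <- choose(mp1, j) * val^(mp1 - j)
    cf
  }

  pieces <- vector("list", length(bp) - 1L)
  for (p in seq_len(length(bp) - 1L)) {
    tm <- (bp[p] + bp[p + 1L]) / 2
    lower_const <- a1 >= tm - b2   # L(t) = max(a1, t - b2)
    upper_const <- b1 <= tm - a2   # U(t) = min(b1, t - a2)
    acc <- 0
    for (term in terms) {
      mp1 <- term[["m"]] + 1L
      up <- if (upper_const) bound_power("const", b1, mp1)
            else bound_power("lin", -a2, mp1)
      lo <- if (lower_const) bound_power("const", a1, mp1)
            else bound_power("lin", -b2, mp1)
      diffp <- poly_add(up, -lo)
      contrib <- poly_scale(diffp, term[["cf"]] / mp1)
      # multiply by t^l
      if (term[["l"]] > 0) contrib <- c(numeric(term[["l"]]), contrib)
      acc <- poly_add(acc, contrib)
    }
    pieces[[p]] <- poly_trim(acc)
  }
  out <- piecewise_polynomial(bp, pieces)
  if (!is.null(refit_degree)) {
    E <- moments_of_sum(P, Q, refit_degree)
    cfg <- fit_config(refit_degree, E$interval, gof = "none")
    attr(out, "refit") <- fit_polynomial_pdf(E, cfg)
  }
  out
}

#' Raw moments of a sum of independent polynomial-density variables
#'
#' Uses the binomial identity
#' \eqn{E[(X + Y)^k] = \sum_j \binom{k}{j} E[X^j] E[Y^{k-j}]} with the
#' closed-form polynomial moments of each density over its own validity
#' interval; this allows re-fitting a single polynomial density to the sum
#' without ever forming the convolution.
#'
#' @param P,Q Normalized [polynomial_density()] objects.
#' @param N Highest moment order.
#' @return A [moment_vector()] on the sum support.
#' @export
moments_of_sum <- function(P, Q, N) {
  for (D in list(P, Q))
    if (!inherits(D, "polynomial_density") || !D$normalized)
      stop("both inputs must be normalized polynomial densities", call. = FALSE)
  EP <- vapply(0:N, function(k) polynomial_moment(P, k), numeric(1))
  EQ <- vapply(0:N, function(k) polynomial_moment(Q, k), numeric(1))
  vals <- vapply(0:N, function(k) {
    j <- 0:k
    sum(choose(k, j) * EP[j + 1L] * EQ[k - j + 1L])
  }, numeric(1))
  iv <- interval(interval_lo(P$validity) + interval_lo(Q$validity),
                 interval_hi(P$validity) + interval_hi(Q$validity))
  moment_vector(vals, iv, source = "supplied")
}
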