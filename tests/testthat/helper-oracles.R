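# Shared fixtures and independent oracles used across the suite.

# brute-force Riemann midpoint moment, independent of the quadrature path
riemann_moment <- function(f, k, lo, hi, panels = 1e6) {
  h <- (hi - lo) / panels
  x <- lo + (seq_len(panels) - 0.5) * h
  sum(x^k * f(x)) * h
}

# numerical convolution of two densities on a fine grid (Riemann sum),
# independent of the closed-form piecewise machinery
numeric_convolution <- function(P, Q, t, panels = 2^14) {
  a1 <- P$validity[[1]]; b1 <- P$validity[[2]]
  vapply(t, function(tt) {
    lo <- max(a1, tt - Q$validity[[2]])
    hi <- min(b1, tt - Q$validity[[1]])
    if (hi <= lo) return(0)
    h <- (hi - lo) / panels
    x <- lo + (seq_len(panels) - 0.5) * h
    sum(evaluate(P, x) * evaluate(Q, tt - x)) * h
  }, numeric(1))
}

weibull32 <- function(x) dweibull(x, 3, 2)

# degree-N fit of a density evaluator with no degree search, gof off
quiet_fit <- function(f, N, a, b, ap = a, bp = b, solver = "factorized") {
  cfg <- fit_config(N, interval(a, b), interval(ap, bp), gof = "none",
                    n_max = N, n_min = N, solver = solver)
  fit_polynomial_pdf(f, cfg)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%.12g - %.12g| <= %g", object, expected, tol))
}
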