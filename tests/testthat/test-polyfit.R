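test_that("polynomial moments, evaluation and CDF have their closed forms", {
  U <- polynomial_density(1, interval(0, 1), normalized = TRUE)
  expect_equal(polynomial_moment(U, 2), 1 / 3)
  lin <- polynomial_density(c(0, 2), interval(0, 1), normalized = TRUE)
  expect_equal(polynomial_moment(lin, 1), 2 / 3)
  u5 <- polynomial_density(0.2, interval(0, 5), normalized = TRUE)
  expect_equal(polynomial_moment(u5, 0), 1)

  expect_equal(evaluate(U, c(-3, 0.2, 9)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(attr(evaluate(U, c(-3, 0.2, 9)), "out_of_support"), c(1L, 3L))
  expect_equal(cdf(lin, 0.5), 0.25)
  expect_equal(cdf(lin, 0), 0)
  expect_equal(cdf(lin, 1), 1)
  expect_error(cdf(polynomial_density(c(0, 2), interval(0, 1)), 0.5), "normalized")
})

test_that("normalization divides by the closed-form mass and is idempotent", {
  P <- polynomial_density(2, interval(0, 1))
  expect_equal(normalize(P)$weights, 1)
  Q <- polynomial_density(c(0, 1), interval(0, 2))
  expect_equal(normalize(Q)$weights, c(0, 0.5))
  expect_equal(normalize(normalize(Q)), normalize(Q))
  neg <- polynomial_density(c(-1), interval(0, 1))
  expect_error(normalize(neg), "cannot normalize")
})

test_that("positivity check finds interior minima and endpoint violations", {
  lin <- polynomial_density(c(-0.5, 1), interval(0, 1))
  rep1 <- check_positivity(lin, interval(0, 1))
  expect_false(rep1$is_nonnegative)
  expect_equal(rep1$min_value, -0.5)
  expect_equal(rep1$argmin, 0)

  expect_true(check_positivity(polynomial_density(0.2, interval(0, 5)))$is_nonnegative)

  # interior dip below zero caught via the derivative's roots
  quad <- polynomial_density(c(0.05, -1, 1), interval(0, 1))  # min at x = 0.5
  rep2 <- check_positivity(quad, interval(0, 1))
  expect_false(rep2$is_nonnegative)
  expect_equal(rep2$argmin, 0.5, tolerance = 1e-6)
  expect_equal(rep2$min_value, 0.05 - 0.25, tolerance = 1e-9)
})

test_that("uniform and triangular densities are recovered exactly from moments", {
  u <- interval(0, 1)
  E <- moment_vector(1 / (1:4), u)
  fit <- fit_polynomial_pdf(E, fit_config(3, u, gof = "none"))
  expect_true(fit$passed)
  expect_equal(fit$density$weights, c(1, 0, 0, 0), tolerance = 1e-8)

  E2 <- moment_vector(c(1, 2 / 3), u)
  fit2 <- fit_polynomial_pdf(E2, fit_config(1, u, gof = "none", n_min = 1))
  expect_equal(fit2$density$weights, c(0, 2), tolerance = 1e-10)
  expect_lt(max(abs(fit2$moment_residuals)), 1e-12)
})

test_that("a polynomial density is its own fit when the degree suffices", {
  # cubic density on [0, 2], fitted from its exact moments at N = 3 and N = 5
  true_w <- c(0.1, 0.3, -0.2, 0.125)
  tw_mass <- sum(true_w * (2^(1:4)) / (1:4))
  true_w <- true_w / tw_mass
  P <- polynomial_density(true_w, interval(0, 2), normalized = TRUE)
  E <- moment_vector(vapply(0:5, function(k) polynomial_moment(P, k), numeric(1)),
                     interval(0, 2))
  for (N in c(3L, 5L)) {
    cfg <- fit_config(N, interval(0, 2), gof = "none", n_max = N, n_min = N)
    fit <- fit_polynomial_pdf(moment_vector(E$values[1:(N + 1)], E$interval), cfg)
    got <- c(fit$density$weights, numeric(6 - N - 1))
    expect_equal(got[1:4], true_w, tolerance = 1e-6)
    if (N > 3) expect_equal(got[5:(N + 1)], numeric(N - 3), tolerance = 1e-6)
  }
  # exact-rational route recovers the coefficients to full double precision
  cfg <- fit_config(3, interval(0, 2), gof = "none", n_max = 3, n_min = 3,
                    solver = "exact_rational")
  fit <- fit_polynomial_pdf(moment_vector(E$values[1:4], E$interval), cfg)
  expect_equal(fit$density$weights, true_w, tolerance = 1e-12)
})

test_that("moments are reproduced by the fitted polynomial before normalization", {
  fw <- weibull32
  for (N in c(4, 8, 12)) {
    fit <- quiet_fit(fw, N, 0, 5)
    E <- vapply(0:N, function(k)
      raw_moment_quadrature(fw, k, interval(0, 5)), numeric(1))
    expect_lt(max(abs(fit$moment_residuals)) / max(abs(E)), 1e-6)
  }
})

test_that("fit quality improves with degree for a smooth target (L1 trend)", {
  errs <- vapply(c(4, 6, 8, 10), function(N) {
    fit <- quiet_fit(weibull32, N, 0, 5)
    density_errors(weibull32, fit$density, interval(0.2, 4))$l1
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # sup-norm also shrinks from N = 4 to N = 10 on the inner interval
  linfs <- vapply(c(4, 10), function(N)
    density_errors(weibull32, quiet_fit(weibull32, N, 0, 5)$density,
                   interval(0.2, 4))$linf, numeric(1))
  expect_lt(linfs[2], linfs[1])
})

test_that("degree search walks upward then downward and reports failures", {
  # a target whose N = 2 fit dips negative on [0, 1] but whose N = 3 fit is fine
  f <- function(x) dbeta(x, 4, 4)
  cfg <- fit_config(2, interval(0, 1), gof = "none", n_max = 3, n_min = 2)
  fit <- fit_polynomial_pdf(f, cfg)
  expect_true(all(fit$trace$degree[1:2] == c(2, 3)))

  # no nonnegative candidate anywhere: passed = FALSE and per-degree minima
  fsin <- function(x) dnorm(x, 2.5, 0.18)
  cfg2 <- fit_config(4, interval(0, 5), gof = "none", n_max = 5, n_min = 4)
  fit2 <- fit_polynomial_pdf(fsin, cfg2)
  expect_false(fit2$passed)
  expect_true(all(is.finite(fit2$trace$min_value)))
  expect_true(all(fit2$trace$min_value < 0))
})

test_that("narrowing the validity interval rescues a fit that dips negative", {
  f <- function(x) dnorm(x, 2.5, sqrt(0.4))
  wide <- quiet_fit(f, 10, 0, 5)
  expect_false(wide$positivity$is_nonnegative)
  narrow <- quiet_fit(f, 10, 0, 5, ap = 2, bp = 3)
  expect_true(narrow$positivity$is_nonnegative)
  expect_true(narrow$passed)
  expect_equal(polynomial_moment(narrow$density, 0, interval(2, 3)), 1,
               tolerance = 1e-9)
})

test_that("tidy and glance expose the coefficients and diagnostics", {
  fit <- quiet_fit(weibull32, 6, 0, 5)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 7)
  expect_equal(td$estimate, fit$density$weights)
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("degree", "condition_estimate", "passed") %in% names(gl)))
})
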