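test_that("the exact linear-kernel solution evaluates and conserves mass", {
  expect_equal(sce_exact_linear(1, 0), exp(-0.5) / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_error(sce_exact_linear(0, 1), "singular")
  # m^{3/2} f stays bounded near the origin with limit e^{-t}/sqrt(2 pi)
  for (t in c(0, 0.7)) {
    m <- 10^seq(-8, -2, length.out = 7)
    corr <- m^1.5 * sce_exact_linear(m, t)
    expect_true(all(is.finite(corr)))
    expect_equal(corr[1], exp(-t) / sqrt(2 * pi), tolerance = 1e-6)
  }
  # total mass integral m f(m, t) dm = 1 at several times
  for (t in c(0, 0.5, 1)) {
    mass <- integrate(function(m) m * sce_exact_linear(m, t), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
})

test_that("closed-form truncated moments reduce to known special values", {
  # order 1 at infinite cutoff is 1 at every time (mass conservation)
  for (t in c(0, 0.3, 1, 2.5))
    expect_equal(sce_truncated_moment(1, Inf, t), 1, tolerance = 1e-14)
  # order 1, t = 0, a = 2 reduces to erf(1)
  erf1 <- 2 * pnorm(sqrt(2)) - 1
  expect_equal(sce_truncated_moment(1, 2, 0), erf1, tolerance = 1e-12)
  # order 2 at infinite cutoff grows like e^{2t}
  for (t in c(0, 0.4, 1))
    expect_equal(sce_truncated_moment(2, Inf, t), exp(2 * t), tolerance = 1e-12)
  expect_error(sce_truncated_moment(0, 5, 1), "diverges")
})

test_that("truncated moments agree with quadrature of the exact solution", {
  for (n in 1:4) for (t in c(0, 0.4, 1)) for (a in c(1, 5, Inf)) {
    got <- sce_truncated_moment(n, a, t)
    want <- integrate(function(m) m^n * sce_exact_linear(m, t), 0,
                      if (is.infinite(a)) Inf else a,
                      rel.tol = 1e-12, subdivisions = 2000L)$value
    expect_equal(got, want, tolerance = 1e-8)
  }
  # half-integer orders (power-law-corrected moments) against quadrature too
  for (n in c(1.5, 2.5)) {
    got <- polydens:::sce_band_moment(n, 0.05, 20, 1)
    want <- integrate(function(m) m^n * sce_exact_linear(m, 1), 0.05, 20,
                      rel.tol = 1e-12)$value
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("the moment hierarchy closes with the expected right-hand sides", {
  const <- kernel_spec("constant", 1)
  expect_equal(sce_moment_rhs(const, c(1), 0), -0.5)
  lin <- kernel_spec("linear", 0.5)
  # mass conservation at order 1 for every kernel
  for (k in list(const, lin, kernel_spec("product", 2)))
    expect_equal(sce_moment_rhs(k, c(1, 1, 3), 1), 0)
  # linear kernel order 2 reduces to M1 * M2
  for (c2 in c(1, 2.7))
    expect_equal(sce_moment_rhs(lin, c(1, 1, c2), 2), c2)
})

test_that("hierarchy derivatives match the closed-form moment evolution", {
  # d/dt of the order-n full moment vs the rhs at the matching state
  lin <- kernel_spec("linear", 1)
  h <- 1e-5
  for (t in c(0.2, 0.8)) for (n in 2:4) {
    state <- vapply(0:4, function(k)
      if (k == 0) NA_real_ else sce_truncated_moment(k, Inf, t), numeric(1))
    state[1] <- 0  # M_0 unused by the linear rhs at orders >= 2 given the cancellation
    num <- (sce_truncated_moment(n, Inf, t + h) -
              sce_truncated_moment(n, Inf, t - h)) / (2 * h)
    expect_equal(sce_moment_rhs(lin, state, n), num, tolerance = 1e-4)
  }
})

test_that("integrating the hierarchy reproduces closed-form trajectories", {
  # constant kernel: M0(t) = M0(0)/(1 + K0 M0(0) t / 2)
  traj <- sce_integrate_moments(kernel_spec("constant", 1.3),
                                c(2, 1, 1.5), seq(0, 2, by = 0.25))
  expect_equal(traj[, "M0"], 2 / (1 + 1.3 * 2 * traj[, "time"] / 2),
               tolerance = 1e-6, ignore_attr = TRUE)
  # linear kernel at amplitude 1: M2 grows like e^{2t}
  traj2 <- sce_integrate_moments(kernel_spec("linear", 1),
                                 c(1, 1, 1, 3), seq(0, 1.5, by = 0.25),
                                 n_orders = 2)
  expect_equal(traj2[, "M2"], exp(2 * traj2[, "time"]), tolerance = 1e-6,
               ignore_attr = TRUE)
  # mass conservation along both trajectories
  expect_lt(max(abs(traj[, "M1"] - 1)), 1e-8)
  expect_lt(max(abs(traj2[, "M1"] - 1)), 1e-8)
})

test_that("the product kernel is guarded against gelation", {
  expect_error(sce_integrate_moments(kernel_spec("product", 1),
                                     c(1, 1, 2), c(0, 0.6)), "gels")
  traj <- sce_integrate_moments(kernel_spec("product", 1),
                                c(1, 1, 2), c(0, 0.3))
  # pre-gelation M2(t) = M2(0)/(1 - A M2(0) t)
  expect_equal(traj[, "M2"], 2 / (1 - 2 * traj[, "time"]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("power-law removal reconstructs the size distribution accurately", {
  band <- interval(0.05, 20)
  rec <- sce_reconstruct(1, band, degree = 8, exponent = 1.5)
  relerr <- function(r) {
    num <- integrate(function(m) abs(m * (r$density(m) - sce_exact_linear(m, 1))),
                     0.05, 20, rel.tol = 1e-8, subdivisions = 2000L)$value
    den <- integrate(function(m) m * sce_exact_linear(m, 1), 0.05, 20,
                     rel.tol = 1e-10)$value
    num / den
  }
  expect_lt(relerr(rec), 0.05)
  # the corrected (power-law-free) fit is nonnegative on the band
  expect_true(rec$positivity$is_nonnegative)
  # without removal the fit oscillates and the error explodes
  rec0 <- sce_reconstruct(1, band, degree = 8, exponent = 0)
  expect_gt(relerr(rec0), relerr(rec))
})

test_that("reconstruction accepts externally supplied corrected moments", {
  band <- interval(0.05, 20)
  vals <- vapply(0:8, function(k)
    integrate(function(m) m^(k + 1.5) * sce_exact_linear(m, 1),
              0.05, 20, rel.tol = 1e-12)$value, numeric(1))
  rec <- sce_reconstruct(1, band, degree = 8, exponent = 1.5,
                         moments = moment_vector(vals, band))
  g <- seq(0.1, 15, length.out = 50)
  expect_equal(rec$density(g), sce_exact_linear(g, 1), tolerance = 1e-4)
})
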