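test_that("probabilists' Hermite polynomials match hand evaluations", {
  x <- c(-1.3, 0, 2, 5)
  expect_equal(hermite(0, x), rep(1, 4))
  expect_equal(hermite(1, x), x)
  expect_equal(hermite(3, 2), 2)          # x^3 - 3x
  expect_equal(hermite(4, 0), 3)          # x^4 - 6x^2 + 3
  expect_equal(hermite(6, x), x^6 - 15 * x^4 + 45 * x^2 - 15)
})

test_that("skewness and excess kurtosis come out right for known laws", {
  expect_equal(skew_kurt(2, 0, 3 * 4), c(gamma1 = 0, gamma2 = 0))  # normal
  expect_equal(skew_kurt(1, 2, 9), c(gamma1 = 2, gamma2 = 6))      # Exp(1)
  # any symmetric density has zero skewness
  m <- catalog_moments("normal", list(mean = 0, sd = 2), 4, interval(-30, 30))
  mu <- polydens:::central_from_raw(m$values, 4)
  gk <- skew_kurt(mu[3], mu[4], mu[5])
  expect_equal(unname(gk[1]), 0, tolerance = 1e-8)
})

test_that("zero skewness and kurtosis collapse the expansion to the Normal", {
  # raw moments of Normal(mean, sd) give gamma1 = gamma2 = 0, so the 4-term
  # expansion must equal the Normal density at every point
  mean <- 1.7; sd <- 0.6
  raw <- vapply(0:4, function(k)
    integrate(function(x) x^k * dnorm(x, mean, sd), -10, 10,
              rel.tol = 1e-12)$value, numeric(1))
  mv <- moment_vector(raw, interval(-10, 10))
  x <- seq(-1, 4, length.out = 101)
  expect_equal(gc_density(x, mean, sd, mv, 4), dnorm(x, mean, sd),
               tolerance = 1e-9)
  expect_equal(edgeworth_density(x, mean, sd, 0, 0), dnorm(x, mean, sd))
})

test_that("generic Hermite coefficients reproduce the closed four-term form", {
  # for arbitrary (gamma1, gamma2), manufacture standardized raw moments with
  # those shape parameters and compare against the explicit formula
  set.seed(21)
  for (i in 1:8) {
    g1 <- runif(1, -1, 1); g2 <- runif(1, -1, 2)
    raw <- c(1, 0, 1, g1, g2 + 3)  # E[Z^3] = gamma1, E[Z^4] = gamma2 + 3
    x <- seq(-3, 3, length.out = 41)
    generic <- gc_density(x, 0, 1, raw, 4)
    closed <- dnorm(x) * (1 + g1 / 6 * hermite(3, x) + g2 / 24 * hermite(4, x))
    expect_equal(generic, closed, tolerance = 1e-12)
  }
})

test_that("Hermite corrections are mass-neutral (densities integrate to 1)", {
  cases <- list(
    list(fam = "weibull", par = list(shape = 1, scale = 1), K = 4),
    list(fam = "weibull", par = list(shape = 3, scale = 2), K = 5),
    list(fam = "normal", par = list(mean = 2.5, sd = 0.4), K = 3))
  for (cs in cases) {
    m <- catalog_moments(cs$fam, cs$par, max(cs$K, 4), interval(-40, 60),
                         rel_tol = 1e-12)
    mean <- m$values[2]; sd <- sqrt(m$values[3] - m$values[2]^2)
    mass <- integrate(function(x) gc_density(x, mean, sd, m, cs$K),
                      mean - 40 * sd, mean + 40 * sd, rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-7)
    if (cs$K == 4) {
      mu <- polydens:::central_from_raw(m$values, 4)
      gk <- skew_kurt(mu[3], mu[4], mu[5])
      em <- integrate(function(x)
        edgeworth_density(x, mean, sd, gk[1], gk[2]),
        mean - 40 * sd, mean + 40 * sd, rel.tol = 1e-10)$value
      expect_equal(em, 1, tolerance = 1e-7)
    }
  }
})

test_that("the exponential-like Weibull(1,1) expansion goes negative", {
  m <- catalog_moments("weibull", list(shape = 1, scale = 1), 4,
                       interval(0, 60), rel_tol = 1e-12)
  mean <- m$values[2]; sd <- sqrt(m$values[3] - m$values[2]^2)
  g <- seq(-1, 5, length.out = 2001)
  vals <- gc_density(g, mean, sd, m, 4)
  expect_lt(min(vals), 0)
})

test_that("location-scale equivariance holds exactly", {
  raw <- c(1, 0, 1, 0.5, 3.6)  # some standardized shape
  x <- seq(-2, 2, length.out = 21)
  base <- gc_density(x, 0, 1, raw, 4)
  # Y = a + bX: density of Y at a + b x is base(x)/b
  a <- 3; b <- 2
  rawY <- vapply(0:4, function(k) {
    j <- 0:k
    sum(choose(k, j) * a^(k - j) * b^j * raw[j + 1])
  }, numeric(1))
  shifted <- gc_density(a + b * x, a, b, rawY, 4)
  expect_equal(shifted, base / b, tolerance = 1e-12)
})

test_that("edgeworth adds the He6 term only through squared skewness", {
  x <- seq(-3, 3, length.out = 31)
  mv <- c(1, 0, 1, 0, 3.8)  # gamma1 = 0, gamma2 = 0.8
  expect_equal(edgeworth_density(x, 0, 1, 0, 0.8),
               gc_density(x, 0, 1, mv, 4), tolerance = 1e-12)
})

test_that("gc_expansion records standardization and coefficients", {
  set.seed(2)
  x <- rweibull(4000, 3, 2)
  ex <- gc_expansion(x, 4)
  expect_equal(ex$coefficients[1:3], c(1, 0, 0))
  expect_equal(ex$mean, mean(x), tolerance = 1e-12)
  expect_s3_class(ex, "gc_expansion")
  ed <- gc_expansion(x, variant = "edgeworth")
  expect_equal(length(ed$coefficients), 5)
  # evaluators produce finite curves
  g <- seq(0, 4, length.out = 50)
  expect_true(all(is.finite(ex$density(g))))
  expect_true(all(is.finite(ed$density(g))))
})
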