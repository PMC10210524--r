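test_that("Owen's T matches its defining integral across shapes", {
  hs <- seq(-8, 8, length.out = 33)
  for (a in c(0.25, 0.9, 1, 2.5, 6, 10, -3)) {
    expect_lt(max(abs(owens_t(hs, a) - owens_t_quadrature(hs, a))), 1e-12)
  }
  expect_equal(owens_t(c(-Inf, Inf), 2), c(0, 0))
})

test_that("alpha = 0 collapses to the normal distribution pointwise", {
  x <- seq(-6, 6, length.out = 1000)
  expect_lt(max(abs(dsn(x, 1, 2, 0) - dnorm(x, 1, 2))), 1e-12)
  expect_lt(max(abs(psn(x, 1, 2, 0) - pnorm(x, 1, 2))), 1e-12)
})

test_that("density has the stated pointwise values and integrates to 1", {
  # at the location the factor 2 * Phi(0) cancels, leaving phi(0)
  for (a in c(-3, 0, 2, 6)) expect_equal(dsn(0, 0, 1, a), dnorm(0))
  expect_equal(dsn(1.5, 0, 1, 0), dnorm(1.5))
  q <- integrate(function(x) dsn(x, 3, 1, 6), -10, 15, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-8)
  expect_error(dsn(NA, 0, 1, 1), "missing")
  expect_error(dsn(1, 0, -1, 1), "omega")
})

test_that("distribution function agrees with quadrature of the density", {
  cases <- expand.grid(x = c(-2, -0.5, 0, 0.7, 2.5),
                       alpha = c(-6, -1, 0.5, 1, 6))
  for (i in seq_len(nrow(cases))) {
    got <- psn(cases$x[i], 0, 1, cases$alpha[i])
    ref <- sn_cdf_quadrature(cases$x[i], 0, 1, cases$alpha[i])
    expect_equal(got, ref, tolerance = 1e-8)
  }
  # known closed value: half-normal folding at the location for alpha = 1
  expect_equal(psn(0, 0, 1, 1), 0.25, tolerance = 1e-12)
  expect_equal(psn(5, 5, 2, 0), 0.5)
  expect_equal(psn(Inf, 0, 1, 3), 1)
  expect_equal(psn(-Inf, 0, 1, 3), 0)
})

test_that("quantile function inverts the CDF", {
  p <- seq(0.01, 0.99, by = 0.01)
  for (a in c(-4, 0, 6)) {
    q <- qsn(p, 2, 1.5, a)
    expect_lt(max(abs(psn(q, 2, 1.5, a) - p)), 1e-8)
  }
})

test_that("moments match the closed forms and simulation", {
  m <- sn_moments(5, 2, 0)
  expect_equal(m$mean, 5)
  expect_equal(m$variance, 4)
  expect_equal(m$skewness, 0)

  m6 <- sn_moments(0, 1, sqrt(6))
  expect_equal(m6$delta, sqrt(6 / 7))
  expect_equal(m6$skewness, 0.56495, tolerance = 1e-3)
  x <- rsn(2e6, 0, 1, sqrt(6), seed = 11)
  expect_equal(mean(x), m6$mean, tolerance = 3e-3)
  expect_equal(mean((x - mean(x))^2), m6$variance, tolerance = 5e-3)
  expect_equal(sample_skewness(x), m6$skewness, tolerance = 0.01)

  # the skewness bound is the |alpha| -> Inf limit of the closed form
  expect_equal(sn_moments(0, 1, 1e8)$skewness, 0.99527, tolerance = 1e-4)
  expect_equal(sn_max_skewness(), 0.99527, tolerance = 1e-4)
})

test_that("moment matching inverts the moment map over a parameter grid", {
  for (alpha in c(-10, -4, -1, -0.2, 0, 0.3, 1, 5, 10)) {
    for (omega in c(0.5, 1, 2)) {
      m <- sn_moments(1.3, omega, alpha)
      fit <- sn_from_moments(m$mean, m$variance, m$skewness)
      back <- sn_moments(fit$xi, fit$omega, fit$alpha)
      expect_equal(back$mean, m$mean, tolerance = 1e-9)
      expect_equal(back$variance, m$variance, tolerance = 1e-9)
      expect_equal(back$skewness, m$skewness, tolerance = 1e-6)
      expect_false(fit$clamped)
    }
  }
})

test_that("near-boundary skewness is matched and the bound is clamped", {
  fit <- sn_from_moments(0, 1, 0.99)
  expect_false(fit$clamped)
  expect_gt(abs(fit$alpha), 20)
  m <- sn_moments(fit$xi, fit$omega, fit$alpha)
  expect_equal(m$skewness, 0.99, tolerance = 1e-6)
  # cross-check the root against a dense grid search over delta
  grid_d <- seq(0.5, 1 - 1e-9, length.out = 2e5)
  b <- sqrt(2 / pi)
  sk <- ((4 - pi) / 2) * (b * grid_d)^3 / (1 - (b * grid_d)^2)^1.5
  expect_equal(fit$delta, grid_d[which.min(abs(sk - 0.99))], tolerance = 1e-5)

  expect_warning(bad <- sn_from_moments(0, 1, 0.999), class = "snroc_feasibility")
  expect_true(bad$clamped)
  expect_error(sn_from_moments(0, -1, 0), "variance")
})

test_that("sampler is reproducible and distributionally correct", {
  expect_identical(rsn(100, 1, 2, 3, seed = 7), rsn(100, 1, 2, 3, seed = 7))
  x <- rsn(1e6, 0, 1, 0, seed = 5)
  expect_lt(abs(mean(x)), 4e-3)
  ks <- suppressWarnings(
    ks.test(rsn(1e5, 0, 1, 6, seed = 9), function(q) psn(q, 0, 1, 6)))
  expect_gt(ks$p.value, 1e-4)
})
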