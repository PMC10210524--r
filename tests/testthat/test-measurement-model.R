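test_that("cross-moment identification recovers the variance components", {
  # degenerate: no noise at all
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  mm <- moments_two_unbiased(x, x)
  expect_equal(mm$sigma2_u, 0)
  expect_equal(mm$sigma2_v, 0)
  expect_equal(mm$sigma2_x, mean((x - mean(x))^2))

  # hand-computable failure: anti-correlated pair has negative cross-moment
  expect_error(moments_two_unbiased(c(1, 2, 3), c(3, 2, 1)),
               "identification")
  expect_error(moments_two_unbiased(1:2, 1:2), "at least 3")

  # consistency at large n
  set.seed(101)
  x <- rnorm(1e5, 3, 1)
  mm <- moments_two_unbiased(x + rnorm(1e5), x + rnorm(1e5))
  expect_equal(mm$mu_x, 3, tolerance = 0.02)
  expect_equal(mm$sigma2_x, 1, tolerance = 0.02)
  expect_equal(mm$sigma2_u, 1, tolerance = 0.02)
  expect_equal(mm$sigma2_v, 1, tolerance = 0.02)
})

test_that("replicate within/between decomposition agrees with cross-moments", {
  x <- rnorm(50, 2)
  expect_equal(replicate_variance_components(x, x)$sigma2_u, 0)
  set.seed(7)
  x <- rnorm(1e5, 3, 1)
  W <- x + rnorm(1e5); M <- x + rnorm(1e5)
  rep_est <- replicate_variance_components(W, M)
  expect_equal(rep_est$sigma2_u, 1, tolerance = 0.02)
  expect_equal(rep_est$sigma2_x, 1, tolerance = 0.02)
  # two identification routes, one estimand
  cross_est <- moments_two_unbiased(W, M)
  expect_lt(abs(rep_est$sigma2_u - mean(c(cross_est$sigma2_u,
                                          cross_est$sigma2_v))), 0.05)
})

test_that("linear calibration identifies the assay slope and intercept", {
  set.seed(21)
  W <- rnorm(100, 3)
  cal <- linear_calibration(rep(0:1, 50), W, W)
  expect_equal(cal$alpha1, 1, tolerance = 1e-12)
  expect_equal(cal$alpha0, 0, tolerance = 1e-12)
  expect_error(linear_calibration(rep(1, 100), W, W), "0/1")

  # generative recovery under the biased-assay design
  set.seed(22)
  n <- 1e5
  y <- rep(c(0L, 1L), each = n / 2)
  x <- rnorm(n, 3 + log(3.2) * y, 1)
  W <- x + rnorm(n); M <- 0.2 + 0.8 * x + rnorm(n)
  cal <- linear_calibration(y, W, M)
  expect_lt(abs(cal$alpha1 - 0.8), 0.03)
  expect_lt(abs(cal$alpha0 - 0.2), 0.1)

  # rescaled series is an unbiased measure with inflated error variance
  Ms <- rescale_m(M, cal$alpha0, cal$alpha1)
  mm <- moments_two_unbiased(W[y == 0], Ms[y == 0])
  expect_equal(mm$sigma2_v, 1 / 0.8^2, tolerance = 0.1)
})

test_that("rescaling is the exact affine inverse", {
  expect_equal(rescale_m(c(1, 2), 0.2, 0.8), c(1.0, 2.25))
  expect_equal(rescale_m(c(-1, 5), 0, 1), c(-1, 5))
  expect_error(rescale_m(1:3, 0, 0), "nonzero")
})

test_that("optimal combination weight minimizes composite error variance", {
  expect_equal(optimal_weight(1, 1), 0.5)
  expect_equal(optimal_weight(0, 0), 0.5)
  g <- optimal_weight(0.04, 1)
  expect_equal(g, 0.9615, tolerance = 1e-4)
  expect_equal(g^2 * 0.04 + (1 - g)^2 * 1, 0.03846, tolerance = 1e-4)

  # brute-force grid oracle on simulated data
  set.seed(31)
  u <- rnorm(2e4, 0, sqrt(0.3)); v <- rnorm(2e4, 0, 1.2)
  gammas <- seq(0, 1, by = 0.01)
  evar <- vapply(gammas,
                 function(g) var(combine_assays(u, v, g)), 0)
  g_star <- optimal_weight(0.3, 1.2^2)
  expect_lt(abs(gammas[which.min(evar)] - g_star), 0.02)
  # composite error variance never exceeds the better single assay
  for (s2u in c(0.1, 1, 3)) for (s2v in c(0.2, 1, 5)) {
    g <- optimal_weight(s2u, s2v)
    expect_lte(g^2 * s2u + (1 - g)^2 * s2v, min(s2u, s2v) + 1e-12)
  }
})

test_that("moment estimators are consistent across repeated datasets", {
  set.seed(41)
  n <- 2000; reps <- 200
  est <- replicate(reps, {
    x <- rnorm(n, 3, 1)
    mm <- moments_two_unbiased(x + rnorm(n), x + rnorm(n))
    c(mm$mu_x, mm$sigma2_x, mm$sigma2_u, mm$sigma2_v)
  })
  means <- rowMeans(est)
  mcse <- apply(est, 1, sd) / sqrt(reps)
  truth <- c(3, 1, 1, 1)
  expect_true(all(abs(means - truth) < 2 * mcse + 1e-3))
})
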