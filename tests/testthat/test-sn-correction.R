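test_that("noiseless skew-normal samples give back their parameters", {
  w <- rsn(1e6, 0, 1, sqrt(6), seed = 51)
  fit <- fit_group_sn(w, 0)
  expect_equal(fit$xi, 0, tolerance = 0.01)
  expect_equal(fit$omega, 1, tolerance = 0.01)
  expect_equal(fit$alpha, sqrt(6), tolerance = 0.15)
  expect_false(fit$clamped)
})

test_that("error correction recovers the shape a naive fit attenuates", {
  # X standardized skew-normal (mean 3, variance 1), plus unit normal noise
  shape <- sqrt(6)
  mz <- sn_moments(0, 1, shape)
  s <- sqrt(mz$variance)
  x <- 3 + (rsn(1e6, 0, 1, shape, seed = 52) - mz$mean) / s
  w <- x + rnorm(1e6)
  corrected <- fit_group_sn(w, 1)
  expect_equal(corrected$alpha, shape, tolerance = 0.2)
  expect_equal(sn_moments(corrected$xi, corrected$omega,
                          corrected$alpha)$variance,
               mean((w - mean(w))^2) - 1, tolerance = 1e-9)
  # ignoring the error variance pulls the fitted shape toward symmetry
  naive <- fit_group_sn(w, 0)
  expect_lt(naive$alpha, corrected$alpha - 0.5)

  # normal data: fitted shape near 0
  wn <- rnorm(1e6, 3, 1)
  expect_lt(abs(fit_group_sn(wn, 0)$alpha), 0.15)

  expect_error(fit_group_sn(rnorm(100), 5), "identification")
})

test_that("fitted-group sensitivity/specificity follow the CDFs", {
  fit1 <- fit_group_sn(rnorm(5e4, 3 + log(3.2), 1), 0)
  fit0 <- fit_group_sn(rnorm(5e4, 3, 1), 0)
  expect_equal(sn_sensitivity(fit1, -50), 1)
  expect_equal(sn_specificity(fit0, -50), 0)
  c_mid <- 3 + log(3.2) / 2
  expect_equal(sn_sensitivity(fit1, c_mid), pnorm(log(3.2) / 2),
               tolerance = 0.02)
  expect_equal(sn_specificity(fit0, c_mid), pnorm(log(3.2) / 2),
               tolerance = 0.02)
})

test_that("ROC-derived AUC matches the direct probability integral", {
  fit0 <- fit_group_sn(rsn(2e5, 3, 1, 4, seed = 53), 0)
  fit1 <- fit_group_sn(rsn(2e5, 3.8, 1.2, -2, seed = 54), 0)
  roc <- sn_roc(fit0, fit1)
  expect_true(all(diff(roc$se) <= 1e-12))
  expect_true(all(diff(roc$sp) >= -1e-12))
  auc <- sn_auc(roc)
  direct <- integrate(function(x)
    dsn(x, fit0$xi, fit0$omega, fit0$alpha) *
      (1 - psn(x, fit1$xi, fit1$omega, fit1$alpha)),
    -15, 25, rel.tol = 1e-10)$value
  expect_equal(auc, direct, tolerance = 2e-4)
  # doubling the grid does not move the trapezoid materially
  expect_equal(sn_auc(sn_roc(fit0, fit1, 4001)), auc, tolerance = 1e-4)
  # identical groups are uninformative
  expect_equal(sn_auc(sn_roc(fit0, fit0)), 0.5, tolerance = 1e-4)
})

test_that("normal-limit AUC ties the SN estimator to the binormal theory", {
  fit0 <- fit_group_sn(rnorm(4e5, 3, 1), 0)
  fit1 <- fit_group_sn(rnorm(4e5, 3 + log(3.2), 1), 0)
  expect_equal(sn_auc(sn_roc(fit0, fit1)),
               binormal_auc(3, 3 + log(3.2), 1, 1), tolerance = 5e-3)
})

test_that("the full two-assay pipeline degenerates cleanly without noise", {
  set.seed(55)
  n <- 400
  y <- rep(0:1, each = n / 2)
  x <- 3 + log(3.2) * y + rsn(n, 0, 1, 3) / 2
  est <- sn_wm_estimate(y, x, x, cutoff = 3.5)
  direct0 <- fit_group_sn(x[y == 0], 0)
  expect_equal(est$fit0$xi, direct0$xi, tolerance = 1e-9)
  expect_equal(est$gamma, 0.5)
  expect_equal(est$sensitivity, sn_sensitivity(est$fit1, 3.5))
})

test_that("SN correction is nearly unbiased for AUC across families", {
  reps <- 100; n <- 2000
  for (family in c("normal", "skew_normal")) {
    sc <- scenario(family, n = n, sigma_u = 1, sigma_v = 1, seed = 60)
    tr <- scenario_truth(sc)
    set.seed(61)
    seeds <- sample.int(2^31 - 2, reps)
    aucs <- vapply(seeds, function(s) {
      d <- generate_data(sc, s)
      suppressWarnings(sn_wm_estimate(d$y, d$w, d$m, cutoff = tr$cutoff)$auc)
    }, 0)
    mcse <- sd(aucs) / sqrt(reps)
    expect_lt(abs(mean(aucs) - tr$auc), 2 * mcse + 2e-3)
  }
})
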