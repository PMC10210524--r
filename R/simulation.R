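# Synthetic case-control biomarker generator and the Monte-Carlo harness.
# Three biomarker families: normal, skew-normal (standardized to unit
# variance) and log-normal; additive normal assay errors; an optional
# linear calibration for the second assay. Defaults are the study
# conditions of the accompanying simulation design: n = 300, 50% disease
# rate, control mean 3 and SD 1, case mean shifted by ln(3.2).

.sn_families <- c("normal", "skew_normal", "log_normal")
.mean_shift <- log(3.2)

#' Simulation scenario
#'
#' Bundles a generative configuration: biomarker family, sample size,
#' disease rate, assay error SDs, the linear calibration of the second
#' assay, the skew-normal shape, replicate count and seeds.
#'
#' @param family `"normal"`, `"skew_normal"` or `"log_normal"`.
#' @param n total sample size (default 300).
#' @param disease_rate case fraction in (0, 1); exactly
#'   `ceiling(n * disease_rate)` cases are generated (no binomial jitter).
#' @param sigma_u,sigma_v error SDs of `W` and `M` (>= 0).
#' @param alpha0,alpha1 calibration of `M = alpha0 + alpha1 X + V`
#'   (default unbiased: 0, 1).
#' @param sn_shape shape of the skew-normal family (default 6).
#' @param reps Monte-Carlo replicates (default 500).
#' @param n_boot bootstrap resamples when the harness computes ASE/CP.
#' @param seed master seed.
#' @return an object of class `snroc_scenario`.
#' @examples
#' scenario("normal", sigma_u = 1, sigma_v = 1)
#' @export
scenario <- function(family = c("normal", "skew_normal", "log_normal"),
                     n = 300, disease_rate = 0.5, sigma_u = 1, sigma_v = 1,
                     alpha0 = 0, alpha1 = 1, sn_shape = 6,
                     reps = 500, n_boot = 200, seed = 1) {
  family <- match.arg(family)
  if (n < 4) stop("'n' must be at least 4", call. = FALSE)
  if (disease_rate <= 0 || disease_rate >= 1)
    stop("'disease_rate' must be in (0, 1)", call. = FALSE)
  if (sigma_u < 0 || sigma_v < 0)
    stop("error SDs must be >= 0", call. = FALSE)
  if (alpha1 == 0) stop("'alpha1' must be nonzero", call. = FALSE)
  structure(list(family = family, n = n, disease_rate = disease_rate,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 alpha0 = alpha0, alpha1 = alpha1, sn_shape = sn_shape,
                 reps = reps, n_boot = n_boot, seed = seed),
            class = "snroc_scenario")
}

#' @export
print.snroc_scenario <- function(x, ...) {
  cat(sprintf(
    "Simulation scenario: %s biomarkers\n  n = %d (disease rate %.2f), sigma_u = %.2f, sigma_v = %.2f\n  M calibration: (%.2f, %.2f); reps = %d, seed = %d\n",
    x$family, x$n, x$disease_rate, x$sigma_u, x$sigma_v,
    x$alpha0, x$alpha1, x$reps, x$seed))
  invisible(x)
}

#' Named scenario presets
#'
#' The five error configurations of the simulation study:
#' `T1` (`sigma_u = sigma_v = 0.71`), `T2` (`1.22`), `T3` (`1, 1`,
#' replicate-like research assays), `T4` (`0.2, 1`, clinical vs research
#' assay) and `T5` (`1, 1` with a linearly biased
#' `M = 0.2 + 0.8 X + V`).
#'
#' @param preset preset name, `"T1"` .. `"T5"`.
#' @param family biomarker family for the preset.
#' @param ... overrides passed to [scenario()].
#' @return an `snroc_scenario`.
#' @export
scenario_preset <- function(preset, family = "normal", ...) {
  cfg <- switch(preset,
    T1 = list(sigma_u = 0.71, sigma_v = 0.71),
    T2 = list(sigma_u = 1.22, sigma_v = 1.22),
    T3 = list(sigma_u = 1, sigma_v = 1),
    T4 = list(sigma_u = 0.2, sigma_v = 1),
    T5 = list(sigma_u = 1, sigma_v = 1, alpha0 = 0.2, alpha1 = 0.8),
    stop("unknown preset: ", preset, call. = FALSE))
  do.call(scenario, utils::modifyList(c(list(family = family), cfg),
                                      list(...)))
}

# standardized-to-(mean 3, SD 1) skew-normal parameters on the X scale:
# X = 3 + (Z - E Z)/sd(Z) for Z ~ SN(0, 1, shape)
.sn_family_params <- function(shape, mean_shift = 0) {
  mz <- sn_moments(0, 1, shape)
  s <- sqrt(mz$variance)
  list(xi = 3 + mean_shift - mz$mean / s, omega = 1 / s, alpha = shape)
}

#' Generate a synthetic case-control dataset
#'
#' Controls follow the family standardized to mean 3 and SD 1 (log-normal:
#' `exp(N(1, 0.3^2))`), cases the same family with the mean shifted by
#' `ln(3.2)` (log-normal: log-scale mean 1.5). Assay measures are
#' `W = X + U` and `M = alpha0 + alpha1 X + V` with independent normal
#' errors.
#'
#' @param sc an `snroc_scenario`.
#' @param seed optional integer seed for this dataset.
#' @return data.frame with columns `id`, `y`, `x`, `w`, `m` (controls
#'   first).
#' @export
generate_data <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "snroc_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n1 <- ceiling(sc$n * sc$disease_rate)
  n0 <- sc$n - n1
  d <- .mean_shift
  x <- switch(sc$family,
    normal = c(stats::rnorm(n0, 3, 1), stats::rnorm(n1, 3 + d, 1)),
    skew_normal = {
      p0 <- .sn_family_params(sc$sn_shape)
      c(rsn(n0, p0$xi, p0$omega, p0$alpha),
        rsn(n1, p0$xi + d, p0$omega, p0$alpha))
    },
    log_normal = c(exp(stats::rnorm(n0, 1, 0.3)),
                   exp(stats::rnorm(n1, 1.5, 0.3))))
  y <- rep(c(0L, 1L), c(n0, n1))
  w <- x + stats::rnorm(sc$n, 0, sc$sigma_u)
  m <- sc$alpha0 + sc$alpha1 * x + stats::rnorm(sc$n, 0, sc$sigma_v)
  data.frame(id = seq_len(sc$n), y = y, x = x, w = w, m = m)
}

#' Population truth for a scenario
#'
#' True AUC (closed form for the normal and log-normal families,
#' quadrature for the skew-normal), the population min-distance cutoff
#' found on a dense grid over the true distributions, and the true
#' sensitivity/specificity at that cutoff.
#'
#' @param sc an `snroc_scenario`.
#' @param n_grid grid size for the cutoff search.
#' @return list with `auc`, `cutoff`, `se`, `sp`, and the true group
#'   distribution/quantile functions `F0`, `F1`, `q0`, `q1`.
#' @export
scenario_truth <- function(sc, n_grid = 4001) {
  stopifnot(inherits(sc, "snroc_scenario"))
  d <- .mean_shift
  fam <- sc$family
  if (fam == "normal") {
    F0 <- function(x) stats::pnorm(x, 3, 1)
    F1 <- function(x) stats::pnorm(x, 3 + d, 1)
    q0 <- function(p) stats::qnorm(p, 3, 1)
    q1 <- function(p) stats::qnorm(p, 3 + d, 1)
    auc <- stats::pnorm(d / sqrt(2))
  } else if (fam == "skew_normal") {
    p0 <- .sn_family_params(sc$sn_shape)
    F0 <- function(x) psn(x, p0$xi, p0$omega, p0$alpha)
    F1 <- function(x) psn(x, p0$xi + d, p0$omega, p0$alpha)
    q0 <- function(p) qsn(p, p0$xi, p0$omega, p0$alpha)
    q1 <- function(p) qsn(p, p0$xi + d, p0$omega, p0$alpha)
    f0 <- function(x) dsn(x, p0$xi, p0$omega, p0$alpha)
    auc <- stats::integrate(function(x) f0(x) * (1 - F1(x)),
                            q0(1e-10) - 1, q1(1 - 1e-10) + 1,
                            rel.tol = 1e-10, subdivisions = 400L)$value
  } else {
    F0 <- function(x) stats::plnorm(x, 1, 0.3)
    F1 <- function(x) stats::plnorm(x, 1.5, 0.3)
    q0 <- function(p) stats::qlnorm(p, 1, 0.3)
    q1 <- function(p) stats::qlnorm(p, 1.5, 0.3)
    auc <- stats::pnorm(0.5 / (0.3 * sqrt(2)))
  }
  grid <- .quantile_hull_grid(q0, q1, n_points = n_grid)
  cutoff <- min_distance_cutoff(function(c) 1 - F1(c), F0, grid)
  list(auc = auc, cutoff = cutoff, se = 1 - F1(cutoff), sp = F0(cutoff),
       F0 = F0, F1 = F1, q0 = q0, q1 = q1)
}

#' Run the Monte-Carlo comparison of the accuracy estimators
#'
#' Replicates the simulation design: generates `reps` datasets from the
#' scenario, evaluates the requested estimators at the fixed
#' population-level min-distance cutoff (determined once from the true
#' biomarker distributions, not re-estimated per replicate), and reports
#' per estimator and measure the bias, the SD of the estimates across
#' replicates, and, when bootstrapping is enabled, the average bootstrap
#' standard error (ASE) and the 95% confidence-interval coverage (CP).
#'
#' @param sc an `snroc_scenario`; `sc$alpha0`/`sc$alpha1` decide whether
#'   the calibrated (`linear_m`) identification is used.
#' @param estimators subset of
#'   `c("naive_m", "cfa_w", "cfa_m", "cfa_wm", "sn_wm")`.
#' @param boot `FALSE` for the fast path (no ASE/CP), `TRUE` to bootstrap
#'   every replicate with `sc$n_boot` resamples.
#' @param reps,seed overrides of the scenario's replicate count and seed.
#' @param ci_method `"normal"` or `"percentile"` intervals for CP.
#' @return data.frame with columns `family`, `estimator`, `measure`,
#'   `truth`, `bias`, `sd`, `ase`, `cp`, `n_reps_used`.
#' @export
run_table <- function(sc, estimators = .estimator_names, boot = FALSE,
                      reps = sc$reps, seed = sc$seed,
                      ci_method = "normal") {
  stopifnot(inherits(sc, "snroc_scenario"))
  estimators <- match.arg(estimators, .estimator_names, several.ok = TRUE)
  tr <- scenario_truth(sc)
  truth <- c(auc = tr$auc, sensitivity = tr$se, specificity = tr$sp)
  model <- if (sc$alpha0 != 0 || sc$alpha1 != 1) "linear_m" else
    "unbiased_pair"
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, reps)
  measures <- c("auc", "sensitivity", "specificity")
  ests <- array(NA_real_, c(reps, length(estimators), 3),
                dimnames = list(NULL, estimators, measures))
  ases <- cover <- if (isTRUE(boot)) ests else NULL
  n_failed <- 0L
  for (r in seq_len(reps)) {
    dat <- generate_data(sc, rep_seeds[r])
    e <- tryCatch(
      suppressWarnings(estimate_accuracy(dat$y, dat$w, dat$m, model = model,
                                         cutoff = tr$cutoff,
                                         estimators = estimators)),
      error = function(err) NULL)
    if (is.null(e)) { n_failed <- n_failed + 1L; next }
    ests[r, , ] <- e
    if (isTRUE(boot)) {
      for (est in estimators) {
        bt <- tryCatch(bootstrap_accuracy(
          function(Y, W, M) estimate_accuracy(Y, W, M, model = model,
                                              cutoff = tr$cutoff,
                                              estimators = est,
                                              clip = TRUE)[1, ],
          dat$y, dat$w, dat$m, n_boot = sc$n_boot,
          seed = rep_seeds[r] %% 2147483L + 1L, method = ci_method),
          error = function(err) NULL)
        if (is.null(bt)) next
        ases[r, est, ] <- bt$se[measures]
        cover[r, est, ] <- as.numeric(bt$lower[measures] <= truth &
                                        truth <= bt$upper[measures])
      }
    }
  }
  out <- expand.grid(estimator = estimators, measure = measures,
                     stringsAsFactors = FALSE)
  out$family <- sc$family
  out$truth <- truth[out$measure]
  out$bias <- mapply(function(es, ms) mean(ests[, es, ms], na.rm = TRUE),
                     out$estimator, out$measure) - out$truth
  out$sd <- mapply(function(es, ms) stats::sd(ests[, es, ms], na.rm = TRUE),
                   out$estimator, out$measure)
  out$ase <- if (isTRUE(boot))
    mapply(function(es, ms) mean(ases[, es, ms], na.rm = TRUE),
           out$estimator, out$measure) else NA_real_
  out$cp <- if (isTRUE(boot))
    mapply(function(es, ms) mean(cover[, es, ms], na.rm = TRUE),
           out$estimator, out$measure) else NA_real_
  out$n_reps_used <- reps - n_failed
  out[, c("family", "estimator", "measure", "truth", "bias", "sd",
          "ase", "cp", "n_reps_used")]
}
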