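# Skew-normal biomarker correction: fit an error-corrected skew-normal
# distribution to each disease group and read corrected sensitivity,
# specificity, the ROC curve and the AUC off the fitted distributions.

#' Error-corrected skew-normal fit for one disease group
#'
#' Method-of-moments fit of a skew-normal distribution to the *true*
#' biomarker in one group, from its error-prone measures: the observed mean
#' and third central moment are unchanged by symmetric, independent
#' measurement error, while the observed variance overstates the biomarker
#' variance by `sigma2_u`. The estimating equations (mean, error-corrected
#' variance, standardized third moment) are solved in closed form through
#' the monotone delta-parameterization of [sn_from_moments()].
#'
#' @param w numeric sample of (possibly composite) assay measures for one
#'   group; at least 8 observations recommended for a stable third moment.
#' @param sigma2_u error variance of the measure (>= 0); must be less than
#'   the sample variance, else all observed variation would be noise.
#' @return an object of class `sn_group_fit`: list with `xi`, `omega`,
#'   `alpha`, `delta`, `sigma2_u`, `n`, `clamped` (boundary-skewness flag).
#' @examples
#' w <- rsn(2000, 3, 1, 4, seed = 1) + rnorm(2000, 0, 0.5)
#' fit_group_sn(w, 0.25)
#' @export
fit_group_sn <- function(w, sigma2_u) {
  if (!is.numeric(w) || anyNA(w) || length(w) < 3)
    stop("'w' must be a numeric sample (n >= 3) without missing values",
         call. = FALSE)
  if (!is.numeric(sigma2_u) || length(sigma2_u) != 1L || sigma2_u < 0)
    stop("'sigma2_u' must be a single number >= 0", call. = FALSE)
  n <- length(w)
  wbar <- mean(w)
  s2w <- mean((w - wbar)^2)
  s2x <- s2w - sigma2_u
  if (s2x <= 0)
    stop("identification failure: sample variance <= error variance",
         call. = FALSE)
  m3 <- mean((w - wbar)^3)
  fit <- sn_from_moments(wbar, s2x, m3 / s2x^1.5)
  structure(list(xi = fit$xi, omega = fit$omega, alpha = fit$alpha,
                 delta = fit$delta, sigma2_u = sigma2_u, n = n,
                 clamped = fit$clamped),
            class = "sn_group_fit")
}

#' @export
print.sn_group_fit <- function(x, ...) {
  cat(sprintf(
    "Skew-normal group fit (n = %d%s)\n  xi = %.4f, omega = %.4f, alpha = %.4f\n  error variance removed: %.4f\n",
    x$n, if (x$clamped) ", skewness clamped at the SN bound" else "",
    x$xi, x$omega, x$alpha, x$sigma2_u))
  invisible(x)
}

#' Sensitivity and specificity from fitted skew-normal groups
#'
#' `Se(c) = pr(X >= c | case) = 1 - F_1(c)` and
#' `Sp(c) = pr(X < c | control) = F_0(c)` under the fitted distributions.
#'
#' @param fit1,fit0 `sn_group_fit` objects for cases and controls.
#' @param cutoff numeric vector of cutoffs.
#' @return probabilities in `[0, 1]`.
#' @export
sn_sensitivity <- function(fit1, cutoff) {
  1 - psn(cutoff, fit1$xi, fit1$omega, fit1$alpha)
}

#' @rdname sn_sensitivity
#' @export
sn_specificity <- function(fit0, cutoff) {
  psn(cutoff, fit0$xi, fit0$omega, fit0$alpha)
}

#' ROC curve and AUC from fitted skew-normal groups
#'
#' Evaluates sensitivity and specificity on a cutoff grid spanning the
#' `1e-6 .. 1-1e-6` quantile hull of both fitted distributions; the AUC is
#' the trapezoidal integral of sensitivity against `1 - specificity`, with
#' the (0,0) and (1,1) endpoints appended.
#'
#' @param fit0,fit1 `sn_group_fit` objects for controls and cases.
#' @param grid_size number of cutoffs (>= 100; default 2001, at which the
#'   trapezoid has converged well past the fourth decimal).
#' @return `sn_roc()`: an object of class `sn_roc` with `cutoffs`, `se`,
#'   `sp`; `sn_auc()`: the AUC.
#' @export
sn_roc <- function(fit0, fit1, grid_size = 2001) {
  if (grid_size < 100) stop("'grid_size' must be >= 100", call. = FALSE)
  grid <- .quantile_hull_grid(
    function(p) qsn(p, fit0$xi, fit0$omega, fit0$alpha),
    function(p) qsn(p, fit1$xi, fit1$omega, fit1$alpha),
    n_points = grid_size)
  if (!all(is.finite(grid)) || grid[1] >= grid[length(grid)])
    stop("degenerate cutoff grid", call. = FALSE)
  structure(list(cutoffs = grid,
                 se = sn_sensitivity(fit1, grid),
                 sp = sn_specificity(fit0, grid)),
            class = "sn_roc")
}

#' @rdname sn_roc
#' @param roc an `sn_roc` object.
#' @export
sn_auc <- function(roc) {
  fpr <- 1 - roc$sp
  ord <- order(fpr)
  x <- c(0, fpr[ord], 1)
  y <- c(0, roc$se[ord], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Skew-normal biomarker correction estimator (SN-WM)
#'
#' Full pipeline for corrected accuracy from two assay measures: identifies
#' the error variances per group ([moments_two_unbiased()];
#' calibrated and rescaled first under the `linear_m` model, pooled error
#' variances where that model requires them), forms the variance-optimal
#' composite measure, fits an error-corrected skew-normal distribution per
#' disease group, and derives sensitivity/specificity at the cutoff and the
#' AUC from the fitted ROC curve.
#'
#' @param Y binary 0/1 disease indicator.
#' @param W unbiased assay measure (`X + U`).
#' @param M second assay measure (`X + V`, or `alpha0 + alpha1 X + V` under
#'   `model = "linear_m"`).
#' @param model `"unbiased_pair"` (per-group identification),
#'   `"replicates"` (common error variance) or `"linear_m"` (calibrated,
#'   pooled error variances).
#' @param cutoff classification cutoff; if `NULL`, chosen by `cutoff_rule`
#'   on the fitted distributions.
#' @param cutoff_rule `"min_distance"` or `"youden"`, applied to the fitted
#'   skew-normal Se/Sp when `cutoff` is not supplied.
#' @param use_m if `FALSE`, fit from `W` alone with its own error variance
#'   instead of the optimal composite.
#' @param grid_size cutoff grid size for the fitted ROC.
#' @return list with `auc`, `sensitivity`, `specificity`, `cutoff`,
#'   `gamma`, `fit0`, `fit1`, `components` (the per-group identification).
#' @export
sn_wm_estimate <- function(Y, W, M,
                           model = c("unbiased_pair", "replicates", "linear_m"),
                           cutoff = NULL, cutoff_rule = "min_distance",
                           use_m = TRUE, grid_size = 2001) {
  model <- match.arg(model)
  id <- identify_components(Y, W, M, model)
  g0 <- Y == 0; g1 <- Y == 1
  if (use_m) {
    fit0 <- fit_group_sn(id$composite[g0], id$sigma2_c0)
    fit1 <- fit_group_sn(id$composite[g1], id$sigma2_c1)
  } else {
    fit0 <- fit_group_sn(W[g0], id$moments0$sigma2_u)
    fit1 <- fit_group_sn(W[g1], id$moments1$sigma2_u)
  }
  roc <- sn_roc(fit0, fit1, grid_size)
  if (is.null(cutoff)) {
    se_fn <- function(c) sn_sensitivity(fit1, c)
    sp_fn <- function(c) sn_specificity(fit0, c)
    cutoff <- switch(cutoff_rule,
                     min_distance = min_distance_cutoff(se_fn, sp_fn, roc$cutoffs),
                     youden = youden_cutoff(se_fn, sp_fn, roc$cutoffs),
                     stop("unknown cutoff rule: ", cutoff_rule, call. = FALSE))
  }
  list(auc = sn_auc(roc),
       sensitivity = sn_sensitivity(fit1, cutoff),
       specificity = sn_specificity(fit0, cutoff),
       cutoff = cutoff, gamma = id$gamma, fit0 = fit0, fit1 = fit1,
       components = id)
}

#' Identify error structure and optimal composite from two assay measures
#'
#' Shared identification step behind the corrected estimators: per-group
#' moment identification, calibration/rescaling of a linearly biased `M`,
#' the optimal combination weight, the composite series and its per-group
#' error variances.
#'
#' Under `"unbiased_pair"` the variance components are identified within
#' each disease group separately; under `"linear_m"` the calibration
#' requires equal error variances across groups, so the error variances are
#' pooled (n-weighted) after per-group estimation; `"replicates"` uses the
#' within/between decomposition with a common error variance.
#'
#' @inheritParams sn_wm_estimate
#' @return list with `moments0`, `moments1` (per-group components),
#'   `calibration`, `m_star`, `gamma`, `composite`, `sigma2_c0`,
#'   `sigma2_c1` (composite error variances).
#' @export
identify_components <- function(Y, W, M,
                                model = c("unbiased_pair", "replicates",
                                          "linear_m")) {
  model <- match.arg(model)
  if (!all(Y %in% c(0, 1)) || !any(Y == 0) || !any(Y == 1))
    stop("'Y' must be 0/1 with both groups nonempty", call. = FALSE)
  if (length(Y) != length(W) || length(Y) != length(M))
    stop("'Y', 'W', 'M' must have equal length", call. = FALSE)
  g0 <- Y == 0; g1 <- Y == 1
  cal <- list(alpha0 = 0, alpha1 = 1)
  if (model == "linear_m") {
    cal <- linear_calibration(Y, W, M)
    m_star <- rescale_m(M, cal$alpha0, cal$alpha1)
  } else {
    m_star <- M
  }
  est <- if (model == "replicates") replicate_variance_components else
    moments_two_unbiased
  mom0 <- est(W[g0], m_star[g0])
  mom1 <- est(W[g1], m_star[g1])
  n0 <- mom0$n; n1 <- mom1$n
  if (model == "linear_m") {
    # equal-error-variance assumption of the calibrated model: pool
    s2u <- (n0 * mom0$sigma2_u + n1 * mom1$sigma2_u) / (n0 + n1)
    s2v <- (n0 * mom0$sigma2_v + n1 * mom1$sigma2_v) / (n0 + n1)
    mom0$sigma2_u <- mom1$sigma2_u <- s2u
    mom0$sigma2_v <- mom1$sigma2_v <- s2v
  }
  s2u_p <- (n0 * mom0$sigma2_u + n1 * mom1$sigma2_u) / (n0 + n1)
  s2v_p <- (n0 * mom0$sigma2_v + n1 * mom1$sigma2_v) / (n0 + n1)
  gamma <- optimal_weight(s2u_p, s2v_p)
  list(moments0 = mom0, moments1 = mom1, calibration = cal, m_star = m_star,
       gamma = gamma, composite = combine_assays(W, m_star, gamma),
       sigma2_c0 = gamma^2 * mom0$sigma2_u + (1 - gamma)^2 * mom0$sigma2_v,
       sigma2_c1 = gamma^2 * mom1$sigma2_u + (1 - gamma)^2 * mom1$sigma2_v)
}
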