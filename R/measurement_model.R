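# Identification of the measurement-error structure from two assay measures
# W = X + U and M = alpha0 + alpha1 X + V (U, V, X mutually independent).
# All moments use the population (divisor-n) convention of the plug-in
# moment estimators; the n vs n-1 difference is O(1/n).

.var_n <- function(x) mean((x - mean(x))^2)
.cov_n <- function(x, y) mean(x * y) - mean(x) * mean(y)

.new_group_moments <- function(mu_x, sigma2_x, sigma2_u, sigma2_v,
                               third_central, n) {
  list(mu_x = mu_x, sigma2_x = sigma2_x, sigma2_u = sigma2_u,
       sigma2_v = sigma2_v, third_central = third_central, n = n)
}

.clamp_nonneg <- function(v, label) {
  if (v < 0) {
    # rounding dust near 0 is clamped silently; a materially negative
    # estimate means "no detectable assay noise" and is worth a warning
    if (v < -1e-8)
      warning(sprintf("negative %s estimate (%.4g) clamped to 0", label, v),
              call. = FALSE)
    return(0)
  }
  v
}

#' Moment identification from two unbiased assay measures
#'
#' For paired unbiased measures `W = X + U`, `M = X + V` of the same
#' biomarker, the cross-moment identifies the true-biomarker variance:
#' `mean(W*M) - mean((W+M)/2)^2` converges to `sigma_x^2`, so the error
#' variances follow by subtraction from `var(W)` and `var(M)`. The third
#' central moment of `W` (equal to that of `X` when the errors are
#' symmetric) is returned for skew-normal fitting.
#'
#' Negative error-variance estimates are clamped to 0 with a warning (no
#' detectable assay noise); a nonpositive `sigma_x^2` estimate means the
#' paired measures carry no common signal and is an error.
#'
#' @param W,M equal-length paired numeric samples, `n >= 3`.
#' @return a list (group moments) with `mu_x`, `sigma2_x`, `sigma2_u`,
#'   `sigma2_v`, `third_central`, `n`.
#' @examples
#' x <- rnorm(500, 3); moments_two_unbiased(x + rnorm(500), x + rnorm(500))
#' @export
moments_two_unbiased <- function(W, M) {
  if (length(W) != length(M))
    stop("'W' and 'M' must have equal length", call. = FALSE)
  n <- length(W)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(W) || anyNA(M)) stop("missing values not allowed", call. = FALSE)
  mu <- mean((W + M) / 2)
  s2x <- mean(W * M) - mu^2
  if (s2x <= 0)
    stop("identification failure: cross-moment variance estimate <= 0",
         call. = FALSE)
  s2u <- .clamp_nonneg(mean((W - mu)^2) - s2x, "sigma_u^2")
  s2v <- .clamp_nonneg(mean((M - mu)^2) - s2x, "sigma_v^2")
  .new_group_moments(mu, s2x, s2u, s2v, mean((W - mu)^3), n)
}

#' Variance components from replicate assay measures
#'
#' For a replicate design (`W` and `M` are two measures with a common error
#' variance), the classical within/between decomposition: the within-pair
#' mean square `mean((W - M)^2)/2` estimates `sigma_u^2`, and the variance
#' of the pair means minus its error share estimates `sigma_x^2`.
#'
#' @inheritParams moments_two_unbiased
#' @return group moments as in [moments_two_unbiased()] (with
#'   `sigma2_v = sigma2_u`).
#' @export
replicate_variance_components <- function(W, M) {
  if (length(W) != length(M))
    stop("'W' and 'M' must have equal length", call. = FALSE)
  n <- length(W)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  s2u <- mean((W - M)^2) / 2
  avg <- (W + M) / 2
  s2x <- .var_n(avg) - s2u / 2
  if (s2x <= 0)
    stop("identification failure: between-pair variance <= error share",
         call. = FALSE)
  mu <- mean(avg)
  .new_group_moments(mu, s2x, s2u, s2u, mean((W - mu)^3), n)
}

#' Calibration of a linearly biased assay
#'
#' When `M = alpha0 + alpha1 X + V` is a biased linear measure while
#' `W = X + U` is unbiased, the slope is identified through the disease
#' indicator: `alpha1 = cov(Y, M)/cov(Y, W)` and
#' `alpha0 = mean(M - alpha1 W)`. Requires equal error variances across the
#' disease groups (the caller asserts this design assumption).
#'
#' @param Y binary 0/1 disease indicator; both groups must be nonempty.
#' @param W,M assay measures, same length as `Y`.
#' @return list with `alpha0`, `alpha1`.
#' @export
linear_calibration <- function(Y, W, M) {
  if (length(unique(stats::na.omit(Y))) < 2 || !all(Y %in% c(0, 1)))
    stop("'Y' must be 0/1 with both groups nonempty", call. = FALSE)
  if (length(Y) != length(W) || length(Y) != length(M))
    stop("'Y', 'W', 'M' must have equal length", call. = FALSE)
  cyw <- .cov_n(Y, W)
  tol <- 1e-10 * max(sqrt(.var_n(W)), 1e-300)
  if (abs(cyw) < tol)
    stop("identification failure: W carries no signal for Y (cov(Y, W) ~ 0)",
         call. = FALSE)
  alpha1 <- .cov_n(Y, M) / cyw
  list(alpha0 = mean(M - alpha1 * W), alpha1 = alpha1)
}

#' Rescale a linearly biased assay to the biomarker scale
#'
#' `M* = (M - alpha0)/alpha1` is again an unbiased measure of `X`, with
#' error variance `sigma_v^2 / alpha1^2`.
#'
#' @param M numeric sample.
#' @param alpha0 intercept.
#' @param alpha1 slope, nonzero.
#' @return rescaled sample of the same length.
#' @export
rescale_m <- function(M, alpha0, alpha1) {
  if (!is.numeric(alpha1) || length(alpha1) != 1L || alpha1 == 0 ||
      !is.finite(alpha1))
    stop("'alpha1' must be a single nonzero finite number", call. = FALSE)
  (M - alpha0) / alpha1
}

#' Optimal combination weight for two noisy measures
#'
#' The variance-minimizing weight for the composite `gamma*W +
#' (1-gamma)*M*` of two unbiased measures is
#' `gamma = sigma_v^2/(sigma_u^2 + sigma_v^2)` (inverse-variance
#' weighting); the composite error variance is
#' `sigma_u^2 sigma_v^2/(sigma_u^2 + sigma_v^2)`, never exceeding the
#' smaller of the two. With both variances zero any weight is equivalent
#' and 0.5 is returned.
#'
#' @param sigma2_u,sigma2_v error variances (>= 0).
#' @return weight in `[0, 1]`.
#' @examples
#' optimal_weight(0.04, 1) # clinical vs research assay: ~ 0.96
#' @export
optimal_weight <- function(sigma2_u, sigma2_v) {
  if (sigma2_u < 0 || sigma2_v < 0)
    stop("error variances must be >= 0", call. = FALSE)
  if (sigma2_u + sigma2_v == 0) return(0.5)
  sigma2_v / (sigma2_u + sigma2_v)
}

#' @rdname optimal_weight
#' @param W,M_star unbiased measures on the biomarker scale.
#' @param gamma combination weight in `[0, 1]`.
#' @return `combine_assays()`: the composite sample.
#' @export
combine_assays <- function(W, M_star, gamma) {
  if (gamma < 0 || gamma > 1) stop("'gamma' must be in [0, 1]", call. = FALSE)
  gamma * W + (1 - gamma) * M_star
}
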