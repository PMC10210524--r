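# Binormal accuracy theory and probit-scale correction for attenuation.
# lambda^2 = sigma_u^2 / sigma_x^2 is the intra- vs inter-individual variance
# ratio; the de-attenuation rescales the probit of an observed accuracy
# measure by sqrt(1 + lambda^2).

.clip01 <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)

.check_prob_open <- function(p, name, clip = FALSE) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (clip) return(.clip01(p))
  if (p <= 0 || p >= 1)
    stop(sprintf("'%s' must lie strictly in (0, 1)", name), call. = FALSE)
  p
}

#' Binormal AUC
#'
#' AUC of a biomarker whose case and control distributions are normal:
#' \eqn{\Phi\{(\mu_1-\mu_0)/\sqrt{\sigma_{x0}^2+\sigma_{x1}^2}\}}. With
#' `with_error = TRUE` the (attenuated) AUC of the error-prone measure is
#' returned, adding the error variances inside the root.
#'
#' @param mu0,mu1 group means (controls, cases). By convention larger values
#'   indicate disease; `mu1 < mu0` triggers an orientation warning.
#' @param sigma_x0,sigma_x1 true-biomarker SDs (> 0).
#' @param sigma_u0,sigma_u1 measurement-error SDs (>= 0).
#' @param with_error include the error variances (AUC of W rather than X)?
#' @return AUC in `[0, 1]`.
#' @examples
#' binormal_auc(3, 3 + log(3.2), 1, 1) # ~ 0.795
#' @export
binormal_auc <- function(mu0, mu1, sigma_x0, sigma_x1,
                         sigma_u0 = 0, sigma_u1 = 0, with_error = FALSE) {
  if (sigma_x0 <= 0 || sigma_x1 <= 0)
    stop("biomarker SDs must be > 0", call. = FALSE)
  if (sigma_u0 < 0 || sigma_u1 < 0)
    stop("error SDs must be >= 0", call. = FALSE)
  if (mu1 < mu0)
    warning("mu1 < mu0: marker oriented with larger values in controls")
  v <- sigma_x0^2 + sigma_x1^2
  if (with_error) v <- v + sigma_u0^2 + sigma_u1^2
  if (v <= 0) stop("total variance must be positive", call. = FALSE)
  stats::pnorm((mu1 - mu0) / sqrt(v))
}

#' Correction for attenuation of an AUC
#'
#' De-attenuates an AUC observed on an error-prone assay:
#' \eqn{A_x = \Phi\{\Phi^{-1}(A_w)\sqrt{1+\lambda^2}\}}. Pass the pooled
#' ratio \eqn{\lambda^2} under equal group variances, or the Reiser ratio
#' \eqn{\lambda^{*2}} when group variances differ.
#'
#' @param auc_w observed AUC, strictly in (0, 1).
#' @param ratio intra/inter variance ratio (>= 0).
#' @param clip clip `auc_w` into `[1e-10, 1-1e-10]` instead of rejecting
#'   boundary values; used inside bootstrap resampling, where an empirical
#'   resample can hit 0 or 1.
#' @return corrected AUC.
#' @examples
#' correct_auc(0.75, 1) # ~ 0.83
#' @export
correct_auc <- function(auc_w, ratio, clip = FALSE) {
  auc_w <- .check_prob_open(auc_w, "auc_w", clip)
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) || ratio < 0)
    stop("'ratio' must be a single finite number >= 0", call. = FALSE)
  stats::pnorm(stats::qnorm(auc_w) * sqrt(1 + ratio))
}

#' Correction for attenuation of sensitivity and specificity
#'
#' Approximate de-attenuation at a fixed cutoff:
#' \eqn{Se_x \approx 1-\Phi\{\Phi^{-1}(1-Se_w)\sqrt{1+\lambda_1^2}\}} and
#' \eqn{Sp_x \approx \Phi\{\Phi^{-1}(Sp_w)\sqrt{1+\lambda_0^2}\}}, with the
#' group-specific ratios \eqn{\lambda_g^2 = \sigma_{u,g}^2/\sigma_{x,g}^2}.
#' The approximation is exact in the large-sample limit.
#'
#' @param se_w,sp_w observed sensitivity / specificity, strictly in (0, 1).
#' @param lambda2_1,lambda2_0 case / control variance ratio (>= 0).
#' @inheritParams correct_auc
#' @return corrected probability in (0, 1).
#' @export
correct_sensitivity <- function(se_w, lambda2_1, clip = FALSE) {
  se_w <- .check_prob_open(se_w, "se_w", clip)
  if (lambda2_1 < 0) stop("'lambda2_1' must be >= 0", call. = FALSE)
  1 - stats::pnorm(stats::qnorm(1 - se_w) * sqrt(1 + lambda2_1))
}

#' @rdname correct_sensitivity
#' @export
correct_specificity <- function(sp_w, lambda2_0, clip = FALSE) {
  sp_w <- .check_prob_open(sp_w, "sp_w", clip)
  if (lambda2_0 < 0) stop("'lambda2_0' must be >= 0", call. = FALSE)
  stats::pnorm(stats::qnorm(sp_w) * sqrt(1 + lambda2_0))
}

#' Intra/inter variance ratios from per-group moment estimates
#'
#' From per-group variance components (e.g. [moments_two_unbiased()] applied
#' within controls and cases) forms the pooled ratio `lambda2`, the Reiser
#' unequal-variance ratio `lambda2_star =
#' (sigma_u0^2 + sigma_u1^2)/(sigma_x0^2 + sigma_x1^2)`, and the
#' group-specific ratios `lambda2_0`, `lambda2_1` used for specificity and
#' sensitivity.
#'
#' @param moments0,moments1 lists with components `sigma2_x`, `sigma2_u`,
#'   `n` for controls and cases.
#' @return list with `lambda2`, `lambda2_star`, `lambda2_0`, `lambda2_1`.
#' @export
noise_ratios <- function(moments0, moments1) {
  s2x0 <- moments0$sigma2_x; s2x1 <- moments1$sigma2_x
  s2u0 <- moments0$sigma2_u; s2u1 <- moments1$sigma2_u
  if (is.null(s2x0) || is.null(s2x1) || s2x0 <= 0 || s2x1 <= 0)
    stop("nonpositive or missing biomarker variance estimate", call. = FALSE)
  if (s2u0 < 0 || s2u1 < 0)
    stop("error variance estimates must be >= 0", call. = FALSE)
  n0 <- if (is.null(moments0$n)) 1 else moments0$n
  n1 <- if (is.null(moments1$n)) 1 else moments1$n
  pooled_u <- (n0 * s2u0 + n1 * s2u1) / (n0 + n1)
  pooled_x <- (n0 * s2x0 + n1 * s2x1) / (n0 + n1)
  list(lambda2 = pooled_u / pooled_x,
       lambda2_star = (s2u0 + s2u1) / (s2x0 + s2x1),
       lambda2_0 = s2u0 / s2x0,
       lambda2_1 = s2u1 / s2x1)
}
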