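# The five accuracy estimators compared throughout: naive (uncorrected)
# use of the research-grade series M, correction-for-attenuation applied to
# W, to M, and to their optimal composite, and the skew-normal correction
# estimator. All share one identification pass over the (W, M) pair.

.estimator_names <- c("naive_m", "cfa_w", "cfa_m", "cfa_wm", "sn_wm")

#' Compute all accuracy estimators on one dataset
#'
#' Evaluates a chosen subset of the five estimators at a fixed cutoff:
#' * `naive_m`: empirical AUC/Se/Sp of the raw `M` series, no correction;
#' * `cfa_w`, `cfa_m`: probit de-attenuation of the empirical accuracy of
#'   the single series, using the Reiser ratio for AUC and the
#'   group-specific ratios for Se/Sp (for `cfa_m` under `model =
#'   "linear_m"`, the calibrated `M*` series);
#' * `cfa_wm`: the same corrections applied to the variance-optimal
#'   composite of `W` and `M*`;
#' * `sn_wm`: the skew-normal correction estimator ([sn_wm_estimate()]).
#'
#' @inheritParams sn_wm_estimate
#' @param cutoff fixed classification cutoff (biomarker scale).
#' @param estimators subset of
#'   `c("naive_m", "cfa_w", "cfa_m", "cfa_wm", "sn_wm")`.
#' @param clip clip empirical probabilities away from 0/1 before the probit
#'   corrections (used inside bootstrap resampling).
#' @return numeric matrix, rows = estimators, columns
#'   `auc`, `sensitivity`, `specificity`.
#' @export
estimate_accuracy <- function(Y, W, M, model = "unbiased_pair", cutoff,
                              estimators = .estimator_names, clip = FALSE) {
  estimators <- match.arg(estimators, .estimator_names, several.ok = TRUE)
  out <- matrix(NA_real_, length(estimators), 3,
                dimnames = list(estimators,
                                c("auc", "sensitivity", "specificity")))
  g0 <- Y == 0; g1 <- Y == 1
  need_id <- any(estimators != "naive_m")
  id <- if (need_id) identify_components(Y, W, M, model) else NULL

  emp <- function(series) c(
    auc = empirical_auc(series[g1], series[g0]),
    sensitivity = empirical_sensitivity(series[g1], cutoff),
    specificity = empirical_specificity(series[g0], cutoff))

  cfa <- function(series, s2u0, s2u1) {
    e <- emp(series)
    lam <- noise_ratios(
      list(sigma2_x = id$moments0$sigma2_x, sigma2_u = s2u0, n = id$moments0$n),
      list(sigma2_x = id$moments1$sigma2_x, sigma2_u = s2u1, n = id$moments1$n))
    c(auc = correct_auc(e[["auc"]], lam$lambda2_star, clip = clip),
      sensitivity = correct_sensitivity(e[["sensitivity"]], lam$lambda2_1,
                                        clip = clip),
      specificity = correct_specificity(e[["specificity"]], lam$lambda2_0,
                                        clip = clip))
  }

  for (est in estimators) {
    out[est, ] <- switch(est,
      naive_m = emp(M),
      cfa_w = cfa(W, id$moments0$sigma2_u, id$moments1$sigma2_u),
      cfa_m = cfa(id$m_star, id$moments0$sigma2_v, id$moments1$sigma2_v),
      cfa_wm = cfa(id$composite, id$sigma2_c0, id$sigma2_c1),
      sn_wm = {
        r <- sn_wm_estimate(Y, W, M, model = model, cutoff = cutoff)
        c(auc = r$auc, sensitivity = r$sensitivity,
          specificity = r$specificity)
      })
  }
  out
}
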