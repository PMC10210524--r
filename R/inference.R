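# Stratified bootstrap standard errors, confidence intervals and coverage
# bookkeeping. Cases and controls are resampled separately so every
# resample preserves n0 and n1, and the full pipeline (including the
# error-variance identification) is recomputed per resample.

#' Stratified bootstrap for accuracy estimators
#'
#' Resamples cases and controls with replacement (separately, preserving
#' both group sizes), recomputes `estimator` on each resample, and returns
#' standard errors and confidence intervals for every component of the
#' estimate. Per-resample seeds are derived deterministically from `seed`,
#' so runs are reproducible. Resamples on which the estimator fails (e.g. a
#' boundary identification failure) are skipped and counted; more than 20%
#' failures aborts.
#'
#' @param estimator `function(Y, W, M)` returning a named numeric vector
#'   (or list) of probability-scale estimates, e.g. `auc`, `sensitivity`,
#'   `specificity`.
#' @param Y binary 0/1 disease indicator.
#' @param W,M assay measures (`M` may be `NULL` for single-assay
#'   estimators; it is then passed through as `NULL`).
#' @param n_boot number of bootstrap resamples (>= 50 recommended for SE
#'   use; default 200).
#' @param seed optional integer master seed.
#' @param ci_level confidence level (default 0.95).
#' @param method `"normal"` (estimate +/- z * SE, truncated to `[0, 1]`) or
#'   `"percentile"`.
#' @return list with `estimate`, `se`, `lower`, `upper` (named numeric
#'   vectors), `n_boot`, `n_failed`, `method`, and the resample draws in
#'   `draws`.
#' @export
bootstrap_accuracy <- function(estimator, Y, W, M = NULL, n_boot = 200,
                               seed = NULL, ci_level = 0.95,
                               method = c("normal", "percentile")) {
  method <- match.arg(method)
  if (ci_level <= 0 || ci_level >= 1)
    stop("'ci_level' must be in (0, 1)", call. = FALSE)
  if (!any(Y == 0) || !any(Y == 1))
    stop("both disease groups must be nonempty", call. = FALSE)
  est <- unlist(estimator(Y, W, M))
  if (is.null(names(est)) || anyNA(est))
    stop("'estimator' must return a complete named numeric result",
         call. = FALSE)
  idx0 <- which(Y == 0); idx1 <- which(Y == 1)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_boot)
  draws <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(sub_seeds[b])
    i <- c(sample(idx0, replace = TRUE), sample(idx1, replace = TRUE))
    r <- tryCatch(
      suppressWarnings(unlist(estimator(Y[i], W[i], if (is.null(M)) NULL else M[i]))),
      error = function(e) NULL)
    if (is.null(r) || anyNA(r)) n_failed <- n_failed + 1L
    else draws[b, ] <- r[names(est)]
  }
  if (n_failed > 0.2 * n_boot)
    stop(sprintf("bootstrap failed on %d of %d resamples", n_failed, n_boot),
         call. = FALSE)
  se <- apply(draws, 2, stats::sd, na.rm = TRUE)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (method == "normal") {
    lower <- pmax(est - z * se, 0)
    upper <- pmin(est + z * se, 1)
  } else {
    qs <- apply(draws, 2, stats::quantile,
                probs = c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                na.rm = TRUE)
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  list(estimate = est, se = se, lower = lower, upper = upper,
       n_boot = n_boot, n_failed = n_failed, method = method, draws = draws)
}

#' Confidence-interval coverage
#'
#' Fraction of intervals containing the true value.
#'
#' @param true_value the target quantity.
#' @param lower,upper equal-length vectors of interval bounds.
#' @return proportion in `[0, 1]`.
#' @export
coverage <- function(true_value, lower, upper) {
  if (length(lower) != length(upper) || length(lower) < 1)
    stop("'lower' and 'upper' must be nonempty and of equal length",
         call. = FALSE)
  mean(lower <= true_value & true_value <= upper, na.rm = TRUE)
}
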