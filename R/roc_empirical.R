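# Naive (uncorrected) empirical accuracy measures and cutoff-selection
# rules. A subject is classified diseased when the marker is >= the cutoff.

#' Empirical AUC (Mann-Whitney)
#'
#' Rank-based estimate of `pr(case > control)` with half weight for ties;
#' identical to exhaustive pair enumeration.
#'
#' @param cases,controls nonempty numeric samples.
#' @return AUC in `[0, 1]`.
#' @examples
#' empirical_auc(c(3, 1, 4), c(2, 2))
#' @export
empirical_auc <- function(cases, controls) {
  n1 <- length(cases); n0 <- length(controls)
  if (n1 < 1 || n0 < 1) stop("both groups must be nonempty", call. = FALSE)
  if (anyNA(cases) || anyNA(controls))
    stop("missing values not allowed", call. = FALSE)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Empirical sensitivity and specificity at a cutoff
#'
#' Proportion of cases at or above / controls below the cutoff.
#'
#' @param cases,controls numeric samples.
#' @param cutoff classification threshold.
#' @return probability in `[0, 1]`.
#' @export
empirical_sensitivity <- function(cases, cutoff) mean(cases >= cutoff)

#' @rdname empirical_sensitivity
#' @export
empirical_specificity <- function(controls, cutoff) mean(controls < cutoff)

#' Cutoff-selection rules
#'
#' Three rules for choosing the operating cutoff from sensitivity and
#' specificity functions evaluated on a grid:
#' * `min_distance_cutoff()`: the ROC point closest to the perfect-test
#'   corner, minimizing `(1-Se)^2 + (1-Sp)^2`;
#' * `youden_cutoff()`: maximizes the Youden index `Se + Sp - 1`;
#' * `constrained_specificity_cutoff()`: maximizes specificity subject to
#'   `Se >= min_se`.
#' Ties are broken by the smallest cutoff.
#'
#' @param se_fn,sp_fn vectorized functions cutoff -> sensitivity /
#'   specificity.
#' @param grid numeric vector of candidate cutoffs (sorted internally).
#' @return the selected cutoff (a grid member).
#' @export
min_distance_cutoff <- function(se_fn, sp_fn, grid) {
  grid <- sort(grid)
  d2 <- (1 - se_fn(grid))^2 + (1 - sp_fn(grid))^2
  grid[which.min(d2)]
}

#' @rdname min_distance_cutoff
#' @export
youden_cutoff <- function(se_fn, sp_fn, grid) {
  grid <- sort(grid)
  j <- se_fn(grid) + sp_fn(grid) - 1
  grid[which.max(j)]
}

#' @rdname min_distance_cutoff
#' @param min_se minimum admissible sensitivity, in `(0, 1)` (0 allowed for
#'   the unconstrained max-specificity endpoint).
#' @export
constrained_specificity_cutoff <- function(se_fn, sp_fn, grid, min_se) {
  if (min_se < 0 || min_se > 1)
    stop("'min_se' must be in [0, 1]", call. = FALSE)
  grid <- sort(grid)
  se <- se_fn(grid)
  ok <- se >= min_se
  if (!any(ok))
    stop("no cutoff attains the required sensitivity", call. = FALSE)
  sp <- sp_fn(grid[ok])
  grid[ok][which.max(sp)]
}

#' Kernel density bandwidth for assay distributions
#'
#' The rule `factor * sd(x) * n^(-1/3)` with `factor` 2 (narrow) or 4
#' (wide), used to display assay densities.
#'
#' @param x numeric sample, `n >= 2`.
#' @param factor bandwidth multiplier, typically 2 or 4.
#' @return bandwidth (0, with a warning, for a degenerate constant sample).
#' @export
kde_bandwidth <- function(x, factor = 2) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) warning("degenerate sample: zero bandwidth")
  factor * s * n^(-1 / 3)
}

# grid spanning the 1e-6 .. 1-1e-6 quantile hull of two distributions
.quantile_hull_grid <- function(qf0, qf1, n_points = 4001, eps = 1e-6) {
  lo <- min(qf0(eps), qf1(eps))
  hi <- max(qf0(1 - eps), qf1(1 - eps))
  seq(lo, hi, length.out = n_points)
}
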