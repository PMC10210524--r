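# Skew-normal distribution with location xi, scale omega > 0 and shape alpha.
# Density: (2/omega) * phi(z) * Phi(alpha * z), z = (x - xi)/omega.
# delta = alpha / sqrt(1 + alpha^2) is the reparameterization in which the
# first three moments are monotone, which is what makes moment matching
# well-posed (a unique delta root instead of possibly multiple alpha roots).

.sn_b <- sqrt(2 / pi)

.sn_env <- new.env(parent = emptyenv())

# 96-node Gauss-Legendre rule on [0, 1], cached per session
.gl01 <- function() {
  if (is.null(.sn_env$gl)) .sn_env$gl <- pracma::gaussLegendre(96, 0, 1)
  .sn_env$gl
}

.check_sn_params <- function(xi, omega, alpha) {
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi))
    stop("'xi' must be a single finite number", call. = FALSE)
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega <= 0)
    stop("'omega' must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("'alpha' must be a single finite number", call. = FALSE)
  invisible(NULL)
}

#' Owen's T function
#'
#' Computes \eqn{T(h, a) = (2\pi)^{-1} \int_0^a e^{-h^2(1+x^2)/2}/(1+x^2)\,dx},
#' used for the skew-normal distribution function. Vectorized over `h`;
#' `a` must be a scalar. Arguments with \eqn{|a| > 1} are reduced to
#' \eqn{|a| \le 1} through the standard reflection identity before Gauss-Legendre
#' quadrature, keeping the integrand well resolved at 96 nodes.
#'
#' @param h numeric vector.
#' @param a single finite number.
#' @return numeric vector of the same length as `h`.
#' @examples
#' owens_t(0.5, 1)
#' @export
owens_t <- function(h, a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("'a' must be a single finite number", call. = FALSE)
  if (!is.numeric(h) || anyNA(h))
    stop("'h' must be numeric without missing values", call. = FALSE)
  if (a == 0) return(rep(0, length(h)))
  if (a < 0) return(-owens_t(h, -a))
  if (a > 1) {
    # T(h,a) = (Phi(h) + Phi(ah))/2 - Phi(h)Phi(ah) - T(ah, 1/a)
    ah <- a * h
    return(0.5 * (stats::pnorm(h) + stats::pnorm(ah)) -
             stats::pnorm(h) * stats::pnorm(ah) - owens_t(ah, 1 / a))
  }
  gl <- .gl01()
  x <- a * gl$x
  w <- a * gl$w
  ex <- exp(-0.5 * outer(h^2, 1 + x^2))
  ex[!is.finite(h), ] <- 0 # h = +/-Inf: integrand is identically 0
  drop(ex %*% (w / (1 + x^2))) / (2 * pi)
}

#' Skew-normal density
#'
#' @param x numeric vector of quantiles (finite).
#' @param xi location parameter.
#' @param omega scale parameter (> 0).
#' @param alpha shape parameter; `alpha = 0` gives the normal density.
#' @param log if `TRUE`, returns the log density.
#' @return numeric vector of densities.
#' @examples
#' dsn(0, 0, 1, 5)
#' @export
dsn <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  .check_sn_params(xi, omega, alpha)
  if (!is.numeric(x) || anyNA(x))
    stop("'x' must be numeric without missing values", call. = FALSE)
  z <- (x - xi) / omega
  logd <- base::log(2 / omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(alpha * z, log.p = TRUE)
  if (log) logd else exp(logd)
}

#' Skew-normal distribution function
#'
#' Evaluated through Owen's T function:
#' \eqn{F(x) = \Phi(z) - 2 T(z, \alpha)} with \eqn{z = (x-\xi)/\omega}.
#'
#' @inheritParams dsn
#' @param q numeric vector of quantiles; `-Inf`/`Inf` allowed.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' psn(0, 0, 1, 1)
#' @export
psn <- function(q, xi = 0, omega = 1, alpha = 0) {
  .check_sn_params(xi, omega, alpha)
  if (!is.numeric(q) || anyNA(q))
    stop("'q' must be numeric without missing values", call. = FALSE)
  z <- (q - xi) / omega
  p <- stats::pnorm(z) - 2 * owens_t(z, alpha)
  pmin(pmax(p, 0), 1)
}

#' Skew-normal quantile function
#'
#' Inverts [psn()] by bracketed root-finding; the bracket is expanded from
#' `xi +/- 10 omega` until it encloses the target probability.
#'
#' @inheritParams dsn
#' @param p numeric vector of probabilities in `(0, 1)`.
#' @return numeric vector of quantiles.
#' @export
qsn <- function(p, xi = 0, omega = 1, alpha = 0) {
  .check_sn_params(xi, omega, alpha)
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("'p' must be numeric in (0, 1)", call. = FALSE)
  vapply(p, function(pp) {
    lo <- xi - 10 * omega
    hi <- xi + 10 * omega
    while (psn(lo, xi, omega, alpha) > pp) lo <- lo - 5 * omega
    while (psn(hi, xi, omega, alpha) < pp) hi <- hi + 5 * omega
    stats::uniroot(function(x) psn(x, xi, omega, alpha) - pp,
                   lower = lo, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}

#' Skew-normal random draws
#'
#' Samples via the convolution representation
#' \eqn{Z = \delta |N_1| + \sqrt{1-\delta^2} N_2} with independent standard
#' normals, then \eqn{X = \xi + \omega Z}; exact in distribution and fast.
#'
#' @inheritParams dsn
#' @param n number of draws.
#' @param seed optional integer; if given, `set.seed(seed)` is called first
#'   so the draw is reproducible.
#' @return numeric vector of length `n`.
#' @export
rsn <- function(n, xi = 0, omega = 1, alpha = 0, seed = NULL) {
  .check_sn_params(xi, omega, alpha)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  delta <- alpha / sqrt(1 + alpha^2)
  z <- delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
  xi + omega * z
}

#' Largest attainable skew-normal skewness
#'
#' The third standardized moment of a skew-normal variate is bounded; the
#' supremum (as `|alpha| ->` infinity, `|delta| -> 1`) is about 0.99527.
#' Moment matching is infeasible at or beyond this bound.
#'
#' @return a single number, the supremum of `|skewness|`.
#' @export
sn_max_skewness <- function() {
  b <- .sn_b
  ((4 - pi) / 2) * b^3 / (1 - b^2)^1.5
}

# third standardized moment as a function of delta in [0, 1)
.sn_skew_of_delta <- function(delta) {
  m <- .sn_b * delta
  v <- 1 - m^2
  ((4 - pi) / 2) * m^3 / v^1.5
}

#' Skew-normal moments
#'
#' Mean, variance and skewness of the skew-normal distribution, from the
#' moment generating function: with \eqn{\delta = \alpha/\sqrt{1+\alpha^2}},
#' \eqn{E(Z) = \delta\sqrt{2/\pi}}, \eqn{var(Z) = 1 - 2\delta^2/\pi}, and
#' skewness \eqn{\{(4-\pi)/2\}\{\delta\sqrt{2/\pi}\}^3 / var(Z)^{3/2}}.
#'
#' @inheritParams dsn
#' @return a list with components `mean`, `variance`, `skewness`, `delta`.
#' @examples
#' sn_moments(0, 1, sqrt(6))
#' @export
sn_moments <- function(xi = 0, omega = 1, alpha = 0) {
  .check_sn_params(xi, omega, alpha)
  delta <- alpha / sqrt(1 + alpha^2)
  m <- .sn_b * delta
  list(mean = xi + omega * m,
       variance = omega^2 * (1 - m^2),
       skewness = .sn_skew_of_delta(delta),
       delta = delta)
}

#' Skew-normal parameters from moments
#'
#' Inverts [sn_moments()]: solves the scalar skewness equation for `|delta|`
#' by bracketed root-finding on `(0, 1)` (the map is strictly increasing, so
#' the root is unique), then recovers `omega` from the variance and `xi`
#' from the mean.
#'
#' Skewness beyond the skew-normal bound (about 0.99527 in absolute value,
#' [sn_max_skewness()]) cannot be matched; the fit is then clamped at
#' `delta = +/-(1 - 1e-6)` with a warning (class `snroc_feasibility`) and
#' flagged via `clamped`, so that downstream resampling never aborts on a
#' boundary sample.
#'
#' @param mean target mean.
#' @param variance target variance (> 0).
#' @param skewness target third standardized moment.
#' @return a list with components `xi`, `omega`, `alpha`, `delta`, `clamped`.
#' @examples
#' sn_from_moments(3, 1, 0.5)
#' @export
sn_from_moments <- function(mean, variance, skewness) {
  if (!is.numeric(variance) || length(variance) != 1L ||
      !is.finite(variance) || variance <= 0)
    stop("'variance' must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("'mean' must be a single finite number", call. = FALSE)
  if (!is.numeric(skewness) || length(skewness) != 1L || !is.finite(skewness))
    stop("'skewness' must be a single finite number", call. = FALSE)
  smax <- sn_max_skewness()
  clamped <- FALSE
  g <- abs(skewness)
  if (g >= smax - 1e-6) {
    delta <- 1 - 1e-6
    clamped <- TRUE
    warning(structure(class = c("snroc_feasibility", "warning", "condition"),
                      list(message = sprintf(
                        "skewness %.5f at/beyond the skew-normal bound %.5f; clamping delta",
                        skewness, smax),
                        call = sys.call())))
  } else if (g < 1e-14) {
    delta <- 0
  } else {
    delta <- stats::uniroot(function(d) .sn_skew_of_delta(d) - g,
                            lower = 0, upper = 1 - 1e-9, tol = 1e-14)$root
  }
  delta <- sign(skewness) * delta
  m <- .sn_b * delta
  omega <- sqrt(variance / (1 - m^2))
  xi <- mean - omega * m
  alpha <- delta / sqrt(1 - delta^2)
  list(xi = xi, omega = omega, alpha = alpha, delta = delta, clamped = clamped)
}
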