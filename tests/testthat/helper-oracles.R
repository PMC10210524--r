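# Independent oracles used across the suite; these deliberately avoid the
# package's own code paths.

# all-pairs Mann-Whitney AUC with half-weight ties
brute_force_auc <- function(cases, controls) {
  s <- 0
  for (x1 in cases) for (x0 in controls)
    s <- s + (x1 > x0) + 0.5 * (x1 == x0)
  s / (length(cases) * length(controls))
}

# sample third standardized moment (divisor n)
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# skew-normal CDF by adaptive quadrature of the density written out directly
sn_cdf_quadrature <- function(x, xi, omega, alpha) {
  dens <- function(t) {
    z <- (t - xi) / omega
    (2 / omega) * dnorm(z) * pnorm(alpha * z)
  }
  integrate(dens, -Inf, x, rel.tol = 1e-12)$value
}

# Owen's T by adaptive quadrature of its defining integral
owens_t_quadrature <- function(h, a) {
  sapply(h, function(hh)
    integrate(function(x) exp(-hh^2 * (1 + x^2) / 2) / (1 + x^2),
              0, a, rel.tol = 1e-13)$value / (2 * pi))
}
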