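# Independent quadrature / finite-difference oracles used across tests.

# brute-force quadrature of integrand over the real line
quad <- function(f, lower = -Inf, upper = Inf, rel.tol = 1e-11) {
  stats::integrate(f, lower, upper, rel.tol = rel.tol, abs.tol = 1e-13)$value
}

# central finite-difference derivatives of g(theta) (scalar-valued)
fd_grad <- function(g, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    e <- replace(numeric(length(theta)), i, h)
    (g(theta + e) - g(theta - e)) / (2 * h)
  }, numeric(1))
}

# N(0,1) and contaminated fixtures
std_normal <- function(x) stats::dnorm(x)

# fixed clean sample used by several estimator tests
clean20 <- function() {
  set.seed(404)
  stats::rnorm(20, 0, 0.15)
}
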