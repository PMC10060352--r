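# Shared helpers: independent oracles and random-input generators.

# brute-force radius oracle: adaptive quadrature of 3 * int gamma^3 R^2 dR
oracle_radius <- function(gamma_fun, R) {
  vapply(R, function(Ri) {
    if (Ri == 0) return(0)
    (3 * stats::integrate(function(x) gamma_fun(x)^3 * x^2, 0, Ri,
                          rel.tol = 1e-12)$value)^(1 / 3)
  }, 0)
}

# random valid dimensionless parameter set
random_dimensionless <- function() {
  dimensionless_params(chat = stats::runif(1, 0.05, 0.95),
                       kappa_mu = stats::runif(1, 0, 5),
                       sigmahat_mu = -stats::runif(1, 0.1, 100),
                       beta = stats::runif(1, 0.5, 8),
                       B_over_L = stats::runif(1, 0.2, 2))
}

# a mildly inhomogeneous test state on [0, 1]
quadratic_gamma_state <- function(n = 400) {
  grid <- spheroid_grid(1, n = n, grading = "uniform")
  spheroid_state(grid, gamma = 1 + grid$R^2)
}
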