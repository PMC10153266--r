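# Independent oracles used across the suite.

# squared contrast by direct numerical quadrature of the triangular-kernel
# variance integral, sigma^2/I^2 = 2 beta / T * int_0^T (1 - tau/T)
# [rho g1 + (1 - rho)]^2 dtau, with g1 the field autocorrelation
quadrature_k2 <- function(x, beta, rho, g1) {
  f <- function(s) (1 - s / x) * (rho * g1(s) + (1 - rho))^2
  (2 * beta / x) * integrate(f, 0, x, rel.tol = 1e-12,
                             subdivisions = 2000L)$value
}

g1_ordered <- function(s) exp(-s)
g1_unordered <- function(s) exp(-sqrt(s))

# finite difference of K^2 over ln T
fd_dk2_dlnT <- function(T, beta, rho, tau_c, d_mu, h = 1e-4) {
  (k2_mixed(T * exp(h), beta, rho, tau_c, d_mu) -
     k2_mixed(T * exp(-h), beta, rho, tau_c, d_mu)) / (2 * h)
}

# exact boundary ratios from the forward models (beta cancels)
exact_ratio_zero <- function(x, rho, d_mu) {
  dk2_dlnT(x, 1, rho, 1, d_mu) / (1 - k2_mixed(x, 1, rho, 1, d_mu))
}
exact_ratio_inf <- function(x, rho, d_mu) {
  dk2_dlnT(x, 1, rho, 1, d_mu) /
    (k2_mixed(x, 1, rho, 1, d_mu) - (1 - rho)^2)
}

# small clean simulation for pipeline tests
tiny_sim <- function(inv_tau_c = 10^seq(2, 4, length.out = 5),
                     rho = c(0.7, 0.9), d_mu = 0, noise = 0, seed = 1L,
                     exposures = exposure_set("logspaced", n = 15)) {
  simulate_curves(
    simulation_grid(inv_tau_c = inv_tau_c, rho = rho, d_mu = d_mu,
                    noise_fraction = noise, seed = seed),
    exposures)
}
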