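#' Specify a simulation benchmark grid
#'
#' Defines the ground-truth parameter grid of the simulation study: every
#' combination of inverse correlation time and dynamic scattering fraction
#' becomes one pixel of a synthetic contrast stack (rows = `inv_tau_c`,
#' columns = `rho`). Defaults reproduce the benchmark conditions:
#' \eqn{1/\tau_c} log-spaced over \eqn{[10^0, 10^5]} s\eqn{^{-1}} (101
#' values), \eqn{\rho} over \eqn{[0.5, 1]} (26 values), \eqn{\beta = 1},
#' pure-model data (`d_mu` 0 or 1), and optional multiplicative uniform
#' noise of a stated fraction of the true value.
#'
#' @param inv_tau_c Inverse correlation times, 1/s.
#' @param rho Dynamic scattering fractions.
#' @param beta Normalization (scalar).
#' @param d_mu Scattering-model weight (scalar: 0 vessel, 1 parenchyma, or
#'   intermediate for mixed-model data).
#' @param noise_fraction Half-width of the uniform multiplicative noise as a
#'   fraction of the true \eqn{K^2} (0 = clean, 0.05 = +/-5%); must be < 1.
#' @param seed Integer RNG seed used when noise is applied.
#' @return An object of class `"simulation_grid"`.
#' @export
simulation_grid <- function(inv_tau_c = 10^seq(0, 5, length.out = 101),
                            rho = seq(0.5, 1, length.out = 26),
                            beta = 1, d_mu = 0, noise_fraction = 0,
                            seed = 1L) {
  if (any(inv_tau_c <= 0)) stop("`inv_tau_c` must be > 0", call. = FALSE)
  if (any(rho < 0) || any(rho > 1)) stop("`rho` must lie in [0, 1]",
                                         call. = FALSE)
  if (noise_fraction < 0 || noise_fraction >= 1) {
    stop("`noise_fraction` must lie in [0, 1)", call. = FALSE)
  }
  validate_params(beta, rho, 1 / inv_tau_c, d_mu)
  structure(list(inv_tau_c = inv_tau_c, rho = rho, beta = beta, d_mu = d_mu,
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "simulation_grid")
}

# K^2 curves for arbitrary per-pixel parameter vectors; optional noise
simulate_k2_matrix <- function(times, beta, rho, tau_c, d_mu,
                               noise_fraction = 0, seed = 1L) {
  n_exp <- length(times)
  n_pix <- length(tau_c)
  k2 <- matrix(0, n_exp, n_pix)
  for (e in seq_len(n_exp)) {
    k2[e, ] <- k2_mixed(times[e], beta, rho, tau_c, d_mu)
  }
  if (noise_fraction > 0) {
    k2 <- withr::with_seed(seed, {
      k2 * (1 + matrix(stats::runif(n_exp * n_pix, -noise_fraction,
                                    noise_fraction), n_exp, n_pix))
    })
  }
  k2
}

#' Simulate multi-exposure contrast curves with known ground truth
#'
#' Evaluates the mixed forward model on every (inverse correlation time,
#' rho) pixel of a [simulation_grid()] at the given exposure ladder, applies
#' multiplicative uniform noise \eqn{K^2 (1 + U(-f, f))} when requested, and
#' returns the stack together with the ground-truth parameter table. With
#' `noise_fraction = 0` the curves equal the forward model exactly; with the
#' same seed the noisy stack is bit-reproducible.
#'
#' @param grid A [simulation_grid()].
#' @param exposures An [exposure_set()].
#' @return A list with components `stack` (a [contrast_stack()], rows
#'   indexing `inv_tau_c`, columns `rho`) and `truth` (tibble: `row`, `col`,
#'   `inv_tau_c`, `rho`, `beta`, `d_mu`, `tau_c`).
#' @export
simulate_curves <- function(grid, exposures) {
  stopifnot(inherits(grid, "simulation_grid"))
  exposures <- if (inherits(exposures, "exposure_set")) exposures
               else as_exposure_set(exposures)
  truth <- tidyr::expand_grid(col = seq_along(grid$rho),
                              row = seq_along(grid$inv_tau_c))
  truth <- tibble::tibble(
    row = truth$row, col = truth$col,
    inv_tau_c = grid$inv_tau_c[truth$row],
    rho = grid$rho[truth$col],
    beta = grid$beta, d_mu = grid$d_mu
  )
  truth$tau_c <- 1 / truth$inv_tau_c
  k2 <- simulate_k2_matrix(as.numeric(exposures), truth$beta, truth$rho,
                           truth$tau_c, truth$d_mu,
                           grid$noise_fraction, grid$seed)
  stack <- matrix_to_stack(k2, c(length(grid$inv_tau_c), length(grid$rho)),
                           exposures)
  list(stack = stack, truth = truth)
}

#' Build a spatial test phantom
#'
#' Constructs per-pixel parameter maps emulating a cortical field of view for
#' testing the spatially regularized estimator: a smooth low-spatial-
#' frequency \eqn{\beta} field (broad 2-D Gaussian bump, relative variation
#' <= 30%), vertical vessel stripes (`d_mu = 0`, higher flow) on a
#' parenchymal background (`d_mu = 1`), and piecewise-constant \eqn{\rho}
#' and \eqn{\tau_c} by region.
#'
#' @param height,width Phantom dimensions in pixels.
#' @param beta_base,beta_amplitude Background level and bump height of the
#'   smooth normalization field.
#' @param vessel_frac Approximate fraction of columns covered by vessels.
#' @param rho_vessel,rho_parenchyma Dynamic scattering fraction by region.
#' @param inv_tau_vessel,inv_tau_parenchyma Inverse correlation time (1/s)
#'   by region.
#' @return An object of class `"spatial_phantom"`: a list of H x W maps
#'   (`beta`, `rho`, `tau_c`, `d_mu`) plus a `layout` description.
#' @export
make_phantom <- function(height = 48, width = 48, beta_base = 0.85,
                         beta_amplitude = 0.15, vessel_frac = 0.2,
                         rho_vessel = 0.95, rho_parenchyma = 0.8,
                         inv_tau_vessel = 2000, inv_tau_parenchyma = 300) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  sig <- 0.6 * min(height, width)
  beta <- beta_base + beta_amplitude *
    exp(-((rr - height / 2)^2 + (cc - width / 2)^2) / (2 * sig^2))
  n_stripes <- max(1L, round(vessel_frac * width / 4))
  stripe_centers <- round(seq(0.2, 0.8, length.out = n_stripes) * width)
  vessel <- matrix(FALSE, height, width)
  for (s in stripe_centers) {
    cols <- pmax(1L, pmin(width, (s - 1L):(s + 1L)))
    vessel[, cols] <- TRUE
  }
  d_mu <- ifelse(vessel, 0, 1)
  rho <- ifelse(vessel, rho_vessel, rho_parenchyma)
  tau_c <- ifelse(vessel, 1 / inv_tau_vessel, 1 / inv_tau_parenchyma)
  structure(list(beta = beta, rho = rho, tau_c = tau_c, d_mu = d_mu,
                 layout = list(vessel = vessel,
                               stripe_centers = stripe_centers)),
            class = "spatial_phantom")
}

#' Simulate a contrast stack from a spatial phantom
#'
#' Evaluates the mixed forward model at each phantom pixel and applies
#' multiplicative uniform noise, mirroring [simulate_curves()] for spatial
#' maps.
#'
#' @param phantom A [make_phantom()] object.
#' @param exposures An [exposure_set()].
#' @param noise_fraction Uniform noise half-width (fraction of true value).
#' @param seed Integer RNG seed.
#' @return A list with `stack` (a [contrast_stack()]) and `truth` (tibble
#'   of per-pixel parameters).
#' @export
simulate_phantom <- function(phantom, exposures, noise_fraction = 0,
                             seed = 1L) {
  stopifnot(inherits(phantom, "spatial_phantom"))
  exposures <- if (inherits(exposures, "exposure_set")) exposures
               else as_exposure_set(exposures)
  d <- dim(phantom$beta)
  truth <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    beta = as.vector(phantom$beta), rho = as.vector(phantom$rho),
    tau_c = as.vector(phantom$tau_c), d_mu = as.vector(phantom$d_mu)
  )
  truth$inv_tau_c <- 1 / truth$tau_c
  k2 <- simulate_k2_matrix(as.numeric(exposures), truth$beta, truth$rho,
                           truth$tau_c, truth$d_mu, noise_fraction, seed)
  list(stack = matrix_to_stack(k2, d, exposures), truth = truth)
}
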