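# The quasi-analytic estimator.
#
# Instead of iterating a nonlinear fit per pixel, the estimator solves the
# model parameters in a fixed order from the shape of K^2 vs ln(T):
#   1. smooth the per-pixel contrast curves along the exposure axis,
#   2. take the semilogarithmic derivative dK^2/dln(T),
#   3. locate the derivative minimum T_peak by quadratic interpolation,
#   4. extrapolate the short-/long-exposure limits through the boundary
#      ratios (first pass with d_mu = 0) to get beta and rho,
#   5. assign the scattering model d_mu by comparing the measured peak
#      amplitude with the theoretical peaks of both pure models,
#   6. (sREMI) spatially smooth the beta map and re-assign d_mu,
#   7. re-extrapolate the limits with the final d_mu, compute the critical
#      contrast K^2(T = tau_c), and read tau_c off the curve by linear
#      interpolation in log-exposure.
# All stages operate on whole exposure-by-pixel matrices; per-pixel failures
# set flags, never abort the frame.

STATIC_DERIV_EPS <- 1e-6

# --- stage 1: pre-filter ---------------------------------------------------

# convolve columns of an (n_exp x n_pix) matrix with a short kernel,
# replicate-padding the ends
filter_replicate <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- nrow(m)
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  p <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * p[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# nonuniform weighted moving average: weights inversely proportional to
# ln-T distance within a window of +/- `half_window_decades`
filter_nonuniform <- function(m, ln_t, half_window_decades) {
  n <- nrow(m)
  half_w <- half_window_decades * log(10)
  spacing <- diff(ln_t)
  h <- stats::median(spacing) / 2 # distance regularizer for the center point
  out <- matrix(0, n, ncol(m))
  for (i in seq_len(n)) {
    d <- abs(ln_t - ln_t[i])
    in_win <- d <= half_w
    w <- 1 / (d[in_win] + h)
    w <- w / sum(w)
    out[i, ] <- crossprod(w, m[in_win, , drop = FALSE])
  }
  out
}

#' Pre-filter a contrast stack along the exposure axis
#'
#' Smooths each pixel's \eqn{K^2(T)} curve before differentiation. For
#' log-uniform ladders a 1:4:1 weighted moving average is convolved along
#' the exposure axis (replicate padding at the ends); for irregular ladders
#' a weighted nonuniform moving average is used, with weights inversely
#' proportional to \eqn{\ln T} distance inside a +/- 1/3-decade window.
#'
#' @param stack A [contrast_stack()] with >= 5 exposures.
#' @return A filtered [contrast_stack()].
#' @export
prefilter <- function(stack) {
  stopifnot(inherits(stack, "contrast_stack"))
  times <- as.numeric(stack$exposures)
  if (length(times) < 5) stop("need at least 5 exposures", call. = FALSE)
  m <- stack_matrix(stack)
  f <- if (exposure_spacing(stack$exposures) == "log_uniform") {
    filter_replicate(m, c(1, 4, 1) / 6)
  } else {
    filter_nonuniform(m, log(times), 1 / 3)
  }
  matrix_to_stack(f, dim(stack$k2)[2:3], stack$exposures)
}

# --- stage 2: semilog derivative -------------------------------------------

#' Semilogarithmic derivative of a (filtered) contrast stack
#'
#' Takes the central difference of \eqn{K^2} over intervals of \eqn{\ln T}
#' (one sample per adjacent exposure pair, positioned at the interval
#' midpoint in \eqn{\ln T}), smooths the derivative a second time (3-point
#' moving average for log-uniform ladders; a 1-decade-wide weighted moving
#' average for irregular ladders), and resamples \eqn{K^2} onto the same
#' midpoint positions by linear interpolation in \eqn{\ln T}.
#'
#' @param stack A (typically [prefilter()]ed) [contrast_stack()].
#' @return An object of class `"derivative_curve"`: list with `ln_t`
#'   (midpoint positions), `t` (seconds), `dk2` and `k2` matrices
#'   (`n_midpoints x n_pixels`), and the source geometry.
#' @export
semilog_derivative <- function(stack) {
  stopifnot(inherits(stack, "contrast_stack"))
  times <- as.numeric(stack$exposures)
  ln_t <- log(times)
  m <- stack_matrix(stack)
  n <- length(times)
  d_raw <- (m[-1, , drop = FALSE] - m[-n, , drop = FALSE]) / diff(ln_t)
  ln_mid <- (ln_t[-1] + ln_t[-n]) / 2
  dk2 <- if (exposure_spacing(stack$exposures) == "log_uniform") {
    filter_replicate(d_raw, c(1, 1, 1) / 3)
  } else {
    filter_nonuniform(d_raw, ln_mid, 0.5)
  }
  # midpoints in ln T are equidistant from both nodes, so linear
  # interpolation in ln T is the two-point average
  k2_mid <- (m[-1, , drop = FALSE] + m[-n, , drop = FALSE]) / 2
  structure(list(ln_t = ln_mid, t = exp(ln_mid), dk2 = dk2, k2 = k2_mid,
                 dims = dim(stack$k2)[2:3], exposures = stack$exposures),
            class = "derivative_curve")
}

# --- stage 3: peak location ------------------------------------------------

#' Locate the derivative peak per pixel
#'
#' Finds the most negative sample of \eqn{dK^2/d\ln T} for every pixel and
#' refines it with the quadratic through that sample and its two neighbours
#' (Newton form), taking the parabola's vertex as \eqn{\ln T_{peak}}; the
#' amplitude is the parabola evaluated at the vertex, increased by 5% to
#' compensate the attenuation of the moving-average filters. When the
#' minimum sits at an end of the ladder the three edge samples are used and
#' the vertex is clamped to the sampled range. Pixels whose derivative never
#' drops below \eqn{-10^{-6}\max K^2} are flagged static.
#'
#' @param curve A [semilog_derivative()] result.
#' @return A list with per-pixel vectors `t_peak` (s), `dk2_peak`
#'   (compensated amplitude) and `static` (logical).
#' @export
locate_peak <- function(curve) {
  stopifnot(inherits(curve, "derivative_curve"))
  dk2 <- curve$dk2
  ln_t <- curve$ln_t
  n <- length(ln_t)
  if (n < 3) stop("need at least 3 derivative samples", call. = FALSE)
  n_pix <- ncol(dk2)
  m_idx <- max.col(t(-dk2), ties.method = "first")
  k2max <- apply(curve$k2, 2, max)
  static <- apply(dk2, 2, min) >= -STATIC_DERIV_EPS * pmax(k2max, 1e-12)
  mc <- pmin(pmax(m_idx, 2L), n - 1L)
  i1 <- mc - 1L; i2 <- mc; i3 <- mc + 1L
  flat_idx <- cbind(seq_len(n_pix))
  d1 <- dk2[cbind(i1, seq_len(n_pix))]
  d2 <- dk2[cbind(i2, seq_len(n_pix))]
  d3 <- dk2[cbind(i3, seq_len(n_pix))]
  l1 <- ln_t[i1]; l2 <- ln_t[i2]; l3 <- ln_t[i3]
  f12 <- (d2 - d1) / (l2 - l1)
  f23 <- (d3 - d2) / (l3 - l2)
  f123 <- (f23 - f12) / (l3 - l1)
  vertex <- ifelse(abs(f123) > 0, (l1 + l2) / 2 - f12 / (2 * f123), l2)
  vertex <- pmin(pmax(vertex, ln_t[1]), ln_t[n])
  amp <- d1 + f12 * (vertex - l1) + f123 * (vertex - l1) * (vertex - l2)
  list(t_peak = exp(vertex), dk2_peak = 1.05 * amp, static = static)
}

# --- stages 4/7: limit extrapolation ---------------------------------------

#' Extrapolate the contrast limits from the curve ends
#'
#' Applies the boundary-ratio extrapolation at the shortest and longest
#' derivative samples: \eqn{K^2(0) = K^2 + dK^2/B_0(\gamma)} with
#' \eqn{\gamma = T_{short}/T_{peak}} gives the \eqn{\beta} estimate, and
#' \eqn{K^2(\infty) = K^2 - dK^2/B_\infty(\gamma)} with
#' \eqn{\gamma = T_{long}/T_{peak}} gives the \eqn{\beta(1-\rho)^2}
#' estimate; \eqn{\rho} follows as \eqn{1 - \sqrt{K^2(\infty)/K^2(0)}}. The
#' end derivatives carry the same 5% filter-attenuation compensation as the
#' peak amplitude. \eqn{K^2(\infty)} is clamped to \eqn{[0, K^2(0)]}.
#'
#' @param curve A [semilog_derivative()] result.
#' @param t_peak Per-pixel peak exposure (s), from [locate_peak()].
#' @param d_mu Scattering-model weight (scalar or per-pixel).
#' @return A list with per-pixel vectors `k2_lim0`, `k2_liminf`, `rho`.
#' @export
estimate_limits <- function(curve, t_peak, d_mu = 0) {
  stopifnot(inherits(curve, "derivative_curve"))
  n <- length(curve$ln_t)
  n_pix <- ncol(curve$dk2)
  d_mu <- rep_len(d_mu, n_pix)
  g0 <- curve$t[1] / t_peak
  ginf <- curve$t[n] / t_peak
  b0 <- boundary_mixed(g0, d_mu, "zero")
  binf <- boundary_mixed(ginf, d_mu, "inf")
  k2_lim0 <- curve$k2[1, ] + 1.05 * curve$dk2[1, ] / b0
  k2_liminf <- curve$k2[n, ] - 1.05 * curve$dk2[n, ] / binf
  k2_lim0 <- pmax(k2_lim0, curve$k2[1, ]) # limits cannot undershoot the data
  k2_liminf <- pmin(pmax(k2_liminf, 0), k2_lim0)
  rho <- 1 - sqrt(ifelse(k2_lim0 > 0, k2_liminf / k2_lim0, 1))
  rho <- pmin(pmax(rho, 0), 1)
  list(k2_lim0 = k2_lim0, k2_liminf = k2_liminf, rho = rho)
}

# vectorized boundary ratio for per-pixel gamma and d_mu
boundary_mixed <- function(gamma, d_mu, limit) {
  gamma <- pmax(gamma, 1e-12)
  if (limit == "zero") {
    (1 - d_mu) * b0_pure(gamma, 0) + d_mu * b0_pure(gamma, 1)
  } else {
    (1 - d_mu) * binf_pure(gamma, 0) + d_mu * binf_pure(gamma, 1)
  }
}

# --- stage 5: scattering-model assignment ----------------------------------

#' Assign the scattering-model weight from the peak amplitude
#'
#' Places each pixel between the two pure scattering models by comparing
#' the measured (compensated) derivative-peak amplitude with the
#' theoretical peak amplitudes of both models at the first-pass
#' \eqn{(\beta, \rho)}:
#' \deqn{D_{MU} = \mathrm{clamp}\left(
#'   \frac{dK^2_{peak} - peak_0(\rho)\beta}{peak_1(\rho)\beta -
#'   peak_0(\rho)\beta}, 0, 1\right)}
#' Pixels where the two theoretical peaks coincide (\eqn{\rho \to 0}) get
#' `d_mu = 0` and a flag.
#'
#' @param dk2_peak Measured peak amplitudes (negative), from
#'   [locate_peak()].
#' @param beta,rho First-pass parameter estimates.
#' @return A list with `d_mu` and logical `degenerate`.
#' @export
assign_dmu <- function(dk2_peak, beta, rho) {
  peaks <- peak_amplitude_poly(rho, beta)
  denom <- peaks$peak1 - peaks$peak0
  degenerate <- abs(denom) < 1e-12
  d_mu <- ifelse(degenerate, 0, (dk2_peak - peaks$peak0) / denom)
  list(d_mu = pmin(pmax(d_mu, 0), 1), degenerate = degenerate)
}

# --- stage 6: spatial regularization of beta (sREMI) -----------------------

gaussian_kernel_1d <- function(sigma, size) {
  half <- (size - 1L) %/% 2L
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with reflective borders
gaussian_blur <- function(m, sigma, size) {
  k <- gaussian_kernel_1d(sigma, size)
  half <- (length(k) - 1L) %/% 2L
  p <- pad_reflect(m, half)
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, nc + 2L * half)
  for (j in seq_along(k)) {
    tmp <- tmp + k[j] * p[(j - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, (j - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

#' Spatially smooth a normalization map
#'
#' Gaussian-filters a per-pixel \eqn{\beta} map. The normalization varies
#' slowly across a field of view (aberrations, defocus), so smoothing it
#' removes salt-and-pepper noise from the short-exposure extrapolation
#' without biasing the flow estimate. Defaults: kernel size 10% of the
#' shorter image side (at least 3 px, forced odd), \eqn{\sigma} = half the
#' kernel size; borders reflective.
#'
#' @param beta_map Numeric H x W matrix.
#' @param sigma Gaussian sigma in pixels.
#' @param size Kernel side length in pixels (forced odd).
#' @return The smoothed matrix.
#' @export
smooth_beta <- function(beta_map, sigma = NULL, size = NULL) {
  stopifnot(is.matrix(beta_map))
  if (is.null(size)) size <- max(3L, round(0.1 * min(dim(beta_map))))
  size <- as.integer(size)
  if (size %% 2L == 0L) size <- size + 1L
  size <- min(size, 2L * min(dim(beta_map)) - 1L)
  if (is.null(sigma)) sigma <- size / 2
  gaussian_blur(beta_map, sigma, size)
}

# --- stage 7: correlation-time interpolation -------------------------------

#' Interpolate the correlation time from the critical contrast
#'
#' For each pixel, finds the last exposure whose (filtered) \eqn{K^2} sits
#' above the critical contrast \eqn{K^2_{crit} = K^2(T = \tau_c)} and
#' linearly interpolates \eqn{\log_{10} \tau_c} between that exposure and
#' the next:
#' \deqn{\log\tau_c = (K^2_{crit} - K^2_{idx})
#'   \frac{\log T_{idx+1} - \log T_{idx}}{K^2_{idx+1} - K^2_{idx}}
#'   + \log T_{idx}}
#' Edge rules: if every sample is above \eqn{K^2_{crit}} the last two
#' exposures are used (extrapolation); if the first sample is already below,
#' the first two are used. For strong static scattering
#' (\eqn{\rho < 0.2}), \eqn{K^2_{crit}} is capped at \eqn{\beta/2} to
#' prevent falsely high flow from the near-zero slope of such curves; the
#' capped value sits below the long-exposure floor
#' \eqn{\beta(1-\rho)^2}, so those pixels fall through to the slow-flow
#' extrapolation rule instead of reporting a spurious crossing.
#'
#' @param k2 Filtered contrast matrix (`n_exposures x n_pixels`).
#' @param times Exposure times, seconds.
#' @param k2_crit Per-pixel critical contrast.
#' @param beta,rho Optional per-pixel estimates enabling the \eqn{\beta/2}
#'   cap (applied where `rho < 0.2` when both are given).
#' @return A list with `tau_c` (per-pixel, seconds; `NA` where
#'   uninterpolatable), `k2_crit` (after the cap) and `flag` (`"ok"`,
#'   `"saturated"` for estimates clamped to one decade beyond the exposure
#'   range, or `"interp_failed"`).
#' @export
interpolate_tau <- function(k2, times, k2_crit, beta = NULL, rho = NULL) {
  if (!is.null(beta) && !is.null(rho)) {
    k2_crit <- ifelse(rho < 0.2, pmin(k2_crit, beta / 2), k2_crit)
  }
  n <- length(times)
  n_pix <- ncol(k2)
  above <- k2 > matrix(k2_crit, n, n_pix, byrow = TRUE)
  idx <- apply(above, 2, function(a) {
    w <- which(a)
    if (length(w) == 0) 1L else max(w)
  })
  idx <- pmin(idx, n - 1L) # all-above pixels use the last two exposures
  sel1 <- cbind(idx, seq_len(n_pix))
  sel2 <- cbind(idx + 1L, seq_len(n_pix))
  k1 <- k2[sel1]; k2v <- k2[sel2]
  lt1 <- log10(times)[idx]; lt2 <- log10(times)[idx + 1L]
  denom <- k2v - k1
  log_tau <- (k2_crit - k1) * (lt2 - lt1) / denom + lt1
  bad <- !is.finite(log_tau) | denom == 0
  # correlation times far outside the ladder are not supported by the data:
  # saturate at one decade beyond the exposure range instead of letting the
  # shallow-slope extrapolation diverge
  lo <- log10(times[1] / 10)
  hi <- log10(times[n] * 10)
  saturated <- !bad & (log_tau < lo | log_tau > hi)
  log_tau <- pmin(pmax(log_tau, lo), hi)
  tau_c <- ifelse(bad, NA_real_, 10^log_tau)
  flag <- ifelse(bad, "interp_failed", ifelse(saturated, "saturated", "ok"))
  list(tau_c = tau_c, k2_crit = k2_crit, flag = flag)
}

# --- orchestration ----------------------------------------------------------

#' Run the quasi-analytic estimator on a contrast stack
#'
#' Full pipeline: [prefilter()] the stack, take the [semilog_derivative()],
#' [locate_peak()], first-pass [estimate_limits()] with `d_mu = 0`,
#' [assign_dmu()], optionally ([smooth_beta()] the \eqn{\beta} map and
#' re-assign `d_mu` from the filtered \eqn{K^2(0)} when `spatial = TRUE`,
#' the sREMI variant), re-estimate the limits with the final `d_mu`,
#' compute the critical contrast [k2_crit()] and [interpolate_tau()]. All
#' stages are vectorized over pixels; per-pixel failures are flagged in the
#' result, never fatal. With `spatial = FALSE` the result is identical to
#' running the stages by hand in the order above.
#'
#' @param stack A [contrast_stack()] with >= 5 exposures.
#' @param spatial Apply the spatial regularization of beta (sREMI)?
#' @param sigma,size Gaussian filter parameters for [smooth_beta()]
#'   (defaults: kernel 10% of the shorter image side, sigma = size/2).
#' @return A `"mesi_fit"` (method `"remi"` or `"sremi"`) whose
#'   `diagnostics` holds per-pixel `t_peak`, `dk2_peak`, `k2_lim0`,
#'   `k2_liminf` and `k2_crit`.
#' @examples
#' sim <- simulate_curves(
#'   simulation_grid(inv_tau_c = 10^seq(2, 4, length.out = 5), rho = 0.9),
#'   exposure_set("logspaced", n = 15))
#' tidy(remi_pipeline(sim$stack))
#' @export
remi_pipeline <- function(stack, spatial = FALSE, sigma = NULL, size = NULL) {
  stopifnot(inherits(stack, "contrast_stack"))
  times <- as.numeric(stack$exposures)
  dims <- dim(stack$k2)[2:3]
  filtered <- prefilter(stack)
  curve <- semilog_derivative(filtered)
  pk <- locate_peak(curve)
  # first pass assuming pure ordered scattering
  lim1 <- estimate_limits(curve, pk$t_peak, d_mu = 0)
  dm1 <- assign_dmu(pk$dk2_peak, lim1$k2_lim0, lim1$rho)
  d_mu <- dm1$d_mu
  # a disabled Gaussian filter (degenerate kernel) reduces the spatial
  # variant to the per-pixel estimator exactly
  if (spatial && ((!is.null(size) && size <= 1) ||
                  (!is.null(sigma) && sigma <= 0))) {
    spatial <- FALSE
  }
  if (spatial) {
    beta1 <- estimate_limits(curve, pk$t_peak, d_mu = d_mu)$k2_lim0
    beta_s <- smooth_beta(matrix(beta1, dims[1], dims[2]), sigma, size)
    beta_s <- as.vector(beta_s)
    # re-assign the model using the spatially filtered K^2(0)
    rho_s <- 1 - sqrt(pmin(pmax(
      ifelse(beta_s > 0, lim1$k2_liminf / beta_s, 1), 0), 1))
    dm2 <- assign_dmu(pk$dk2_peak, beta_s, rho_s)
    d_mu <- dm2$d_mu
    lim2 <- estimate_limits(curve, pk$t_peak, d_mu = d_mu)
    beta <- beta_s
    k2_liminf <- pmin(lim2$k2_liminf, beta)
    rho <- 1 - sqrt(pmin(pmax(
      ifelse(beta > 0, k2_liminf / beta, 1), 0), 1))
  } else {
    lim2 <- estimate_limits(curve, pk$t_peak, d_mu = d_mu)
    beta <- lim2$k2_lim0
    k2_liminf <- lim2$k2_liminf
    rho <- lim2$rho
  }
  kc <- k2_crit(pmin(pmax(beta, 1e-6), BETA_SOFT_MAX),
                pmin(pmax(rho, 0), 1), d_mu)
  fm <- stack_matrix(filtered)
  it <- interpolate_tau(fm, times, kc, beta = beta, rho = rho)
  tau_c <- it$tau_c
  tau_c[pk$static] <- NA_real_
  flag <- it$flag
  flag[pk$static] <- "static"
  rho[pk$static] <- 0
  # saturated estimates (clamped to a decade beyond the ladder) are kept in
  # the maps for display continuity but masked from downstream statistics
  valid <- flag == "ok" & is.finite(tau_c) & is.finite(beta) & beta > 0
  est <- tibble::tibble(
    pixel = seq_len(prod(dims)),
    row = rep(seq_len(dims[1]), times = dims[2]),
    col = rep(seq_len(dims[2]), each = dims[1]),
    beta = beta, rho = rho, tau_c = tau_c, d_mu = d_mu,
    flag = flag, valid = valid
  )
  diagnostics <- tibble::tibble(
    pixel = est$pixel, t_peak = pk$t_peak, dk2_peak = pk$dk2_peak,
    k2_lim0 = beta, k2_liminf = k2_liminf, k2_crit = it$k2_crit
  )
  new_mesi_fit(est, method = if (spatial) "sremi" else "remi",
               exposures = stack$exposures, dims = dims,
               options = list(spatial = spatial, sigma = sigma, size = size),
               diagnostics = diagnostics)
}
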