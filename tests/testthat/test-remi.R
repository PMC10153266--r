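# Quasi-analytic estimator stages and pipeline.

log_lad <- exposure_set("logspaced", n = 15)

test_that("pre-filter preserves constants and applies the 1:4:1 kernel", {
  lad <- exposure_set("logspaced", n = 7, t_min = 1e-4, t_max = 1e-1)
  flat <- contrast_stack(matrix(0.42, 7, 1), lad)
  expect_equal(remispeckle:::stack_matrix(prefilter(flat)),
               matrix(0.42, 7, 1), tolerance = 1e-14)
  # interior sample with neighbours (0.2, 0.5, 0.2)
  k2 <- matrix(c(0.9, 0.8, 0.2, 0.5, 0.2, 0.1, 0.05), 7, 1)
  f <- remispeckle:::stack_matrix(prefilter(contrast_stack(k2, lad)))
  expect_equal(f[4, 1], (0.2 + 4 * 0.5 + 0.2) / 6, tolerance = 1e-14)
  # normalized kernel: interior mass preserved for a constant section
  expect_error(prefilter(contrast_stack(matrix(1, 4, 1),
    as_exposure_set(c(1, 2, 4, 8) * 1e-4))), "5 exposures")
})

test_that("nonuniform pre-filter also preserves constants", {
  lad <- exposure_set("typical")
  flat <- contrast_stack(matrix(0.37, 15, 1), lad)
  expect_equal(remispeckle:::stack_matrix(prefilter(flat)),
               matrix(0.37, 15, 1), tolerance = 1e-12)
})

test_that("semilog derivative is exact on curves linear in ln T", {
  for (kind in c("logspaced", "typical")) {
    lad <- if (kind == "logspaced") exposure_set("logspaced", n = 12)
           else exposure_set("typical")
    slope <- -0.07
    k2 <- matrix(1 + slope * log(as.numeric(lad)), ncol = 1)
    k2 <- k2 - min(k2) + 0.1 # keep positive
    cv <- semilog_derivative(contrast_stack(k2, lad))
    expect_equal(as.vector(cv$dk2), rep(slope, length(cv$ln_t)),
                 tolerance = 1e-10)
  }
})

test_that("semilog derivative tracks the analytic slope on model curves", {
  # a ladder dense enough that the smoothing attenuation stays below the
  # comparison band
  tau <- 1e-3
  lad <- exposure_set("logspaced", n = 40, t_min = tau / 100,
                      t_max = 100 * tau)
  k2 <- matrix(k2_vessel(as.numeric(lad), 1, 0.9, tau), ncol = 1)
  cv <- semilog_derivative(contrast_stack(k2, lad))
  interior <- 3:(length(cv$ln_t) - 2)
  an <- dk2_dlnT(cv$t[interior], 1, 0.9, tau, 0)
  expect_equal(as.vector(cv$dk2[interior, 1]), an, tolerance = 0.02)
  # monotone decreasing contrast means non-positive derivative samples
  expect_true(all(cv$dk2 <= 1e-12))
})

test_that("peak location refines the derivative minimum by a parabola", {
  fake_curve <- function(ln_t, dk2) {
    structure(list(ln_t = ln_t, t = exp(ln_t),
                   dk2 = matrix(dk2, ncol = 1),
                   k2 = matrix(seq(1, 0.5, length.out = length(ln_t)),
                               ncol = 1),
                   dims = c(1L, 1L)),
              class = "derivative_curve")
  }
  # symmetric parabola: vertex at the centre sample, amplitude x 1.05
  pk <- locate_peak(fake_curve(c(-1, 0, 1), c(-0.9, -1.0, -0.9)))
  expect_equal(pk$t_peak, 1, tolerance = 1e-12)
  expect_equal(pk$dk2_peak, -1.05, tolerance = 1e-12)
  # asymmetric samples: quadratic Newton vertex, frozen hand arithmetic
  pk <- locate_peak(fake_curve(c(0, 1, 2), c(-0.8, -1.0, -0.96)))
  expect_equal(log(pk$t_peak), 4 / 3, tolerance = 1e-12)
  expect_equal(pk$dk2_peak, 1.05 * (-0.8 - 0.2 * (4 / 3) +
                                      0.12 * (4 / 3) * (1 / 3)),
               tolerance = 1e-12)
  expect_false(pk$static)
})

test_that("peak of a clean model curve lands in the shifted-peak band", {
  tau <- 1e-3
  for (d in c(0, 1)) {
    sim <- tiny_sim(inv_tau_c = 1 / tau, rho = 0.8, d_mu = d,
                    exposures = exposure_set("logspaced", n = 20))
    cv <- semilog_derivative(prefilter(sim$stack))
    pk <- locate_peak(cv)
    expect_gte(pk$t_peak / tau, 0.8)
    expect_lte(pk$t_peak / tau, 3.3)
  }
})

test_that("flat curves are flagged static", {
  lad <- exposure_set("logspaced", n = 10)
  flat <- contrast_stack(matrix(0.8, 10, 1), lad)
  pk <- locate_peak(semilog_derivative(prefilter(flat)))
  expect_true(pk$static)
})

test_that("limit extrapolation with zero end-derivative returns K^2 itself", {
  ln_t <- log(10^seq(-4, -1, length.out = 8))
  curve <- structure(list(
    ln_t = ln_t, t = exp(ln_t),
    dk2 = matrix(0, 8, 1),
    k2 = matrix(seq(0.9, 0.3, length.out = 8), ncol = 1),
    dims = c(1L, 1L)), class = "derivative_curve")
  lim <- estimate_limits(curve, t_peak = 1e-2, d_mu = 0)
  expect_equal(lim$k2_lim0, 0.9, tolerance = 1e-12)
  expect_equal(lim$k2_liminf, 0.3, tolerance = 1e-12)
  expect_equal(lim$rho, 1 - sqrt(0.3 / 0.9), tolerance = 1e-12)
})

test_that("clean vessel curves recover beta and rho from the limits", {
  tau <- 1e-3
  lad <- exposure_set("logspaced", n = 15, t_min = tau / 100,
                      t_max = 100 * tau)
  for (rho in c(0.7, 0.9, 1)) {
    sim <- tiny_sim(inv_tau_c = 1 / tau, rho = rho, exposures = lad)
    cv <- semilog_derivative(prefilter(sim$stack))
    pk <- locate_peak(cv)
    lim <- estimate_limits(cv, pk$t_peak, d_mu = 0)
    expect_equal(lim$k2_lim0, 1, tolerance = 0.03)
    expect_equal(lim$rho, rho, tolerance = 0.05)
  }
})

test_that("scattering-model assignment interpolates between the peaks", {
  peaks <- peak_amplitude_poly(0.8, 1)
  expect_equal(assign_dmu(peaks$peak0, 1, 0.8)$d_mu, 0)
  expect_equal(assign_dmu(peaks$peak1, 1, 0.8)$d_mu, 1)
  expect_equal(assign_dmu((peaks$peak0 + peaks$peak1) / 2, 1, 0.8)$d_mu,
               0.5, tolerance = 1e-12)
  # out-of-band amplitudes clamp
  expect_equal(assign_dmu(peaks$peak0 * 1.5, 1, 0.8)$d_mu, 0)
  expect_equal(assign_dmu(peaks$peak1 * 0.5, 1, 0.8)$d_mu, 1)
  # degenerate rho -> flagged, vessel default
  dm <- assign_dmu(-0.001, 1, 0)
  expect_equal(dm$d_mu, 0)
  expect_true(dm$degenerate)
})

test_that("beta smoothing preserves constants and the map mean", {
  const <- matrix(0.8, 30, 30)
  expect_equal(smooth_beta(const), const, tolerance = 1e-12)
  set.seed(21)
  ph <- make_phantom(height = 40, width = 40)
  noisy <- ph$beta + matrix(rnorm(1600, 0, 0.05), 40, 40)
  sm <- smooth_beta(noisy, sigma = 2, size = 9)
  expect_lt(abs(mean(sm) - mean(noisy)) / mean(noisy), 0.01)
  # salt-and-pepper removal: smoothed map closer to the clean field
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(sm, ph$beta), rmse(noisy, ph$beta))
})

test_that("correlation-time interpolation follows the crossing rule", {
  # K^2crit = 0.5 bracketed by 0.6 at 1 ms and 0.4 at 10 ms -> 10^-2.5 s
  times <- c(1e-4, 1e-3, 1e-2, 1e-1)
  k2 <- matrix(c(0.9, 0.6, 0.4, 0.2), ncol = 1)
  it <- interpolate_tau(k2, times, 0.5)
  expect_equal(it$tau_c, 10^(-2.5), tolerance = 1e-12)
  # crossing exactly at a knot
  it <- interpolate_tau(k2, times, 0.4)
  expect_equal(it$tau_c, 1e-2, tolerance = 1e-12)
  # all samples above K^2crit: extrapolate from the last two exposures
  it <- interpolate_tau(k2, times, 0.1)
  slope <- (0.2 - 0.4) / (log10(1e-1) - log10(1e-2))
  expect_equal(log10(it$tau_c),
               log10(1e-2) + (0.1 - 0.4) / slope, tolerance = 1e-12)
  expect_equal(it$flag, "ok")
  # first sample already below: use the first two exposures
  it <- interpolate_tau(k2, times, 0.95)
  expect_equal(log10(it$tau_c),
               log10(1e-4) + (0.95 - 0.9) * (log10(1e-3) - log10(1e-4)) /
                 (0.6 - 0.9), tolerance = 1e-12)
  # beta/2 cap engages only at low dynamic scattering
  capped <- interpolate_tau(k2, times, 0.85, beta = 1, rho = 0.1)
  expect_equal(capped$k2_crit, 0.5)
  uncapped <- interpolate_tau(k2, times, 0.85, beta = 1, rho = 0.9)
  expect_equal(uncapped$k2_crit, 0.85)
})

test_that("pipeline equals its stages run by hand", {
  sim <- tiny_sim(d_mu = 0, noise = 0.03, seed = 9)
  fit <- remi_pipeline(sim$stack)
  # manual orchestration
  filtered <- prefilter(sim$stack)
  cv <- semilog_derivative(filtered)
  pk <- locate_peak(cv)
  lim1 <- estimate_limits(cv, pk$t_peak, d_mu = 0)
  dm <- assign_dmu(pk$dk2_peak, lim1$k2_lim0, lim1$rho)
  lim2 <- estimate_limits(cv, pk$t_peak, d_mu = dm$d_mu)
  kc <- k2_crit(pmin(pmax(lim2$k2_lim0, 1e-6), 1.05),
                pmin(pmax(lim2$rho, 0), 1), dm$d_mu)
  it <- interpolate_tau(remispeckle:::stack_matrix(filtered),
                        as.numeric(sim$stack$exposures), kc,
                        beta = lim2$k2_lim0, rho = lim2$rho)
  e <- tidy(fit)
  expect_equal(e$tau_c, it$tau_c, tolerance = 1e-14)
  expect_equal(e$beta, lim2$k2_lim0, tolerance = 1e-14)
  expect_equal(e$d_mu, dm$d_mu, tolerance = 1e-14)
})

test_that("spatial variant reduces to the plain estimator when disabled", {
  sim <- tiny_sim(inv_tau_c = 10^seq(2, 4, length.out = 6),
                  rho = seq(0.6, 1, length.out = 6), noise = 0.05, seed = 2)
  plain <- remi_pipeline(sim$stack, spatial = FALSE)
  disabled <- remi_pipeline(sim$stack, spatial = TRUE, size = 1)
  expect_identical(tidy(plain)$tau_c, tidy(disabled)$tau_c)
  expect_identical(tidy(plain)$beta, tidy(disabled)$beta)
})

test_that("clean in-range recovery meets the accuracy bands", {
  sim <- tiny_sim(inv_tau_c = 10^seq(2, 4, length.out = 9),
                  rho = seq(0.6, 1, length.out = 5),
                  exposures = exposure_set("logspaced", n = 20))
  e <- tidy(remi_pipeline(sim$stack))
  expect_true(all(e$valid))
  expect_lt(max(abs(e$beta - 1)), 0.05)
  expect_lt(max(abs(e$rho - sim$truth$rho)), 0.05)
  expect_lt(max(abs(log10(1 / e$tau_c) - log10(sim$truth$inv_tau_c))), 0.1)
})

test_that("static pixels are flagged without spurious flow", {
  lad <- exposure_set("logspaced", n = 12)
  k2 <- matrix(k2_mixed(as.numeric(lad), 0.9, 0, 1e-3, 0), ncol = 1)
  e <- tidy(remi_pipeline(contrast_stack(k2, lad)))
  expect_equal(e$flag, "static")
  expect_true(is.na(e$tau_c))
  expect_equal(e$rho, 0)
  expect_false(e$valid)
})

test_that("estimates saturate rather than diverge outside the ladder", {
  # truth two decades beyond the longest exposure
  sim <- tiny_sim(inv_tau_c = c(0.1, 1), rho = 0.8,
                  exposures = exposure_set("logspaced", n = 12))
  e <- tidy(remi_pipeline(sim$stack))
  expect_true(all(is.finite(e$tau_c)))
  expect_true(all(e$tau_c <= max(sim$stack$exposures) * 10 + 1e-12))
  expect_true(all(e$flag %in% c("ok", "saturated")))
})
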