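# Forward models: limits, closed-form values, quadrature oracle,
# derivatives, critical contrast, peak-amplitude polynomials.

test_that("contrast models reach their exposure-time limits", {
  set.seed(11)
  for (i in 1:10) {
    beta <- runif(1, 0.4, 1)
    rho <- runif(1, 0.1, 1)
    tau <- 10^runif(1, -5, 0)
    for (d in c(0, runif(1), 1)) {
      expect_equal(k2_mixed(1e-9 * tau, beta, rho, tau, d), beta,
                   tolerance = 1e-3)
      expect_equal(k2_mixed(1e9 * tau, beta, rho, tau, d),
                   beta * (1 - rho)^2, tolerance = 1e-3)
    }
  }
  # tighter small-x limit for the ordered model
  expect_equal(k2_vessel(1e-9 * 1e-3, 1, 0.7, 1e-3), 1, tolerance = 1e-4)
  expect_equal(k2_vessel(1e9 * 1e-3, 0.4, 0.5, 1e-3), 0.4 * 0.25,
               tolerance = 1e-4)
  expect_equal(k2_parenchyma(1e-12 * 1e-3, 1, 0.8, 1e-3), 1,
               tolerance = 1e-3)
  expect_equal(k2_parenchyma(1e12 * 1e-3, 1, 0.8, 1e-3), 0.04,
               tolerance = 1e-3)
})

test_that("closed forms match the x = 1 hand values", {
  expect_equal(k2_vessel(1e-3, 1, 1, 1e-3), (1 + exp(-2)) / 2,
               tolerance = 1e-12)
  expect_equal(k2_single(1e-3, 1, 1e-3), (1 + exp(-2)) / 2,
               tolerance = 1e-12)
  # frozen regression constant, cross-checked against the quadrature
  # oracle below
  expect_equal(k2_parenchyma(1e-3, 1, 1, 1e-3), (13 * exp(-2) - 1) / 2,
               tolerance = 1e-12)
})

test_that("closed forms match direct quadrature of the variance integral", {
  set.seed(42)
  xs <- 10^runif(20, -2, 2)
  rhos <- runif(20, 0.2, 1)
  for (i in seq_along(xs)) {
    expect_equal(
      k2_vessel(xs[i], 0.8, rhos[i], 1),
      quadrature_k2(xs[i], 0.8, rhos[i], g1_ordered),
      tolerance = 1e-6)
    expect_equal(
      k2_parenchyma(xs[i], 0.8, rhos[i], 1),
      quadrature_k2(xs[i], 0.8, rhos[i], g1_unordered),
      tolerance = 1e-6)
  }
})

test_that("single-model contrast equals the ordered model at rho = 1", {
  set.seed(7)
  for (i in 1:20) {
    T <- 10^runif(1, -5, 0); beta <- runif(1, 0.2, 1)
    tau <- 10^runif(1, -5, 0)
    expect_equal(k2_single(T, beta, tau), k2_vessel(T, beta, 1, tau),
                 tolerance = 1e-12)
  }
})

test_that("mixed model is the convex combination of the pure models", {
  set.seed(8)
  for (i in 1:20) {
    T <- 10^runif(1, -5, 0); beta <- runif(1, 0.2, 1)
    rho <- runif(1); tau <- 10^runif(1, -5, 0)
    v <- k2_vessel(T, beta, rho, tau)
    p <- k2_parenchyma(T, beta, rho, tau)
    expect_identical(k2_mixed(T, beta, rho, tau, 0), v)
    expect_identical(k2_mixed(T, beta, rho, tau, 1), p)
    expect_equal(k2_mixed(T, beta, rho, tau, 0.5), (v + p) / 2,
                 tolerance = 1e-14)
  }
})

test_that("contrast decreases strictly with exposure for rho > 0", {
  Tgrid <- 10^seq(-6, 1, length.out = 200)
  for (d in c(0, 0.5, 1)) {
    for (rho in c(0.3, 0.7, 1)) {
      k2 <- k2_mixed(Tgrid, 1, rho, 1e-3, d)
      expect_true(all(diff(k2) < 0))
    }
  }
  # static scatterers: flat at beta
  expect_equal(k2_mixed(Tgrid, 0.9, 0, 1e-3, 0.5), rep(0.9, 200),
               tolerance = 1e-14)
})

test_that("analytic semilog derivative matches finite differences", {
  set.seed(13)
  for (i in 1:50) {
    T <- 10^runif(1, -3, 3) # in units of tau_c
    rho <- runif(1, 0.1, 1)
    d <- sample(c(0, 1, runif(1)), 1)
    an <- dk2_dlnT(T, 1, rho, 1, d)
    fd <- fd_dk2_dlnT(T, 1, rho, 1, d)
    expect_equal(an, fd, tolerance = 1e-5)
  }
})

test_that("semilog derivative is non-positive and vanishes at extremes", {
  Tgrid <- 10^seq(-4, 4, length.out = 100)
  for (d in c(0, 1)) {
    dk <- dk2_dlnT(Tgrid, 1, 0.8, 1, d)
    expect_true(all(dk <= 0))
    expect_lt(abs(dk2_dlnT(1e-8, 1, 0.8, 1, d)), 1e-3)
    expect_lt(abs(dk2_dlnT(1e8, 1, 0.8, 1, d)), 1e-3)
  }
  expect_equal(dk2_dlnT(Tgrid, 1, 0, 1, 0.5), rep(0, 100),
               tolerance = 1e-14)
})

test_that("derivative peak sits between 0.8 and 3.3 correlation times", {
  for (d in c(0, 1)) {
    for (rho in seq(0.5, 1, by = 0.1)) {
      xp <- remispeckle:::peak_location_x(rho, d)
      expect_gte(xp, 0.8)
      expect_lte(xp, 3.3)
    }
  }
})

test_that("rho is recovered from the exact contrast limits", {
  for (rho in c(0, 0.25, 0.5, 0.9, 1)) {
    beta <- 0.85
    lim0 <- beta
    liminf <- beta * (1 - rho)^2
    expect_equal(1 - sqrt(liminf / lim0), rho, tolerance = 1e-12)
  }
})

test_that("single-exposure flow estimate follows beta / (T K^2)", {
  expect_equal(lsci_flow(0.04, 5e-3, 1), 5000)
  expect_equal(lsci_flow(0.04, 5e-3, 0.5), 2500)
  expect_true(is.na(lsci_flow(0, 5e-3, 1)))
  expect_true(is.na(lsci_flow(-0.1, 5e-3, 1)))
  expect_equal(lsci_flow(c(0.04, 0), 5e-3, 1), c(5000, NA))
})

test_that("critical contrast equals the mixed model at T = tau_c", {
  set.seed(9)
  for (i in 1:50) {
    beta <- runif(1, 0.2, 1); rho <- runif(1); d <- runif(1)
    tau <- 10^runif(1, -5, 0)
    expect_equal(k2_crit(beta, rho, d),
                 k2_mixed(tau, beta, rho, tau, d), tolerance = 1e-12)
  }
  expect_equal(k2_crit(1, 1, 0), (1 + exp(-2)) / 2, tolerance = 1e-12)
  expect_equal(k2_crit(0.7, 0, 0.3), 0.7, tolerance = 1e-12) # static limit
})

test_that("peak-amplitude polynomials track direct minimization", {
  rhos <- seq(0, 1, length.out = 21)
  direct0 <- vapply(rhos, function(r) {
    if (r == 0) return(0)
    optimize(function(lx) dk2_dlnT(exp(lx), 1, r, 1, 0),
             interval = log(c(1e-4, 1e4)), tol = 1e-12)$objective
  }, numeric(1))
  direct1 <- vapply(rhos, function(r) {
    if (r == 0) return(0)
    optimize(function(lx) dk2_dlnT(exp(lx), 1, r, 1, 1),
             interval = log(c(1e-4, 1e4)), tol = 1e-12)$objective
  }, numeric(1))
  peaks <- peak_amplitude_poly(rhos, 1)
  expect_lt(max(abs(peaks$peak0 - direct0)), 1e-4)
  expect_lt(max(abs(peaks$peak1 - direct1)), 1e-4)
  # beta is an exact multiplicative prefactor
  half <- peak_amplitude_poly(rhos, 0.5)
  expect_equal(half$peak0, 0.5 * peaks$peak0, tolerance = 1e-14)
  expect_equal(half$peak1, 0.5 * peaks$peak1, tolerance = 1e-14)
  # no dynamic scattering, flat curve
  z <- peak_amplitude_poly(0, 1)
  expect_equal(z$peak0, 0)
  expect_equal(z$peak1, 0)
})

test_that("model inputs are validated", {
  expect_error(k2_vessel(-1e-3, 1, 0.5, 1e-3), "exposure")
  expect_error(k2_vessel(1e-3, 1, 0.5, -1), "tau_c")
  expect_error(k2_mixed(1e-3, 1, 1.5, 1e-3, 0), "rho")
  expect_error(k2_mixed(1e-3, 1, 0.5, 1e-3, 2), "d_mu")
  expect_error(k2_vessel(1e-3, 0, 0.5, 1e-3), "beta")
  expect_error(lsci_flow(0.04, -1, 1), "exposure")
})
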