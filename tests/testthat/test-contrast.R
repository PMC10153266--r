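# Sliding-window contrast computation and stack utilities.

make_frames <- function(imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  out <- array(0, dim = c(length(imgs), H, W))
  for (i in seq_along(imgs)) out[i, , ] <- imgs[[i]]
  out
}

five_exposures <- as_exposure_set(c(1, 2, 4, 8, 16) * 1e-4)

test_that("constant images give zero contrast", {
  frames <- make_frames(replicate(5, matrix(100, 12, 12), simplify = FALSE))
  cs <- compute_contrast(frames, five_exposures, window = 5)
  expect_equal(max(abs(cs$k2)), 0)
  expect_equal(dim(cs$k2)[2:3], c(12L, 12L))
})

test_that("window statistics match hand arithmetic", {
  # 5x5 window holding thirteen 2s and twelve 0s: mean 26/25, sample
  # variance (13 (2 - 1.04)^2 + 12 (1.04)^2) / 24 = 1.04, so K^2 = 1/1.04
  img <- matrix(0, 11, 11)
  patt <- matrix(rep_len(c(2, 0), 25), 5, 5)  # 13 twos, 12 zeros
  img[4:8, 4:8] <- patt
  frames <- make_frames(replicate(5, img, simplify = FALSE))
  cs <- compute_contrast(frames, five_exposures, window = 5)
  mu <- 26 / 25
  v <- (13 * (2 - mu)^2 + 12 * mu^2) / 24
  expect_equal(cs$k2[1, 6, 6], v / mu^2, tolerance = 1e-12)
  expect_equal(v / mu^2, 1 / 1.04, tolerance = 1e-12)
})

test_that("contrast is invariant to a pure intensity gain", {
  set.seed(5)
  img <- matrix(rpois(400, 80), 20, 20)
  f1 <- make_frames(replicate(5, img, simplify = FALSE))
  f2 <- f1 * 3.7
  c1 <- compute_contrast(f1, five_exposures, window = 7)
  c2 <- compute_contrast(f2, five_exposures, window = 7)
  expect_equal(c1$k2, c2$k2, tolerance = 1e-12)
})

test_that("borders are flagged and geometry is preserved", {
  set.seed(6)
  frames <- array(rpois(5 * 15 * 17, 50), dim = c(5, 15, 17))
  cs <- compute_contrast(frames, five_exposures, window = 5)
  valid <- attr(cs, "valid")
  expect_equal(dim(valid), c(15L, 17L))
  expect_false(any(valid[1:2, ]))
  expect_false(any(valid[, 16:17]))
  expect_true(all(valid[3:13, 3:15]))
})

test_that("replicate frames are averaged per exposure", {
  set.seed(12)
  base <- matrix(rpois(144, 60), 12, 12)
  # two replicates whose average is `base`
  up <- base + 1; dn <- base - 1
  frames <- make_frames(rep(list(up, dn), 5))
  cs2 <- compute_contrast(frames, five_exposures, window = 5, replicates = 2)
  cs1 <- compute_contrast(make_frames(replicate(5, base, simplify = FALSE)),
                          five_exposures, window = 5)
  expect_equal(cs2$k2, cs1$k2, tolerance = 1e-12)
})

test_that("contrast input validation", {
  frames <- array(1, dim = c(5, 8, 8))
  expect_error(compute_contrast(frames, five_exposures, window = 4), "odd")
  expect_error(compute_contrast(frames, five_exposures, window = 1), "odd")
  expect_error(compute_contrast(array(1, dim = c(4, 8, 8)), five_exposures),
               "frame count")
  expect_error(compute_contrast(matrix(1, 5, 5), five_exposures), "3-D")
})

test_that("averaging contrast stacks is the elementwise mean", {
  z <- contrast_stack(array(0, dim = c(5, 4, 4)), five_exposures)
  tw <- contrast_stack(array(2, dim = c(5, 4, 4)), five_exposures)
  expect_equal(average_contrast(list(z))$k2, z$k2)
  expect_equal(average_contrast(list(tw, tw))$k2, tw$k2)
  expect_equal(average_contrast(list(z, tw))$k2,
               array(1, dim = c(5, 4, 4)))
  expect_error(average_contrast(list(z, contrast_stack(
    array(1, dim = c(5, 3, 3)), five_exposures))), "geometry")
})

test_that("contrast stack objects validate and convert", {
  k2 <- array(0.5, dim = c(5, 3, 2))
  cs <- contrast_stack(k2, five_exposures)
  expect_s3_class(cs, "contrast_stack")
  expect_equal(dim(cs), c(5L, 3L, 2L))
  tb <- tibble::as_tibble(cs)
  expect_equal(nrow(tb), 5 * 3 * 2)
  expect_equal(unique(tb$k2), 0.5)
  expect_error(contrast_stack(-k2, five_exposures), "non-negative")
  expect_error(contrast_stack(k2[1:3, , ], five_exposures), "match")
})
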