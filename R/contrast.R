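#' Multi-exposure contrast stacks
#'
#' A contrast stack is the universal exchange object of the package: squared
#' speckle contrast \eqn{K^2} indexed by (exposure, row, column), plus the
#' exposure ladder. `contrast_stack()` accepts a 3-D array
#' (`n_exposures x H x W`) or a matrix (`n_exposures x n_pixels`, treated as
#' an `n_pixels x 1` image).
#'
#' @param k2 Array of squared contrast values, `n_exposures` first.
#' @param exposures An [exposure_set()] (or coercible numeric vector) of the
#'   same length as the first dimension of `k2`.
#' @return An object of class `"contrast_stack"`.
#' @export
contrast_stack <- function(k2, exposures) {
  exposures <- if (inherits(exposures, "exposure_set")) exposures
               else as_exposure_set(exposures)
  if (is.matrix(k2)) dim(k2) <- c(nrow(k2), ncol(k2), 1L)
  if (length(dim(k2)) != 3) {
    stop("`k2` must be a 3-D array (exposure, row, col) or a matrix",
         call. = FALSE)
  }
  if (dim(k2)[1] != length(exposures)) {
    stop("first dimension of `k2` must match the number of exposures",
         call. = FALSE)
  }
  if (any(k2[is.finite(k2)] < 0)) {
    stop("`k2` must be non-negative", call. = FALSE)
  }
  structure(list(k2 = k2, exposures = exposures), class = "contrast_stack")
}

#' @export
print.contrast_stack <- function(x, ...) {
  d <- dim(x$k2)
  cat(sprintf(
    "<contrast_stack: %d exposures (%.3g-%.3g s, %s), %d x %d pixels>\n",
    d[1], min(x$exposures), max(x$exposures),
    exposure_spacing(x$exposures), d[2], d[3]))
  invisible(x)
}

#' @export
dim.contrast_stack <- function(x) dim(x$k2)

# exposures x pixels view (columns in column-major pixel order)
stack_matrix <- function(stack) {
  d <- dim(stack$k2)
  matrix(stack$k2, nrow = d[1], ncol = d[2] * d[3])
}

matrix_to_stack <- function(m, dims, exposures) {
  contrast_stack(array(m, dim = c(nrow(m), dims[1], dims[2])), exposures)
}

#' @exportS3Method tibble::as_tibble
as_tibble.contrast_stack <- function(x, ...) {
  d <- dim(x$k2)
  tibble::tibble(
    exposure = rep(as.numeric(x$exposures), times = d[2] * d[3]),
    row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    col = rep(seq_len(d[3]), each = d[1] * d[2]),
    k2 = as.vector(x$k2)
  )
}

# reflective padding of a matrix by r rows/cols on every side
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("window too large for image", call. = FALSE)
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  m[ri, ci, drop = FALSE]
}

# sliding-window sums via shift-and-add on the padded image
window_sums <- function(m, window) {
  r <- (window - 1L) %/% 2L
  p <- pad_reflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (dr in 0:(window - 1L)) {
    for (dc in 0:(window - 1L)) {
      acc <- acc + p[dr + seq_len(nr), dc + seq_len(nc)]
    }
  }
  acc
}

#' Compute speckle contrast from raw intensity frames
#'
#' Converts raw speckle intensity images (one per exposure) into a stack of
#' squared speckle contrast maps using the sliding-window definition
#' \eqn{K = \sigma / \bar I}: at every pixel, the sample standard deviation
#' divided by the mean of the intensities in a `window x window`
#' neighbourhood (5x5 or 7x7 in common practice). Borders are handled by
#' reflective padding and flagged in the validity mask; windows with
#' non-positive mean yield `NA`. When `replicates > 1`, consecutive groups of
#' frames for the same exposure are averaged before the window statistics.
#'
#' The sample (N-1) standard deviation is used; K is invariant to a pure
#' intensity gain.
#'
#' @param frames 3-D numeric array (`n_frames x H x W`) of raw intensities,
#'   page order matching `exposures` (grouped by exposure when
#'   `replicates > 1`).
#' @param exposures An [exposure_set()] for the stack.
#' @param window Odd window side length, >= 3 (typically 5 or 7).
#' @param replicates Number of consecutive frames per exposure to average.
#' @return A [contrast_stack()] with attribute `"valid"` (logical H x W mask,
#'   `FALSE` on border pixels and failed windows).
#' @export
compute_contrast <- function(frames, exposures, window = 7L,
                             replicates = 1L) {
  exposures <- if (inherits(exposures, "exposure_set")) exposures
               else as_exposure_set(exposures)
  if (length(dim(frames)) != 3) {
    stop("`frames` must be a 3-D array (frame, row, col)", call. = FALSE)
  }
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  n_exp <- length(exposures)
  if (dim(frames)[1] != n_exp * replicates) {
    stop("frame count must equal n_exposures * replicates", call. = FALSE)
  }
  H <- dim(frames)[2]; W <- dim(frames)[3]
  n <- window^2
  k2 <- array(NA_real_, dim = c(n_exp, H, W))
  valid <- matrix(TRUE, H, W)
  r <- (window - 1L) %/% 2L
  valid[c(seq_len(r), H + 1L - seq_len(r)), ] <- FALSE
  valid[, c(seq_len(r), W + 1L - seq_len(r))] <- FALSE
  for (e in seq_len(n_exp)) {
    img <- frames[(e - 1L) * replicates + 1L, , ]
    if (replicates > 1L) {
      for (j in 2:replicates) img <- img + frames[(e - 1L) * replicates + j, , ]
      img <- img / replicates
    }
    s1 <- window_sums(img, window)
    s2 <- window_sums(img^2, window)
    mu <- s1 / n
    v <- (s2 - s1^2 / n) / (n - 1)
    v[v < 0] <- 0 # numerical round-off on flat windows
    k2e <- v / mu^2
    k2e[!is.finite(k2e) | mu <= 0] <- NA_real_
    k2[e, , ] <- k2e
  }
  valid <- valid & apply(k2, c(2, 3), function(z) all(is.finite(z)))
  out <- contrast_stack(k2, exposures)
  attr(out, "valid") <- valid
  out
}

#' Average several contrast stacks
#'
#' Elementwise temporal mean over a window of contrast stacks with identical
#' geometry and exposures, as used when smoothing per-frame contrast images
#' before model fitting (e.g. a 5-point moving average of speckle contrast
#' images).
#'
#' @param stacks A list of [contrast_stack()] objects.
#' @param window_len Number of trailing stacks to average (default: all).
#' @return A single averaged [contrast_stack()].
#' @export
average_contrast <- function(stacks, window_len = length(stacks)) {
  if (length(stacks) < 1) stop("need at least one stack", call. = FALSE)
  stacks <- tail(stacks, window_len)
  d <- dim(stacks[[1]]$k2)
  ok <- vapply(stacks, function(s) identical(dim(s$k2), d), logical(1))
  if (!all(ok)) stop("stacks must share geometry", call. = FALSE)
  acc <- Reduce(`+`, lapply(stacks, function(s) s$k2))
  contrast_stack(acc / length(stacks), stacks[[1]]$exposures)
}
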