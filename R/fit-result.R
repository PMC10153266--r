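# Common container for fitted parameter maps (least-squares and
# quasi-analytic alike): a tibble of per-pixel estimates plus geometry,
# exposures and the options that produced it.

new_mesi_fit <- function(estimates, method, exposures, dims,
                         options = list(), diagnostics = NULL) {
  structure(list(estimates = estimates, method = method,
                 exposures = exposures, dims = dims, options = options,
                 diagnostics = diagnostics),
            class = "mesi_fit")
}

#' @export
print.mesi_fit <- function(x, ...) {
  cat(sprintf("<mesi_fit: %s, %d x %d pixels, %d valid>\n",
              x$method, x$dims[1], x$dims[2], sum(x$estimates$valid)))
  print(head(x$estimates, 5))
  invisible(x)
}

#' Extract parameter maps from a fit
#'
#' Reshapes the per-pixel estimates of a `"mesi_fit"` into named H x W
#' matrices.
#'
#' @param fit A `"mesi_fit"` object.
#' @return A list of matrices: `beta`, `rho`, `tau_c`, `d_mu`, `valid`.
#' @export
fit_maps <- function(fit) {
  d <- fit$dims
  shape <- function(v) matrix(v, d[1], d[2])
  list(beta = shape(fit$estimates$beta), rho = shape(fit$estimates$rho),
       tau_c = shape(fit$estimates$tau_c), d_mu = shape(fit$estimates$d_mu),
       valid = shape(fit$estimates$valid))
}

#' Tidy a fitted parameter map
#'
#' Returns the per-pixel estimates as a tibble (one row per pixel), in the
#' broom sense of `tidy()`.
#'
#' @param x A `"mesi_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `pixel`, `row`, `col`, `beta`, `rho`,
#'   `tau_c`, `d_mu`, `valid` and method-specific diagnostics.
#' @exportS3Method generics::tidy
tidy.mesi_fit <- function(x, ...) x$estimates

#' Glance at a fitted parameter map
#'
#' One-row summary of a fit: pixel counts, validity, and medians of the
#' fitted parameters over valid pixels.
#'
#' @param x A `"mesi_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.mesi_fit <- function(x, ...) {
  e <- x$estimates[x$estimates$valid, ]
  tibble::tibble(
    method = x$method,
    n_pixels = nrow(x$estimates),
    n_valid = nrow(e),
    median_beta = stats::median(e$beta, na.rm = TRUE),
    median_rho = stats::median(e$rho, na.rm = TRUE),
    median_inv_tau_c = stats::median(1 / e$tau_c, na.rm = TRUE)
  )
}

#' Plot fitted parameter maps
#'
#' Raster panels of the fitted `beta`, `rho`, `log10(1/tau_c)` and `d_mu`
#' maps.
#'
#' @param object A `"mesi_fit"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mesi_fit <- function(object, ...) {
  df <- object$estimates |>
    dplyr::mutate(`log10 flow` = log10(1 / .data$tau_c)) |>
    dplyr::select("row", "col", "beta", "rho", "log10 flow", "d_mu") |>
    tidyr::pivot_longer(cols = c("beta", "rho", "log10 flow", "d_mu"),
                        names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = object$method, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot contrast curves from a stack
#'
#' Squared-contrast vs exposure curves (log-x) for a subset of pixels,
#' useful for eyeballing simulated or measured stacks.
#'
#' @param object A [contrast_stack()].
#' @param pixels Indices of pixels (column-major) to draw; defaults to up to
#'   20 evenly spaced pixels.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.contrast_stack <- function(object, pixels = NULL, ...) {
  m <- stack_matrix(object)
  if (is.null(pixels)) {
    pixels <- unique(round(seq(1, ncol(m), length.out = min(20, ncol(m)))))
  }
  df <- tidyr::expand_grid(pixel = pixels,
                           exposure = as.numeric(object$exposures))
  df$k2 <- as.vector(m[, pixels])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exposure, y = .data$k2,
                                   group = .data$pixel,
                                   colour = factor(.data$pixel))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "exposure time (s)", y = expression(K^2)) +
    ggplot2::theme_minimal()
}
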