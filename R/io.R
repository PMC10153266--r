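# Disk interchange: multi-page 32-bit TIFF + JSON sidecar metadata.
#
# The TIFF writer stores samples normalized to [0, 1], so every map is
# written divided by a per-file (or per-map) scale factor recorded in the
# JSON sidecar; readers reverse the scaling. NA pixels are stored as 0 --
# the validity mask, not the raw map, is authoritative for them.

sidecar_path <- function(path) paste0(path, ".json")

#' Read and write contrast stacks as multi-page TIFF
#'
#' A contrast stack is serialized as a multi-page 32-bit TIFF (one page per
#' exposure, page order = exposure order) together with a JSON sidecar
#' (`<path>.json`) recording the exposure times in seconds, the spacing
#' tag, and the intensity scale factor (TIFF samples are stored normalized
#' to \[0, 1\]). `read_contrast_stack()` accepts either the sidecar or an
#' explicit `exposures` argument (in which case the data are assumed
#' unscaled).
#'
#' @param stack A [contrast_stack()].
#' @param path TIFF file path.
#' @param exposures Optional [exposure_set()] overriding the sidecar.
#' @return `write_contrast_stack()` returns `path` invisibly;
#'   `read_contrast_stack()` returns a [contrast_stack()].
#' @export
write_contrast_stack <- function(stack, path) {
  scale <- max(1, max(stack$k2[is.finite(stack$k2)]))
  pages <- lapply(seq_len(dim(stack$k2)[1]), function(e) {
    page <- stack$k2[e, , ] / scale
    page[!is.finite(page)] <- 0
    page
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(exposure_s = as.numeric(stack$exposures),
         spacing = exposure_spacing(stack$exposures),
         n_exposures = length(stack$exposures),
         scale = scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contrast_stack
#' @export
read_contrast_stack <- function(path, exposures = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  if (is.null(exposures)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc)) {
      stop("no sidecar metadata found; pass `exposures`", call. = FALSE)
    }
    meta <- jsonlite::read_json(sc)
    exposures <- as_exposure_set(unlist(meta$exposure_s))
    if (!is.null(meta$scale)) scale <- meta$scale
  }
  k2 <- array(NA_real_, dim = c(length(pages), nrow(pages[[1]]),
                                ncol(pages[[1]])))
  for (e in seq_along(pages)) k2[e, , ] <- pages[[e]] * scale
  contrast_stack(k2, exposures)
}

#' Write fitted parameter maps to disk
#'
#' Serializes a fit result (see [remi_pipeline()], [fit_mixed()]) as one
#' 32-bit TIFF per parameter map (`beta`, `rho`, `tau_c`, `d_mu`), a
#' validity-mask TIFF, and a JSON manifest listing the method, options,
#' exposure times, and the per-map scale factors used to normalize the
#' TIFF samples into \[0, 1\] (invalid pixels are stored as 0; consult the
#' mask).
#'
#' @param fit A `"mesi_fit"` object.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_fit_maps <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- fit_maps(fit)
  scales <- list()
  for (nm in c("beta", "rho", "tau_c", "d_mu")) {
    m <- maps[[nm]]
    finite <- m[is.finite(m)]
    scale <- if (length(finite)) max(1e-12, max(abs(finite))) else 1
    m <- m / scale
    m[!is.finite(m)] <- 0
    scales[[nm]] <- scale
    tiff::writeTIFF(m, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32L)
  }
  tiff::writeTIFF(maps$valid * 1, file.path(dir, "valid.tif"),
                  bits.per.sample = 32L)
  manifest <- list(method = fit$method,
                   exposures_s = as.numeric(fit$exposures),
                   dims = fit$dims, options = fit$options,
                   map_scales = scales,
                   package_version = as.character(
                     utils::packageVersion("remispeckle")))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fitted parameter maps written by [write_fit_maps()]
#'
#' @param dir Directory holding the map TIFFs and `manifest.json`.
#' @return A list of matrices (`beta`, `rho`, `tau_c`, `d_mu`, `valid`)
#'   plus the parsed `manifest`.
#' @export
read_fit_maps <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list()
  for (nm in c("beta", "rho", "tau_c", "d_mu")) {
    m <- tiff::readTIFF(file.path(dir, paste0(nm, ".tif")))
    out[[nm]] <- m * manifest$map_scales[[nm]]
  }
  out$valid <- tiff::readTIFF(file.path(dir, "valid.tif")) > 0.5
  out$manifest <- manifest
  out
}
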