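#' Exposure-time ladders
#'
#' An exposure set is the ordered list of camera exposure times (seconds) at
#' which speckle contrast was (or is to be) measured, together with spacing
#' metadata: `"log_uniform"` when consecutive ratios are constant (to within
#' 1e-6 relative), `"irregular"` otherwise. The spacing tag selects the
#' uniform-kernel vs nonuniform-kernel filtering paths in the quasi-analytic
#' estimator.
#'
#' `exposure_set()` builds the two ladders used throughout the simulation
#' benchmark: `"logspaced"` returns `n` geometrically spaced times between
#' `t_min` and `t_max` (default 20 exposures from 20 us to 650 ms);
#' `"typical"` returns the irregular 15-exposure ladder spanning
#' 50 us – 80 ms that mirrors the exposure lists commonly used in the MESI
#' literature, loaded from the editable config
#' `inst/extdata/typical_exposures.csv`. `as_exposure_set()` wraps an
#' arbitrary vector of times.
#'
#' @param kind `"logspaced"` or `"typical"`.
#' @param n Number of exposures for the log-spaced ladder (>= 2).
#' @param t_min,t_max Shortest/longest exposure, seconds.
#' @return A numeric vector of class `"exposure_set"` with attribute
#'   `spacing`.
#' @examples
#' exposure_set("logspaced", n = 20, t_min = 2e-5, t_max = 0.65)
#' exposure_set("typical")
#' @export
exposure_set <- function(kind = c("logspaced", "typical"), n = 20,
                         t_min = 2e-5, t_max = 0.65) {
  kind <- match.arg(kind)
  if (kind == "logspaced") {
    if (t_min >= t_max) stop("`t_min` must be < `t_max`", call. = FALSE)
    if (n < 2) stop("`n` must be >= 2", call. = FALSE)
    times <- 10^seq(log10(t_min), log10(t_max), length.out = n)
    times[1] <- t_min
    times[n] <- t_max
  } else {
    path <- system.file("extdata", "typical_exposures.csv",
                        package = "remispeckle")
    times <- read.csv(path, comment.char = "#")$exposure_s
  }
  as_exposure_set(times)
}

#' @param times Strictly increasing positive exposure times, seconds.
#' @rdname exposure_set
#' @export
as_exposure_set <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2 || any(!is.finite(times)) || any(times <= 0) ||
      any(diff(times) <= 0)) {
    stop("exposure times must be positive, finite and strictly increasing",
         call. = FALSE)
  }
  ratios <- times[-1] / times[-length(times)]
  spacing <- if (max(ratios) - min(ratios) <= 1e-6 * min(ratios)) {
    "log_uniform"
  } else {
    "irregular"
  }
  structure(times, class = "exposure_set", spacing = spacing)
}

#' @export
print.exposure_set <- function(x, ...) {
  cat(sprintf("<exposure_set: %d exposures, %.3g-%.3g s, %s spacing>\n",
              length(x), min(x), max(x), attr(x, "spacing")))
  print(as.numeric(x))
  invisible(x)
}

exposure_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) attr(as_exposure_set(as.numeric(x)), "spacing") else sp
}
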