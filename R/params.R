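#' Physical parameters of the speckle contrast models
#'
#' Constructs and validates the per-pixel physical state evaluated by every
#' forward model and returned by every fitter:
#'
#' * `beta` — normalization accounting for speckle/pixel size mismatch and
#'   source coherence; the zero-exposure limit of \eqn{K^2}. Physically
#'   \eqn{\beta \le 1}; values up to a soft bound of 1.05 are tolerated (noisy
#'   data routinely fit slightly above 1) and values above the soft bound are
#'   clamped with a warning.
#' * `rho` — fraction of detected light scattered by moving particles; sets
#'   the long-exposure contrast floor \eqn{\beta(1-\rho)^2}.
#' * `tau_c` — correlation time of the field autocorrelation, in seconds;
#'   `1/tau_c` is the flow index.
#' * `d_mu` — mixing weight between the multiple-ordered (vessel, `d_mu = 0`)
#'   and multiple-unordered (parenchyma, `d_mu = 1`) scattering models.
#'
#' Arguments are recycled to a common length, so the constructor doubles as a
#' tidy way to build parameter grids.
#'
#' @param beta Normalization, in (0, 1.05].
#' @param rho Dynamic scattering fraction, in \[0, 1\].
#' @param tau_c Correlation time in seconds, > 0.
#' @param d_mu Scattering-model mixing weight, in \[0, 1\].
#' @return A tibble with columns `beta`, `rho`, `tau_c`, `d_mu`.
#' @examples
#' speckle_params(beta = 1, rho = c(0.5, 0.9), tau_c = 1e-3)
#' @export
speckle_params <- function(beta = 1, rho = 1, tau_c = 1e-3, d_mu = 0) {
  n <- max(length(beta), length(rho), length(tau_c), length(d_mu))
  p <- tibble::tibble(
    beta = rep_len(as.numeric(beta), n),
    rho = rep_len(as.numeric(rho), n),
    tau_c = rep_len(as.numeric(tau_c), n),
    d_mu = rep_len(as.numeric(d_mu), n)
  )
  validate_params(p$beta, p$rho, p$tau_c, p$d_mu)
  p$beta <- clamp_beta(p$beta)
  p
}

BETA_SOFT_MAX <- 1.05

validate_params <- function(beta, rho, tau_c, d_mu) {
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop("`beta` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1)) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(tau_c)) || any(tau_c <= 0)) {
    stop("`tau_c` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(d_mu)) || any(d_mu < 0) || any(d_mu > 1)) {
    stop("`d_mu` must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

clamp_beta <- function(beta) {
  over <- beta > BETA_SOFT_MAX
  if (any(over)) {
    warning(sprintf("%d beta value(s) above the soft bound %.2f were clamped",
                    sum(over), BETA_SOFT_MAX), call. = FALSE)
    beta[over] <- BETA_SOFT_MAX
  }
  beta
}
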