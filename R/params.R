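#' Observer parameters
#'
#' Bundle of the generative/ideal-observer parameters: the standard deviations
#' of the Gaussian sensory noise on the extraretinal gaze-displacement cue
#' (`sigma_e`) and on the retinal misalignment cue (`sigma_r`), the diffusion
#' coefficient `D` of the Brownian drift prior, and the inter-stimulus
#' interval `T`. Under the Brownian prior the gaze displacement over the ISI
#' is centred on zero with standard deviation `sqrt(2 * D * T)`.
#'
#' @param sigma_e Extraretinal noise sd in arcmin; `Inf` is allowed and means
#'   the observer has no trial-specific extraretinal information.
#' @param sigma_r Retinal noise sd in arcmin; must be strictly positive.
#' @param D Drift diffusion coefficient in arcmin^2/ms; displacement variance
#'   per axis over a lag `dt` is `2 * D * dt`.
#' @param T Inter-stimulus interval in ms.
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(sigma_e = 2, sigma_r = 0.5, D = 0.08, T = 100)
#' @export
observer_params <- function(sigma_e, sigma_r, D, T) {
  stopifnot(is.numeric(sigma_e), length(sigma_e) == 1L,
            is.numeric(sigma_r), length(sigma_r) == 1L,
            is.numeric(D), length(D) == 1L,
            is.numeric(T), length(T) == 1L)
  if (is.na(sigma_e) || sigma_e < 0)
    stop("'sigma_e' must be >= 0 (Inf permitted)")
  if (is.na(sigma_r) || sigma_r <= 0 || !is.finite(sigma_r))
    stop("'sigma_r' must be finite and > 0")
  if (is.na(D) || D < 0 || !is.finite(D))
    stop("'D' must be finite and >= 0")
  if (is.na(T) || T <= 0 || !is.finite(T))
    stop("'T' must be finite and > 0")
  structure(list(sigma_e = sigma_e, sigma_r = sigma_r, D = D, T = T),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Observer parameters\n")
  cat(sprintf("  sigma_e: %s arcmin   sigma_r: %g arcmin\n",
              format(x$sigma_e), x$sigma_r))
  cat(sprintf("  D: %g arcmin^2/ms   ISI T: %g ms   prior sd sqrt(2DT): %g arcmin\n",
              x$D, x$T, sqrt(2 * x$D * x$T)))
  cat(sprintf("  extraretinal weight w = 2DT/(sigma_e^2 + 2DT): %.4f\n",
              extraretinal_weight(x)))
  invisible(x)
}

as_observer_params <- function(x) {
  if (inherits(x, "observer_params")) return(x)
  if (is.list(x) && all(c("sigma_e", "sigma_r", "D", "T") %in% names(x)))
    return(observer_params(x$sigma_e, x$sigma_r, x$D, x$T))
  stop("cannot interpret 'params' as observer parameters")
}
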