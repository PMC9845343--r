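## Bayesian cue-combination ideal observer.
##
## The observer measures the gaze displacement between the two bar exposures
## (extraretinal cue, x_e) and the residual retinal misalignment caused by
## display quantization (retinal cue, x_r), both corrupted by additive
## Gaussian noise.  It holds a prior that ocular drift is Brownian, i.e. the
## true displacement over the ISI is N(0, sqrt(2 D T)), and a uniform prior
## over the retinal misalignment.  The posterior over the Vernier offset
## X = X_E + X_R is Gaussian; the report is the side with the larger mass.

# weight of the extraretinal cue in the posterior mean; 0 when D = 0 or
# sigma_e = Inf, 1 when sigma_e = 0 (and D > 0)
obs_weight <- function(params) {
  two_dt <- 2 * params$D * params$T
  if (two_dt == 0) return(0)
  two_dt / (params$sigma_e^2 + two_dt)
}

# posterior variance of X_E given the extraretinal measurement:
# 2DT sigma_e^2 / (sigma_e^2 + 2DT), written to be stable at sigma_e = Inf
obs_post_var_e <- function(params) {
  two_dt <- 2 * params$D * params$T
  if (two_dt == 0) return(0)
  if (is.infinite(params$sigma_e)) return(two_dt)
  two_dt / (1 + two_dt / params$sigma_e^2)
}

#' Extraretinal cue weight
#'
#' The weight `w = 2DT / (sigma_e^2 + 2DT)` that the ideal observer's
#' posterior mean assigns to the measured gaze displacement. `w = 0` when the
#' Brownian prior is degenerate (`D = 0`) or the extraretinal measurement is
#' useless (`sigma_e = Inf`); `w = 1` when the measurement is noiseless.
#'
#' @param params An [observer_params()] object.
#' @return A number in `[0, 1]`.
#' @examples
#' extraretinal_weight(observer_params(4, 0.5, 0.08, 100)) # 2DT = 16 -> 0.5
#' @export
extraretinal_weight <- function(params) {
  params <- as_observer_params(params)
  obs_weight(params)
}

#' Posterior over the Vernier offset given noisy measurements
#'
#' Given noisy sensory measurements of the gaze displacement and the retinal
#' misalignment, returns the Gaussian posterior over the Vernier offset on
#' the display: mean `x_r + w * x_e`, sd
#' `sqrt(sigma_r^2 + 2DT sigma_e^2 / (sigma_e^2 + 2DT))`, together with the
#' probabilities of the two reports, `p_right = P(X > 0)` and
#' `p_left = P(X < 0)`.
#'
#' @param x_e_meas Measured gaze displacement(s), arcmin.
#' @param x_r_meas Measured retinal misalignment(s), arcmin (recycled).
#' @param params An [observer_params()] object.
#' @return A data frame with columns `mean`, `sd`, `p_right`, `p_left`.
#' @examples
#' offset_posterior(2.5, -0.6, observer_params(2, 0.5, 0.08, 100))
#' @export
offset_posterior <- function(x_e_meas, x_r_meas, params) {
  params <- as_observer_params(params)
  n <- max(length(x_e_meas), length(x_r_meas))
  x_e_meas <- rep_len(x_e_meas, n)
  x_r_meas <- rep_len(x_r_meas, n)
  if (any(!is.finite(x_r_meas)) || any(!is.finite(x_e_meas) & obs_weight(params) > 0))
    stop("measurements must be finite")
  w <- obs_weight(params)
  m <- x_r_meas + if (w > 0) w * x_e_meas else 0
  s <- sqrt(params$sigma_r^2 + obs_post_var_e(params))
  p_right <- stats::pnorm(m / s)
  data.frame(mean = m, sd = s, p_right = p_right, p_left = 1 - p_right)
}

#' Report probability of the single-cue (reduced) observers
#'
#' `p_right_extraretinal_only()` is the observer that ignores the retinal
#' cue: the marginal posterior over the offset is
#' `N(w * x_e, sqrt(2DT sigma_e^2/(sigma_e^2 + 2DT)))`.
#' `p_right_retinal_only()` ignores the extraretinal cue: the posterior is
#' `N(x_r, sigma_r)`.
#'
#' @param x_e_meas,x_r_meas Measured cue value(s), arcmin.
#' @param params An [observer_params()] object.
#' @return Probability of reporting "Right", vectorized over measurements.
#' @examples
#' p <- observer_params(2, 0.5, 0.08, 100)
#' p_right_retinal_only(0.5, p) # Phi(1) for x_r = sigma_r
#' @export
p_right_extraretinal_only <- function(x_e_meas, params) {
  params <- as_observer_params(params)
  w <- obs_weight(params)
  v <- obs_post_var_e(params)
  if (w == 0 || v == 0)
    stop("extraretinal-only observer is degenerate (D = 0, sigma_e = 0 or sigma_e = Inf)")
  stats::pnorm(w * x_e_meas / sqrt(v))
}

#' @rdname p_right_extraretinal_only
#' @export
p_right_retinal_only <- function(x_r_meas, params) {
  params <- as_observer_params(params)
  stats::pnorm(x_r_meas / params$sigma_r)
}

#' Marginal report probability given the true cue values
#'
#' Probability that the observer reports "Right" on a trial with TRUE cue
#' values `(x_e, x_r)`, with the Gaussian measurement noise marginalized
#' analytically. For a `"map"` observer (reports the more probable side given
#' its measurements) the decision variable is `xh_r + w * xh_e`, so
#' `P(Right) = pnorm((x_r + w x_e) / sqrt(sigma_r^2 + w^2 sigma_e^2))`.
#' For a `"sample"` observer (reports "Right" with probability equal to its
#' per-measurement posterior mass) the posterior variance is added to the
#' denominator. Reduced variants use the corresponding single cue.
#'
#' This is the per-trial probability used by the maximum-likelihood fit.
#'
#' @param x_e,x_r True cue values, arcmin (vectorized, recycled).
#' @param params An [observer_params()] object.
#' @param variant `"full"`, `"extraretinal_only"` or `"retinal_only"`.
#' @param decision `"map"` (default) or `"sample"`.
#' @return Vector of probabilities of a "Right" report.
#' @export
p_right_response <- function(x_e, x_r, params,
                             variant = c("full", "extraretinal_only", "retinal_only"),
                             decision = c("map", "sample")) {
  params <- as_observer_params(params)
  variant <- match.arg(variant)
  decision <- match.arg(decision)
  n <- max(length(x_e), length(x_r))
  x_e <- rep_len(x_e, n)
  x_r <- rep_len(x_r, n)
  w <- obs_weight(params)
  v_e <- obs_post_var_e(params)        # posterior variance of X_E term
  w2se2 <- w * v_e                     # equals w^2 * sigma_e^2, stable at Inf
  switch(variant,
    full = {
      num <- x_r + if (w > 0) w * x_e else 0
      var_meas <- params$sigma_r^2 + w2se2
      var_dec <- var_meas + if (decision == "sample") params$sigma_r^2 + v_e else 0
      stats::pnorm(num / sqrt(var_dec))
    },
    extraretinal_only = {
      if (w == 0 || v_e == 0)
        stop("extraretinal-only observer is degenerate for these parameters")
      var_dec <- w2se2 + if (decision == "sample") v_e else 0
      stats::pnorm(w * x_e / sqrt(var_dec))
    },
    retinal_only = {
      var_dec <- params$sigma_r^2 * if (decision == "sample") 2 else 1
      stats::pnorm(x_r / sqrt(var_dec))
    })
}

#' Brute-force quadrature oracle for the report probability
#'
#' Numerically integrates the unnormalized joint posterior over
#' `(X_E, X_R)` -- Gaussian likelihoods for the two measurements times a
#' prior that is `N(0, sqrt(2DT))` in `X_E` and uniform in `X_R` -- over the
#' half-plane `X_E + X_R > 0`, and returns the normalized mass. Composite
#' Simpson quadrature is used in both dimensions, with the inner integration
#' limits placed exactly on the decision boundary so the kink costs no
#' accuracy. Intended as an independent check of the closed-form posterior;
#' it shares no code with [offset_posterior()].
#'
#' @param x_e_meas,x_r_meas Measured cue values, arcmin (scalars).
#' @param params An [observer_params()] object (finite `sigma_e`, `D > 0`).
#' @param n_grid Number of Simpson intervals per dimension (even).
#' @param span_sd Half-width of the integration box in posterior sds (>= 6).
#' @param check If `TRUE`, recompute with half the step and error out if the
#'   two results differ by more than `1e-7`.
#' @return `P(Right)` as a scalar.
#' @export
posterior_2d_oracle <- function(x_e_meas, x_r_meas, params,
                                n_grid = 600L, span_sd = 8, check = FALSE) {
  params <- as_observer_params(params)
  stopifnot(length(x_e_meas) == 1L, length(x_r_meas) == 1L,
            is.finite(x_e_meas), is.finite(x_r_meas))
  if (span_sd < 6) stop("'span_sd' must cover at least 6 sd per dimension")
  if (!is.finite(params$sigma_e) || params$D <= 0)
    stop("oracle requires finite sigma_e and D > 0")
  if (n_grid %% 2L != 0L) n_grid <- n_grid + 1L

  mass <- function(n) {
    se <- params$sigma_e; sr <- params$sigma_r
    sp <- sqrt(2 * params$D * params$T)
    # X_E box: cover both the likelihood and the prior
    lo_e <- min(x_e_meas - span_sd * se, -span_sd * sp)
    hi_e <- max(x_e_meas + span_sd * se, span_sd * sp)
    lo_r <- x_r_meas - span_sd * sr
    hi_r <- x_r_meas + span_sd * sr
    w_simp <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
    s01 <- seq(0, 1, length.out = n + 1L)
    inner <- function(a) {
      # a: vector of lower bounds, one per X_E node; returns column integrals
      len <- pmax(hi_r - a, 0)
      pts <- outer(s01, len) + rep(a, each = n + 1L)     # (n+1) x (n+1)
      dens <- stats::dnorm(x_r_meas, pts, sr)
      colSums(dens * w_simp) * len / (3 * n)
    }
    # The half-plane mass as a function of X_E turns over on the scale of
    # sigma_r around X_E = -x_r_meas; refine the outer grid there so a small
    # sigma_r is resolved regardless of the overall box size.
    edges <- sort(unique(pmin(pmax(
      c(lo_e, hi_e,
        -x_r_meas + c(-1, 1) * span_sd * sr,     # decision-boundary turnover
        x_e_meas + c(-1, 1) * span_sd * se,      # likelihood support
        c(-1, 1) * span_sd * sp),                # prior support
      lo_e), hi_e)))
    den_full <- inner(lo_r)   # full-range X_R integral, same for every column
    num <- 0; den <- 0
    for (k in seq_len(length(edges) - 1L)) {
      a <- edges[k]; b <- edges[k + 1L]
      if (b <= a) next
      xe <- seq(a, b, length.out = n + 1L)
      f_e <- stats::dnorm(x_e_meas, xe, se) * stats::dnorm(xe, 0, sp)
      h_e <- (b - a) / n
      num <- num + sum(w_simp * f_e * inner(pmax(-xe, lo_r))) * h_e / 3
      den <- den + sum(w_simp * f_e) * den_full * h_e / 3
    }
    num / den
  }
  p <- mass(n_grid)
  if (check) {
    p2 <- mass(2L * n_grid)
    if (abs(p - p2) > 1e-7)
      stop(sprintf("quadrature not converged: |delta| = %.3g at n_grid = %d",
                   abs(p - p2), n_grid))
    p <- p2
  }
  p
}

#' Turn a report probability into a Left/Right decision
#'
#' `mode = "map"` reports "Right" iff `p_right > 0.5`; an exact tie is broken
#' at random (seeded) or deterministically according to `tie`.
#' `mode = "sample"` reports "Right" with probability `p_right`.
#'
#' @param p_right Probability (or vector) of a "Right" report.
#' @param mode `"map"` or `"sample"`.
#' @param seed Optional integer seed making tie-breaks/sampling reproducible.
#' @param tie Tie policy for `mode = "map"`: `"random"`, `"left"` or `"right"`.
#' @return Character vector of `"Left"` / `"Right"`.
#' @export
decide_response <- function(p_right, mode = c("map", "sample"), seed = NULL,
                            tie = c("random", "left", "right")) {
  mode <- match.arg(mode)
  tie <- match.arg(tie)
  stopifnot(all(p_right >= 0 & p_right <= 1))
  if (!is.null(seed)) set.seed(seed)
  if (mode == "map") {
    out <- ifelse(p_right > 0.5, "Right", "Left")
    ties <- p_right == 0.5
    if (any(ties)) {
      out[ties] <- switch(tie,
        random = ifelse(stats::runif(sum(ties)) < 0.5, "Left", "Right"),
        left = "Left", right = "Right")
    }
    out
  } else {
    ifelse(stats::runif(length(p_right)) < p_right, "Right", "Left")
  }
}

# -1/+1 coding of responses ("Left" -> -1, "Right" -> +1)
binarize_response <- function(response) {
  out <- ifelse(response == "Right", 1, ifelse(response == "Left", -1, NA_real_))
  if (any(is.na(out))) stop("responses must be 'Left' or 'Right'")
  out
}
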