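## Synthetic gaze-contingent Vernier experiment.
##
## All positions are in arcmin, all times in ms on a 1 kHz grid.  Sign
## convention: positive x is rightward on the display; a positive Vernier
## offset means the bottom bar is right of the top bar and "Right" is the
## correct report.

#' Simulate a Brownian ocular drift trace
#'
#' Horizontal and vertical gaze position evolve as independent Brownian
#' paths sampled exactly on a 1 ms grid: each 1 ms increment is drawn from
#' `N(0, sqrt(2 * D))` per axis, so displacement variance over a lag `dt` is
#' `2 * D * dt`. All samples are labelled `"drift"`.
#'
#' @param D Diffusion coefficient, arcmin^2/ms (`>= 0`).
#' @param duration Trace duration in ms (`>= 1`).
#' @param seed Optional integer seed; identical seeds give identical traces.
#' @param start Starting `(x, y)` position, arcmin.
#' @return An `eye_trace`: data frame with columns `t` (ms), `x`, `y`
#'   (arcmin) and `label` (`"drift"`, `"saccade"` or `"lost"`).
#' @examples
#' tr <- simulate_drift_trace(D = 0.08, duration = 1000, seed = 1)
#' sd(diff(tr$x, lag = 100)) # about sqrt(2 * 0.08 * 100) = 4 arcmin
#' @export
simulate_drift_trace <- function(D, duration, seed = NULL, start = c(0, 0)) {
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D < 0)
    stop("'D' must be a single number >= 0")
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) || duration < 1)
    stop("'duration' must be >= 1 ms")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(floor(duration))
  step_sd <- sqrt(2 * D)
  x <- start[1] + c(0, cumsum(stats::rnorm(n, 0, step_sd)))
  y <- start[2] + c(0, cumsum(stats::rnorm(n, 0, step_sd)))
  trace <- data.frame(t = 0:n, x = x, y = y,
                      label = rep("drift", n + 1L),
                      stringsAsFactors = FALSE)
  class(trace) <- c("eye_trace", "data.frame")
  trace
}

validate_trace <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("t", "x", "y", "label") %in% names(trace)))
  dt <- diff(trace$t)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9))
    stop("trace must be on a uniform, strictly increasing time grid")
  ok <- trace$label != "lost"
  if (any(!is.finite(trace$x[ok])) || any(!is.finite(trace$y[ok])))
    stop("trace has non-finite positions outside 'lost' periods")
  invisible(trace)
}

# nearest sample index for time t (ms) on the trace grid
trace_index <- function(trace, t) {
  i <- round((t - trace$t[1]) / (trace$t[2] - trace$t[1])) + 1L
  if (any(i < 1L | i > nrow(trace))) stop("time outside trace extent")
  as.integer(i)
}

#' Insert artificial saccades into a trace
#'
#' Adds raised-cosine horizontal ramps (smooth step displacements) to a
#' trace. A ramp of amplitude `A` over `d` ms has peak speed `A * pi / (2 d)`
#' arcmin/ms, so e.g. 30 arcmin over 20 ms peaks near 39 deg/s, far above
#' the 3 deg/s segmentation threshold. Labels are left untouched; the ground
#' truth is returned in the `"saccade_truth"` attribute for use in tests of
#' the segmentation.
#'
#' @param trace An eye trace.
#' @param times Saccade onset times, ms.
#' @param amplitudes Horizontal amplitudes, arcmin (recycled).
#' @param saccade_duration Ramp duration, ms (recycled).
#' @return The modified trace with attribute `saccade_truth` (data frame
#'   with `start`, `end`, `amplitude`).
#' @export
inject_saccades <- function(trace, times, amplitudes, saccade_duration = 20) {
  validate_trace(trace)
  if (length(times) == 0L) return(trace)
  amplitudes <- rep_len(amplitudes, length(times))
  dur <- rep_len(saccade_duration, length(times))
  o <- order(times)
  times <- times[o]; amplitudes <- amplitudes[o]; dur <- dur[o]
  if (any(times < trace$t[1] | times + dur > trace$t[nrow(trace)]))
    stop("saccade extends outside trace extent")
  if (any(diff(times) < dur[-length(dur)]))
    stop("saccades overlap")
  for (k in seq_along(times)) {
    i0 <- trace_index(trace, times[k])
    i1 <- trace_index(trace, times[k] + dur[k])
    u <- seq(0, 1, length.out = i1 - i0 + 1L)
    ramp <- amplitudes[k] * (1 - cos(pi * u)) / 2
    trace$x[i0:i1] <- trace$x[i0:i1] + ramp
    if (i1 < nrow(trace))
      trace$x[(i1 + 1L):nrow(trace)] <- trace$x[(i1 + 1L):nrow(trace)] + amplitudes[k]
  }
  attr(trace, "saccade_truth") <- data.frame(start = times, end = times + dur,
                                             amplitude = amplitudes)
  trace
}

# nearest integer multiple index of `pitch`, ties away from zero
quantize_index <- function(x, pitch) {
  k <- x / pitch
  r <- floor(k + 0.5)                       # half up
  tie <- abs(k + 0.5 - round(k + 0.5)) < 1e-12 & k < 0
  r[tie] <- r[tie] - 1                      # negative half-ties away from zero
  r
}

# round to the nearest integer multiple of `pitch`, ties away from zero
quantize_position <- function(x, pitch) quantize_index(x, pitch) * pitch

#' Generate one gaze-contingent Vernier trial from a trace
#'
#' The first bar is exposed at a random time `t1` uniform on 1000--2000 ms
#' (the random delay after fixation-marker offset), the second at
#' `t2 = t1 + isi_T`. Each bar is rendered at the display pixel/LED column
#' nearest to the gaze position at its exposure time, so the displayed
#' Vernier offset is the quantized gaze displacement: `x_display = x_e + x_r`
#' where `x_e = x(t2) - x(t1)` is the true gaze displacement and `x_r` the
#' quantization residual (`|x_r| < pixel_pitch`).
#'
#' @param trace An eye trace covering at least `[0, 2000 + isi_T]` ms.
#' @param isi_T Inter-stimulus interval, ms.
#' @param pixel_pitch Display quantization step, arcmin (1.4 for the CRT,
#'   1.9 for the LED array).
#' @param seed Optional integer seed (trial timing and bar order).
#' @param trial_id Identifier stored in the record.
#' @return A one-row data frame (a `TrialRecord`) with columns `trial_id`,
#'   `isi_T`, `t1`, `t2`, `x_e`, `x_r`, `x_display`, `bottom_first`,
#'   `response` (`NA` until filled in), `pixel_pitch`.
#' @export
generate_trial <- function(trace, isi_T, pixel_pitch, seed = NULL, trial_id = 1L) {
  validate_trace(trace)
  if (!is.null(seed)) set.seed(seed)
  if (trace$t[nrow(trace)] < 2000 + isi_T || trace$t[1] > 1000)
    stop("trace too short to place the bar exposures (needs [1000, 2000 + isi_T] ms)")
  t1 <- sample(1000:2000, 1L)
  t2 <- t1 + isi_T
  g1 <- trace$x[trace_index(trace, t1)]
  g2 <- trace$x[trace_index(trace, t2)]
  k1 <- quantize_index(g1, pixel_pitch)
  k2 <- quantize_index(g2, pixel_pitch)
  x_e <- g2 - g1
  x_display <- (k2 - k1) * pixel_pitch   # exact multiple, no rounding noise
  data.frame(trial_id = trial_id, isi_T = isi_T, t1 = t1, t2 = t2,
             x_e = x_e, x_r = x_display - x_e, x_display = x_display,
             bottom_first = stats::runif(1) < 0.5,
             response = NA_character_, pixel_pitch = pixel_pitch,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic experimental session
#'
#' Simulates `n_trials` independent Brownian drift traces and one Vernier
#' trial per trace, optionally filling in responses from a generative noisy
#' observer. Defaults reproduce the study conditions of the LED experiment
#' at the short ISI: `D = 0.08` arcmin^2/ms (100 ms displacements spread
#' around +/-4 arcmin), `isi_T = 100` ms, `pixel_pitch = 1.9` arcmin.
#'
#' @param n_trials Number of trials.
#' @param D Diffusion coefficient, arcmin^2/ms.
#' @param isi_T Inter-stimulus interval, ms.
#' @param pixel_pitch Display quantization step, arcmin.
#' @param seed Integer master seed; trace, trial and response substreams are
#'   derived from it deterministically.
#' @param params Optional [observer_params()]; if supplied, responses are
#'   generated with [generate_responses()].
#' @param variant,mode Passed to [generate_responses()].
#' @param trace_duration Trace length in ms; must cover the bar exposures
#'   plus any reverse-correlation windows to be analysed later.
#' @return A list with elements `trials` (data frame, one row per trial) and
#'   `traces` (list of eye traces, parallel to `trials`).
#' @export
generate_session <- function(n_trials, D = 0.08, isi_T = 100, pixel_pitch = 1.9,
                             seed = 1L, params = NULL, variant = "full",
                             mode = "map", trace_duration = 2000 + isi_T + 500) {
  stopifnot(n_trials >= 1)
  trial_seeds <- derive_seeds(seed, "session", 2L * n_trials)
  traces <- vector("list", n_trials)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    traces[[i]] <- simulate_drift_trace(D, trace_duration, seed = trial_seeds[2L * i - 1L])
    rows[[i]] <- generate_trial(traces[[i]], isi_T, pixel_pitch,
                                seed = trial_seeds[2L * i], trial_id = i)
  }
  trials <- do.call(rbind, rows)
  if (!is.null(params))
    trials <- generate_responses(trials, params, variant = variant, mode = mode,
                                 seed = derive_seeds(seed, "responses", 1L))
  list(trials = trials, traces = traces)
}

#' Draw observer responses for a table of trials
#'
#' For each trial, noisy measurements `xh_e ~ N(x_e, sigma_e)` and
#' `xh_r ~ N(x_r, sigma_r)` are drawn and the decision rule of the stated
#' observer variant is applied to them: `"map"` reports the side with the
#' larger posterior mass, `"sample"` reports "Right" with probability equal
#' to the posterior mass on the right.
#'
#' @param trials Trial table with columns `x_e`, `x_r`.
#' @param params An [observer_params()] object.
#' @param variant `"full"`, `"extraretinal_only"` or `"retinal_only"`.
#' @param mode Decision mode, `"map"` (default) or `"sample"`.
#' @param seed Integer seed; identical seeds give identical responses.
#' @return `trials` with the `response` column filled with `"Left"`/`"Right"`.
#' @export
generate_responses <- function(trials, params,
                               variant = c("full", "extraretinal_only", "retinal_only"),
                               mode = c("map", "sample"), seed = NULL) {
  params <- as_observer_params(params)
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  stopifnot(all(c("x_e", "x_r") %in% names(trials)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  w <- obs_weight(params)
  xh_e <- if (is.finite(params$sigma_e) && w > 0)
    stats::rnorm(n, trials$x_e, params$sigma_e) else rep(0, n)
  xh_r <- stats::rnorm(n, trials$x_r, params$sigma_r)
  p_right <- switch(variant,
    full = offset_posterior(xh_e, xh_r, params)$p_right,
    extraretinal_only = p_right_extraretinal_only(xh_e, params),
    retinal_only = p_right_retinal_only(xh_r, params))
  trials$response <- decide_response(p_right, mode = mode)
  trials
}

#' Retinal leakage from a miscalibrated eye tracker
#'
#' Models a tracker whose measured displacement is `gain` times the true
#' displacement. Bars are rendered at the *measured* gaze, so a systematic
#' offset `(1 - 1/gain)` times the measured displacement leaks onto the
#' retina. The function simulates sessions at each gain and reports the
#' proportion correct achievable by an observer using ONLY the leaked
#' retinal cue (noise `sigma_r`), i.e. how much task performance tracker
#' miscalibration alone could produce.
#'
#' @param gains Vector of tracker gains (> 0); 1 = perfect calibration.
#' @param D,isi_T,pixel_pitch Simulation parameters as in [generate_session()].
#' @param n_trials Trials per gain.
#' @param sigma_r Retinal measurement noise of the probe observer, arcmin.
#' @param seed Integer seed.
#' @return Data frame with columns `gain`, `prop_correct`, `n`.
#' @export
simulate_tracker_gain_error <- function(gains, D = 0.08, isi_T = 100,
                                        pixel_pitch = 1.9, n_trials = 2000,
                                        sigma_r = 0.5, seed = 1L) {
  if (any(gains <= 0)) stop("'gains' must be > 0")
  out <- lapply(seq_along(gains), function(k) {
    g <- gains[k]
    set.seed(derive_seeds(seed, "tracker", length(gains))[k])
    x_e <- stats::rnorm(n_trials, 0, sqrt(2 * D * isi_T))   # true displacement
    meas <- g * x_e                                         # tracker output
    # bars rendered at measured gaze: retinal offset = rendered - true
    rendered <- quantize_position(meas, pixel_pitch) -
      quantize_position(0, pixel_pitch)
    leak <- rendered - x_e
    x_display <- rendered
    keep <- x_display != 0
    params <- observer_params(Inf, sigma_r, D, isi_T)
    p_right <- p_right_retinal_only(stats::rnorm(sum(keep), leak[keep], sigma_r),
                                    params)
    resp <- decide_response(p_right, mode = "map")
    correct <- (resp == "Right") == (x_display[keep] > 0)
    data.frame(gain = g, prop_correct = mean(correct), n = sum(keep))
  })
  do.call(rbind, out)
}

# Deterministic substream seeds below 2^31, derived from a master seed and a
# stage name; avoids correlated streams across pipeline stages.
derive_seeds <- function(seed, stage, n) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  base <- (as.double(seed) * 48271 + h * 16807) %% 2147483629
  as.integer((base + 9973 * seq_len(n)) %% 2147483629 + 1)
}
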