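## Reverse-correlation temporal-window analysis: find the interval of gaze
## displacement whose value best predicts the binary perceptual reports, by
## scanning a grid of window durations T_W and lags dt_W (lag of the window
## center relative to the onset of the first bar).

#' Gaze displacement over an observation window
#'
#' `dx = x(t_ref + dt_w + t_w/2) - x(t_ref + dt_w - t_w/2)`, with endpoints
#' taken at the nearest trace samples (no interpolation; immaterial on a
#' 1 ms grid).
#'
#' @param trace An eye trace.
#' @param t_ref Reference time (onset of the first bar), ms.
#' @param dt_w Lag of the window center relative to `t_ref`, ms.
#' @param t_w Window duration, ms.
#' @return Displacement in arcmin.
#' @export
window_displacement <- function(trace, t_ref, dt_w, t_w) {
  validate_trace(trace)
  i1 <- trace_index(trace, t_ref + dt_w - t_w / 2)
  i2 <- trace_index(trace, t_ref + dt_w + t_w / 2)
  trace$x[i2] - trace$x[i1]
}

#' Correlation between windowed gaze displacement and reports
#'
#' For each cell of a (duration, lag) grid, computes the Pearson
#' correlation between the responses in binary format (-1 for "Left", +1
#' for "Right") and the per-trial gaze displacement in the window
#' `[dt_w - t_w/2, dt_w + t_w/2]` relative to the onset of the first bar.
#' Cells whose window extends past the trace extent in any trial are
#' dropped (`NA`), not padded.
#'
#' @param trials Trial table with `t1` and responses.
#' @param traces List of eye traces parallel to the rows of `trials`.
#' @param dt_range Lag range `c(min, max)` in ms (default -200..300).
#' @param tw_range Duration range `c(min, max)` in ms (default 20..300).
#' @param step Grid step in ms (default 10).
#' @return A `window_grid` object: `rho` matrix (durations x lags),
#'   `durations`, `lags`, `n_trials`.
#' @export
correlation_grid <- function(trials, traces, dt_range = c(-200, 300),
                             tw_range = c(20, 300), step = 10) {
  stopifnot(all(c("t1", "response") %in% names(trials)))
  n <- nrow(trials)
  if (n < 20L) stop("need at least 20 trials")
  if (length(traces) != n) stop("need one trace per trial")
  z <- binarize_response(trials$response)
  lags <- seq(dt_range[1], dt_range[2], by = step)
  durs <- seq(tw_range[1], tw_range[2], by = step)
  # endpoint offsets needed: dt +/- tw/2 over the whole grid
  offs <- sort(unique(c(outer(lags, durs / 2, `+`), outer(lags, durs / 2, `-`))))
  # per-trial positions at t1 + off, NA when outside the trace
  pos <- matrix(NA_real_, n, length(offs))
  for (i in seq_len(n)) {
    tr <- traces[[i]]
    tt <- trials$t1[i] + offs
    idx <- round((tt - tr$t[1]) / (tr$t[2] - tr$t[1])) + 1
    ok <- idx >= 1 & idx <= nrow(tr)
    pos[i, ok] <- tr$x[idx[ok]]
  }
  colnames(pos) <- format(offs)
  rho <- matrix(NA_real_, length(durs), length(lags),
                dimnames = list(T_W = durs, dt_W = lags))
  for (a in seq_along(durs)) {
    for (b in seq_along(lags)) {
      j1 <- match(lags[b] - durs[a] / 2, offs)
      j2 <- match(lags[b] + durs[a] / 2, offs)
      dx <- pos[, j2] - pos[, j1]
      if (any(is.na(dx))) next               # window leaves the trace: drop
      if (stats::sd(dx) == 0 || stats::sd(z) == 0) next
      rho[a, b] <- stats::cor(dx, z)
    }
  }
  structure(list(rho = rho, durations = durs, lags = lags, n_trials = n,
                 step = step),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("Window correlation grid: %d durations x %d lags, %d trials; max rho = %.3f\n",
              length(x$durations), length(x$lags), x$n_trials,
              max(x$rho, na.rm = TRUE)))
  invisible(x)
}

#' Locate the peak of a window correlation grid
#'
#' Returns the (duration, lag) cell with the maximum correlation, the
#' window onset relative to the first bar (`dt_w - t_w/2`; negative onset
#' means the window anticipates the stimulus), and, optionally, a bootstrap
#' over trials of the peak location.
#'
#' @param grid A `window_grid`.
#' @param trials,traces If supplied (with `n_boot > 0`), trials are
#'   resampled with replacement and the grid and peak recomputed to give
#'   the spread of the peak location.
#' @param n_boot Number of bootstrap resamples (0 = none).
#' @param seed Integer seed for the bootstrap.
#' @return List with `t_w`, `dt_w`, `rho`, `onset`, `ties` (all argmax
#'   cells, flagged if more than one) and optionally `boot` (data frame of
#'   resampled peaks with sds).
#' @export
find_peak <- function(grid, trials = NULL, traces = NULL, n_boot = 0,
                      seed = 1L) {
  stopifnot(inherits(grid, "window_grid"))
  if (all(is.na(grid$rho))) stop("empty grid: every cell undefined")
  mx <- max(grid$rho, na.rm = TRUE)
  idx <- which(grid$rho >= mx - 1e-12, arr.ind = TRUE)
  ties <- data.frame(t_w = grid$durations[idx[, 1]],
                     dt_w = grid$lags[idx[, 2]], rho = mx)
  peak <- list(t_w = ties$t_w[1], dt_w = ties$dt_w[1], rho = mx,
               onset = ties$dt_w[1] - ties$t_w[1] / 2,
               ties = ties, multiple = nrow(ties) > 1L)
  if (peak$multiple)
    warning("multiple global maxima; all returned in $ties")
  if (n_boot > 0) {
    if (is.null(trials) || is.null(traces))
      stop("bootstrap needs 'trials' and 'traces'")
    seeds <- derive_seeds(seed, "peakboot", n_boot)
    boots <- do.call(rbind, lapply(seq_len(n_boot), function(b) {
      set.seed(seeds[b])
      i <- sample.int(nrow(trials), nrow(trials), replace = TRUE)
      g <- correlation_grid(trials[i, , drop = FALSE], traces[i],
                            dt_range = range(grid$lags),
                            tw_range = range(grid$durations),
                            step = grid$step)
      m <- which.max(g$rho)
      ai <- arrayInd(m, dim(g$rho))
      data.frame(t_w = g$durations[ai[1]], dt_w = g$lags[ai[2]])
    }))
    boots$onset <- boots$dt_w - boots$t_w / 2
    peak$boot <- boots
    peak$sd_t_w <- stats::sd(boots$t_w)
    peak$sd_dt_w <- stats::sd(boots$dt_w)
    peak$sd_onset <- stats::sd(boots$onset)
  }
  peak
}
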