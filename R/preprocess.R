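## Segmentation of eye traces into drift and saccade periods, the trial
## exclusion rule (drift-only analysis), and drift statistics.

# 1 arcmin/ms = 1000/60 deg/s
ARCMIN_PER_MS_TO_DEG_PER_S <- 1000 / 60

# symmetric Hamming-window FIR low-pass, unit DC gain, edge-replicated
fir_smooth <- function(x, taps = 41L) {
  if (taps < 3L || taps %% 2L == 0L) stop("'taps' must be odd and >= 3")
  k <- seq_len(taps) - 1L
  h <- 0.54 - 0.46 * cos(2 * pi * k / (taps - 1L))
  h <- h / sum(h)
  half <- (taps - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, h, sides = 2L))[(half + 1L):(half + length(x))]
}

#' Segment an eye trace into drift and saccade periods
#'
#' Instantaneous speed is computed by central differences of the FIR-smoothed
#' horizontal and vertical position. Runs of samples whose speed exceeds the
#' threshold are labelled saccades; supra-threshold runs separated by less
#' than `merge_ms` are merged, and merged runs shorter than `min_duration_ms`
#' are discarded. Everything else is drift, so the intervals tile the trace.
#'
#' Raw 1 kHz differences of a Brownian path have speeds far above any
#' physiological threshold, so a documented smoother is what makes a speed
#' criterion meaningful on sampled data. The default 121-tap kernel puts the
#' smoothed Brownian drift speed sd (D = 0.08 arcmin^2/ms) near 0.6 deg/s,
#' making 3 deg/s a five-sigma event, while 20 ms saccades remain far above
#' threshold; the smoother is configurable and echoed in the result.
#'
#' @param trace An eye trace on a uniform 1 ms grid (>= 3 samples).
#' @param speed_threshold Saccade threshold in deg/s (default 3).
#' @param smooth_taps FIR length in samples (odd; default 121).
#' @param merge_ms Merge window between supra-threshold runs, ms.
#' @param min_duration_ms Minimum saccade duration, ms.
#' @return A `segmentation` object: list with `intervals` (data frame
#'   `start`, `end`, `category`), `speed` (deg/s per sample),
#'   `speed_threshold`, and the smoother settings.
#' @export
segment_trace <- function(trace, speed_threshold = 3, smooth_taps = 121L,
                          merge_ms = 15, min_duration_ms = 6) {
  validate_trace(trace)
  n <- nrow(trace)
  if (n < 3L) stop("trace must have at least 3 samples")
  dt <- trace$t[2] - trace$t[1]
  if (abs(dt - 1) > 1e-9) stop("segmentation expects a 1 ms grid")
  xs <- fir_smooth(trace$x, smooth_taps)
  ys <- fir_smooth(trace$y, smooth_taps)
  cd <- function(p) c(p[2] - p[1], (p[3:n] - p[1:(n - 2L)]) / 2, p[n] - p[n - 1L])
  speed <- sqrt(cd(xs)^2 + cd(ys)^2) * ARCMIN_PER_MS_TO_DEG_PER_S
  supra <- speed > speed_threshold

  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sac <- which(runs$values)
  # merge saccade runs separated by sub-threshold gaps shorter than merge_ms
  if (length(sac) > 1L) {
    merged <- list(c(starts[sac[1]], ends[sac[1]]))
    for (k in sac[-1]) {
      last <- merged[[length(merged)]]
      if ((starts[k] - last[2] - 1L) * dt < merge_ms)
        merged[[length(merged)]][2] <- ends[k]
      else merged[[length(merged) + 1L]] <- c(starts[k], ends[k])
    }
  } else if (length(sac) == 1L) {
    merged <- list(c(starts[sac], ends[sac]))
  } else merged <- list()
  merged <- Filter(function(iv) (iv[2] - iv[1] + 1L) * dt >= min_duration_ms, merged)

  is_sac <- rep(FALSE, n)
  for (iv in merged) is_sac[iv[1]:iv[2]] <- TRUE
  runs2 <- rle(is_sac)
  e2 <- cumsum(runs2$lengths); s2 <- e2 - runs2$lengths + 1L
  intervals <- data.frame(start = trace$t[s2], end = trace$t[e2],
                          category = ifelse(runs2$values, "saccade", "drift"),
                          stringsAsFactors = FALSE)
  structure(list(intervals = intervals, speed = speed,
                 speed_threshold = speed_threshold,
                 smooth_taps = smooth_taps, merge_ms = merge_ms,
                 min_duration_ms = min_duration_ms),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  ns <- sum(x$intervals$category == "saccade")
  cat(sprintf("Trace segmentation: %d interval(s), %d saccade(s); threshold %g deg/s (%d-tap FIR)\n",
              nrow(x$intervals), ns, x$speed_threshold, x$smooth_taps))
  invisible(x)
}

#' Keep only trials whose stimulus window is pure drift
#'
#' Implements the drift-only exclusion rule: a trial survives only if its
#' whole window `[t1 - guard, t2 + guard]` lies inside drift-labelled
#' intervals of its segmentation (no saccades or microsaccades; anything
#' supra-threshold excludes the trial).
#'
#' @param trials Trial table with `t1`, `t2` (and `trial_id`).
#' @param segmentations A single `segmentation` shared by all trials, or a
#'   list parallel to the rows of `trials`.
#' @param guard Guard margin in ms added on both sides (default 0).
#' @return The surviving rows of `trials`.
#' @export
exclude_non_drift_trials <- function(trials, segmentations, guard = 0) {
  stopifnot(all(c("t1", "t2") %in% names(trials)))
  one <- inherits(segmentations, "segmentation")
  if (!one && length(segmentations) != nrow(trials))
    stop("need one segmentation per trial (or a single shared one)")
  keep <- vapply(seq_len(nrow(trials)), function(i) {
    seg <- if (one) segmentations else segmentations[[i]]
    if (!inherits(seg, "segmentation")) stop("missing segmentation for trial ", i)
    iv <- seg$intervals
    lo <- trials$t1[i] - guard; hi <- trials$t2[i] + guard
    if (lo < min(iv$start) || hi > max(iv$end))
      stop("segmentation does not cover trial window for trial ", i)
    sac <- iv[iv$category == "saccade", , drop = FALSE]
    !any(sac$start <= hi & sac$end >= lo)
  }, logical(1))
  trials[keep, , drop = FALSE]
}

#' Estimate the drift diffusion coefficient from traces
#'
#' Computes the empirical variance of the horizontal gaze displacement
#' `x(t + lag) - x(t)` at each requested lag, restricted to spans entirely
#' labelled drift, and regresses variance on lag by ordinary least squares.
#' Under Brownian drift the variance is `2 D lag`, so `D_hat = slope / 2`;
#' the intercept absorbs any lag-independent noise floor and is reported but
#' not used for `D_hat`.
#'
#' @param traces One eye trace or a list of them.
#' @param lags Lags in ms (>= 2 of them). The default spans the 100 ms ISI
#'   of the short-interval condition; shorter lags contribute many more
#'   independent displacement pairs, so the slope is sampled tightly.
#' @param min_pairs Minimum displacement pairs required at every lag.
#' @return A `drift_stats` object: `D_hat` (arcmin^2/ms), `slope`,
#'   `intercept`, `r_squared`, and the per-lag variance table.
#' @export
estimate_diffusion <- function(traces, lags = seq(10, 100, by = 10),
                               min_pairs = 100L) {
  if (inherits(traces, "eye_trace") || (is.data.frame(traces) && "x" %in% names(traces)))
    traces <- list(traces)
  if (length(lags) < 2L) stop("need at least 2 lags")
  lags <- as.integer(sort(lags))
  disp <- vector("list", length(lags))
  for (tr in traces) {
    validate_trace(tr)
    drift <- tr$label == "drift"
    for (k in seq_along(lags)) {
      L <- lags[k]
      if (L >= nrow(tr)) next
      i0 <- seq_len(nrow(tr) - L)
      # span must be drift throughout
      cum <- cumsum(!drift)
      ok <- (cum[i0 + L] - c(0, cum)[i0]) == 0
      d <- tr$x[i0 + L][ok] - tr$x[i0][ok]
      disp[[k]] <- c(disp[[k]], d)
    }
  }
  n_pairs <- vapply(disp, length, integer(1))
  if (any(n_pairs < min_pairs))
    stop("insufficient drift data at lag(s) ",
         paste(lags[n_pairs < min_pairs], collapse = ", "), " ms")
  v <- vapply(disp, stats::var, numeric(1))
  fit <- stats::lm(v ~ lags)
  structure(list(D_hat = max(unname(stats::coef(fit)[2]) / 2, 0),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 table = data.frame(lag = lags, variance = v, n = n_pairs)),
            class = "drift_stats")
}

#' @export
print.drift_stats <- function(x, ...) {
  cat(sprintf("Drift diffusion: D_hat = %.4g arcmin^2/ms (slope %.4g, intercept %.4g, R^2 %.4f)\n",
              x$D_hat, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Distribution of gaze displacement between bar exposures
#'
#' Normalized histogram plus summary moments of the extraretinal
#' displacement `x_e` across trials, with a flag for directional bias.
#'
#' @param trials Trial table with column `x_e`.
#' @param binwidth Histogram bin width, arcmin.
#' @param bias_fraction Flag `biased = TRUE` if `|mean| > bias_fraction * sd`.
#' @return List with `breaks`, `density` (integrates to 1), `counts`,
#'   `mean`, `sd`, `skew`, `biased`.
#' @export
displacement_distribution <- function(trials, binwidth = 1, bias_fraction = 0.25) {
  x <- trials$x_e
  if (is.null(x) || length(x) == 0L) stop("no trials with 'x_e'")
  lim <- max(abs(x)) + binwidth
  breaks <- seq(-lim, lim, by = binwidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  m <- mean(x); s <- stats::sd(x)
  skew <- if (s > 0) mean((x - m)^3) / s^3 else 0
  list(breaks = h$breaks, density = h$density, counts = h$counts,
       mean = m, sd = s, skew = skew,
       biased = is.finite(s) && s > 0 && abs(m) > bias_fraction * s)
}
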