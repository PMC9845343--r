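## Performance quantification: proportion correct, d-prime with the Right
## response as the "signal" report, bootstrap significance, binned response
## surfaces over (x_e, x_r), and the opposite-sign control analysis.

# 1/(2N) extreme-rate correction so z-transforms stay finite
clamp_rate <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))

correct_response <- function(trials) {
  (trials$response == "Right") == (trials$x_display > 0)
}

#' Proportion of correct responses per Vernier offset
#'
#' A response is correct when its sign matches the sign of the displayed
#' offset. Zero-offset trials have no defined correct answer and are
#' excluded here (they still enter bias and surface analyses).
#'
#' @param trials Trial table with `x_display` and `response`.
#' @param group_by_offset If `FALSE`, a single overall row is returned.
#' @return Data frame with `offset` (arcmin, magnitude), `n`, `prop_correct`.
#' @export
proportion_correct <- function(trials, group_by_offset = TRUE) {
  t2 <- trials[trials$x_display != 0 & !is.na(trials$response), , drop = FALSE]
  if (nrow(t2) == 0L) stop("no non-zero-offset trials with responses")
  ok <- correct_response(t2)
  if (!group_by_offset)
    return(data.frame(offset = NA_real_, n = nrow(t2), prop_correct = mean(ok)))
  mag <- abs(t2$x_display)
  out <- lapply(sort(unique(mag)), function(m)
    data.frame(offset = m, n = sum(mag == m), prop_correct = mean(ok[mag == m])))
  do.call(rbind, out)
}

#' Discriminability index d-prime per Vernier offset
#'
#' Left/right discrimination mapped onto signal detection with "Right" as
#' the signal report: the hit rate is `P(Right | X > 0)`, the false-alarm
#' rate `P(Right | X < 0)`, and `d' = z(H) - z(F)`. Rates are corrected by
#' the `1/(2N)` rule before the z-transform (switchable), so d-prime is
#' always finite.
#'
#' @param trials Trial table with `x_display` and `response`.
#' @param correction Apply the extreme-rate correction (default `TRUE`).
#' @param drop_incomplete Offsets lacking trials of one sign are an error
#'   by default; set `TRUE` to drop them silently (useful when offsets
#'   arise from unbounded drift and the largest are rare).
#' @return Data frame with `offset`, `n`, `hit_rate`, `fa_rate`, `dprime`.
#' @export
dprime <- function(trials, correction = TRUE, drop_incomplete = FALSE) {
  t2 <- trials[trials$x_display != 0 & !is.na(trials$response), , drop = FALSE]
  if (nrow(t2) == 0L) stop("no non-zero-offset trials with responses")
  mag <- abs(t2$x_display)
  right <- t2$response == "Right"
  out <- lapply(sort(unique(mag)), function(m) {
    pos <- mag == m & t2$x_display > 0
    neg <- mag == m & t2$x_display < 0
    if (!any(pos) || !any(neg)) {
      if (drop_incomplete) return(NULL)
      stop(sprintf("offset %g arcmin lacks trials of one sign", m))
    }
    h <- mean(right[pos]); f <- mean(right[neg])
    if (correction) {
      h <- clamp_rate(h, sum(pos)); f <- clamp_rate(f, sum(neg))
    }
    data.frame(offset = m, n = sum(pos) + sum(neg), hit_rate = h, fa_rate = f,
               dprime = stats::qnorm(h) - stats::qnorm(f))
  })
  do.call(rbind, out)
}

#' Bootstrap test of a trial-level statistic against chance
#'
#' Resamples trials with replacement, recomputes the statistic, and returns
#' a percentile confidence interval together with a bootstrap p-value
#' against the null value (0.5 for accuracies, 0 for d-prime).
#'
#' @param trials Trial table.
#' @param statistic Function `trials -> scalar`.
#' @param n_boot Number of resamples (>= 1000 recommended; enforced >= 100).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param null_value Null value of the statistic (default 0.5).
#' @param conf Confidence level of the percentile interval.
#' @return List with `estimate`, `ci`, `p_value`, `n_boot`, `alternative`.
#' @export
bootstrap_test <- function(trials, statistic, n_boot = 2000, seed = 1L,
                           alternative = c("two.sided", "greater", "less"),
                           null_value = 0.5, conf = 0.95) {
  alternative <- match.arg(alternative)
  if (n_boot < 100) stop("'n_boot' too small for a meaningful test")
  set.seed(seed)
  est <- statistic(trials)
  n <- nrow(trials)
  boots <- vapply(seq_len(n_boot), function(b) {
    s <- statistic(trials[sample.int(n, n, replace = TRUE), , drop = FALSE])
    if (length(s) != 1L) NA_real_ else as.numeric(s)
  }, numeric(1))
  boots <- boots[!is.na(boots)]
  n_boot <- length(boots)
  ci <- unname(stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                               na.rm = TRUE))
  # achieved significance: fraction of the bootstrap distribution on the
  # null side, with the +1 continuity bound
  p_gr <- (sum(boots <= null_value) + 1) / (n_boot + 1)
  p_ls <- (sum(boots >= null_value) + 1) / (n_boot + 1)
  p <- switch(alternative,
              greater = p_gr, less = p_ls,
              two.sided = min(1, 2 * min(p_gr, p_ls)))
  if (stats::sd(boots) == 0)
    p <- if (est == null_value) 1 else 1 / (n_boot + 1)  # degenerate bound
  list(estimate = est, ci = ci, p_value = p, n_boot = n_boot,
       alternative = alternative, null_value = null_value)
}

#' Binned response surface over the two cues
#'
#' Bins trials over `(x_e, x_r)` with equal-count (quantile) bin edges per
#' axis so bins hold a near-constant number of trials, targeting a mean
#' occupancy (60 by default), and tabulates the probability of "Right" per
#' bin. Bins sharing `x_e + x_r` lie on -45 degree lines of constant
#' displayed offset. Also returns the marginal probability of "Right" as a
#' function of `x_e` split by the sign of `x_r`.
#'
#' @param trials Trial table with `x_e`, `x_r`, `response`.
#' @param target_bin_count Target mean trials per bin.
#' @return A `response_surface` object: `bins` (long-format data frame with
#'   `x_e_lo/hi`, `x_r_lo/hi`, `n`, `p_right`), `assign` (bin row per
#'   trial), `edges_x_e`, `edges_x_r`, `marginals`.
#' @export
response_surface <- function(trials, target_bin_count = 60) {
  stopifnot(all(c("x_e", "x_r", "response") %in% names(trials)))
  t2 <- trials[!is.na(trials$response), , drop = FALSE]
  n <- nrow(t2)
  k <- floor(sqrt(n / target_bin_count))
  if (k < 4L) stop("too few trials for at least 4 bins per axis at this target count")
  edges_e <- unique(stats::quantile(t2$x_e, probs = seq(0, 1, length.out = k + 1)))
  edges_r <- unique(stats::quantile(t2$x_r, probs = seq(0, 1, length.out = k + 1)))
  bi_e <- cut(t2$x_e, edges_e, include.lowest = TRUE, labels = FALSE)
  bi_r <- cut(t2$x_r, edges_r, include.lowest = TRUE, labels = FALSE)
  ne <- length(edges_e) - 1L; nr <- length(edges_r) - 1L
  cell <- (bi_r - 1L) * ne + bi_e
  right <- t2$response == "Right"
  bins <- do.call(rbind, lapply(sort(unique(cell)), function(cl) {
    ie <- (cl - 1L) %% ne + 1L; ir <- (cl - 1L) %/% ne + 1L
    sel <- cell == cl
    data.frame(x_e_lo = edges_e[ie], x_e_hi = edges_e[ie + 1L],
               x_r_lo = edges_r[ir], x_r_hi = edges_r[ir + 1L],
               n = sum(sel), p_right = mean(right[sel]))
  }))
  assign <- match(cell, sort(unique(cell)))
  marg <- do.call(rbind, lapply(c(-1, 1), function(s) {
    sel0 <- if (s < 0) t2$x_r < 0 else t2$x_r > 0
    do.call(rbind, lapply(seq_len(ne), function(ie) {
      sel <- sel0 & bi_e == ie
      if (!any(sel)) return(NULL)
      data.frame(x_r_sign = s, x_e_mid = (edges_e[ie] + edges_e[ie + 1L]) / 2,
                 n = sum(sel), p_right = mean(right[sel]))
    }))
  }))
  structure(list(bins = bins, assign = assign, edges_x_e = unname(edges_e),
                 edges_x_r = unname(edges_r), marginals = marg,
                 target_bin_count = target_bin_count,
                 trials_used = which(!is.na(trials$response))),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("Response surface: %d bins, mean occupancy %.1f trials (target %g)\n",
              nrow(x$bins), mean(x$bins$n), x$target_bin_count))
  invisible(x)
}

#' Performance when the two cues disagree in sign
#'
#' Accuracy restricted to the trials in which the retinal misalignment
#' points opposite to the gaze displacement (`sign(x_e) != sign(x_r)`, both
#' nonzero, nonzero displayed offset) -- the trials in which the retinal cue
#' alone predicts the wrong response.
#'
#' @param trials Trial table with responses.
#' @param n_boot,seed,conf Bootstrap settings for the confidence interval
#'   and the test against chance.
#' @return List with `n`, `accuracy`, `ci`, `p_above_chance`,
#'   `p_below_chance`, `by_offset`, and the subset row indices.
#' @export
opposite_sign_performance <- function(trials, n_boot = 2000, seed = 1L,
                                      conf = 0.95) {
  sel <- sign(trials$x_e) != sign(trials$x_r) &
    trials$x_e != 0 & trials$x_r != 0 & trials$x_display != 0 &
    !is.na(trials$response)
  sub <- trials[sel, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no opposite-sign trials")
  acc <- function(tt) mean(correct_response(tt))
  bt_gr <- bootstrap_test(sub, acc, n_boot = n_boot, seed = seed,
                          alternative = "greater", null_value = 0.5, conf = conf)
  bt_ls <- bootstrap_test(sub, acc, n_boot = n_boot, seed = seed,
                          alternative = "less", null_value = 0.5, conf = conf)
  list(n = nrow(sub), accuracy = acc(sub), ci = bt_gr$ci,
       p_above_chance = bt_gr$p_value, p_below_chance = bt_ls$p_value,
       by_offset = proportion_correct(sub), subset = which(sel))
}

#' Pearson correlation between a cue and the binary responses
#'
#' @param trials Trial table with responses.
#' @param cue Column name, e.g. `"x_e"` or `"x_r"`.
#' @return Pearson correlation coefficient.
#' @export
response_correlation <- function(trials, cue = "x_r") {
  if (!cue %in% names(trials)) stop("unknown cue column: ", cue)
  x <- trials[[cue]]
  z <- binarize_response(trials$response)
  if (stats::sd(x) == 0) stop("cue '", cue, "' has zero variance")
  stats::cor(x, z)
}

#' Psychometric summary table per Vernier offset
#'
#' Convenience wrapper combining [proportion_correct()], [dprime()] and
#' per-offset bootstrap tests against chance into one table.
#'
#' @param trials Trial table with responses.
#' @param n_boot,seed Bootstrap settings.
#' @return Data frame with one row per offset magnitude: `n`,
#'   `prop_correct` with CI and p-value vs 0.5, `dprime` with CI and
#'   p-value vs 0.
#' @export
psychometric_summary <- function(trials, n_boot = 2000, seed = 1L) {
  pc <- proportion_correct(trials)
  dp <- dprime(trials, drop_incomplete = TRUE)
  seeds <- derive_seeds(seed, "psummary", 2L * nrow(pc))
  rows <- lapply(seq_len(nrow(pc)), function(i) {
    m <- pc$offset[i]
    sub <- trials[abs(trials$x_display) == m & !is.na(trials$response), ,
                  drop = FALSE]
    bt_pc <- bootstrap_test(sub, function(tt) mean(correct_response(tt)),
                            n_boot = n_boot, seed = seeds[2L * i - 1L],
                            alternative = "greater", null_value = 0.5)
    has_dp <- m %in% dp$offset
    bt_dp <- if (has_dp)
      bootstrap_test(sub, function(tt) {
        d <- dprime(tt, drop_incomplete = TRUE)
        if (is.null(d) || nrow(d) == 0L) NA_real_ else d$dprime[1]
      },
        n_boot = n_boot, seed = seeds[2L * i],
        alternative = "greater", null_value = 0)
    data.frame(offset = m, n = pc$n[i],
               prop_correct = pc$prop_correct[i],
               pc_lo = bt_pc$ci[1], pc_hi = bt_pc$ci[2],
               p_pc_vs_chance = bt_pc$p_value,
               dprime = if (has_dp) dp$dprime[match(m, dp$offset)] else NA_real_,
               dp_lo = if (has_dp) bt_dp$ci[1] else NA_real_,
               dp_hi = if (has_dp) bt_dp$ci[2] else NA_real_,
               p_dp_vs_chance = if (has_dp) bt_dp$p_value else NA_real_)
  })
  do.call(rbind, rows)
}
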