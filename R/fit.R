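## Maximum-likelihood estimation of the observer's sensory noise parameters
## (sigma_e, sigma_r) with D and T fixed, plus model comparison and the
## ISI-scaling predictions.

#' Per-trial response log-likelihood
#'
#' Log-probability that the observer model reproduces each recorded
#' response, `log P(response_i | x_e_i, x_r_i, params)`, using the
#' measurement-noise-marginalized response probability of
#' [p_right_response()]. Probabilities are floored (default `1e-9`) so a
#' single lapse cannot send the log-likelihood to `-Inf`; the number of
#' floored trials is reported in the `"n_clipped"` attribute.
#'
#' @param trials Trial table with `x_e`, `x_r` and `response`.
#' @param params An [observer_params()] object.
#' @param variant,decision Passed to [p_right_response()].
#' @param floor Probability floor.
#' @return Numeric vector of per-trial log-likelihoods (nats), with
#'   attribute `n_clipped`.
#' @export
trial_log_likelihood <- function(trials, params, variant = "full",
                                 decision = "map", floor = 1e-9) {
  if (is.null(trials$response) || any(is.na(trials$response)))
    stop("all trials must have a response")
  z <- binarize_response(trials$response)
  p_right <- p_right_response(trials$x_e, trials$x_r, params,
                              variant = variant, decision = decision)
  p <- ifelse(z > 0, p_right, 1 - p_right)
  clipped <- p < floor
  ll <- log(pmax(p, floor))
  attr(ll, "n_clipped") <- sum(clipped)
  ll
}

#' Fit the ideal-observer noise parameters by maximum likelihood
#'
#' Estimates the sensory noise standard deviations from a table of trials
#' with responses, holding the drift diffusion coefficient `D` and the ISI
#' `T` fixed (these are measured from the eye traces, not fitted). The full
#' variant fits `(sigma_e, sigma_r)`; the reduced single-cue variants fit
#' only the relevant sigma. Optimization is a deterministic coarse-to-fine
#' scheme: a log-spaced grid over `[1e-2, 1e3]` arcmin followed by a
#' derivative-free local polish, so refits reproduce the same values.
#'
#' @param trials Trial table with `x_e`, `x_r`, `response`.
#' @param D Diffusion coefficient, arcmin^2/ms (> 0; fixed).
#' @param T Inter-stimulus interval, ms (fixed). Defaults to the `isi_T`
#'   column when present.
#' @param variant `"full"`, `"extraretinal_only"` or `"retinal_only"`.
#' @param decision Observer decision mode assumed by the likelihood,
#'   `"map"` (default) or `"sample"`; see [p_right_response()].
#' @param bounds Lower/upper bounds for the sigmas, arcmin.
#' @param grid_n Grid resolution per dimension for the coarse stage.
#' @param floor Probability floor for the likelihood.
#' @return An object of class `drift_fit` with methods `print()`,
#'   `summary()`, `coef()`, `logLik()`, `predict()`, `simulate()`,
#'   `residuals()` and `plot()`.
#' @examples
#' truth <- observer_params(2, 0.5, 0.08, 100)
#' ses <- generate_session(800, seed = 7, params = truth)
#' fit <- fit_observer(ses$trials, D = 0.08)
#' coef(fit)
#' @export
fit_observer <- function(trials, D, T = NULL,
                         variant = c("full", "extraretinal_only", "retinal_only"),
                         decision = c("map", "sample"),
                         bounds = c(1e-2, 1e3), grid_n = 40L, floor = 1e-9) {
  variant <- match.arg(variant)
  decision <- match.arg(decision)
  if (is.null(T)) {
    T <- unique(trials$isi_T)
    if (length(T) != 1L) stop("'T' must be given when trials mix ISIs")
  }
  if (!is.numeric(D) || D <= 0) stop("'D' must be > 0")
  if (nrow(trials) < 50L) stop("need at least 50 trials with responses")
  if (any(is.na(trials$response))) stop("all trials must have a response")

  lb <- log10(bounds[1]); ub <- log10(bounds[2])
  nll <- function(ls_e, ls_r) {
    p <- observer_params(10^ls_e, 10^ls_r, D, T)
    -sum(trial_log_likelihood(trials, p, variant, decision, floor))
  }
  grid <- seq(lb, ub, length.out = grid_n)

  if (variant == "full") {
    gv <- outer(grid, grid, Vectorize(nll))
    best <- arrayInd(which.min(gv), dim(gv))
    start <- c(grid[best[1]], grid[best[2]])
    opt <- stats::optim(start, function(p) {
      if (any(p < lb | p > ub)) return(1e12)
      nll(p[1], p[2])
    }, method = "Nelder-Mead",
    control = list(maxit = 1000, reltol = 1e-10))
    sigma_e <- 10^opt$par[1]; sigma_r <- 10^opt$par[2]
    ll <- -opt$value
    conv <- opt$convergence
    grid_stage <- list(par = 10^start, value = -gv[best])
  } else {
    # only one sigma is free; the other is irrelevant to the reduced model
    f <- if (variant == "extraretinal_only") {
      function(ls) nll(ls, 0)
    } else {
      function(ls) nll(0, ls)
    }
    g1 <- vapply(grid, f, numeric(1))
    i <- which.min(g1)
    win <- c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))])
    opt <- stats::optimize(f, interval = win, tol = 1e-9)
    if (variant == "extraretinal_only") {
      sigma_e <- 10^opt$minimum; sigma_r <- 1
    } else {
      sigma_e <- Inf; sigma_r <- 10^opt$minimum
    }
    ll <- -opt$objective
    conv <- 0L
    grid_stage <- list(par = 10^grid[i], value = -g1[i])
  }
  params <- observer_params(sigma_e, sigma_r, D, T)
  p_right <- p_right_response(trials$x_e, trials$x_r, params, variant, decision)
  structure(list(params = params, variant = variant, decision = decision,
                 log_likelihood = ll, n_trials = nrow(trials),
                 n_clipped = attr(trial_log_likelihood(trials, params, variant,
                                                       decision, floor),
                                  "n_clipped"),
                 convergence = conv, grid_stage = grid_stage,
                 bounds = bounds, floor = floor,
                 trials = trials, fitted_p_right = p_right,
                 call = match.call()),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("Ideal-observer fit (%s variant, %s decisions), %d trials\n",
              x$variant, x$decision, x$n_trials))
  cat(sprintf("  sigma_e = %s arcmin, sigma_r = %s arcmin (D = %g, T = %g fixed)\n",
              format(x$params$sigma_e, digits = 4),
              format(x$params$sigma_r, digits = 4), x$params$D, x$params$T))
  cat(sprintf("  log-likelihood %.2f nats (%d trial(s) at probability floor)\n",
              x$log_likelihood, x$n_clipped))
  invisible(x)
}

#' @export
coef.drift_fit <- function(object, ...) {
  c(sigma_e = object$params$sigma_e, sigma_r = object$params$sigma_r)
}

#' @export
logLik.drift_fit <- function(object, ...) {
  df <- if (object$variant == "full") 2L else 1L
  structure(object$log_likelihood, df = df, nobs = object$n_trials,
            class = "logLik")
}

#' @export
summary.drift_fit <- function(object, ...) {
  w <- extraretinal_weight(object$params)
  out <- list(fit = object, weight = w,
              posterior_sd = sqrt(object$params$sigma_r^2 +
                                    obs_post_var_e(object$params)),
              r_squared = tryCatch(
                variance_explained(object$trials, object$params,
                                   object$variant, object$decision),
                error = function(e) NA_real_))
  class(out) <- "summary.drift_fit"
  out
}

#' @export
print.summary.drift_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  extraretinal weight w = %.3f, posterior sd = %.3f arcmin\n",
              x$weight, x$posterior_sd))
  if (!is.na(x$r_squared))
    cat(sprintf("  binned response variance explained R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Predicted response probabilities from a fit
#'
#' @param object A `drift_fit`.
#' @param newdata Trial table (defaults to the fitted trials).
#' @param type `"p_right"` for probabilities, `"response"` for the modal
#'   Left/Right report.
#' @param ... Unused.
#' @return Numeric or character vector, one element per trial.
#' @export
predict.drift_fit <- function(object, newdata = NULL,
                              type = c("p_right", "response"), ...) {
  type <- match.arg(type)
  trials <- if (is.null(newdata)) object$trials else newdata
  p <- p_right_response(trials$x_e, trials$x_r, object$params,
                        object$variant, object$decision)
  if (type == "p_right") p else ifelse(p > 0.5, "Right", "Left")
}

#' @export
residuals.drift_fit <- function(object, ...) {
  (binarize_response(object$trials$response) + 1) / 2 - object$fitted_p_right
}

#' Simulate responses from a fitted observer
#'
#' @param object A `drift_fit`.
#' @param nsim Number of simulated response sets.
#' @param seed Integer seed.
#' @param newdata Trial table (defaults to the fitted trials).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of `"Left"`/`"Right"` responses.
#' @export
simulate.drift_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  trials <- if (is.null(newdata)) object$trials else newdata
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, generate_responses(
    trials, object$params, variant = object$variant,
    mode = object$decision)$response, simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @export
plot.drift_fit <- function(x, target_bin_count = 60, ...) {
  sur <- response_surface(x$trials, target_bin_count = target_bin_count)
  obs <- sur$bins$p_right
  t2 <- x$trials[sur$trials_used, , drop = FALSE]
  p_trial <- p_right_response(t2$x_e, t2$x_r, x$params, x$variant, x$decision)
  pred <- as.numeric(tapply(p_trial, sur$assign, mean))
  graphics::plot(pred, obs, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "model P(Right) per bin", ylab = "observed P(Right) per bin",
                 main = sprintf("%s variant", x$variant), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(data.frame(predicted = pred, observed = obs))
}

#' Variance in binned responses explained by a model
#'
#' Bins trials over `(x_e, x_r)` with equal-count bins (targeting a mean
#' occupancy, 60 by default), computes the observed probability of "Right"
#' per bin and the model-predicted probability per bin (mean of the
#' per-trial response probability), and returns `R^2 = 1 - SSE/SST` across
#' bins. Can be negative for a model worse than the constant prediction.
#'
#' @param trials Trial table with responses.
#' @param params An [observer_params()] object, or a `drift_fit` (whose
#'   variant and decision mode are then used).
#' @param variant,decision Passed to [p_right_response()].
#' @param target_bin_count Target mean trials per bin.
#' @param min_bin Bins with fewer trials are dropped with a warning.
#' @return `R^2` with attribute `bins` (per-bin table).
#' @export
variance_explained <- function(trials, params, variant = "full",
                               decision = "map", target_bin_count = 60,
                               min_bin = 10) {
  if (inherits(params, "drift_fit")) {
    variant <- params$variant; decision <- params$decision
    params <- params$params
  }
  sur <- response_surface(trials, target_bin_count = target_bin_count)
  bins <- sur$bins
  t2 <- trials[sur$trials_used, , drop = FALSE]
  p_trial <- p_right_response(t2$x_e, t2$x_r, params, variant, decision)
  pred <- as.numeric(tapply(p_trial, sur$assign, mean))
  small <- bins$n < min_bin
  if (any(small)) {
    warning(sum(small), " bin(s) below ", min_bin, " trials dropped")
    bins <- bins[!small, , drop = FALSE]; pred <- pred[!small]
  }
  obs <- bins$p_right
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  structure(1 - sse / sst,
            bins = cbind(bins, predicted = pred))
}

#' Scale a 100 ms fit to a longer ISI under a drift-estimation hypothesis
#'
#' Given a full-model fit at a base ISI, produces the parameters the model
#' predicts at an ISI `factor` times longer, with no free parameters:
#' the Brownian prior sd scales by `sqrt(factor)` automatically (through
#' `T`), `sigma_r` is unchanged, and `sigma_e` scales by `factor` under the
#' `"extrapolation"` hypothesis (drift estimated over a fixed short window
#' and extrapolated, noise growing linearly in time) or by `sqrt(factor)`
#' under the `"integration"` hypothesis (noisy velocity integrated over the
#' whole interval, noise growing as the square root of time).
#'
#' @param fit_base A full-variant `drift_fit` (or [observer_params()]) at
#'   the base ISI.
#' @param hypothesis `"extrapolation"` or `"integration"`.
#' @param factor ISI ratio (default 5: 100 ms -> 500 ms).
#' @return An `isi_scaling` object: `params_base`, `params_scaled`,
#'   `hypothesis`, `factor`.
#' @export
predict_isi_scaling <- function(fit_base,
                                hypothesis = c("extrapolation", "integration"),
                                factor = 5) {
  hypothesis <- match.arg(hypothesis)
  base <- if (inherits(fit_base, "drift_fit")) fit_base$params
          else as_observer_params(fit_base)
  k <- if (hypothesis == "extrapolation") factor else sqrt(factor)
  scaled <- observer_params(base$sigma_e * k, base$sigma_r,
                            base$D, base$T * factor)
  structure(list(params_base = base, params_scaled = scaled,
                 hypothesis = hypothesis, factor = factor),
            class = "isi_scaling")
}

#' @export
print.isi_scaling <- function(x, ...) {
  cat(sprintf("ISI scaling (%s, x%g): sigma_e %g -> %g arcmin, T %g -> %g ms (sigma_r fixed at %g)\n",
              x$hypothesis, x$factor, x$params_base$sigma_e,
              x$params_scaled$sigma_e, x$params_base$T, x$params_scaled$T,
              x$params_base$sigma_r))
  invisible(x)
}

#' Model-predicted d-prime per Vernier offset
#'
#' Computes the d-prime the observer model predicts on a given trial set:
#' per offset magnitude, the model hit rate is the mean response probability
#' over the positive-offset trials and the false-alarm rate the mean over
#' the negative-offset trials; both pass through the same extreme-rate
#' correction as the empirical [dprime()].
#'
#' @param params [observer_params()] or a `drift_fit`.
#' @param trials Trial table (responses not needed).
#' @param variant,decision Passed to [p_right_response()].
#' @return Data frame with `offset`, `dprime_pred`, `n`.
#' @export
predict_dprime <- function(params, trials, variant = "full", decision = "map") {
  if (inherits(params, "drift_fit")) {
    variant <- params$variant; decision <- params$decision
    params <- params$params
  }
  t2 <- trials[trials$x_display != 0, , drop = FALSE]
  p <- p_right_response(t2$x_e, t2$x_r, params, variant, decision)
  mag <- abs(t2$x_display)
  out <- lapply(sort(unique(mag)), function(m) {
    pos <- mag == m & t2$x_display > 0
    neg <- mag == m & t2$x_display < 0
    if (!any(pos) || !any(neg)) return(NULL)
    h <- clamp_rate(mean(p[pos]), sum(pos))
    f <- clamp_rate(mean(p[neg]), sum(neg))
    data.frame(offset = m, dprime_pred = stats::qnorm(h) - stats::qnorm(f),
               n = sum(pos) + sum(neg))
  })
  do.call(rbind, out)
}

#' Compare fitted model variants on a common trial set
#'
#' @param trials The shared trial table.
#' @param fits List of `drift_fit` objects fitted to `trials`.
#' @param target_bin_count Binning target for the R^2 computation.
#' @return A `model_comparison`: table of variant, log-likelihood, df, R^2,
#'   with the per-variant predicted d-prime tables attached.
#' @export
compare_models <- function(trials, fits, target_bin_count = 60) {
  if (inherits(fits, "drift_fit")) fits <- list(fits)
  for (f in fits)
    if (f$n_trials != nrow(trials))
      stop("all fits must share the trial set")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(variant = f$variant,
               log_likelihood = f$log_likelihood,
               df = if (f$variant == "full") 2L else 1L,
               r_squared = as.numeric(variance_explained(
                 trials, f, target_bin_count = target_bin_count)),
               stringsAsFactors = FALSE)
  }))
  dp <- lapply(fits, function(f) predict_dprime(f, trials))
  names(dp) <- tab$variant
  structure(list(table = tab[order(-tab$log_likelihood), ],
                 dprime = dp, n_trials = nrow(trials)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison over %d trials\n", x$n_trials))
  print(x$table, row.names = FALSE)
  invisible(x)
}
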