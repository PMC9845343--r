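test_that("per-trial log-likelihood matches direct evaluation", {
  truth <- truth_params()
  tt <- data.frame(x_e = c(0, 5, -5), x_r = c(0, 0.5, -0.5),
                   response = c("Right", "Right", "Left"))
  ll <- trial_log_likelihood(tt, truth)
  expect_equal(ll[1], log(0.5))
  expect_gt(ll[2], log(0.95))          # saturated trial: near 0
  # sum over a session equals a brute-force per-trial loop
  ses <- cached_session(400, seed = 23)
  tr <- generate_responses(ses$trials, truth, seed = 9)
  ll_vec <- trial_log_likelihood(tr, truth)
  brute <- sum(vapply(seq_len(nrow(tr)), function(i) {
    p <- p_right_response(tr$x_e[i], tr$x_r[i], truth)
    log(if (tr$response[i] == "Right") p else 1 - p)
  }, numeric(1)))
  expect_equal(sum(ll_vec), brute, tolerance = 1e-10)
  expect_error(trial_log_likelihood(ses$trials, truth), "response")
})

test_that("the floor guards against lapse trials", {
  truth <- observer_params(0.01, 0.01, 0.08, 100)
  tt <- data.frame(x_e = 10, x_r = 0.5, response = "Left")  # gross lapse
  ll <- trial_log_likelihood(tt, truth)
  expect_equal(as.numeric(ll), log(1e-9))
  expect_equal(attr(ll, "n_clipped"), 1L)
})

test_that("the extraretinal noise parameter is recovered from responses", {
  truth <- truth_params()
  ses <- cached_session(5000, seed = 31, params = truth)
  fit <- fit_observer(ses$trials, D = 0.08)
  expect_s3_class(fit, "drift_fit")
  expect_equal(unname(coef(fit)["sigma_e"]), 2, tolerance = 0.2)
  expect_lte(fit$log_likelihood, 0)
  # refitting reproduces the values exactly (deterministic optimizer)
  fit2 <- fit_observer(ses$trials, D = 0.08)
  expect_identical(coef(fit), coef(fit2))
  expect_equal(attr(logLik(fit), "df"), 2L)
})

test_that("sigma_e recovery error shrinks with the trial count", {
  truth <- truth_params()
  rmse <- vapply(c(500, 8000), function(n) {
    e <- vapply(1:3, function(s) {
      ses <- generate_session(n, seed = 600 + s, params = truth)
      coef(fit_observer(ses$trials, D = 0.08))["sigma_e"] - 2
    }, numeric(1))
    sqrt(mean(e^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("expected log-likelihood is maximal at the generative parameters", {
  # Gibbs inequality, evaluated exactly: E[ll] under the truth beats any
  # perturbed parameter set on the same trials
  truth <- truth_params()
  tr <- cached_session(2000, seed = 23)$trials
  p0 <- p_right_response(tr$x_e, tr$x_r, truth)
  ell <- function(params) {
    q <- p_right_response(tr$x_e, tr$x_r, params)
    sum(p0 * log(q) + (1 - p0) * log(1 - q))
  }
  base <- ell(truth)
  for (fe in c(0.5, 0.8, 1.25, 2))
    for (fr in c(0.5, 1, 2))
      if (fe != 1 || fr != 1)
        expect_lte(ell(observer_params(2 * fe, 0.5 * fr, 0.08, 100)), base)
})

test_that("reduced variants fit only their own cue", {
  truth <- truth_params()
  ses <- cached_session(2000, seed = 37, params = truth)
  fe <- fit_observer(ses$trials, D = 0.08, variant = "extraretinal_only")
  fr <- fit_observer(ses$trials, D = 0.08, variant = "retinal_only")
  expect_true(is.finite(coef(fe)["sigma_e"]))
  expect_identical(unname(coef(fr)["sigma_e"]), Inf)
  expect_equal(attr(logLik(fe), "df"), 1L)
  # responses generated from the retinal-only observer: the full model earns
  # almost nothing over the retinal-only fit
  ret_truth <- observer_params(Inf, 0.5, 0.08, 100)
  tr_ret <- generate_responses(ses$trials, ret_truth, variant = "retinal_only",
                               seed = 12)
  f_full <- fit_observer(tr_ret, D = 0.08)
  f_ret <- fit_observer(tr_ret, D = 0.08, variant = "retinal_only")
  expect_lt(f_full$log_likelihood - f_ret$log_likelihood,
            2 * nrow(tr_ret) / 1000)
})

test_that("a fit to shuffled responses predicts at chance", {
  truth <- truth_params()
  ses <- cached_session(2000, seed = 37, params = truth)
  tr <- ses$trials
  set.seed(8)
  tr$response <- sample(tr$response)
  fit <- fit_observer(tr, D = 0.08)
  held <- generate_responses(cached_session(1000, seed = 43)$trials, truth,
                             seed = 13)
  # the fitted observer has learned nothing: its response probabilities sit
  # at chance and responses simulated from it score at chance accuracy
  p <- predict(fit, held)
  expect_lt(mean(abs(p - 0.5)), 0.05)
  sim <- generate_responses(held, fit$params, seed = 14)
  nz <- sim$x_display != 0
  expect_equal(mean((sim$response[nz] == "Right") == (sim$x_display[nz] > 0)),
               0.5, tolerance = 0.08)
})

test_that("model methods honour the standard contracts", {
  truth <- truth_params()
  ses <- cached_session(2000, seed = 37, params = truth)
  fit <- fit_observer(ses$trials, D = 0.08)
  expect_output(print(fit), "Ideal-observer fit")
  expect_output(print(summary(fit)), "extraretinal weight")
  p <- predict(fit)
  expect_true(all(p >= 0 & p <= 1))
  r <- residuals(fit)
  expect_equal(length(r), nrow(ses$trials))
  expect_lt(abs(mean(r)), 0.05)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_equal(dim(sims), c(nrow(ses$trials), 2L))
  expect_identical(simulate(fit, seed = 4), simulate(fit, seed = 4))
  pdf(NULL)
  on.exit(dev.off())
  agree <- plot(fit)
  expect_gt(cor(agree$predicted, agree$observed), 0.95)
})

test_that("variance explained is near 1 for the truth and <= 0 for a flat model", {
  truth <- truth_params()
  ses <- cached_session(5000, seed = 31, params = truth)
  r2 <- suppressWarnings(variance_explained(ses$trials, truth))
  expect_gt(r2, 0.9)
  # R^2 = 1 - SSE/SST can go negative: a model anti-correlated with the data
  # (here, the truth scored against sign-flipped responses) is worse than the
  # constant prediction
  flipped <- ses$trials
  flipped$response <- ifelse(flipped$response == "Right", "Left", "Right")
  expect_lt(suppressWarnings(variance_explained(flipped, truth)), 0)
})

test_that("variant ordering on full-model data mirrors the two-cue structure", {
  truth <- truth_params()
  ses <- cached_session(5000, seed = 31, params = truth)
  fits <- lapply(c("full", "extraretinal_only", "retinal_only"), function(v)
    fit_observer(ses$trials, D = 0.08, variant = v))
  comp <- suppressWarnings(compare_models(ses$trials, fits))
  tab <- comp$table[match(c("full", "extraretinal_only", "retinal_only"),
                          comp$table$variant), ]
  expect_true(tab$r_squared[1] > tab$r_squared[2])
  expect_true(tab$r_squared[2] > tab$r_squared[3])
  expect_true(tab$log_likelihood[1] > tab$log_likelihood[2])
  expect_true(tab$log_likelihood[2] > tab$log_likelihood[3])
  # single variant reduces to its own fit
  solo <- suppressWarnings(compare_models(ses$trials, fits[[1]]))
  expect_equal(nrow(solo$table), 1L)
  expect_equal(solo$table$log_likelihood, fits[[1]]$log_likelihood)
  # the comparison table round-trips through JSON losslessly
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(comp$table, f, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$log_likelihood, comp$table$log_likelihood)
  expect_equal(back$r_squared, comp$table$r_squared)
  expect_error(compare_models(ses$trials[1:100, ], fits), "share")
})

test_that("ISI scaling applies the exact hypothesis factors", {
  fit <- observer_params(2, 0.5, 0.08, 100)
  ext <- predict_isi_scaling(fit, "extrapolation")
  int <- predict_isi_scaling(fit, "integration")
  expect_identical(ext$params_scaled$sigma_e / fit$sigma_e, 5)
  expect_equal(int$params_scaled$sigma_e / fit$sigma_e, sqrt(5))
  # prior sd scales by exactly sqrt(5) under both hypotheses
  prior_sd <- function(p) sqrt(2 * p$D * p$T)
  expect_equal(prior_sd(ext$params_scaled) / prior_sd(fit), sqrt(5))
  expect_equal(prior_sd(int$params_scaled) / prior_sd(fit), sqrt(5))
  expect_identical(ext$params_scaled$sigma_r, fit$sigma_r)
  expect_error(predict_isi_scaling(fit, "bogus"), "arg")
})

test_that("d-prime predictions fall monotonically with extraretinal noise", {
  trials <- cached_session(3000, seed = 47, isi_T = 500)$trials
  lo <- predict_dprime(observer_params(2 * sqrt(5), 0.5, 0.08, 500), trials)
  hi <- predict_dprime(observer_params(2 * 5, 0.5, 0.08, 500), trials)
  m <- merge(lo, hi, by = "offset")
  m <- m[m$n.x >= 50, ]
  expect_true(all(m$dprime_pred.y < m$dprime_pred.x))
})
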