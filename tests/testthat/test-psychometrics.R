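make_rate_trials <- function(n_pos, n_neg, k_right_pos, k_right_neg, offset = 1.9) {
  data.frame(
    x_display = rep(c(offset, -offset), c(n_pos, n_neg)),
    x_e = rep(c(offset, -offset), c(n_pos, n_neg)),
    x_r = 0,
    response = c(rep(c("Right", "Left"), c(k_right_pos, n_pos - k_right_pos)),
                 rep(c("Right", "Left"), c(k_right_neg, n_neg - k_right_neg))))
}

test_that("proportion correct counts sign agreement and excludes zero offsets", {
  tt <- make_rate_trials(10, 10, 10, 0)
  expect_equal(proportion_correct(tt)$prop_correct, 1)
  tt0 <- tt; tt0$x_display[1:5] <- 0
  pc <- proportion_correct(tt0)
  expect_equal(pc$n, 15L)
  z <- tt; z$x_display <- 0
  expect_error(proportion_correct(z), "non-zero")
})

test_that("d-prime reproduces the z-transform arithmetic", {
  # H = 0.841, F = 0.159 -> d' = 2 (up to the 1/(2N) correction at N = 1000)
  tt <- make_rate_trials(1000, 1000, 841, 159)
  expect_equal(dprime(tt)$dprime, 2, tolerance = 0.01)
  expect_equal(dprime(tt, correction = FALSE)$dprime,
               qnorm(0.841) - qnorm(0.159))
  # random responses give d' near 0
  set.seed(2)
  rnd <- make_rate_trials(2000, 2000, 1000, 1000)
  rnd$response <- sample(rnd$response)
  expect_equal(dprime(rnd)$dprime, 0, tolerance = 0.15)
  # perfect performance stays finite through the correction
  perf <- make_rate_trials(50, 50, 50, 0)
  expect_true(is.finite(dprime(perf)$dprime))
  one_sided <- tt[tt$x_display > 0, ]
  expect_error(dprime(one_sided), "sign")
  expect_silent(dprime(one_sided, drop_incomplete = TRUE))
})

test_that("bootstrap test is seeded, bounded and calibrated", {
  tt <- make_rate_trials(200, 200, 170, 30)
  acc <- function(x) mean((x$response == "Right") == (x$x_display > 0))
  a <- bootstrap_test(tt, acc, n_boot = 500, seed = 3, alternative = "greater")
  b <- bootstrap_test(tt, acc, n_boot = 500, seed = 3, alternative = "greater")
  expect_identical(a$p_value, b$p_value)
  expect_true(a$ci[1] <= a$estimate && a$estimate <= a$ci[2])
  expect_lt(a$p_value, 0.01)
  # constant statistic: zero-width CI, p reported as a bound
  const <- bootstrap_test(tt, function(x) 0.75, n_boot = 200, seed = 1)
  expect_equal(diff(const$ci), 0)
  expect_equal(const$p_value, 1 / 201)
  # under the null the p-value is roughly uniform across datasets
  set.seed(9)
  ps <- vapply(1:60, function(i) {
    null <- make_rate_trials(60, 60, rbinom(1, 60, 0.5), rbinom(1, 60, 0.5))
    bootstrap_test(null, acc, n_boot = 200, seed = i)$p_value
  }, numeric(1))
  expect_equal(mean(ps), 0.5, tolerance = 0.15)
})

test_that("bootstrap confidence intervals cover the generative accuracy", {
  truth <- truth_params()
  base <- cached_session(300, seed = 53)$trials
  nz <- base[base$x_display != 0, ]
  p_true <- mean(ifelse(nz$x_display > 0,
                        p_right_response(nz$x_e, nz$x_r, truth),
                        1 - p_right_response(nz$x_e, nz$x_r, truth)))
  acc <- function(x) mean((x$response == "Right") == (x$x_display > 0))
  hits <- vapply(1:100, function(i) {
    tt <- generate_responses(nz, truth, seed = 7000 + i)
    ci <- bootstrap_test(tt, acc, n_boot = 300, seed = i)$ci
    ci[1] <= p_true && p_true <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 1.0)
})

test_that("response surface bins equally, flips with the cue signs, and tracks the model", {
  truth <- truth_params()
  ses <- cached_session(5000, seed = 31, params = truth)
  sur <- response_surface(ses$trials, target_bin_count = 60)
  expect_equal(mean(sur$bins$n), 60, tolerance = 0.35)
  expect_true(all(sur$bins$p_right >= 0 & sur$bins$p_right <= 1))
  # sign flip of both cues and responses mirrors the surface
  flip <- ses$trials
  flip$x_e <- -flip$x_e; flip$x_r <- -flip$x_r
  flip$response <- ifelse(flip$response == "Right", "Left", "Right")
  sur_f <- response_surface(flip, target_bin_count = 60)
  # rows are ordered x_r-major then x_e; the mirrored surface reverses both
  o <- order(-sur_f$bins$x_r_lo, -sur_f$bins$x_e_lo)
  expect_equal(sur_f$bins$p_right[o], 1 - sur$bins$p_right, tolerance = 1e-9)
  # binned rates agree with the analytic response probability in most bins
  t2 <- ses$trials[sur$trials_used, ]
  pred <- tapply(p_right_response(t2$x_e, t2$x_r, truth), sur$assign, mean)
  se <- sqrt(pred * (1 - pred) / sur$bins$n)
  frac_ok <- mean(abs(sur$bins$p_right - pred) < 2 * se + 1e-9)
  expect_gte(frac_ok, 0.9)
  expect_error(response_surface(ses$trials[1:50, ], 60), "4 bins")
})

test_that("opposite-sign trials separate the two observer families", {
  ses <- cached_session(2000, seed = 59)
  # extraretinal-dominated observer: correct even when x_r points the wrong way
  ext <- generate_responses(ses$trials, observer_params(1, 5, 0.08, 100),
                            seed = 21)
  res_ext <- opposite_sign_performance(ext, n_boot = 500, seed = 2)
  expect_gt(res_ext$accuracy, 0.5)
  expect_lt(res_ext$p_above_chance, 0.05)
  # retinal-only observer: systematically wrong on this subset
  ret <- generate_responses(ses$trials, observer_params(Inf, 0.5, 0.08, 100),
                            variant = "retinal_only", seed = 22)
  res_ret <- opposite_sign_performance(ret, n_boot = 500, seed = 2)
  expect_lt(res_ret$accuracy, 0.5)
  expect_lt(res_ret$p_below_chance, 0.05)
  # subset selection is exact
  sub <- ext[res_ext$subset, ]
  expect_true(all(sign(sub$x_e) != sign(sub$x_r)))
  expect_true(all(sub$x_r != 0 & sub$x_display != 0))
})

test_that("response correlation behaves at its fixed points", {
  set.seed(4)
  cue <- sample(c(-1, 1), 500, replace = TRUE)
  tt <- data.frame(x_e = cue, x_r = 0,
                   response = ifelse(cue > 0, "Right", "Left"))
  expect_equal(response_correlation(tt, "x_e"), 1)
  tt$response <- sample(tt$response)
  expect_lt(abs(response_correlation(tt, "x_e")), 0.15)
  expect_error(response_correlation(tt, "x_r"), "zero variance")
  expect_error(response_correlation(tt, "nope"), "unknown cue")
  # generative data: responses track x_e much more than x_r, as when the
  # weighted extraretinal spread dominates the retinal one
  ses <- cached_session(5000, seed = 31, params = truth_params())
  expect_gt(response_correlation(ses$trials, "x_e"),
            abs(response_correlation(ses$trials, "x_r")) + 0.3)
})

test_that("proportion correct and d-prime cohere as Phi(d'/2)", {
  truth <- truth_params()
  ses <- cached_session(5000, seed = 31, params = truth)
  dp <- dprime(ses$trials, drop_incomplete = TRUE)
  pc <- proportion_correct(ses$trials)
  m <- merge(dp, pc, by = "offset")
  m <- m[m$n.x >= 300, ]
  expect_gt(nrow(m), 1)
  se <- sqrt(m$prop_correct * (1 - m$prop_correct) / m$n.y)
  expect_true(all(abs(pnorm(m$dprime / 2) - m$prop_correct) < 3 * se + 0.02))
})

test_that("psychometric summary binds accuracy and d-prime with uncertainty", {
  ses <- cached_session(2000, seed = 59)
  tt <- generate_responses(ses$trials, truth_params(), seed = 25)
  ps <- psychometric_summary(tt, n_boot = 200, seed = 5)
  expect_true(all(c("prop_correct", "dprime", "p_pc_vs_chance") %in% names(ps)))
  big <- ps[ps$n >= 200, ]
  expect_true(all(big$p_pc_vs_chance < 0.05))   # well above chance
  expect_true(all(big$pc_lo <= big$prop_correct & big$prop_correct <= big$pc_hi))
})
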