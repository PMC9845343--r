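# driftscope

Ideal-observer analysis of fixational ocular drift in a gaze-contingent
Vernier task.

## The problem

Fixational eye drift moves the line of sight by several arcminutes within a
tenth of a second. In a gaze-contingent Vernier paradigm the two bars of a
Vernier are flashed sequentially at the current gaze position, so the bars
land aligned on the retina while their offset on the display equals the gaze
displacement between the flashes. Judging the offset then requires
*extraretinal* knowledge of one's own drift — plus whatever tiny retinal
misalignment (`x_r`, bounded by one pixel) display quantization leaves
behind. `driftscope` is for researchers modelling this kind of experiment:
it simulates the paradigm, preprocesses eye traces, fits the Bayesian
cue-combination observer, and quantifies performance.

## The model

On each trial the observer measures the gaze displacement and the retinal
misalignment with Gaussian noise (sd `sigma_E`, `sigma_R`), and combines
them with a Brownian-motion prior on drift, `X_E ~ N(0, sqrt(2DT))`, where
`D` is the drift diffusion coefficient and `T` the inter-stimulus interval.
The posterior over the displayed offset `X = X_E + X_R` is Gaussian:

    mean = x_R + w * x_E,  w = 2DT / (sigma_E^2 + 2DT)
    sd   = sqrt(sigma_R^2 + 2DT * sigma_E^2 / (sigma_E^2 + 2DT))

and the observer reports the side with more posterior mass. `sigma_E` and
`sigma_R` are fitted per observer by maximum likelihood with `D` and `T`
fixed at their measured values; reduced single-cue variants, an
ISI-scaling prediction (`sigma_E` growing like `t` vs `sqrt(t)`), binned
response surfaces, d-prime, bootstrap tests and a reverse-correlation
temporal-window analysis complete the chain.

## Worked example

```r
library(driftscope)

truth <- observer_params(sigma_e = 2, sigma_r = 0.5, D = 0.08, T = 100)
ses <- generate_session(n_trials = 2000, seed = 42, params = truth)

fit <- fit_observer(ses$trials, D = 0.08)
summary(fit)
#> Ideal-observer fit (full variant, map decisions), 2000 trials
#>   sigma_e = 1.648 arcmin, sigma_r = 1.108 arcmin (D = 0.08, T = 100 fixed)
#>   log-likelihood -634.36 nats (0 trial(s) at probability floor)
#>   extraretinal weight w = 0.855, posterior sd = 1.884 arcmin
#>   binned response variance explained R^2 = 0.996

dprime(ses$trials, drop_incomplete = TRUE)[1:2, ]
#>   offset   n  hit_rate    fa_rate   dprime
#> 1    1.9 653 0.8089172 0.18584071 1.767241
#> 2    3.8 468 0.9658120 0.03418803 3.645041

opp <- opposite_sign_performance(ses$trials, n_boot = 1000, seed = 1)
sprintf("opposite-sign accuracy: %.3f (n = %d, p = %.4f)", opp$accuracy, opp$n, opp$p_above_chance)
#> "opposite-sign accuracy: 0.913 (n = 678, p = 0.0010)"
```

The fit recovers the extraretinal noise well (`sigma_e` 1.65 vs truth 2,
weight `w = 0.86` vs 0.8) and explains essentially all binned response
variance; the retinal noise is weakly identified in this regime (see the
methods vignette). d-prime roughly doubles from the one-pixel offset
(1.9 arcmin) to the two-pixel offset, and accuracy stays far above chance on
the trials where the retinal cue points the *wrong* way — the signature of
extraretinal knowledge of drift.

An end-to-end run (simulate, segment, exclude, fit all variants,
psychometrics, window analysis, manifest with hashes) is one call:

```r
cfg <- list(D = 0.08, sigma_e = 2, sigma_r = 0.5, isi_T = 100,
            pixel_pitch = 1.9, n_trials = 400, seed = 7)
report <- run_pipeline(cfg, "out/run1")
```

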