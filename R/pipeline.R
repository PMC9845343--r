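## End-to-end orchestration: simulate a session, preprocess, fit the
## observer variants, run the psychometric and window analyses, and write
## machine-readable outputs with a manifest.  Every stochastic stage draws
## a named substream seed from the config's master seed, so a rerun with
## the same config is bit-identical.

#' Run the full analysis pipeline from a configuration
#'
#' Stages: `simulate` (drift traces, quantized Vernier trials, generative
#' responses), `preprocess` (segmentation, drift-only trial exclusion,
#' diffusion estimate), `fit` (full and reduced observer variants),
#' `psycho` (psychometric summary, response surface, opposite-sign
#' control), `window` (reverse-correlation grid and peak). Outputs are
#' written under `out_dir`: `trials.csv`, `traces/`, `fits/*.json`,
#' `psychometrics.csv`, `surface.csv`, `window_grid.csv`, `report.json`
#' and `manifest.json` (settings plus MD5 hashes of every output).
#'
#' @param config A [read_run_config()] result, a path to one, or a named
#'   list.
#' @param out_dir Output directory (created if needed).
#' @param write_traces Write one CSV per trace under `traces/` (default
#'   `TRUE`; they are the bulkiest output).
#' @return The report, invisibly (also serialized to `report.json`).
#' @export
run_pipeline <- function(config, out_dir, write_traces = TRUE) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  report <- list(config = unclass(cfg))
  tryCatch({
    truth <- observer_params(cfg$sigma_e, cfg$sigma_r, cfg$D, cfg$isi_T)
    ses <- generate_session(cfg$n_trials, D = cfg$D, isi_T = cfg$isi_T,
                            pixel_pitch = cfg$pixel_pitch,
                            seed = derive_seeds(cfg$seed, "simulate", 1L),
                            params = truth, variant = cfg$variant,
                            mode = cfg$mode)
    write_trials(ses$trials, file.path(out_dir, "trials.csv"))
    if (write_traces) {
      dir.create(file.path(out_dir, "traces"), showWarnings = FALSE)
      for (i in seq_along(ses$traces))
        write_trace(ses$traces[[i]],
                    file.path(out_dir, "traces", sprintf("trace_%04d.csv", i)))
    }

    stage <- "preprocess"
    segs <- lapply(ses$traces, segment_trace)
    trials <- exclude_non_drift_trials(ses$trials, segs)
    kept <- match(trials$trial_id, ses$trials$trial_id)
    dstats <- estimate_diffusion(ses$traces[kept])
    report$preprocess <- list(n_input = nrow(ses$trials), n_kept = nrow(trials),
                              D_hat = dstats$D_hat,
                              variogram_r2 = dstats$r_squared)

    stage <- "fit"
    dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)
    fits <- lapply(c("full", "extraretinal_only", "retinal_only"), function(v)
      fit_observer(trials, D = cfg$D, T = cfg$isi_T, variant = v,
                   decision = cfg$mode))
    names(fits) <- vapply(fits, `[[`, "", "variant")
    for (f in fits)
      jsonlite::write_json(list(schema = "driftscope-fit/1",
                                variant = f$variant, decision = f$decision,
                                sigma_e = f$params$sigma_e,
                                sigma_r = f$params$sigma_r,
                                D = f$params$D, T = f$params$T,
                                log_likelihood = f$log_likelihood,
                                n_trials = f$n_trials,
                                n_clipped = f$n_clipped,
                                convergence = f$convergence),
                          file.path(out_dir, "fits", paste0(f$variant, ".json")),
                          auto_unbox = TRUE, digits = NA, pretty = TRUE)
    # keep at least 4 bins per axis on small sessions
    bin_target <- max(5, min(cfg$target_bin_count, floor(nrow(trials) / 16)))
    comp <- compare_models(trials, fits, target_bin_count = bin_target)
    report$fit <- comp$table

    stage <- "psycho"
    psy <- psychometric_summary(trials, n_boot = cfg$n_boot,
                                seed = derive_seeds(cfg$seed, "psycho", 1L))
    utils::write.csv(psy, file.path(out_dir, "psychometrics.csv"),
                     row.names = FALSE)
    sur <- response_surface(trials, target_bin_count = bin_target)
    utils::write.csv(sur$bins, file.path(out_dir, "surface.csv"),
                     row.names = FALSE)
    opp <- opposite_sign_performance(trials, n_boot = cfg$n_boot,
                                     seed = derive_seeds(cfg$seed, "opp", 1L))
    report$psycho <- list(summary = psy,
                          opposite_sign = opp[c("n", "accuracy",
                                                "p_above_chance")],
                          rho_x_r = response_correlation(trials, "x_r"),
                          rho_x_e = response_correlation(trials, "x_e"))

    stage <- "window"
    grid <- correlation_grid(trials, ses$traces[kept],
                             dt_range = cfg$dt_range, tw_range = cfg$tw_range,
                             step = cfg$grid_step)
    long <- expand.grid(t_w = grid$durations, dt_w = grid$lags)
    long$rho <- as.vector(grid$rho)
    utils::write.csv(long, file.path(out_dir, "window_grid.csv"),
                     row.names = FALSE)
    peak <- find_peak(grid)
    report$window <- peak[c("t_w", "dt_w", "rho", "onset")]

    stage <- "report"
    report$schema <- "driftscope-report/1"
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    files <- setdiff(list.files(out_dir, recursive = TRUE),
                     "manifest.json")
    manifest <- list(schema = "driftscope-manifest/1",
                     package_version = as.character(utils::packageVersion("driftscope")),
                     config = unclass(cfg),
                     hashes = as.list(tools::md5sum(file.path(out_dir, files))))
    names(manifest$hashes) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(report)
}

#' Synthetic short- vs long-ISI comparison of drift-estimation hypotheses
#'
#' Runs the synthetic analogue of the ISI-scaling experiment: fit the full
#' observer to a 100 ms ISI session, scale the fit to a 500 ms ISI under
#' both the extrapolation (`sigma_e` x5) and the integration (`sigma_e`
#' x sqrt(5)) hypotheses, simulate a 500 ms session from the
#' extrapolation-truth generative model, and compare each hypothesis'
#' parameter-free d-prime prediction with the observed 500 ms d-prime.
#' Under extrapolation truth the x5 prediction should track the data and
#' the x sqrt(5) prediction should overestimate performance.
#'
#' @param seed Integer master seed.
#' @param truth Generative [observer_params()] at the 100 ms ISI.
#' @param n_100,n_500 Trials per session.
#' @param pixel_pitch Display quantization, arcmin.
#' @param min_per_offset Offsets with fewer trials of either sign are not
#'   compared.
#' @return A list: `fit_100`, the two scaled parameter sets, `dprime_100`,
#'   and a `comparison` table with observed and predicted d-prime per
#'   offset at 500 ms.
#' @export
run_isi_comparison <- function(seed = 1L,
                               truth = observer_params(2, 0.5, 0.08, 100),
                               n_100 = 3000, n_500 = 6000,
                               pixel_pitch = 1.9, min_per_offset = 100) {
  ses100 <- generate_session(n_100, D = truth$D, isi_T = truth$T,
                             pixel_pitch = pixel_pitch,
                             seed = derive_seeds(seed, "isi100", 1L),
                             params = truth)
  fit100 <- fit_observer(ses100$trials, D = truth$D, T = truth$T)

  sc_ext <- predict_isi_scaling(fit100, "extrapolation")
  sc_int <- predict_isi_scaling(fit100, "integration")

  # 500 ms data generated under the extrapolation hypothesis applied to the
  # generative truth
  truth500 <- predict_isi_scaling(truth, "extrapolation")$params_scaled
  ses500 <- generate_session(n_500, D = truth$D, isi_T = truth500$T,
                             pixel_pitch = pixel_pitch,
                             seed = derive_seeds(seed, "isi500", 1L),
                             params = truth500)
  obs500 <- dprime(ses500$trials, drop_incomplete = TRUE)
  pred_ext <- predict_dprime(sc_ext$params_scaled, ses500$trials)
  pred_int <- predict_dprime(sc_int$params_scaled, ses500$trials)

  comp <- merge(merge(obs500[, c("offset", "n", "dprime")],
                      pred_ext[, c("offset", "dprime_pred")], by = "offset"),
                pred_int[, c("offset", "dprime_pred")], by = "offset",
                suffixes = c("_extrapolation", "_integration"))
  # require both signs well populated
  ok <- vapply(comp$offset, function(m) {
    sum(ses500$trials$x_display == m) >= min_per_offset / 2 &&
      sum(ses500$trials$x_display == -m) >= min_per_offset / 2
  }, logical(1))
  comp <- comp[ok & comp$n >= min_per_offset, , drop = FALSE]
  list(fit_100 = fit100, scaling_extrapolation = sc_ext,
       scaling_integration = sc_int,
       dprime_100 = dprime(ses100$trials, drop_incomplete = TRUE),
       comparison = comp)
}
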