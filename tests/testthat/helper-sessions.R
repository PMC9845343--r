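# Shared fixtures, built in code. Sessions are cached per (n, seed, params)
# within a test run so several tests can reuse one simulation.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(n, seed, params = NULL, isi_T = 100,
                           pixel_pitch = 1.9, D = 0.08, ...) {
  key <- paste(n, seed, isi_T, pixel_pitch, D,
               if (is.null(params)) "none"
               else paste(params$sigma_e, params$sigma_r, params$D, params$T),
               sep = "|")
  if (is.null(.session_cache[[key]]))
    .session_cache[[key]] <- generate_session(n, D = D, isi_T = isi_T,
                                              pixel_pitch = pixel_pitch,
                                              seed = seed, params = params, ...)
  .session_cache[[key]]
}

truth_params <- function() observer_params(2, 0.5, 0.08, 100)

# random parameter/measurement draws spanning the tested regime
random_draws <- function(n, seed) {
  set.seed(seed)
  data.frame(sigma_e = 10^runif(n, -1, 2),
             sigma_r = 10^runif(n, -1, 1),
             DT = 10^runif(n, -1, 2),
             x_r = runif(n, -2, 2))
}
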