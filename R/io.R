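## Delimited-text interchange formats: trial tables and eye traces as CSV,
## run configuration as YAML or JSON, segmentations as JSON intervals.

TRIAL_COLUMNS <- c("trial_id", "isi_T", "t1", "t2", "x_e", "x_r", "x_display",
                   "bottom_first", "response", "pixel_pitch")

#' Read and write trial tables
#'
#' CSV with one header row and columns exactly `trial_id, isi_T, t1, t2,
#' x_e, x_r, x_display, bottom_first, response, pixel_pitch`.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `read_trials()` returns the trial data frame; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing)) stop("trial table lacks column(s): ",
                            paste(missing, collapse = ", "))
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(response = "character"))
  missing <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing)) stop("trial file lacks column(s): ",
                            paste(missing, collapse = ", "))
  tr$response[!is.na(tr$response) & tr$response == ""] <- NA_character_
  tr$bottom_first <- as.logical(tr$bottom_first)
  tr
}

#' Read and write eye traces
#'
#' CSV with columns `t, x, y, label` on a 1 kHz grid.
#'
#' @param trace An eye trace.
#' @param path File path.
#' @return `read_trace()` returns the trace; `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  utils::write.csv(trace[, c("t", "x", "y", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trace(tr)
  class(tr) <- c("eye_trace", "data.frame")
  tr
}

#' Write a segmentation as JSON intervals
#'
#' @param seg A `segmentation`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  jsonlite::write_json(list(speed_threshold = seg$speed_threshold,
                            smooth_taps = seg$smooth_taps,
                            merge_ms = seg$merge_ms,
                            min_duration_ms = seg$min_duration_ms,
                            intervals = seg$intervals),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML or JSON (by extension) with the experiment block keys `D`,
#' `sigma_e`, `sigma_r`, `isi_T`, `pixel_pitch`, `n_trials`, `seed` and
#' optional analysis keys (`n_boot`, `target_bin_count`, `dt_range`,
#' `tw_range`, `grid_step`, `variant`, `mode`). Missing analysis keys get
#' defaults; missing experiment keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a named list
#'   (already-parsed config).
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
  need <- c("D", "sigma_e", "sigma_r", "isi_T", "pixel_pitch", "n_trials", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) stop("config lacks key(s): ", paste(missing, collapse = ", "))
  if (any(unlist(cfg[c("isi_T", "n_trials", "pixel_pitch")]) <= 0))
    stop("isi_T, pixel_pitch and n_trials must be positive")
  defaults <- list(n_boot = 2000, target_bin_count = 60,
                   dt_range = c(-200, 300), tw_range = c(20, 300),
                   grid_step = 10, variant = "full", mode = "map")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
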