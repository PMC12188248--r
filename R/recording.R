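RECORDING_FORMAT <- "flyssvep-recording"
RECORDING_VERSION <- "1.0"

#' Construct a multichannel recording object
#'
#' The in-memory container tying together the LFP matrix, the behavioural
#' traces, the stimulus event log and (for simulated data) the ground-truth
#' labels. All traces share one sample clock.
#'
#' @param lfp Numeric matrix, channels x samples (arbitrary-unit volts).
#' @param fs Sampling rate, Hz.
#' @param movement Per-sample movement-activity magnitude.
#' @param proboscis Per-sample proboscis extension distance.
#' @param events Stimulus event tibble (see [build_trial()]).
#' @param truth Optional ground-truth list with elements `bouts`, `deep`,
#'   `pe_events` and `amplitudes`; `NULL` for real data.
#' @param config Optional simulator configuration list.
#' @param channel_ids Original 1-based channel indices for each LFP row
#'   (re-referencing drops a channel but keeps the original numbering).
#' @param processed Character vector of preprocessing steps already applied.
#' @param fly_id Identifier carried into all downstream tables.
#' @return An object of class `"fly_recording"`.
#' @export
new_recording <- function(lfp, fs, movement = numeric(nrow_samples),
                          proboscis = numeric(nrow_samples),
                          events = NULL, truth = NULL, config = NULL,
                          channel_ids = seq_len(nrow(lfp)),
                          processed = character(0), fly_id = "fly01") {
  stopifnot(is.matrix(lfp))
  nrow_samples <- ncol(lfp)
  n <- ncol(lfp)
  if (length(movement) != n || length(proboscis) != n) {
    abort_flyssvep("all traces must share the LFP sample count.",
                   "flyssvep_invalid_spec")
  }
  structure(
    list(lfp = lfp, fs = fs, movement = as.numeric(movement),
         proboscis = as.numeric(proboscis), events = events, truth = truth,
         config = config, channel_ids = as.integer(channel_ids),
         processed = processed, fly_id = fly_id),
    class = "fly_recording")
}

#' @export
print.fly_recording <- function(x, ...) {
  cat(sprintf("<fly_recording> %s: %d channels x %d samples @ %g Hz (%.1f min)\n",
              x$fly_id, nrow(x$lfp), ncol(x$lfp), x$fs,
              ncol(x$lfp) / x$fs / 60))
  cat(sprintf("  events: %d | truth: %s | processed: %s\n",
              if (is.null(x$events)) 0L else nrow(x$events),
              if (is.null(x$truth)) "absent" else "present",
              if (length(x$processed)) paste(x$processed, collapse = " -> ")
              else "none"))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [new_recording()] object.
#' @return Length of the recording in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$lfp) / rec$fs

#' Write a recording to a directory container
#'
#' Serialises all traces, the event log, the ground truth and the
#' configuration losslessly: a `meta.json` header plus Parquet tables
#' (`lfp`, `traces`, `events`, `truth_*`). Round-tripping reproduces the
#' LFP matrix bitwise.
#'
#' @param rec A [new_recording()] object.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fly_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = RECORDING_FORMAT, version = RECORDING_VERSION,
               fs = rec$fs, n_channels = nrow(rec$lfp),
               channel_ids = rec$channel_ids, fly_id = rec$fly_id,
               processed = rec$processed, has_truth = !is.null(rec$truth),
               config = rec$config)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  lfp_df <- as.data.frame(t(rec$lfp))
  names(lfp_df) <- sprintf("ch_%02d", rec$channel_ids)
  arrow::write_parquet(lfp_df, file.path(path, "lfp.parquet"))
  arrow::write_parquet(
    data.frame(movement = rec$movement, proboscis = rec$proboscis),
    file.path(path, "traces.parquet"))
  if (!is.null(rec$events)) {
    arrow::write_parquet(rec$events, file.path(path, "events.parquet"))
    utils::write.csv(rec$events, file.path(path, "events.csv"),
                     row.names = FALSE)
  }
  if (!is.null(rec$truth)) {
    for (nm in c("bouts", "deep", "pe_events", "amplitudes")) {
      if (!is.null(rec$truth[[nm]])) {
        arrow::write_parquet(rec$truth[[nm]],
                             file.path(path, sprintf("truth_%s.parquet", nm)))
      }
    }
    if (!is.null(rec$truth$bouts)) {
      utils::write.csv(rec$truth$bouts, file.path(path, "bouts.csv"),
                       row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a recording from a directory container
#'
#' A container without truth tables loads with `truth = NULL` (real-data
#' mode). Malformed containers raise a format error naming the missing
#' component; a version mismatch raises an unsupported-version error.
#'
#' @param path Directory written by [write_recording()].
#' @return A [new_recording()] object.
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    abort_flyssvep("container is missing component 'meta.json'.",
                   "flyssvep_format")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, RECORDING_FORMAT)) {
    abort_flyssvep("file is not a flyssvep recording container.",
                   "flyssvep_format")
  }
  if (!identical(meta$version, RECORDING_VERSION)) {
    abort_flyssvep(
      sprintf("unsupported container version '%s' (expected '%s').",
              meta$version, RECORDING_VERSION),
      "flyssvep_unsupported_version")
  }
  for (f in c("lfp.parquet", "traces.parquet")) {
    if (!file.exists(file.path(path, f))) {
      abort_flyssvep(sprintf("container is missing component '%s'.", f),
                     "flyssvep_format")
    }
  }
  lfp <- t(as.matrix(as.data.frame(
    arrow::read_parquet(file.path(path, "lfp.parquet")))))
  dimnames(lfp) <- NULL
  traces <- arrow::read_parquet(file.path(path, "traces.parquet"))
  events <- NULL
  if (file.exists(file.path(path, "events.parquet"))) {
    events <- tibble::as_tibble(
      arrow::read_parquet(file.path(path, "events.parquet")))
  }
  truth <- NULL
  if (isTRUE(meta$has_truth)) {
    truth <- list()
    for (nm in c("bouts", "deep", "pe_events", "amplitudes")) {
      f <- file.path(path, sprintf("truth_%s.parquet", nm))
      if (file.exists(f)) {
        truth[[nm]] <- tibble::as_tibble(arrow::read_parquet(f))
      }
    }
    if (length(truth) == 0) truth <- NULL
  }
  new_recording(lfp, fs = meta$fs, movement = traces$movement,
                proboscis = traces$proboscis, events = events, truth = truth,
                config = meta$config, channel_ids = meta$channel_ids,
                processed = as.character(meta$processed %||% character(0)),
                fly_id = meta$fly_id %||% "fly01")
}
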