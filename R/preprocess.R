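#' Downsample all traces of a recording
#'
#' Resamples the LFP, movement and proboscis traces to `target_fs` on one
#' shared clock. Integer decimation with an anti-aliasing FIR low-pass is
#' used (`signal::decimate`); event onset times are stored in seconds and
#' are unchanged.
#'
#' @param rec A [new_recording()].
#' @param target_fs Target sampling rate, Hz. Must not exceed the current
#'   rate and must divide it.
#' @return The downsampled recording.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "fly_recording"))
  if (target_fs > rec$fs) {
    abort_flyssvep("`target_fs` must not exceed the recording rate.",
                   "flyssvep_invalid_argument")
  }
  if (target_fs == rec$fs) {
    rec$processed <- union(rec$processed, "downsample")
    return(rec)
  }
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    abort_flyssvep("`target_fs` must divide the recording rate.",
                   "flyssvep_invalid_argument")
  }
  q <- as.integer(round(q))
  # Fourier anti-aliasing: zero all content at or above the new Nyquist,
  # then take every q-th sample. Exact for band-limited signals.
  dec <- function(x) {
    n <- length(x)
    X <- stats::fft(x)
    f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * rec$fs / n
    X[f >= target_fs / 2] <- 0
    Re(stats::fft(X, inverse = TRUE) / n)[seq(1, n, by = q)]
  }
  lfp <- t(apply(rec$lfp, 1, dec))
  rec$lfp <- lfp
  rec$movement <- dec(rec$movement)[seq_len(ncol(lfp))]
  rec$proboscis <- dec(rec$proboscis)[seq_len(ncol(lfp))]
  rec$fs <- target_fs
  rec$processed <- union(rec$processed, "downsample")
  rec
}

# FFT-domain notch: zero a band of half-width `bw/2` around each target
# frequency (and its mirror), then invert. Linear-phase, exact passband.
fft_notch <- function(x, fs, freqs, bw = 1) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_sym <- pmin(f, fs - f)
  kill <- rep(FALSE, n)
  for (f0 in freqs) kill <- kill | abs(f_sym - f0) <= bw / 2
  X[kill] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Remove mains line noise at a base frequency and its harmonics
#'
#' Applies a narrow (1 Hz bandwidth) spectral notch at `base_hz` and every
#' harmonic below the Nyquist frequency, on all LFP channels. Stimulus-band
#' power (10 Hz carrier, 2 Hz deviant) is untouched. A no-op if no harmonic
#' lies below Nyquist.
#'
#' @param rec A [new_recording()].
#' @param base_hz Mains base frequency (default 50).
#' @param bw Notch bandwidth in Hz (default 1).
#' @return The filtered recording.
#' @export
remove_line_noise <- function(rec, base_hz = 50, bw = 1) {
  stopifnot(inherits(rec, "fly_recording"))
  nyq <- rec$fs / 2
  harmonics <- base_hz * seq_len(floor((nyq - 1e-9) / base_hz))
  if (length(harmonics) > 0) {
    for (ch in seq_len(nrow(rec$lfp))) {
      rec$lfp[ch, ] <- fft_notch(rec$lfp[ch, ], rec$fs, harmonics, bw)
    }
  }
  rec$processed <- union(rec$processed, "line_noise")
  rec
}

#' Locate the polarity-reversal channel
#'
#' Computes the per-channel event-locked average response over one
#' inter-stimulus interval and returns the channel with the smallest
#' peak-trough amplitude among channels at which the dominant deflection
#' (the signed extremum of the average waveform) changes sign between
#' neighbouring channels. Ties break to the lower index. Raises a
#' no-reversal error when no sign change exists, the signature of an
#' insertion without a visual response.
#'
#' @param rec A [new_recording()].
#' @param events Stimulus events to average over; defaults to the
#'   recording's own event table.
#' @param max_events Cap on the number of (earliest) events used
#'   (default 2000).
#' @param window_s ERP window after onset, seconds (default one 10 Hz
#'   inter-stimulus interval).
#' @return The 1-based reversal channel index (original channel numbering).
#' @export
find_reversal_channel <- function(rec, events = rec$events,
                                  max_events = 2000, window_s = 0.1) {
  stopifnot(inherits(rec, "fly_recording"))
  if (is.null(events) || nrow(events) < 100) {
    abort_flyssvep("at least 100 stimulus events are required.",
                   "flyssvep_invalid_argument")
  }
  events <- utils::head(dplyr::arrange(events, .data$onset_time_s), max_events)
  L <- as.integer(round(window_s * rec$fs))
  onset_idx <- as.integer(round(events$onset_time_s * rec$fs)) + 1L
  onset_idx <- onset_idx[onset_idx + L - 1L <= ncol(rec$lfp) & onset_idx >= 1L]
  cols <- outer(onset_idx, 0:(L - 1L), `+`)
  erp <- matrix(0, nrow = nrow(rec$lfp), ncol = L)
  for (ch in seq_len(nrow(rec$lfp))) {
    m <- matrix(rec$lfp[ch, ][cols], nrow = length(onset_idx))
    erp[ch, ] <- colMeans(m)
  }
  amp <- row_max(erp) - row_min(erp)
  # dominant deflection sign: sign of the extremum with the larger magnitude
  dom <- apply(erp, 1, function(w) sign(w[which.max(abs(w))]))
  flips <- which(dom[-1] * dom[-length(dom)] < 0)
  if (length(flips) == 0) {
    abort_flyssvep(
      "no polarity reversal found: recording lacks a sign-inverting visual response.",
      "flyssvep_no_reversal")
  }
  candidates <- sort(unique(c(flips, flips + 1L)))
  ch <- candidates[which.min(amp[candidates])]
  rec$channel_ids[ch]
}

#' Re-reference a recording to one channel
#'
#' Subtracts the reference channel from every other channel and drops it,
#' leaving `n_channels - 1` channels; any signal common to all channels is
#' removed exactly. The retained rows keep their original channel indices
#' in `channel_ids`.
#'
#' @param rec A [new_recording()].
#' @param ref_channel Original 1-based index of the reference channel.
#' @return The re-referenced recording.
#' @export
rereference <- function(rec, ref_channel) {
  stopifnot(inherits(rec, "fly_recording"))
  row <- match(ref_channel, rec$channel_ids)
  if (is.na(row)) {
    abort_flyssvep("`ref_channel` is not a channel of this recording.",
                   "flyssvep_invalid_argument")
  }
  ref <- rec$lfp[row, ]
  lfp <- sweep(rec$lfp[-row, , drop = FALSE], 2, ref, "-")
  rec$lfp <- lfp
  rec$channel_ids <- rec$channel_ids[-row]
  rec$reference_channel <- as.integer(ref_channel)
  rec$processed <- union(rec$processed, "rereference")
  rec
}

#' Assign the three analysis regions from the reversal channel
#'
#' Central = reversal - 8, intermediate = reversal - 3, peripheral =
#' reversal + 3, each clamped into `1..n_channels` with a warning when
#' clamping occurs (for a typical reversal at channel 11 this gives
#' channels 3, 8 and 14).
#'
#' @param reversal_channel 1-based reversal channel index.
#' @param n_channels Total number of channels (default 16).
#' @return A list of class `"channel_map"` with elements `reversal_channel`,
#'   `central`, `intermediate`, `peripheral`.
#' @export
#' @examples
#' assign_regions(11)
assign_regions <- function(reversal_channel, n_channels = 16) {
  if (reversal_channel < 1 || reversal_channel > n_channels) {
    abort_flyssvep("`reversal_channel` must lie within 1..n_channels.",
                   "flyssvep_invalid_argument")
  }
  clamp <- function(x, name) {
    y <- min(max(x, 1L), n_channels)
    if (y != x) {
      warning(sprintf("%s channel %d clamped to %d.", name, x, y),
              call. = FALSE)
    }
    as.integer(y)
  }
  structure(
    list(reversal_channel = as.integer(reversal_channel),
         central = clamp(reversal_channel - 8L, "central"),
         intermediate = clamp(reversal_channel - 3L, "intermediate"),
         peripheral = clamp(reversal_channel + 3L, "peripheral")),
    class = "channel_map")
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf(
    "<channel_map> reversal %d | central %d, intermediate %d, peripheral %d\n",
    x$reversal_channel, x$central, x$intermediate, x$peripheral))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' Fixed order: downsample, line-noise removal, reversal detection,
#' re-referencing, region assignment. Refuses to re-run on a recording that
#' has already been preprocessed.
#'
#' @param rec A raw [new_recording()].
#' @param target_fs Target sampling rate (default: keep the current rate).
#' @param base_hz Mains frequency for the notch (default 50).
#' @param max_span_s Only the first `max_span_s` seconds are retained for
#'   analysis (default 6 h), mirroring long-recording practice where signal
#'   quality degrades over time.
#' @return A list with `rec` (the processed recording), `channel_map`,
#'   `reversal_channel`, and a machine-readable `report` (reversal channel,
#'   region map, clamping warnings, fraction of the recording retained);
#'   see [write_preprocessing_report()].
#' @export
preprocess_recording <- function(rec, target_fs = rec$fs, base_hz = 50,
                                 max_span_s = 6 * 3600) {
  stopifnot(inherits(rec, "fly_recording"))
  if (length(rec$processed) > 0) {
    abort_flyssvep("recording has already been preprocessed; refusing to re-run.",
                   "flyssvep_already_processed")
  }
  if (recording_duration(rec) > max_span_s) {
    keep <- seq_len(as.integer(max_span_s * rec$fs))
    rec$lfp <- rec$lfp[, keep, drop = FALSE]
    rec$movement <- rec$movement[keep]
    rec$proboscis <- rec$proboscis[keep]
    rec$events <- rec$events[rec$events$onset_time_s +
                               rec$events$duration_s <= max_span_s, ]
  }
  full_span <- recording_duration(rec)
  rec <- downsample(rec, target_fs)
  rec <- remove_line_noise(rec, base_hz)
  rev_ch <- find_reversal_channel(rec)
  rec <- rereference(rec, rev_ch)
  clamp_warnings <- character(0)
  cmap <- withCallingHandlers(
    assign_regions(rev_ch, n_channels = length(rec$channel_ids) + 1L),
    warning = function(w) {
      clamp_warnings <<- c(clamp_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  report <- list(reversal_channel = rev_ch,
                 region_map = unclass(cmap),
                 clamping_warnings = clamp_warnings,
                 fs = rec$fs,
                 fraction_retained = recording_duration(rec) / full_span)
  list(rec = rec, channel_map = cmap, reversal_channel = rev_ch,
       report = report)
}

#' Write the preprocessing report as JSON
#'
#' @param pp Output of [preprocess_recording()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_preprocessing_report <- function(pp, path) {
  jsonlite::write_json(pp$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
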