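#' Extract event-locked epochs
#'
#' One waveform slice per stimulus event per analysis channel, time-locked
#' to the event onset over `window_s` (default one inter-stimulus interval,
#' so consecutive epochs never overlap). Events whose window would run past
#' the end of the recording are dropped and counted in the
#' `"n_dropped"` attribute.
#'
#' @param rec A [new_recording()].
#' @param events Stimulus events (default: the recording's event table).
#' @param channels Original channel indices to extract (default: all).
#' @param window_s Two-element window relative to onset, seconds.
#' @return A tibble: `fly_id`, `trial_id`, `seq_index`, `channel`, `epoch`
#'   (list-column of numeric vectors).
#' @export
extract_epochs <- function(rec, events = rec$events,
                           channels = rec$channel_ids,
                           window_s = c(0, 0.1)) {
  stopifnot(inherits(rec, "fly_recording"))
  isi <- 1 / infer_f1(events)
  if (diff(window_s) > isi + 1e-9) {
    abort_flyssvep("epoch window exceeds the inter-stimulus interval.",
                   "flyssvep_invalid_argument")
  }
  L <- as.integer(round(diff(window_s) * rec$fs))
  off <- as.integer(round(window_s[1] * rec$fs))
  onset_idx <- as.integer(round(events$onset_time_s * rec$fs)) + 1L + off
  ok <- onset_idx >= 1L & onset_idx + L - 1L <= ncol(rec$lfp)
  n_dropped <- sum(!ok)
  events <- events[ok, ]
  onset_idx <- onset_idx[ok]
  cols <- outer(onset_idx, 0:(L - 1L), `+`)
  out <- purrr::map(channels, function(ch) {
    row <- match(ch, rec$channel_ids)
    m <- matrix(rec$lfp[row, ][cols], nrow = nrow(events))
    tibble::tibble(fly_id = rec$fly_id, trial_id = events$trial_id,
                   seq_index = events$seq_index, channel = ch,
                   epoch = purrr::map(asplit(m, 1), as.numeric))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "fs") <- rec$fs
  out
}

infer_f1 <- function(events) {
  d <- diff(sort(events$onset_time_s))
  d <- d[d > 0]
  if (length(d) == 0) return(10)
  1 / min(d)
}

#' Peak-trough amplitude of one epoch
#'
#' `max(epoch) - min(epoch)` over the post-onset window, order-agnostic:
#' the peak may precede or follow the trough. Invariant to adding a
#' constant; scales linearly with the epoch.
#'
#' @param epoch Numeric waveform.
#' @return Non-negative scalar amplitude.
#' @export
#' @examples
#' epoch_amplitude(c(0, 3, -2, 1)) # 5
epoch_amplitude <- function(epoch) {
  if (length(epoch) == 0) {
    abort_flyssvep("`epoch` is empty.", "flyssvep_invalid_argument")
  }
  max(epoch) - min(epoch)
}

#' Compute per-event SSVEP amplitude records
#'
#' Vectorised peak-trough amplitude of every stimulus event on each analysis
#' channel, assembled into the long amplitude-record table that all
#' downstream grouping, normalisation and statistics operate on.
#'
#' @param rec A [new_recording()].
#' @param channel_map A [assign_regions()] map (rows are produced for the
#'   central, intermediate and peripheral channels), or a plain integer
#'   vector of original channel indices (region is then `"ch<k>"`,
#'   supporting the all-channels analysis mode).
#' @param events Stimulus events (default: the recording's table).
#' @param window_s Amplitude search window after onset, seconds.
#' @return A tibble: `fly_id`, `trial_id`, `seq_index`, `onset_time_s`,
#'   `channel`, `region`, `color`, `role`, `amp_raw`.
#' @export
compute_amplitudes <- function(rec, channel_map, events = rec$events,
                               window_s = c(0, 0.1)) {
  stopifnot(inherits(rec, "fly_recording"))
  if (inherits(channel_map, "channel_map")) {
    channels <- c(channel_map$central, channel_map$intermediate,
                  channel_map$peripheral)
    regions <- c("central", "intermediate", "peripheral")
  } else {
    channels <- as.integer(channel_map)
    regions <- sprintf("ch%02d", channels)
  }
  isi <- 1 / infer_f1(events)
  if (diff(window_s) > isi + 1e-9) {
    abort_flyssvep("amplitude window exceeds the inter-stimulus interval.",
                   "flyssvep_invalid_argument")
  }
  L <- as.integer(round(diff(window_s) * rec$fs))
  off <- as.integer(round(window_s[1] * rec$fs))
  onset_idx <- as.integer(round(events$onset_time_s * rec$fs)) + 1L + off
  ok <- onset_idx >= 1L & onset_idx + L - 1L <= ncol(rec$lfp)
  events <- events[ok, ]
  onset_idx <- onset_idx[ok]
  cols <- outer(onset_idx, 0:(L - 1L), `+`)
  recs <- purrr::map2(channels, regions, function(ch, rg) {
    row <- match(ch, rec$channel_ids)
    if (is.na(row)) {
      abort_flyssvep(sprintf("channel %d is not in the recording.", ch),
                     "flyssvep_invalid_argument")
    }
    m <- matrix(rec$lfp[row, ][cols], nrow = nrow(events))
    tibble::tibble(
      fly_id = rec$fly_id, trial_id = events$trial_id,
      seq_index = events$seq_index, onset_time_s = events$onset_time_s,
      channel = ch, region = rg, color = events$color, role = events$role,
      amp_raw = row_max(m) - row_min(m))
  })
  dplyr::bind_rows(recs)
}

#' Label stimulus history on an event table
#'
#' Annotates every event with the colour and role of the immediately
#' preceding event in its trial (`prev_color`, `prev_role`; `NA` for the
#' first event of a trial, which is thereby excluded from history-matched
#' contrasts) and numbers the carriers following each deviant in order
#' (`carrier_order` 1, 2, 3, ...). Carriers before the first deviant of a
#' trial, and deviants themselves, have `carrier_order = NA`.
#'
#' @param events A stimulus event tibble.
#' @return The events with `prev_color`, `prev_role`, `carrier_order` added.
#' @export
label_history <- function(events) {
  events <- dplyr::arrange(events, .data$trial_id, .data$onset_time_s)
  events <- dplyr::mutate(
    dplyr::group_by(events, .data$trial_id),
    prev_color = dplyr::lag(.data$color),
    prev_role = dplyr::lag(.data$role),
    .block = cumsum(.data$role == "deviant"),
    # carriers preceding each deviant: gap to the previous deviant (the
    # run of carriers since the trial start, for the first deviant)
    carrier_run = dplyr::if_else(
      .data$role == "deviant",
      dplyr::row_number() -
        dplyr::lag(dplyr::if_else(.data$role == "deviant",
                                  dplyr::row_number(), NA_integer_) |>
                     cumsummax(), default = 0L) - 1L,
      NA_integer_))
  events <- dplyr::mutate(
    dplyr::group_by(events, .data$trial_id, .data$.block),
    carrier_order = dplyr::if_else(
      .data$role == "carrier" & .data$.block > 0,
      dplyr::row_number() - 1L, NA_integer_))
  dplyr::select(dplyr::ungroup(events), -".block")
}

# running maximum that carries the last non-NA value forward
cumsummax <- function(x) {
  out <- x
  last <- 0L
  for (i in seq_along(x)) {
    if (is.na(x[i])) out[i] <- last else last <- out[i] <- x[i]
  }
  out
}

#' Label behavioural state, segment and proboscis context on records
#'
#' Adds `state` (wake/sleep of the bout containing each event's onset),
#' `segment` (the one-minute segment label when the onset falls in one,
#' else `NA`) and, when spells and their events are supplied, `pe_context`
#' (`"in_spell_window_sleep"` / `"in_spell_window_wake"` for events lying
#' in an inter-extension sampling window of a rhythmic spell, `"none"`
#' otherwise) together with `pe_segment` (the segment label of the spell's
#' start).
#'
#' @param records An event or amplitude-record tibble with `onset_time_s`.
#' @param bouts Output of [score_bouts()].
#' @param segments Optional output of [segment_bouts()].
#' @param pe Optional output of [classify_pe()].
#' @param guard_s,min_window_s Passed to [inter_pe_windows()].
#' @return `records` with the state/segment/PE-context columns added.
#' @export
label_state <- function(records, bouts, segments = NULL, pe = NULL,
                        guard_s = 0.05, min_window_s = 0.1) {
  i <- findInterval(records$onset_time_s, bouts$start_s)
  i[i < 1] <- 1L
  records$state <- bouts$state[i]
  records$segment <- NA_character_
  if (!is.null(segments) && nrow(segments) > 0) {
    for (k in seq_len(nrow(segments))) {
      in_seg <- records$onset_time_s >= segments$start_s[k] &
        records$onset_time_s < segments$end_s[k]
      records$segment[in_seg] <- segments$label[k]
    }
  }
  records$pe_context <- "none"
  records$pe_segment <- NA_character_
  if (!is.null(pe) && nrow(pe$spells) > 0) {
    for (k in seq_len(nrow(pe$spells))) {
      sid <- pe$spells$spell_id[k]
      ev <- pe$events[!is.na(pe$events$spell_id) & pe$events$spell_id == sid, ]
      if (nrow(ev) < 2) next
      win <- inter_pe_windows(ev, guard_s = guard_s,
                              min_window_s = min_window_s)
      if (nrow(win) == 0) next
      hit <- rep(FALSE, nrow(records))
      for (w in seq_len(nrow(win))) {
        hit <- hit | (records$onset_time_s >= win$start_s[w] &
                        records$onset_time_s < win$end_s[w])
      }
      ctx <- if (identical(pe$spells$state[k], "sleep")) {
        "in_spell_window_sleep"
      } else {
        "in_spell_window_wake"
      }
      records$pe_context[hit] <- ctx
      if (!is.null(segments) && nrow(segments) > 0) {
        j <- which(segments$start_s <= pe$spells$start_s[k] &
                     segments$end_s > pe$spells$start_s[k])
        if (length(j) == 1) records$pe_segment[hit] <- segments$label[j]
      }
    }
  }
  records
}

#' Per-colour normalisation of raw amplitudes
#'
#' Within each fly and channel, the mean raw amplitude of all events of a
#' colour (carriers and deviants pooled, "regardless of identity") is the
#' denominator; each event's `amp_norm` is its proportion of that value, so
#' `mean(amp_norm)` is exactly 1 over every normalisation pool.
#'
#' @param records Amplitude records from [compute_amplitudes()].
#' @return `records` with `amp_norm` added.
#' @export
normalize_amplitudes <- function(records) {
  out <- dplyr::mutate(
    dplyr::group_by(records, .data$fly_id, .data$channel, .data$color),
    .pool_mean = mean(.data$amp_raw),
    amp_norm = .data$amp_raw / .data$.pool_mean) |>
    dplyr::ungroup()
  if (any(out$.pool_mean == 0)) {
    abort_flyssvep("a normalisation pool has zero mean amplitude.",
                   "flyssvep_degenerate_normalization")
  }
  dplyr::select(out, -".pool_mean")
}

CONTRASTS <- c("carrier_vs_deviant", "carrier_order", "wake_vs_sleep",
               "segments", "pe_context", "jitter_vs_phasic")

#' Select the event groups of a named contrast
#'
#' Implements the comparisons of the analysis: all are history-matched so
#' both groups share a colour-transition history.
#'
#' * `carrier_vs_deviant`: within a colour, first carriers after a deviant
#'   (`carrier_order == 1`) vs deviants preceded by a carrier.
#' * `carrier_order`: within a colour, carriers of order 1-4 (groups
#'   `"1"`..`"4"`).
#' * `wake_vs_sleep`: within a role (same event selection as
#'   `carrier_vs_deviant`), grouped by behavioural state.
#' * `segments`: within a role, grouped by one-minute segment label.
#' * `pe_context`: within a role, only events inside inter-extension
#'   sampling windows of rhythmic spells, grouped by the spell's segment
#'   label.
#' * `jitter_vs_phasic`: deviants preceded by exactly four carriers,
#'   grouped by trial type (requires a `trial_type` column).
#'
#' @param records Labelled amplitude records (after [label_history()] /
#'   [label_state()] joins).
#' @param contrast One of the names above.
#' @param color Restrict to one colour (`NULL` pools both, retaining the
#'   within-colour normalisation).
#' @param role For the state/segment/PE contrasts: `"carrier"` or
#'   `"deviant"`.
#' @return The selected records with a `group` factor column; attribute
#'   `"contrast"` records the name.
#' @export
select_contrast <- function(records, contrast, color = NULL, role = "deviant") {
  if (!contrast %in% CONTRASTS) {
    abort_flyssvep(sprintf("unknown contrast '%s'.", contrast),
                   "flyssvep_invalid_argument")
  }
  if (!is.null(color)) records <- records[records$color == color, ]
  matched_sel <- function(r) {
    (r$role == "carrier" & !is.na(r$carrier_order) & r$carrier_order == 1L) |
      (r$role == "deviant" & !is.na(r$prev_role) & r$prev_role == "carrier")
  }
  out <- switch(
    contrast,
    carrier_vs_deviant = {
      r <- records[matched_sel(records), ]
      r$group <- r$role
      r
    },
    carrier_order = {
      r <- records[records$role == "carrier" & !is.na(records$carrier_order) &
                     records$carrier_order %in% 1:4, ]
      r$group <- as.character(r$carrier_order)
      r
    },
    wake_vs_sleep = {
      r <- records[matched_sel(records) & records$role == role, ]
      r$group <- r$state
      r
    },
    segments = {
      r <- records[matched_sel(records) & records$role == role &
                     !is.na(records$segment), ]
      r$group <- r$segment
      r
    },
    pe_context = {
      r <- records[matched_sel(records) & records$role == role &
                     records$pe_context != "none" &
                     !is.na(records$pe_segment), ]
      r$group <- r$pe_segment
      r
    },
    jitter_vs_phasic = {
      if (!"trial_type" %in% names(records)) {
        abort_flyssvep("`jitter_vs_phasic` needs a `trial_type` column.",
                       "flyssvep_invalid_argument")
      }
      r <- records[records$role == "deviant" & !is.na(records$carrier_run) &
                     records$carrier_run == 4L, ]
      r$group <- r$trial_type
      r
    })
  out$group <- factor(out$group)
  attr(out, "contrast") <- contrast
  out
}

#' Comparison-specific corrected amplitudes
#'
#' For each fly, the unweighted mean of its per-group mean normalised
#' amplitudes is subtracted from every record, yielding the
#' comparison-specific "corrected amplitude": within each fly the group
#' means of `amp_corrected` average to zero exactly. Flies missing any
#' group of the contrast are excluded (with a message).
#'
#' @param records Output of [select_contrast()] (has a `group` column).
#' @return The records of retained flies with `amp_corrected` added.
#' @export
corrected_amplitude <- function(records) {
  n_groups <- length(unique(records$group))
  complete <- dplyr::summarise(
    dplyr::group_by(records, .data$fly_id),
    ok = length(unique(.data$group)) == n_groups, .groups = "drop")
  dropped <- complete$fly_id[!complete$ok]
  if (length(dropped) > 0) {
    message(sprintf("excluding %d fly/flies missing a group: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    records <- records[!records$fly_id %in% dropped, ]
  }
  fly_center <- dplyr::summarise(
    dplyr::group_by(records, .data$fly_id, .data$group),
    .gmean = mean(.data$amp_norm), .groups = "drop_last") |>
    dplyr::summarise(.center = mean(.data$.gmean), .groups = "drop")
  out <- dplyr::left_join(records, fly_center, by = "fly_id")
  out$amp_corrected <- out$amp_norm - out$.center
  attr_keep <- attr(records, "contrast")
  out <- dplyr::select(out, -".center")
  attr(out, "contrast") <- attr_keep
  out
}

#' Trial-averaged LFP power spectrum
#'
#' Single-taper periodogram of one channel over each full trial span
#' (frequency resolution `1 / trial duration`, 0.05 Hz for 20 s trials),
#' normalised to unit total power per trial, then averaged across trials.
#' The carrier frequency appears as the F1 peak; with deviants present, the
#' deviant rate appears as the low-frequency F2 peak.
#'
#' @param rec A [new_recording()].
#' @param channel Original channel index to analyse.
#' @param trial_ids Trials to include (default: all trials in the event
#'   table).
#' @param trial_duration_s Span of one trial, seconds (default inferred
#'   from the events: `n_events / f1`).
#' @return A tibble of class `"flyssvep_spectrum"`: `freq_hz`, `power`
#'   (mean normalised power), `n_trials`.
#' @export
power_spectrum <- function(rec, channel, trial_ids = NULL,
                           trial_duration_s = NULL) {
  stopifnot(inherits(rec, "fly_recording"))
  events <- rec$events
  if (is.null(events) || nrow(events) == 0) {
    abort_flyssvep("recording has no stimulus events.",
                   "flyssvep_invalid_argument")
  }
  trial_ids <- trial_ids %||% unique(events$trial_id)
  row <- match(channel, rec$channel_ids)
  if (is.na(row)) {
    abort_flyssvep(sprintf("channel %d is not in the recording.", channel),
                   "flyssvep_invalid_argument")
  }
  starts <- dplyr::summarise(
    dplyr::group_by(events[events$trial_id %in% trial_ids, ],
                    .data$trial_id),
    t0 = min(.data$onset_time_s), n_ev = dplyr::n(), .groups = "drop")
  f1 <- infer_f1(events)
  trial_duration_s <- trial_duration_s %||% (max(starts$n_ev) / f1)
  n <- as.integer(round(trial_duration_s * rec$fs))
  specs <- list()
  for (k in seq_len(nrow(starts))) {
    i0 <- as.integer(round(starts$t0[k] * rec$fs)) + 1L
    if (i0 + n - 1L > ncol(rec$lfp)) next
    x <- rec$lfp[row, i0:(i0 + n - 1L)]
    P <- Mod(stats::fft(x - mean(x)))^2
    half <- 2:(floor(n / 2) + 1)       # exclude DC
    P <- P[half]
    specs[[length(specs) + 1]] <- P / sum(P)
  }
  if (length(specs) == 0) {
    abort_flyssvep("no complete trial lies within the recording.",
                   "flyssvep_invalid_argument")
  }
  freq <- (seq_len(floor(n / 2))) * rec$fs / n
  out <- tibble::tibble(freq_hz = freq,
                        power = Reduce(`+`, specs) / length(specs),
                        n_trials = length(specs))
  class(out) <- c("flyssvep_spectrum", class(out))
  out
}

#' Frequencies of the F1 and F2 spectral peaks
#'
#' F1 is the global maximum above `min_hz`; F2 is the maximum within the
#' low-frequency search band.
#'
#' @param spectrum A [power_spectrum()] result.
#' @param min_hz Lower edge of both searches (default 0.5).
#' @param f2_band Upper edge of the F2 search band, Hz (default 5).
#' @return Named list with `f1_hz` and `f2_hz`.
#' @export
spectrum_peaks <- function(spectrum, min_hz = 0.5, f2_band = 5) {
  s <- spectrum[spectrum$freq_hz >= min_hz, ]
  f1 <- s$freq_hz[which.max(s$power)]
  s2 <- s[s$freq_hz <= f2_band, ]
  f2 <- s2$freq_hz[which.max(s2$power)]
  list(f1_hz = f1, f2_hz = f2)
}

#' Grand-average event-related potential
#'
#' Pointwise mean of epochs within each fly, then across flies, per
#' grouping cell.
#'
#' @param epochs Output of [extract_epochs()], optionally with extra label
#'   columns joined on.
#' @param by Character vector of grouping columns (default `"channel"`).
#' @return A tibble with the grouping columns, `time_s`, `mean_lfp` and
#'   `n_flies`.
#' @export
average_erp <- function(epochs, by = "channel") {
  fs <- attr(epochs, "fs")
  long <- tidyr::unnest_longer(
    dplyr::mutate(epochs,
                  .t = purrr::map(.data$epoch, ~ seq_along(.x))),
    c("epoch", ".t"))
  long$time_s <- (long$.t - 1) / fs
  per_fly <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(by, "fly_id", "time_s")))),
    m = mean(.data$epoch), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_fly, dplyr::across(dplyr::all_of(c(by, "time_s")))),
    mean_lfp = mean(.data$m), n_flies = dplyr::n_distinct(.data$fly_id),
    .groups = "drop")
}
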