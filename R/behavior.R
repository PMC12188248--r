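#' Convert a movement trace into a binary activity series
#'
#' Bins the movement-activity magnitude (default 1 s bins) and marks a bin
#' active when its peak magnitude exceeds a threshold. By default the
#' threshold is a fixed fraction of a high quantile of the per-bin peaks,
#' which adapts to the sensor scale; an all-zero trace yields no active
#' bins.
#'
#' @param movement Numeric movement trace.
#' @param fs Sampling rate of the trace, Hz.
#' @param bin_s Bin width, seconds (default 1).
#' @param threshold Absolute activity threshold; if `NULL` (default),
#'   `0.2 * quantile(bin peaks, 0.95)`.
#' @return A tibble with one row per bin: `start_s`, `end_s`, `activity`
#'   (peak magnitude) and `active` (logical).
#' @export
quantify_movement <- function(movement, fs, bin_s = 1, threshold = NULL) {
  if (length(movement) == 0) {
    abort_flyssvep("`movement` is empty.", "flyssvep_invalid_input")
  }
  assert_positive(bin_s, "bin_s")
  bin_len <- as.integer(round(bin_s * fs))
  n_bins <- length(movement) %/% bin_len
  if (n_bins == 0) {
    abort_flyssvep("`movement` is shorter than one bin.", "flyssvep_invalid_input")
  }
  m <- matrix(movement[seq_len(n_bins * bin_len)], nrow = bin_len)
  activity <- apply(abs(m), 2, max)
  threshold <- threshold %||%
    (0.2 * stats::quantile(activity, 0.95, names = FALSE))
  tibble::tibble(
    start_s = (seq_len(n_bins) - 1) * bin_s,
    end_s = seq_len(n_bins) * bin_s,
    activity = activity,
    active = activity > threshold)
}

#' Score wake and sleep bouts from a binary activity series
#'
#' Maximal runs of inactive bins lasting `min_sleep_s` seconds or more
#' (boundary inclusive: exactly 5 min of quiescence is sleep) become sleep
#' bouts; all remaining time is wake. Adjacent same-state bouts are merged,
#' so the bouts tile the scored span with alternating states.
#'
#' @param activity Output of [quantify_movement()].
#' @param min_sleep_s Minimum quiescence duration counted as sleep,
#'   seconds (default 300).
#' @return A tibble of bouts: `state` (`"wake"`/`"sleep"`), `start_s`,
#'   `end_s`, `duration_s`.
#' @export
score_bouts <- function(activity, min_sleep_s = 300) {
  if (nrow(activity) == 0) {
    abort_flyssvep("`activity` is empty.", "flyssvep_invalid_input")
  }
  r <- rle(!activity$active)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  bin_s <- activity$end_s[1] - activity$start_s[1]
  state <- ifelse(r$values & r$lengths * bin_s >= min_sleep_s, "sleep", "wake")
  tbl <- tibble::tibble(
    state = state,
    start_s = activity$start_s[run_start],
    end_s = activity$end_s[run_end])
  # merge adjacent same-state runs (sub-threshold quiescence folds into wake)
  grp <- cumsum(c(TRUE, tbl$state[-1] != tbl$state[-nrow(tbl)]))
  out <- dplyr::summarise(
    dplyr::group_by(tbl, grp = grp),
    state = dplyr::first(.data$state),
    start_s = min(.data$start_s), end_s = max(.data$end_s), .groups = "drop")
  out <- dplyr::arrange(dplyr::select(out, -"grp"), .data$start_s)
  out$duration_s <- out$end_s - out$start_s
  out
}

minute_window <- function(bout_start_s, minute_1based) {
  tibble::tibble(start_s = bout_start_s + (minute_1based - 1) * 60,
                 end_s = bout_start_s + minute_1based * 60)
}

#' Segment bouts into labelled one-minute windows
#'
#' Each sleep bout contributes five one-minute windows: its first and second
#' minutes (`sleep_1st`, `sleep_2nd`), its middle minute (`mid_sleep`; for a
#' bout of D whole minutes the window starting at minute
#' `floor((D - 1) / 2) + 1`), and its last two minutes (`sleep_2nd_last`,
#' `sleep_last`). The wake bout immediately preceding each sleep bout
#' contributes its middle minute (`mid_wake`) and final minute
#' (`last_wake`); wake bouts shorter than two minutes yield no wake
#' segments. When windows from a short bout would overlap, first/last
#' windows take priority over middle ones and the overlapping middle
#' windows are dropped (impossible for sleep bouts of 5 min or more).
#'
#' @param bouts Output of [score_bouts()].
#' @return A tibble of segments: `bout_index`, `state`, `label`, `start_s`,
#'   `end_s`.
#' @export
segment_bouts <- function(bouts) {
  segs <- list()
  add <- function(bout_index, state, label, w) {
    segs[[length(segs) + 1]] <<- tibble::tibble(
      bout_index = bout_index, state = state, label = label,
      start_s = w$start_s, end_s = w$end_s)
  }
  for (i in seq_len(nrow(bouts))) {
    b <- bouts[i, ]
    if (b$state != "sleep") next
    d_min <- floor((b$end_s - b$start_s) / 60)
    if (d_min < 1) next
    mid <- floor((d_min - 1) / 2) + 1
    cand <- list(
      sleep_1st = 1, sleep_2nd = 2, mid_sleep = mid,
      sleep_2nd_last = d_min - 1, sleep_last = d_min)
    # priority: first/last windows beat middle ones on overlap
    priority <- c("sleep_1st", "sleep_last", "sleep_2nd", "sleep_2nd_last",
                  "mid_sleep")
    used <- integer(0)
    chosen <- list()
    for (lab in priority) {
      m <- cand[[lab]]
      if (m >= 1 && m <= d_min && !(m %in% used)) {
        used <- c(used, m)
        chosen[[lab]] <- m
      }
    }
    for (lab in names(cand)) {
      if (!is.null(chosen[[lab]])) {
        add(i, "sleep", lab, minute_window(b$start_s, chosen[[lab]]))
      }
    }
    # segments of the immediately preceding wake bout
    if (i > 1 && bouts$state[i - 1] == "wake") {
      wb <- bouts[i - 1, ]
      w_min <- floor((wb$end_s - wb$start_s) / 60)
      if (w_min >= 2) {
        w_mid <- floor((w_min - 1) / 2) + 1
        add(i - 1, "wake", "last_wake", minute_window(wb$start_s, w_min))
        if (w_mid != w_min) {
          add(i - 1, "wake", "mid_wake", minute_window(wb$start_s, w_mid))
        }
      }
    }
  }
  if (length(segs) == 0) {
    return(tibble::tibble(bout_index = integer(0), state = character(0),
                          label = character(0), start_s = numeric(0),
                          end_s = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(segs), .data$start_s)
}

#' Detect proboscis-extension events from the extension-distance trace
#'
#' Threshold crossings of the extension distance become events; crossings
#' separated by less than `merge_gap_s` are merged. Each event carries its
#' peak time, duration and peak amplitude.
#'
#' @param proboscis Numeric extension-distance trace.
#' @param fs Sampling rate, Hz.
#' @param threshold Extension-distance threshold (default 0.3).
#' @param merge_gap_s Crossings closer than this are merged, seconds
#'   (default 0.1).
#' @return A tibble of events: `start_s`, `end_s`, `peak_time_s`,
#'   `duration_s`, `amplitude`.
#' @export
detect_pe_events <- function(proboscis, fs, threshold = 0.3,
                             merge_gap_s = 0.1) {
  above <- proboscis > threshold
  if (!any(above)) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          peak_time_s = numeric(0), duration_s = numeric(0),
                          amplitude = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  ev <- data.frame(i0 = starts[on], i1 = ends[on])
  # merge events separated by less than merge_gap_s
  gap <- as.integer(round(merge_gap_s * fs))
  if (nrow(ev) > 1) {
    merged <- list(ev[1, ])
    for (k in 2:nrow(ev)) {
      last <- merged[[length(merged)]]
      if (ev$i0[k] - last$i1 <= gap) {
        merged[[length(merged)]]$i1 <- ev$i1[k]
      } else {
        merged[[length(merged) + 1]] <- ev[k, ]
      }
    }
    ev <- do.call(rbind, merged)
  }
  peak_idx <- mapply(function(a, b) a - 1L + which.max(proboscis[a:b]),
                     ev$i0, ev$i1)
  tibble::tibble(
    start_s = (ev$i0 - 1) / fs,
    end_s = ev$i1 / fs,
    peak_time_s = (peak_idx - 0.5) / fs,
    duration_s = (ev$i1 - ev$i0 + 1) / fs,
    amplitude = proboscis[peak_idx])
}

#' Classify proboscis events into rhythmic spells and reaches
#'
#' Events are grouped into spells when consecutive peak times are at most
#' `spell_gap_s` apart and the group has at least `min_spell_events`
#' members; spell members are `rhythmic_extension`. Isolated events (or
#' members of too-small groups) of duration above `reach_min_duration_s`
#' are `reach`; the rest are `unclassified`. When `bouts` is supplied,
#' groups are split at bout boundaries so every spell has an unambiguous
#' wake/sleep context, recorded per spell.
#'
#' @param events Output of [detect_pe_events()].
#' @param spell_gap_s Maximum inter-event interval within a spell (default 5).
#' @param min_spell_events Minimum events per spell (default 3).
#' @param reach_min_duration_s Minimum duration of a reach, seconds
#'   (default 1.5).
#' @param bouts Optional [score_bouts()] table used to split spells at
#'   state transitions and label their context.
#' @return A list with `events` (input plus `kind` and `spell_id`) and
#'   `spells` (tibble: `spell_id`, `start_s`, `end_s`, `n_events`, `state`).
#' @export
classify_pe <- function(events, spell_gap_s = 5, min_spell_events = 3,
                        reach_min_duration_s = 1.5, bouts = NULL) {
  if (nrow(events) == 0) {
    return(list(
      events = dplyr::mutate(events, kind = character(0),
                             spell_id = integer(0)),
      spells = tibble::tibble(spell_id = integer(0), start_s = numeric(0),
                              end_s = numeric(0), n_events = integer(0),
                              state = character(0))))
  }
  events <- dplyr::arrange(events, .data$peak_time_s)
  new_grp <- c(TRUE, diff(events$peak_time_s) > spell_gap_s)
  if (!is.null(bouts)) {
    bout_of <- findInterval(events$peak_time_s, bouts$start_s)
    bout_of[bout_of < 1] <- 1L
    new_grp <- new_grp | c(TRUE, diff(bout_of) != 0)
  } else {
    bout_of <- rep(NA_integer_, nrow(events))
  }
  grp <- cumsum(new_grp)
  grp_size <- table(grp)[as.character(grp)]
  is_spell <- as.integer(grp_size) >= min_spell_events
  kind <- ifelse(is_spell, "rhythmic_extension",
                 ifelse(events$duration_s > reach_min_duration_s,
                        "reach", "unclassified"))
  spell_id <- rep(NA_integer_, nrow(events))
  spell_grps <- unique(grp[is_spell])
  spell_id[is_spell] <- match(grp[is_spell], spell_grps)
  events$kind <- kind
  events$spell_id <- spell_id
  spells <- if (any(is_spell)) {
    dplyr::summarise(
      dplyr::group_by(events[is_spell, ], spell_id = .data$spell_id),
      start_s = min(.data$start_s), end_s = max(.data$end_s),
      n_events = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(spell_id = integer(0), start_s = numeric(0),
                   end_s = numeric(0), n_events = integer(0))
  }
  if (!is.null(bouts) && nrow(spells) > 0) {
    i <- findInterval(spells$start_s, bouts$start_s)
    i[i < 1] <- 1L
    spells$state <- bouts$state[i]
  } else {
    spells$state <- NA_character_
  }
  list(events = events, spells = spells)
}

#' Sampling windows between the extensions of a spell
#'
#' Open intervals between the end of one extension and the start of the
#' next, trimmed by a guard margin on both sides; windows shorter than one
#' stimulus period are dropped. These are the only times at which SSVEPs
#' are sampled in proboscis-extension-contextual analyses, so the
#' extension epochs themselves are excluded.
#'
#' @param spell_events Events of one spell (rows of the `events` table of
#'   [classify_pe()] sharing a `spell_id`), needing `start_s`/`end_s`.
#' @param guard_s Guard margin trimmed from each side, seconds (default
#'   0.05).
#' @param min_window_s Minimum retained window length, seconds (default
#'   0.1, one stimulus period at 10 Hz).
#' @return A tibble of windows: `start_s`, `end_s`.
#' @export
inter_pe_windows <- function(spell_events, guard_s = 0.05,
                             min_window_s = 0.1) {
  if (nrow(spell_events) < 2) {
    abort_flyssvep("a spell needs at least 2 events.",
                   "flyssvep_invalid_argument")
  }
  spell_events <- dplyr::arrange(spell_events, .data$start_s)
  ws <- spell_events$end_s[-nrow(spell_events)] + guard_s
  we <- spell_events$start_s[-1] - guard_s
  keep <- we - ws >= min_window_s
  tibble::tibble(start_s = ws[keep], end_s = we[keep])
}
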