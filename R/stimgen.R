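#' Describe one 20 s stimulus trial
#'
#' A trial is a train of brief full-field flashes delivered at the carrier
#' frequency (F1, default 10 Hz) with a 50% duty cycle, so each flash lasts
#' `0.5 / f1_hz` seconds. Three trial types exist: `"carrier_only"` (a single
#' colour throughout), `"phasic"` (every `deviant_every`-th event is a
#' differently coloured deviant, i.e. a 2 Hz deviant rate at the defaults)
#' and `"jittering"` (deviant positions displaced by a rounded Gaussian
#' offset around the phasic positions).
#'
#' @param trial_type One of `"carrier_only"`, `"phasic"`, `"jittering"`.
#' @param carrier_color,deviant_color `"green"` or `"blue"`. `deviant_color`
#'   must be `NULL` for carrier-only trials and must differ from
#'   `carrier_color` otherwise.
#' @param n_events Number of stimulus events in the trial (default 200,
#'   i.e. 20 s at 10 Hz).
#' @param f1_hz Carrier frequency in Hz.
#' @param deviant_every Nominal deviant spacing in events (default 5).
#' @param jitter_sd Standard deviation, in sequence positions, of the
#'   Gaussian jitter applied to deviant positions (jittering trials only).
#' @param start_time Trial onset in seconds from experiment start.
#' @param trial_id Integer trial identifier.
#'
#' @return A list of class `"trial_spec"`.
#' @export
#' @examples
#' trial_spec("phasic", carrier_color = "blue", deviant_color = "green")
trial_spec <- function(trial_type = c("carrier_only", "phasic", "jittering"),
                       carrier_color = "green",
                       deviant_color = NULL,
                       n_events = 200,
                       f1_hz = 10,
                       deviant_every = 5,
                       jitter_sd = 1.0,
                       start_time = 0,
                       trial_id = 1L) {
  trial_type <- rlang::arg_match(trial_type)
  assert_color(carrier_color, "carrier_color")
  assert_positive(n_events, "n_events")
  assert_positive(f1_hz, "f1_hz")
  assert_positive(deviant_every, "deviant_every")
  if (jitter_sd < 0) {
    abort_flyssvep("`jitter_sd` must be >= 0.", "flyssvep_invalid_spec")
  }
  if (trial_type == "carrier_only") {
    if (!is.null(deviant_color)) {
      abort_flyssvep("carrier-only trials take no `deviant_color`.",
                     "flyssvep_invalid_spec")
    }
  } else {
    if (is.null(deviant_color)) deviant_color <- other_color(carrier_color)
    assert_color(deviant_color, "deviant_color")
    if (identical(deviant_color, carrier_color)) {
      abort_flyssvep("carrier and deviant colors must differ.",
                     "flyssvep_invalid_spec")
    }
  }
  structure(
    list(trial_type = trial_type, carrier_color = carrier_color,
         deviant_color = deviant_color, n_events = as.integer(n_events),
         f1_hz = f1_hz, deviant_every = as.integer(deviant_every),
         jitter_sd = jitter_sd, start_time = start_time,
         trial_id = as.integer(trial_id)),
    class = "trial_spec")
}

new_event_tbl <- function(spec, roles) {
  k <- seq_len(spec$n_events)
  tibble::tibble(
    trial_id = spec$trial_id,
    seq_index = k,
    onset_time_s = spec$start_time + (k - 1) / spec$f1_hz,
    duration_s = 0.5 / spec$f1_hz,
    color = ifelse(roles == "deviant", spec$deviant_color, spec$carrier_color),
    role = roles
  )
}

#' Build the event table for a carrier-only trial
#'
#' All events share the carrier colour; onsets are evenly spaced at
#' `1 / f1_hz` starting at `start_time`.
#'
#' @param spec A [trial_spec()] with `trial_type = "carrier_only"`.
#' @return A tibble with one row per stimulus event: `trial_id`, `seq_index`
#'   (1-based), `onset_time_s`, `duration_s`, `color`, `role`.
#' @export
build_carrier_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  if (spec$trial_type != "carrier_only") {
    abort_flyssvep("`spec` is not a carrier-only trial.", "flyssvep_invalid_spec")
  }
  new_event_tbl(spec, rep("carrier", spec$n_events))
}

#' Build the event table for a phasic-deviant trial
#'
#' Events at sequence positions that are multiples of `deviant_every`
#' (5, 10, ..., at the defaults, so each trial opens with carriers) take the
#' deviant role and colour; at the defaults the deviant rate is
#' `f1_hz / deviant_every` = 2 Hz.
#'
#' @param spec A [trial_spec()] with `trial_type = "phasic"`.
#' @inherit build_carrier_trial return
#' @export
build_phasic_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  if (spec$trial_type != "phasic") {
    abort_flyssvep("`spec` is not a phasic trial.", "flyssvep_invalid_spec")
  }
  k <- seq_len(spec$n_events)
  roles <- ifelse(k %% spec$deviant_every == 0, "deviant", "carrier")
  new_event_tbl(spec, roles)
}

# Jittered deviant positions: each nominal position gets an independent
# rounded Gaussian offset. A draw that collides with (or order-swaps against)
# an already accepted deviant, or falls outside 1..n_events, is redrawn up to
# `max_redraws` times; after that the nominal position is kept if still
# admissible, otherwise the deviant is dropped.
jitter_positions <- function(nominal, n_events, jitter_sd, max_redraws = 100) {
  pos <- integer(0)
  for (p in nominal) {
    cand <- NA_integer_
    for (i in seq_len(max_redraws)) {
      d <- p + as.integer(round(stats::rnorm(1, 0, jitter_sd)))
      if (d >= 1L && d <= n_events && (length(pos) == 0L || d > pos[length(pos)])) {
        cand <- d
        break
      }
    }
    if (is.na(cand) &&
        p <= n_events && (length(pos) == 0L || p > pos[length(pos)])) {
      cand <- p
    }
    if (!is.na(cand)) pos <- c(pos, cand)
  }
  pos
}

#' Build the event table for a jittering-deviant trial
#'
#' Deviant positions are the phasic positions displaced by
#' `round(N(0, jitter_sd))`, kept within the trial, strictly increasing and
#' non-colliding (collisions are redrawn; deviants jittered past the trial
#' end are dropped). With `jitter_sd = 0` the result is identical to
#' [build_phasic_trial()]. Uses the current R random stream; call
#' `set.seed()` beforehand for reproducibility.
#'
#' @param spec A [trial_spec()] with `trial_type = "jittering"`.
#' @inherit build_carrier_trial return
#' @export
build_jittering_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  if (spec$trial_type != "jittering") {
    abort_flyssvep("`spec` is not a jittering trial.", "flyssvep_invalid_spec")
  }
  nominal <- seq(spec$deviant_every, spec$n_events, by = spec$deviant_every)
  pos <- jitter_positions(nominal, spec$n_events, spec$jitter_sd)
  roles <- rep("carrier", spec$n_events)
  roles[pos] <- "deviant"
  new_event_tbl(spec, roles)
}

#' Build any trial type from its spec
#'
#' Dispatches to the carrier-only, phasic or jittering builder.
#'
#' @param spec A [trial_spec()].
#' @inherit build_carrier_trial return
#' @export
build_trial <- function(spec) {
  switch(spec$trial_type,
         carrier_only = build_carrier_trial(spec),
         phasic = build_phasic_trial(spec),
         jittering = build_jittering_trial(spec))
}

#' Construct a counterbalanced experiment schedule
#'
#' Assigns colours to trials so that each colour serves as carrier (and,
#' for deviant trial types, as deviant) in an equal number of trials (within
#' one when `n_trials` is odd), randomises the trial order, and lays trials
#' out in time separated by `pause_s` seconds.
#'
#' @param n_trials Number of trials.
#' @param trial_type Trial type shared by all trials.
#' @param pause_s Pause between consecutive trials, seconds (default 3).
#' @param n_events,f1_hz,deviant_every,jitter_sd Passed to each [trial_spec()].
#' @param start_time Onset of the first trial, seconds.
#'
#' @return A tibble of class `"flyssvep_schedule"` with one row per trial
#'   (columns `trial_id`, `trial_type`, `carrier_color`, `deviant_color`,
#'   `n_events`, `f1_hz`, `deviant_every`, `jitter_sd`, `start_time`) and
#'   attribute `pause_s`. Trial `k` starts at
#'   `start_time + (k - 1) * (n_events / f1_hz + pause_s)`.
#' @export
#' @examples
#' set.seed(1)
#' counterbalance_schedule(4, "phasic")
counterbalance_schedule <- function(n_trials,
                                    trial_type = c("carrier_only", "phasic", "jittering"),
                                    pause_s = 3,
                                    n_events = 200, f1_hz = 10,
                                    deviant_every = 5, jitter_sd = 1.0,
                                    start_time = 0) {
  trial_type <- rlang::arg_match(trial_type)
  assert_positive(n_trials, "n_trials")
  n_trials <- as.integer(n_trials)
  # Balanced color-role assignment, order randomized by the current RNG.
  n_a <- ceiling(n_trials / 2)
  carriers <- sample(c(rep("green", n_a), rep("blue", n_trials - n_a)))
  trial_dur <- n_events / f1_hz
  deviants <- if (trial_type == "carrier_only") {
    rep(NA_character_, n_trials)
  } else {
    vapply(carriers, other_color, character(1), USE.NAMES = FALSE)
  }
  tbl <- tibble::tibble(
    trial_id = seq_len(n_trials),
    trial_type = trial_type,
    carrier_color = carriers,
    deviant_color = deviants,
    n_events = as.integer(n_events),
    f1_hz = f1_hz,
    deviant_every = as.integer(deviant_every),
    jitter_sd = jitter_sd,
    start_time = start_time + (seq_len(n_trials) - 1) * (trial_dur + pause_s)
  )
  attr(tbl, "pause_s") <- pause_s
  class(tbl) <- c("flyssvep_schedule", class(tbl))
  tbl
}

#' Expand a schedule into its full stimulus event log
#'
#' @param schedule A [counterbalance_schedule()] tibble.
#' @return One tibble of stimulus events across all trials, ordered by onset.
#' @export
schedule_events <- function(schedule) {
  specs <- purrr::pmap(
    schedule[c("trial_type", "carrier_color", "deviant_color", "n_events",
               "f1_hz", "deviant_every", "jitter_sd", "start_time", "trial_id")],
    function(trial_type, carrier_color, deviant_color, n_events, f1_hz,
             deviant_every, jitter_sd, start_time, trial_id) {
      trial_spec(trial_type, carrier_color,
                 if (is.na(deviant_color %||% NA_character_)) NULL else deviant_color,
                 n_events, f1_hz, deviant_every, jitter_sd, start_time, trial_id)
    })
  dplyr::bind_rows(purrr::map(specs, build_trial))
}

#' Write / read a schedule as JSON
#'
#' Serialises the trial table together with its inter-trial pause so a
#' schedule can be regenerated or audited outside R; the event log is the
#' natural CSV companion (`write.csv(schedule_events(x), ...)`).
#'
#' @param schedule A [counterbalance_schedule()] tibble.
#' @param path JSON file path.
#' @return `path` (write) or the schedule (read).
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(
    list(pause_s = attr(schedule, "pause_s"),
         trials = as.data.frame(schedule)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tbl <- tibble::as_tibble(raw$trials)
  if (!"deviant_color" %in% names(tbl)) tbl$deviant_color <- NA_character_
  tbl$deviant_color <- as.character(tbl$deviant_color)
  attr(tbl, "pause_s") <- raw$pause_s
  class(tbl) <- c("flyssvep_schedule", class(tbl))
  tbl
}

#' Render a sample-aligned stimulus trace
#'
#' Digital twin of the acquisition system's stimulus-identity channel: a
#' square wave that is 1 during each event's `[onset, onset + duration)`
#' with per-sample colour and role labels. Onsets are rounded to the nearest
#' sample.
#'
#' @param events A stimulus event tibble (see [build_trial()]).
#' @param fs Sampling rate, Hz. Must be at least twice the carrier frequency
#'   implied by the event spacing.
#' @param duration_s Total trace duration; defaults to the end of the last
#'   event plus one inter-stimulus interval.
#' @return A tibble with one row per sample: `time_s`, `stim_on` (0/1),
#'   `color`, `role` (`NA` when off).
#' @export
render_stimulus_trace <- function(events, fs, duration_s = NULL) {
  assert_positive(fs, "fs")
  if (nrow(events) > 0) {
    min_gap <- min(diff(sort(unique(events$onset_time_s))), Inf)
    if (is.finite(min_gap) && fs < 2 / min_gap) {
      abort_flyssvep("`fs` is too low to represent the stimulus duty cycle.",
                     "flyssvep_invalid_spec")
    }
    if (any(round(events$duration_s * fs) < 1)) {
      abort_flyssvep("`fs` is too low to represent the stimulus duty cycle.",
                     "flyssvep_invalid_spec")
    }
  }
  duration_s <- duration_s %||%
    (if (nrow(events) == 0) 1 else
       max(events$onset_time_s + 2 * events$duration_s))
  n <- as.integer(round(duration_s * fs))
  on <- integer(n)
  color <- rep(NA_character_, n)
  role <- rep(NA_character_, n)
  for (i in seq_len(nrow(events))) {
    i0 <- as.integer(round(events$onset_time_s[i] * fs)) + 1L
    len <- as.integer(round(events$duration_s[i] * fs))
    idx <- i0:min(i0 + len - 1L, n)
    on[idx] <- 1L
    color[idx] <- events$color[i]
    role[idx] <- events$role[i]
  }
  tibble::tibble(time_s = (seq_len(n) - 1) / fs, stim_on = on,
                 color = color, role = role)
}
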