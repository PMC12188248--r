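#' Simulator configuration
#'
#' Parameters of the statistical forward model used to generate synthetic
#' overnight recordings with known ground truth. The defaults encode the
#' qualitative structure the analysis pipeline is designed to detect:
#' a polarity reversal in the lobula region (channel 12), evoked responses
#' whose amplitude tapers to zero at the reversal and flips sign outboard of
#' it, deviant responses attenuated in central channels and further
#' attenuated during deep sleep (central channels only), state-invariant
#' carrier responses, alternating wake/sleep bouts with median durations of
#' 11.2 and 12.8 min, rhythmic proboscis-extension spells concentrated in
#' deep (mid-bout) sleep, 1/f background activity with a component shared
#' across channels, and 50 Hz line noise.
#'
#' @param n_channels Number of electrode channels (default 16).
#' @param fs Sampling rate of the simulated recording, Hz (default 200, the
#'   overnight analysis rate; use 1000 to exercise downsampling).
#' @param reversal_channel 1-based index of the polarity-reversal channel.
#' @param kernel Evoked-response kernel parameters: `latency_s`, `rise_tau_s`
#'   (alpha-function rise constant of the main lobe), `lobe_delay_s` and
#'   `decay_tau_s` (delay and time constant of the opposing lobe),
#'   `second_lobe` (relative amplitude of the opposing lobe, < 1 so the
#'   kernel has net area and low-frequency content), `base_amplitude`
#'   (peak-trough amplitude, arbitrary-unit volts, of a unit-gain response
#'   at the most central channel).
#' @param color_gain Named multiplicative amplitude gain per stimulus colour;
#'   blue < green mimics colour-dependent response size, and gives deviants a
#'   kernel amplitude distinct from carriers within any mixed trial.
#' @param gains Role/state gain table: `deviant` (named per-region gains,
#'   all < 1: deviant responses are smaller than carrier responses, most so
#'   centrally), `deviant_deep_sleep_factor` (< 1: deep sleep further
#'   attenuates deviant responses in central channels only) and
#'   `carrier_order` (gain of carriers 1-4 after a deviant, applied outside
#'   the central group: the first carrier after a colour change responds
#'   differently in the optic lobes, while the central brain is insensitive
#'   to carrier order). Carrier gains are state-invariant everywhere.
#' @param noise `pink_sd` (per-channel 1/f background), `shared_sd`
#'   (1/f component common to all channels, i.e. removable by
#'   re-referencing), `hp_corner_hz` (high-pass corner of the background,
#'   the signature of AC-coupled acquisition), `line_amp` and `line_hz`
#'   (mains noise), `movement_sd` and `proboscis_sd` (sensor noise on the
#'   behaviour traces).
#' @param bout_model Lognormal wake/sleep bout-duration model:
#'   `wake_median_min`, `sleep_median_min`, `sdlog`.
#' @param pe_model Proboscis-extension model: spell rates per minute by
#'   context (`deep_spell_rate`, `light_spell_rate`, `wake_spell_rate`),
#'   wake `reach_rate`, `extensions_per_spell` (mean; at least 3),
#'   `inter_extension_s`, `extension_duration_s`, `reach_duration_s`,
#'   `amplitude`.
#' @param stim Stimulus-schedule parameters shared by all trials:
#'   `trial_type`, `n_events`, `f1_hz`, `deviant_every`, `jitter_sd`,
#'   `pause_s`.
#' @return A validated configuration list of class `"sim_config"`.
#' @export
sim_config <- function(n_channels = 16,
                       fs = 200,
                       reversal_channel = 12,
                       kernel = list(),
                       color_gain = c(green = 1, blue = 0.8),
                       gains = list(),
                       noise = list(),
                       bout_model = list(),
                       pe_model = list(),
                       stim = list()) {
  kernel <- utils::modifyList(
    list(latency_s = 0.015, rise_tau_s = 0.015, lobe_delay_s = 0.025,
         decay_tau_s = 0.012, second_lobe = 0.3, base_amplitude = 1),
    kernel)
  gains <- utils::modifyList(
    list(deviant = c(central = 0.7, intermediate = 0.7, peripheral = 0.85),
         deviant_deep_sleep_factor = 0.6,
         carrier_order = c(0.8, 0.9, 1, 1)), gains)
  noise <- utils::modifyList(
    list(pink_sd = 0.04, shared_sd = 0.02, hp_corner_hz = 1,
         line_amp = 0.05, line_hz = 50,
         movement_sd = 0.02, proboscis_sd = 0.01), noise)
  bout_model <- utils::modifyList(
    list(wake_median_min = 11.2, sleep_median_min = 12.8, sdlog = 0.6),
    bout_model)
  pe_model <- utils::modifyList(
    list(deep_spell_rate = 0.5, light_spell_rate = 0.05,
         wake_spell_rate = 0.02, reach_rate = 0.2,
         extensions_per_spell = 6, inter_extension_s = 1.0,
         extension_duration_s = 0.4, reach_duration_s = 2.5,
         amplitude = 1), pe_model)
  stim <- utils::modifyList(
    list(trial_type = "phasic", n_events = 200, f1_hz = 10,
         deviant_every = 5, jitter_sd = 1.0, pause_s = 3), stim)
  if (reversal_channel < 1 || reversal_channel > n_channels) {
    abort_flyssvep("`reversal_channel` must lie within 1..n_channels.",
                   "flyssvep_invalid_config")
  }
  if (any(unlist(gains) <= 0) || any(color_gain <= 0)) {
    abort_flyssvep("all gains must be > 0.", "flyssvep_invalid_config")
  }
  if (bout_model$wake_median_min <= 0 || bout_model$sleep_median_min <= 0) {
    abort_flyssvep("bout medians must be > 0.", "flyssvep_invalid_config")
  }
  if (any(unlist(pe_model[c("deep_spell_rate", "light_spell_rate",
                            "wake_spell_rate", "reach_rate")]) < 0)) {
    abort_flyssvep("proboscis-extension rates must be >= 0.",
                   "flyssvep_invalid_config")
  }
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         reversal_channel = as.integer(reversal_channel),
         kernel = kernel, color_gain = as.list(color_gain), gains = gains,
         noise = noise, bout_model = bout_model, pe_model = pe_model,
         stim = stim),
    class = "sim_config")
}

#' Evoked-response kernel waveform
#'
#' Biphasic difference-of-alpha-functions kernel: a main lobe followed by a
#' smaller opposing lobe, onset latency ~20 ms, total span under one
#' inter-stimulus interval (100 ms at 10 Hz) so consecutive responses do not
#' overlap. Normalised to unit peak-trough amplitude.
#'
#' @param fs Sampling rate, Hz.
#' @param kernel Kernel parameter list (see [sim_config()]).
#' @param span_s Kernel support in seconds (default 0.1).
#' @return Numeric vector of `round(span_s * fs)` samples with
#'   `max(k) - min(k) == 1`.
#' @export
kernel_waveform <- function(fs, kernel = sim_config()$kernel, span_s = 0.1) {
  L <- as.integer(round(span_s * fs))
  t <- (seq_len(L) - 1) / fs
  alpha_fn <- function(u, tau) ifelse(u > 0, (u / tau) * exp(1 - u / tau), 0)
  u <- t - kernel$latency_s
  k <- alpha_fn(u, kernel$rise_tau_s) -
    kernel$second_lobe * alpha_fn(u - kernel$lobe_delay_s, kernel$decay_tau_s)
  k / (max(k) - min(k))
}

# Signed per-channel amplitude profile: +- linear taper that crosses zero at
# the reversal channel (sign flip outboard, zero amplitude at the reversal).
channel_profile <- function(n_channels, reversal_channel) {
  ch <- seq_len(n_channels)
  (reversal_channel - ch) / max(reversal_channel - 1, n_channels - reversal_channel)
}

#' Region group of each channel in the simulator's geometry
#'
#' Central channels lie well inboard of the reversal (6 or more channels),
#' peripheral channels outboard of it, the rest are intermediate. This is
#' the generative counterpart of [assign_regions()].
#'
#' @param channel Integer channel indices.
#' @param reversal_channel The polarity-reversal channel.
#' @return Character vector: `"central"`, `"intermediate"` or `"peripheral"`.
#' @export
region_group <- function(channel, reversal_channel) {
  dplyr::case_when(
    channel <= reversal_channel - 6 ~ "central",
    channel > reversal_channel ~ "peripheral",
    .default = "intermediate")
}

# 1/f amplitude-spectrum noise via spectral shaping of white noise, with a
# first-order high-pass corner (AC-coupled acquisition) below `hp_corner_hz`.
pink_noise <- function(n, sd, fs = n, hp_corner_hz = 0) {
  if (sd <= 0 || n == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f_hz <- pmin(k, n - k) * fs / n   # symmetric -> real inverse transform
  f_eff <- pmax(f_hz, fs / n)
  scale <- 1 / sqrt(f_eff)
  if (hp_corner_hz > 0) {
    below <- f_eff < hp_corner_hz
    scale[below] <- (f_eff[below] / hp_corner_hz) / sqrt(hp_corner_hz)
  }
  out <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  out / stats::sd(out) * sd
}

# Alternating wake/sleep bouts from the lognormal bout model, starting
# awake, final bout truncated at duration_s.
draw_bouts <- function(bout_model, duration_s) {
  states <- character(0); durs <- numeric(0)
  state <- "wake"; total <- 0
  while (total < duration_s) {
    med <- if (state == "wake") bout_model$wake_median_min else
      bout_model$sleep_median_min
    d <- stats::rlnorm(1, meanlog = log(med * 60), sdlog = bout_model$sdlog)
    states <- c(states, state); durs <- c(durs, d)
    total <- total + d
    state <- if (state == "wake") "sleep" else "wake"
  }
  ends <- pmin(cumsum(durs), duration_s)
  starts <- c(0, ends[-length(ends)])
  keep <- ends > starts
  tibble::tibble(state = states[keep], start_s = starts[keep],
                 end_s = ends[keep])
}

#' Simulate behavioural state and the movement trace
#'
#' Draws alternating wake/sleep bouts from the lognormal bout model (the
#' recording starts awake; the final bout is truncated at `duration_s`) and
#' renders a movement-activity magnitude trace: bursts of activity every
#' second during wake, near-zero during sleep. Mid-bout minutes of each
#' sleep bout (from minute 3 to the 2nd-last minute) are flagged as deep
#' sleep in the truth. Uses the current RNG stream.
#'
#' @param config A [sim_config()].
#' @param duration_s Recording duration, seconds.
#' @return List with `movement` (numeric trace), `bouts` (tibble `state`,
#'   `start_s`, `end_s`) and `deep` (tibble `start_s`, `end_s`).
#' @export
simulate_behavior <- function(config, duration_s) {
  assert_positive(duration_s, "duration_s")
  bouts <- draw_bouts(config$bout_model, duration_s)

  fs <- config$fs
  n <- as.integer(round(duration_s * fs))
  movement <- numeric(n)
  burst_len <- max(1L, as.integer(round(0.2 * fs)))
  burst_shape <- sin(pi * (seq_len(burst_len) - 0.5) / burst_len)
  wake_bouts <- bouts[bouts$state == "wake", ]
  for (i in seq_len(nrow(wake_bouts))) {
    lo <- ceiling(wake_bouts$start_s[i])
    hi <- floor(wake_bouts$end_s[i]) - 1
    secs <- if (hi >= lo) lo:hi else integer(0)
    for (s in secs) {
      i0 <- as.integer(round(s * fs)) + 1L
      idx <- i0:min(i0 + burst_len - 1L, n)
      movement[idx] <- movement[idx] +
        stats::runif(1, 0.5, 1.5) * burst_shape[seq_along(idx)]
    }
  }
  if (config$noise$movement_sd > 0) {
    movement <- movement + abs(stats::rnorm(n, 0, config$noise$movement_sd))
  }

  sleep_bouts <- bouts[bouts$state == "sleep", ]
  deep <- tibble::tibble(start_s = sleep_bouts$start_s + 120,
                         end_s = sleep_bouts$end_s - 120)
  deep <- deep[deep$end_s > deep$start_s, ]
  list(movement = movement, bouts = bouts, deep = deep)
}

place_bumps <- function(trace, fs, centers_s, durations_s, amplitudes) {
  n <- length(trace)
  for (i in seq_along(centers_s)) {
    L <- max(2L, as.integer(round(durations_s[i] * fs)))
    i0 <- as.integer(round((centers_s[i] - durations_s[i] / 2) * fs)) + 1L
    idx <- max(i0, 1L):min(i0 + L - 1L, n)
    if (length(idx) == 0) next
    shape <- sin(pi * (seq_len(L) - 0.5) / L)
    trace[idx] <- trace[idx] + amplitudes[i] * shape[idx - i0 + 1L]
  }
  trace
}

#' Simulate the proboscis-extension trace
#'
#' Places rhythmic extension spells (several short extensions at a regular
#' interval) preferentially in deep-sleep minutes, at low rates elsewhere in
#' sleep and in wake, plus single long "reach" events during wake. Spells
#' never cross bout boundaries and spans never overlap. Uses the current
#' RNG stream.
#'
#' @param config A [sim_config()].
#' @param behavior Output of [simulate_behavior()].
#' @param duration_s Recording duration, seconds.
#' @return List with `proboscis` (numeric trace) and `pe_events` (tibble:
#'   `time_s` peak time, `start_s`, `end_s`, `duration_s`, `amplitude`,
#'   `kind` in `rhythmic_extension`/`reach`, `spell_id`).
#' @export
simulate_proboscis <- function(config, behavior, duration_s) {
  pm <- config$pe_model
  fs <- config$fs
  n <- as.integer(round(duration_s * fs))
  bouts <- behavior$bouts
  deep <- behavior$deep

  # candidate intervals with their spell rate per minute
  ivals <- list()
  add_ival <- function(start, end, spell_rate, reach_rate = 0) {
    if (end > start) {
      ivals[[length(ivals) + 1]] <<-
        list(start = start, end = end, spell_rate = spell_rate,
             reach_rate = reach_rate)
    }
  }
  for (i in seq_len(nrow(bouts))) {
    b <- bouts[i, ]
    if (b$state == "wake") {
      add_ival(b$start_s, b$end_s, pm$wake_spell_rate, pm$reach_rate)
    } else {
      d <- deep[deep$start_s >= b$start_s & deep$end_s <= b$end_s, ]
      if (nrow(d) == 1) {
        add_ival(b$start_s, d$start_s, pm$light_spell_rate)
        add_ival(d$start_s, d$end_s, pm$deep_spell_rate)
        add_ival(d$end_s, b$end_s, pm$light_spell_rate)
      } else {
        add_ival(b$start_s, b$end_s, pm$light_spell_rate)
      }
    }
  }

  occupied <- matrix(numeric(0), ncol = 2)  # placed spans, with margin
  span_free <- function(s, e, margin = 6) {
    nrow(occupied) == 0 ||
      all(e + margin < occupied[, 1] | s - margin > occupied[, 2])
  }
  events <- list()
  spell_id <- 0L
  for (iv in ivals) {
    len_min <- (iv$end - iv$start) / 60
    n_spells <- stats::rpois(1, iv$spell_rate * len_min)
    for (k in seq_len(n_spells)) {
      n_ext <- 3L + stats::rpois(1, max(pm$extensions_per_spell - 3, 0))
      span <- (n_ext - 1) * pm$inter_extension_s + pm$extension_duration_s
      if (iv$end - iv$start <= span) next
      t0 <- stats::runif(1, iv$start, iv$end - span)
      if (!span_free(t0, t0 + span)) next
      occupied <- rbind(occupied, c(t0, t0 + span))
      spell_id <- spell_id + 1L
      centers <- t0 + pm$extension_duration_s / 2 +
        (seq_len(n_ext) - 1) * pm$inter_extension_s
      events[[length(events) + 1]] <- tibble::tibble(
        time_s = centers, duration_s = pm$extension_duration_s,
        amplitude = stats::runif(n_ext, 0.8, 1.2) * pm$amplitude,
        kind = "rhythmic_extension", spell_id = spell_id)
    }
    n_reach <- stats::rpois(1, iv$reach_rate * len_min)
    for (k in seq_len(n_reach)) {
      if (iv$end - iv$start <= pm$reach_duration_s) next
      t0 <- stats::runif(1, iv$start, iv$end - pm$reach_duration_s)
      if (!span_free(t0, t0 + pm$reach_duration_s)) next
      occupied <- rbind(occupied, c(t0, t0 + pm$reach_duration_s))
      events[[length(events) + 1]] <- tibble::tibble(
        time_s = t0 + pm$reach_duration_s / 2,
        duration_s = pm$reach_duration_s,
        amplitude = stats::runif(1, 0.8, 1.2) * pm$amplitude,
        kind = "reach", spell_id = NA_integer_)
    }
  }
  pe_events <- if (length(events)) {
    dplyr::arrange(dplyr::bind_rows(events), .data$time_s)
  } else {
    tibble::tibble(time_s = numeric(0), duration_s = numeric(0),
                   amplitude = numeric(0), kind = character(0),
                   spell_id = integer(0))
  }
  pe_events$start_s <- pe_events$time_s - pe_events$duration_s / 2
  pe_events$end_s <- pe_events$time_s + pe_events$duration_s / 2

  proboscis <- place_bumps(numeric(n), fs, pe_events$time_s,
                           pe_events$duration_s, pe_events$amplitude)
  if (config$noise$proboscis_sd > 0) {
    proboscis <- proboscis + abs(stats::rnorm(n, 0, config$noise$proboscis_sd))
  }
  list(proboscis = proboscis, pe_events = pe_events)
}

# state ("wake"/"sleep") and deep-sleep flag at given times
state_at <- function(times, bouts, deep) {
  i <- findInterval(times, bouts$start_s)
  i[i < 1] <- 1L
  state <- bouts$state[i]
  is_deep <- rep(FALSE, length(times))
  if (nrow(deep) > 0) {
    j <- findInterval(times, deep$start_s)
    ok <- j >= 1
    is_deep[ok] <- times[ok] < deep$end_s[j[ok]]
  }
  list(state = state, deep = is_deep)
}

#' Simulate the multichannel LFP and assemble a full recording
#'
#' The LFP of each channel is the sum of (i) per-channel 1/f background
#' noise, (ii) a 1/f component shared across channels (synchronized
#' endogenous activity; removed exactly by re-referencing), (iii) mains
#' noise, and (iv) one evoked-response kernel per stimulus event scaled by
#' the signed channel profile (zero at the reversal channel, opposite sign
#' outboard), the colour gain and the role/state gain at the event's onset.
#' The noise-free peak-trough amplitude of every event on every channel is
#' recorded in the truth. Uses the current RNG stream.
#'
#' @param config A [sim_config()].
#' @param events Stimulus event tibble covering the recording.
#' @param behavior Output of [simulate_behavior()].
#' @param proboscis Output of [simulate_proboscis()] (optional).
#' @param duration_s Recording duration, seconds.
#' @param fly_id Identifier stored on the recording.
#' @return A [new_recording()] with truth tables `bouts`, `deep`,
#'   `pe_events` and `amplitudes` (per event and channel: `amp_true`,
#'   `state`, `deep`).
#' @export
simulate_lfp <- function(config, events, behavior, proboscis = NULL,
                         duration_s, fly_id = "fly01") {
  fs <- config$fs
  n <- as.integer(round(duration_s * fs))
  nch <- config$n_channels
  prof <- channel_profile(nch, config$reversal_channel)
  kern <- kernel_waveform(fs, config$kernel)
  L <- length(kern)

  hp <- config$noise$hp_corner_hz %||% 0
  lfp <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq_len(nch)) {
    lfp[ch, ] <- pink_noise(n, config$noise$pink_sd, fs, hp)
  }
  if (config$noise$shared_sd > 0) {
    shared <- pink_noise(n, config$noise$shared_sd, fs, hp)
    lfp <- sweep(lfp, 2, shared, "+")
  }
  if (config$noise$line_amp > 0) {
    tt <- (seq_len(n) - 1) / fs
    line <- config$noise$line_amp * sin(2 * pi * config$noise$line_hz * tt)
    lfp <- sweep(lfp, 2, line, "+")
  }

  st <- state_at(events$onset_time_s, behavior$bouts, behavior$deep)
  region <- region_group(seq_len(nch), config$reversal_channel)
  is_central <- region == "central"
  col_gain <- unlist(config$color_gain)[events$color]
  dev <- events$role == "deviant"
  dev_gain_by_region <- config$gains$deviant[region]
  order_gain_tbl <- config$gains$carrier_order
  hist <- dplyr::left_join(
    events[c("trial_id", "seq_index")],
    label_history(events)[c("trial_id", "seq_index", "carrier_order")],
    by = c("trial_id", "seq_index"))
  ord <- pmin(dplyr::coalesce(hist$carrier_order, 99L),
              length(order_gain_tbl))
  order_gain <- ifelse(is.na(hist$carrier_order), 1, order_gain_tbl[ord])

  base <- config$kernel$base_amplitude
  onset_idx <- as.integer(round(events$onset_time_s * fs)) + 1L
  keep <- onset_idx + L - 1L <= n & onset_idx >= 1L
  amp_true <- matrix(NA_real_, nrow = nrow(events), ncol = nch)
  deep_factor <- config$gains$deviant_deep_sleep_factor
  for (e in which(keep)) {
    if (dev[e]) {
      g <- dev_gain_by_region
      if (st$state[e] == "sleep" && st$deep[e]) {
        g[is_central] <- g[is_central] * deep_factor
      }
    } else {
      # carrier-order modulation is an optic-lobe phenomenon: absent centrally
      g <- ifelse(is_central, 1, order_gain[e])
    }
    s_ch <- base * col_gain[e] * prof * g
    idx <- onset_idx[e]:(onset_idx[e] + L - 1L)
    lfp[, idx] <- lfp[, idx] + s_ch %o% kern
    amp_true[e, ] <- abs(s_ch)
  }

  amplitudes <- tibble::tibble(
    trial_id = rep(events$trial_id, nch),
    seq_index = rep(events$seq_index, nch),
    channel = rep(seq_len(nch), each = nrow(events)),
    amp_true = as.vector(amp_true),
    state = rep(st$state, nch),
    deep = rep(st$deep, nch))
  amplitudes <- amplitudes[!is.na(amplitudes$amp_true), ]

  new_recording(
    lfp, fs = fs, movement = behavior$movement,
    proboscis = if (is.null(proboscis)) numeric(n) else proboscis$proboscis,
    events = events,
    truth = list(bouts = behavior$bouts, deep = behavior$deep,
                 pe_events = if (is.null(proboscis)) NULL else proboscis$pe_events,
                 amplitudes = amplitudes),
    config = unclass(config), fly_id = fly_id)
}

#' Simulate one complete fly recording
#'
#' Builds a counterbalanced stimulus schedule filling the recording, draws
#' the behavioural state and proboscis traces, then renders the multichannel
#' LFP. Each component uses its own sub-seed derived deterministically from
#' `seed`, so identical `(config, duration_s, seed)` give a bitwise-identical
#' recording.
#'
#' @param config A [sim_config()].
#' @param duration_s Recording duration, seconds (default 1800).
#' @param seed Master seed (integer).
#' @param fly_id Identifier stored on the recording.
#' @return A [new_recording()] with full ground truth.
#' @export
#' @examples
#' rec <- simulate_recording(sim_config(), duration_s = 120, seed = 1)
#' rec
simulate_recording <- function(config = sim_config(), duration_s = 1800,
                               seed = 1, fly_id = "fly01") {
  stim <- config$stim
  trial_span <- stim$n_events / stim$f1_hz + stim$pause_s
  n_trials <- max(1L, as.integer(floor((duration_s + stim$pause_s) / trial_span)))
  set.seed(derive_seed(seed, 1))
  schedule <- counterbalance_schedule(
    n_trials, stim$trial_type, pause_s = stim$pause_s,
    n_events = stim$n_events, f1_hz = stim$f1_hz,
    deviant_every = stim$deviant_every, jitter_sd = stim$jitter_sd)
  events <- schedule_events(schedule)
  set.seed(derive_seed(seed, 2))
  behavior <- simulate_behavior(config, duration_s)
  set.seed(derive_seed(seed, 3))
  prob <- simulate_proboscis(config, behavior, duration_s)
  set.seed(derive_seed(seed, 4))
  simulate_lfp(config, events, behavior, prob, duration_s, fly_id = fly_id)
}
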