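# Shared fixtures, all generated in code.

# A silent simulator configuration: no noise anywhere, so measured
# quantities equal ground truth.
noise_free_config <- function(...) {
  sim_config(noise = list(pink_sd = 0, shared_sd = 0, line_amp = 0,
                          movement_sd = 0, proboscis_sd = 0), ...)
}

# Tiny two-channel recording whose channels carry mirrored kernels, for
# reversal/re-referencing toys. `n_events` kernel responses at 10 Hz.
mirrored_toy_recording <- function(n_events = 120, fs = 200,
                                   amps = c(1, -0.2)) {
  kern <- kernel_waveform(fs)
  n <- n_events * fs / 10 + length(kern)
  lfp <- matrix(0, nrow = length(amps), ncol = n)
  onsets <- (seq_len(n_events) - 1) / 10
  for (e in seq_len(n_events)) {
    idx <- round(onsets[e] * fs) + seq_along(kern)
    for (ch in seq_along(amps)) {
      lfp[ch, idx] <- lfp[ch, idx] + amps[ch] * kern
    }
  }
  events <- tibble::tibble(trial_id = 1L, seq_index = seq_len(n_events),
                           onset_time_s = onsets, duration_s = 0.05,
                           color = "green", role = "carrier")
  new_recording(lfp, fs = fs, movement = numeric(n), proboscis = numeric(n),
                events = events)
}

# Hand-built amplitude record table for normalisation/correction arithmetic.
toy_records <- function(amps, fly_id = "flyA", channel = 3L,
                        color = "green", role = "carrier") {
  tibble::tibble(fly_id = fly_id, trial_id = 1L,
                 seq_index = seq_along(amps), onset_time_s = seq_along(amps),
                 channel = channel, region = "central", color = color,
                 role = role, amp_raw = amps)
}
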