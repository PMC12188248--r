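# Amplitude extraction, normalisation, history labelling, contrasts, spectra.

toy_trial_events <- function() {
  roles <- rep("carrier", 12)
  roles[c(3, 8)] <- "deviant"
  tibble::tibble(trial_id = 1L, seq_index = 1:12,
                 onset_time_s = (0:11) / 10, duration_s = 0.05,
                 color = ifelse(roles == "deviant", "green", "blue"),
                 role = roles)
}

test_that("epoch extraction yields one slice per event and channel", {
  rec <- simulate_recording(sim_config(), duration_s = 25, seed = 1)
  one_trial <- rec$events[rec$events$trial_id == 1, ]
  ep <- extract_epochs(rec, events = one_trial, channels = c(4, 9, 15))
  expect_equal(nrow(ep), 200 * 3)
  expect_equal(unique(lengths(ep$epoch)), 20)  # 0.1 s at 200 Hz
  expect_error(extract_epochs(rec, events = one_trial, channels = 4,
                              window_s = c(0, 0.2)),
               class = "flyssvep_invalid_argument")
})

test_that("noise-free epochs reproduce the configured kernel shape", {
  cfg <- noise_free_config()
  rec <- simulate_recording(cfg, duration_s = 25, seed = 1)
  ev <- rec$events[1, ]
  ep <- extract_epochs(rec, events = ev, channels = 1)
  kern <- kernel_waveform(cfg$fs)
  got <- ep$epoch[[1]]
  expect_equal(got / (max(got) - min(got)), kern, tolerance = 1e-9)
})

test_that("peak-trough amplitude is order-agnostic, shift-invariant and linear", {
  expect_equal(epoch_amplitude(c(0, 3, -2, 1)), 5)
  expect_equal(epoch_amplitude(rep(2, 10)), 0)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(30)
    a <- epoch_amplitude(x)
    expect_gte(a, 0)
    expect_equal(epoch_amplitude(x + 17.3), a)
    expect_equal(epoch_amplitude(3.5 * x), 3.5 * a)
    expect_equal(epoch_amplitude(rev(x)), a)
  }
  expect_error(epoch_amplitude(numeric(0)),
               class = "flyssvep_invalid_argument")
})

test_that("per-colour normalisation pools roles and averages to one", {
  r <- toy_records(c(2, 4))
  n <- normalize_amplitudes(r)
  expect_equal(sort(n$amp_norm), c(2 / 3, 4 / 3))
  expect_equal(mean(n$amp_norm), 1)

  same <- normalize_amplitudes(toy_records(rep(3, 5)))
  expect_true(all(same$amp_norm == 1))

  # carriers and deviants of one colour share a single denominator
  mixed <- dplyr::bind_rows(
    toy_records(c(2, 2), role = "carrier"),
    toy_records(c(6, 6), role = "deviant"))
  nm <- normalize_amplitudes(mixed)
  expect_equal(unique(nm$amp_norm[nm$role == "carrier"]), 0.5)
  expect_equal(unique(nm$amp_norm[nm$role == "deviant"]), 1.5)

  expect_error(normalize_amplitudes(toy_records(c(0, 0))),
               class = "flyssvep_degenerate_normalization")
})

test_that("normalisation identity holds per fly, channel and colour on simulated data", {
  rec <- simulate_recording(sim_config(), duration_s = 120, seed = 2)
  amps <- compute_amplitudes(rec, channel_map = c(4L, 9L))
  n <- normalize_amplitudes(amps)
  pools <- dplyr::summarise(
    dplyr::group_by(n, fly_id, channel, color),
    m = mean(amp_norm), .groups = "drop")
  expect_true(all(abs(pools$m - 1) < 1e-12))
})

test_that("corrected amplitudes centre the two group means at zero per fly", {
  r <- dplyr::bind_rows(
    dplyr::mutate(toy_records(c(0.9, 0.9)), group = "a", amp_norm = amp_raw),
    dplyr::mutate(toy_records(c(1.1, 1.1)), group = "b", amp_norm = amp_raw))
  cc <- corrected_amplitude(r)
  expect_equal(unique(cc$amp_corrected[cc$group == "a"]), -0.1)
  expect_equal(unique(cc$amp_corrected[cc$group == "b"]), 0.1)

  ident <- dplyr::bind_rows(
    dplyr::mutate(toy_records(c(1, 2)), group = "a", amp_norm = amp_raw),
    dplyr::mutate(toy_records(c(1, 2)), group = "b", amp_norm = amp_raw))
  ci <- corrected_amplitude(ident)
  expect_equal(mean(ci$amp_corrected), 0)

  # a fly with only one group is excluded, not an error
  lop <- dplyr::bind_rows(
    dplyr::mutate(toy_records(c(1, 2)), group = "a", amp_norm = amp_raw),
    dplyr::mutate(toy_records(c(2, 3)), group = "b", amp_norm = amp_raw),
    dplyr::mutate(toy_records(c(5, 6), fly_id = "flyB"), group = "a",
                  amp_norm = amp_raw))
  expect_message(cl <- corrected_amplitude(lop), "flyB")
  expect_false("flyB" %in% cl$fly_id)
})

test_that("history labels match hand enumeration on a toy trial", {
  ev <- label_history(toy_trial_events())
  expect_equal(ev$prev_role,
               c(NA, "carrier", "carrier", "deviant", "carrier", "carrier",
                 "carrier", "carrier", "deviant", "carrier", "carrier",
                 "carrier"))
  expect_equal(ev$carrier_order,
               c(NA, NA, NA, 1L, 2L, 3L, 4L, NA, 1L, 2L, 3L, 4L))
  expect_equal(ev$carrier_run[ev$role == "deviant"], c(2L, 4L))

  # phasic trial: carriers 6..9 after the deviant at 5 are orders 1..4
  ph <- label_history(build_phasic_trial(
    trial_spec("phasic", carrier_color = "blue")))
  expect_equal(ph$carrier_order[6:9], 1:4)
  expect_true(is.na(ph$carrier_order[10]))   # the next deviant
  expect_equal(ph$carrier_run[ph$seq_index == 10], 4L)
  expect_true(all(is.na(ph$carrier_order[1:5])))
})

test_that("contrast selection matches hand enumeration", {
  ev <- label_history(toy_trial_events())
  ev$fly_id <- "flyA"; ev$amp_norm <- 1
  ev$state <- "wake"; ev$segment <- NA_character_
  sel <- select_contrast(ev, "carrier_vs_deviant")
  expect_setequal(sel$seq_index[sel$group == "carrier"], c(4, 9))
  expect_setequal(sel$seq_index[sel$group == "deviant"], c(3, 8))

  orders <- select_contrast(ev, "carrier_order")
  expect_equal(sort(table(orders$group)[c("1", "2", "3", "4")] |>
                      as.vector()), c(2, 2, 2, 2))

  ws <- select_contrast(ev, "wake_vs_sleep", role = "deviant")
  expect_true(all(ws$role == "deviant"))

  expect_error(select_contrast(ev, "not_a_contrast"),
               class = "flyssvep_invalid_argument")
})

test_that("jitter-matched deviants are selected by their carrier run", {
  ev <- label_history(toy_trial_events())
  ev$trial_type <- "jittering"
  sel <- select_contrast(ev, "jitter_vs_phasic")
  expect_equal(sel$seq_index, 8)   # only the deviant preceded by 4 carriers
})

test_that("simulated phasic trials show F1 and F2 spectral peaks at the configured rates", {
  rec <- simulate_recording(sim_config(), duration_s = 6 * 23, seed = 5)
  sp <- power_spectrum(rec, channel = 9)
  expect_lte(max(diff(sp$freq_hz)), 0.25)
  pk <- spectrum_peaks(sp)
  expect_equal(pk$f1_hz, 10)
  expect_equal(pk$f2_hz, 2)

  # carrier-only trials: no 2 Hz peak above its neighbourhood
  cfg0 <- sim_config(stim = list(trial_type = "carrier_only"))
  rec0 <- simulate_recording(cfg0, duration_s = 6 * 23, seed = 5)
  sp0 <- power_spectrum(rec0, channel = 9)
  p2 <- sp0$power[sp0$freq_hz == 2]
  nbhd <- sp0$power[sp0$freq_hz > 1 & sp0$freq_hz < 3 & sp0$freq_hz != 2]
  expect_lt(p2, 3 * stats::median(nbhd))
  expect_error(power_spectrum(rec0, channel = 99),
               class = "flyssvep_invalid_argument")
})

test_that("average ERPs respect grouping and symmetry", {
  rec <- simulate_recording(noise_free_config(), duration_s = 25, seed = 1)
  carriers <- rec$events[rec$events$trial_id == 1 &
                           rec$events$role == "carrier", ][1:40, ]
  ep <- extract_epochs(rec, events = carriers, channels = 4)
  erp <- average_erp(ep)
  expect_equal(erp$mean_lfp, ep$epoch[[1]], tolerance = 1e-9,
               ignore_attr = TRUE)

  # epochs straddling the reversal (mirrored profile) average to ~zero
  ep2 <- extract_epochs(rec, events = carriers, channels = c(8, 16))
  erp2 <- average_erp(dplyr::mutate(ep2, channel = 0L))
  expect_lt(max(abs(erp2$mean_lfp)),
            0.05 * max(abs(erp$mean_lfp)))
})
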