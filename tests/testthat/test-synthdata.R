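# Forward simulator: ground-truth fidelity, determinism, serialisation.

test_that("identical config and seed give a bitwise-identical recording", {
  cfg <- sim_config()
  a <- simulate_recording(cfg, duration_s = 120, seed = 5)
  b <- simulate_recording(cfg, duration_s = 120, seed = 5)
  expect_identical(a$lfp, b$lfp)
  expect_identical(a$movement, b$movement)
  expect_identical(a$proboscis, b$proboscis)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  c <- simulate_recording(cfg, duration_s = 120, seed = 6)
  expect_false(identical(a$lfp, c$lfp))
})

test_that("bout generator alternates states, tiles the span and hits its medians", {
  bm <- sim_config()$bout_model
  set.seed(21)
  bouts <- flyssvep:::draw_bouts(bm, 6 * 3600)
  expect_true(all(bouts$end_s > bouts$start_s))
  expect_equal(bouts$start_s[-1], bouts$end_s[-nrow(bouts)])
  expect_true(all(bouts$state[-1] != bouts$state[-nrow(bouts)]))

  # pooled medians converge to the configured targets within 5%
  set.seed(22)
  pool <- dplyr::bind_rows(lapply(1:60, function(i)
    flyssvep:::draw_bouts(bm, 6 * 3600)))
  pool$dur_min <- (pool$end_s - pool$start_s) / 60
  pool <- pool[pool$dur_min > 0.5, ]  # drop truncated tail bouts
  expect_gt(nrow(pool), 200)
  med <- tapply(pool$dur_min, pool$state, median)
  expect_lt(abs(med[["sleep"]] - 12.8) / 12.8, 0.05)
  expect_lt(abs(med[["wake"]] - 11.2) / 11.2, 0.05)
})

test_that("a forced single wake bout keeps movement active throughout", {
  cfg <- sim_config(bout_model = list(wake_median_min = 1e6))
  set.seed(1)
  beh <- simulate_behavior(cfg, duration_s = 300)
  expect_equal(nrow(beh$bouts), 1)
  expect_equal(beh$bouts$state, "wake")
  act <- quantify_movement(beh$movement, cfg$fs)
  expect_gt(mean(act$active), 0.99)
  expect_error(sim_config(bout_model = list(sleep_median_min = -1)),
               class = "flyssvep_invalid_config")
})

test_that("noise-free movement round-trips through sleep scoring to the truth bouts", {
  cfg <- noise_free_config()
  set.seed(31)  # this seed's bout draw contains sleep within the span
  beh <- simulate_behavior(cfg, duration_s = 2400)
  expect_true(any(beh$bouts$state == "sleep"))
  act <- quantify_movement(beh$movement, cfg$fs)
  scored <- score_bouts(act)
  truth_sleep <- beh$bouts[beh$bouts$state == "sleep" &
                             beh$bouts$end_s - beh$bouts$start_s >= 300, ]
  got_sleep <- scored[scored$state == "sleep", ]
  expect_equal(nrow(got_sleep), nrow(truth_sleep))
  expect_true(all(abs(got_sleep$start_s - truth_sleep$start_s) <= 1))
  expect_true(all(abs(got_sleep$end_s - truth_sleep$end_s) <= 1))
})

test_that("proboscis model places rhythmic spells in deep sleep and long reaches in wake", {
  cfg <- sim_config(pe_model = list(deep_spell_rate = 1.5, reach_rate = 0.4))
  set.seed(41)
  beh <- simulate_behavior(cfg, duration_s = 3000)
  prob <- simulate_proboscis(cfg, beh, duration_s = 3000)
  ev <- prob$pe_events
  expect_true(nrow(ev) > 0)
  rhythmic <- ev[ev$kind == "rhythmic_extension", ]
  reaches <- ev[ev$kind == "reach", ]
  if (nrow(reaches) > 0 && nrow(rhythmic) > 0) {
    expect_gt(min(reaches$duration_s), max(rhythmic$duration_s))
  }
  # rhythmic events sit inside deep-sleep intervals more than anywhere else
  if (nrow(rhythmic) > 0 && nrow(beh$deep) > 0) {
    in_deep <- sapply(rhythmic$time_s, function(t)
      any(t >= beh$deep$start_s & t <= beh$deep$end_s))
    expect_gt(mean(in_deep), 0.5)
  }

  quiet <- sim_config(pe_model = list(deep_spell_rate = 0,
                                      light_spell_rate = 0,
                                      wake_spell_rate = 0, reach_rate = 0),
                      noise = list(proboscis_sd = 0))
  prob0 <- simulate_proboscis(quiet, beh, duration_s = 3000)
  expect_equal(nrow(prob0$pe_events), 0)
  expect_true(all(prob0$proboscis == 0))
  expect_error(sim_config(pe_model = list(reach_rate = -1)),
               class = "flyssvep_invalid_config")
})

test_that("noise-free measured amplitudes equal the configured truth", {
  cfg <- noise_free_config()
  rec <- simulate_recording(cfg, duration_s = 120, seed = 3)
  amps <- compute_amplitudes(rec, channel_map = seq_len(16))
  truth <- rec$truth$amplitudes
  joined <- dplyr::inner_join(amps, truth,
                              by = c("trial_id", "seq_index", "channel"))
  expect_gt(nrow(joined), 1000)
  nonzero <- joined[joined$amp_true > 0, ]
  expect_lt(max(abs(nonzero$amp_raw - nonzero$amp_true) / nonzero$amp_true),
            1e-6)
  # the reversal channel has zero evoked amplitude
  expect_true(all(joined$amp_true[joined$channel == 12] == 0))
})

test_that("channels on opposite sides of the reversal are anticorrelated", {
  rec <- simulate_recording(sim_config(), duration_s = 120, seed = 4)
  ep <- extract_epochs(rec, channels = c(4, 15))
  erp <- average_erp(ep)
  w4 <- erp$mean_lfp[erp$channel == 4]
  w15 <- erp$mean_lfp[erp$channel == 15]
  expect_lt(cor(w4, w15), -0.8)
})

test_that("deviant responses are smaller than carrier responses in central channels during wake", {
  rec <- simulate_recording(sim_config(), duration_s = 240, seed = 8)
  truth <- rec$truth$amplitudes
  central <- truth[truth$channel == 4 & truth$state == "wake", ]
  ev <- dplyr::inner_join(
    central, rec$events[c("trial_id", "seq_index", "role")],
    by = c("trial_id", "seq_index"))
  expect_lt(mean(ev$amp_true[ev$role == "deviant"]),
            mean(ev$amp_true[ev$role == "carrier"]))
})

test_that("the recording container round-trips losslessly", {
  rec <- simulate_recording(sim_config(), duration_s = 60, seed = 9)
  path <- withr::local_tempdir()
  dir <- file.path(path, "rec")
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_identical(back$lfp, rec$lfp)
  expect_identical(back$movement, rec$movement)
  expect_identical(back$proboscis, rec$proboscis)
  expect_equal(back$events, rec$events)
  expect_equal(back$truth$bouts, rec$truth$bouts)
  expect_equal(back$truth$amplitudes, rec$truth$amplitudes)
  expect_equal(back$fs, rec$fs)
})

test_that("containers without truth load in real-data mode and bad containers fail loudly", {
  rec <- simulate_recording(sim_config(), duration_s = 60, seed = 9)
  path <- withr::local_tempdir()
  dir <- file.path(path, "rec")
  rec$truth <- NULL
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_null(back$truth)

  # tampered version field
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  meta$version <- "99.0"
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  expect_error(read_recording(dir), class = "flyssvep_unsupported_version")

  # missing component
  meta$version <- "1.0"
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  file.remove(file.path(dir, "lfp.parquet"))
  err <- tryCatch(read_recording(dir), error = function(e) e)
  expect_s3_class(err, "flyssvep_format")
  expect_match(conditionMessage(err), "lfp.parquet")

  expect_error(read_recording(file.path(path, "nonexistent")),
               class = "flyssvep_format")
})
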