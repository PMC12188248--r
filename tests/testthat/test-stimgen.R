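# Stimulus-schedule generation: counterbalanced carrier/deviant trains.

test_that("carrier-only trials have exact event counts and spacing", {
  spec <- trial_spec("carrier_only", carrier_color = "green")
  ev <- build_carrier_trial(spec)
  expect_equal(nrow(ev), 200)
  expect_true(all(ev$role == "carrier"))
  expect_true(all(ev$color == "green"))
  expect_equal(unique(ev$duration_s), 0.05)
  expect_equal(diff(ev$onset_time_s), rep(0.1, 199))
  expect_equal(ev$onset_time_s[200], 19.9)

  one <- build_carrier_trial(trial_spec("carrier_only", n_events = 1,
                                        start_time = 5))
  expect_equal(nrow(one), 1)
  expect_equal(one$onset_time_s, 5)
  expect_equal(one$duration_s, 0.05)

  expect_error(trial_spec("carrier_only", n_events = 0),
               class = "flyssvep_invalid_spec")
  expect_error(trial_spec("carrier_only", f1_hz = -1),
               class = "flyssvep_invalid_spec")
})

test_that("phasic trials place deviants at every fifth position", {
  spec <- trial_spec("phasic", carrier_color = "blue",
                     deviant_color = "green")
  ev <- build_phasic_trial(spec)
  expect_equal(which(ev$role == "deviant"), seq(5, 200, by = 5))
  expect_equal(sum(ev$role == "deviant"), 40)
  expect_equal(sum(ev$role == "carrier"), 160)
  expect_true(all(ev$color[ev$role == "deviant"] == "green"))
  # deviant rate = f1 / deviant_every = 2 Hz
  dev_onsets <- ev$onset_time_s[ev$role == "deviant"]
  expect_equal(diff(dev_onsets), rep(0.5, 39))
  # gap between consecutive deviants is always 4 carriers
  gaps <- diff(which(ev$role == "deviant")) - 1
  expect_true(all(gaps == 4))

  all_dev <- build_phasic_trial(trial_spec("phasic", deviant_every = 1,
                                           carrier_color = "green"))
  expect_true(all(all_dev$role == "deviant"))

  expect_error(trial_spec("phasic", carrier_color = "green",
                          deviant_color = "green"),
               class = "flyssvep_invalid_spec")
})

test_that("zero jitter reduces a jittering trial to the phasic trial", {
  jspec <- trial_spec("jittering", carrier_color = "blue", jitter_sd = 0)
  pspec <- trial_spec("phasic", carrier_color = "blue")
  set.seed(99)
  jit <- build_jittering_trial(jspec)
  pha <- build_phasic_trial(pspec)
  expect_identical(jit$role, pha$role)
  expect_identical(jit$color, pha$color)
  expect_error(trial_spec("jittering", jitter_sd = -1),
               class = "flyssvep_invalid_spec")
})

test_that("jittered deviant positions stay ordered within the trial and are seed-deterministic", {
  spec <- trial_spec("jittering", carrier_color = "green", jitter_sd = 1.5)
  set.seed(7); a <- build_jittering_trial(spec)
  set.seed(7); b <- build_jittering_trial(spec)
  expect_identical(a, b)
  pos <- which(a$role == "deviant")
  expect_true(all(diff(pos) >= 1))
  expect_true(all(pos >= 1 & pos <= 200))
})

test_that("jitter gap distribution is modal at four carriers", {
  spec <- trial_spec("jittering", carrier_color = "green", jitter_sd = 1)
  set.seed(11)
  gaps <- unlist(lapply(1:300, function(i) {
    pos <- which(build_jittering_trial(spec)$role == "deviant")
    diff(pos) - 1
  }))
  tab <- table(gaps)
  top <- names(sort(tab, decreasing = TRUE))
  expect_equal(top[1], "4")
  expect_setequal(top[2:3], c("3", "5"))
})

test_that("schedules are counterbalanced, paused and deterministic", {
  set.seed(1)
  two <- counterbalance_schedule(2, "phasic")
  expect_setequal(two$deviant_color, c("green", "blue"))

  set.seed(2)
  s72 <- counterbalance_schedule(72, "phasic")
  expect_equal(sum(s72$deviant_color == "green"), 36)
  expect_equal(sum(s72$deviant_color == "blue"), 36)
  # trials laid out with 3 s pauses: stride = 20 s + 3 s
  expect_equal(unique(diff(s72$start_time)), 23)

  set.seed(3)
  s3 <- counterbalance_schedule(3, "phasic")
  expect_setequal(as.vector(table(s3$deviant_color)), c(2, 1))

  set.seed(5); a <- counterbalance_schedule(8, "jittering")
  set.seed(5); b <- counterbalance_schedule(8, "jittering")
  expect_identical(a, b)
  set.seed(5); ea <- schedule_events(a)
  set.seed(5); eb <- schedule_events(b)
  expect_identical(ea, eb)
})

test_that("schedules round-trip through JSON", {
  set.seed(4)
  sch <- counterbalance_schedule(6, "phasic")
  path <- file.path(withr::local_tempdir(), "schedule.json")
  write_schedule(sch, path)
  back <- read_schedule(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(sch))
  expect_equal(attr(back, "pause_s"), 3)
  set.seed(1); ea <- schedule_events(back)
  set.seed(1); eb <- schedule_events(sch)
  expect_identical(ea, eb)
})

test_that("the rendered stimulus trace is a sample-aligned square wave", {
  one <- build_carrier_trial(trial_spec("carrier_only", n_events = 1))
  tr <- render_stimulus_trace(one, fs = 1000)
  expect_equal(sum(tr$stim_on), 50)
  expect_true(all(which(tr$stim_on == 1) == 1:50))
  expect_equal(unique(tr$color[tr$stim_on == 1]), "green")

  full <- build_carrier_trial(trial_spec("carrier_only"))
  tr2 <- render_stimulus_trace(full, fs = 1000)
  expect_equal(sum(tr2$stim_on), 200 * 50)

  empty <- full[0, ]
  tr3 <- render_stimulus_trace(empty, fs = 100)
  expect_true(all(tr3$stim_on == 0))

  expect_error(render_stimulus_trace(full, fs = 15),
               class = "flyssvep_invalid_spec")
})
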