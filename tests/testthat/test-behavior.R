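# Sleep scoring, bout segmentation and proboscis-event classification.

make_activity <- function(active_runs_s) {
  # build an activity table from alternating (active, quiet) run lengths
  active <- unlist(mapply(function(len, act) rep(act, len),
                          active_runs_s, rep(c(TRUE, FALSE),
                                             length.out = length(active_runs_s)),
                          SIMPLIFY = FALSE))
  tibble::tibble(start_s = seq_along(active) - 1, end_s = seq_along(active),
                 activity = as.numeric(active), active = active)
}

test_that("movement quantification thresholds per-bin activity", {
  expect_error(quantify_movement(numeric(0), 100),
               class = "flyssvep_invalid_input")
  act <- quantify_movement(rep(0, 1000), fs = 100)
  expect_true(all(!act$active))

  # alternating 1 s active / 1 s quiet blocks recovered exactly
  fs <- 100
  trace <- rep(c(rep(1, fs), rep(0, fs)), 10)
  act2 <- quantify_movement(trace, fs)
  expect_equal(act2$active, rep(c(TRUE, FALSE), 10))
})

test_that("the five-minute immobility boundary is inclusive", {
  a299 <- make_activity(c(60, 299, 60))
  b299 <- score_bouts(a299)
  expect_equal(b299$state, "wake")
  expect_equal(nrow(b299), 1)

  a300 <- make_activity(c(60, 300, 60))
  b300 <- score_bouts(a300)
  expect_equal(b300$state, c("wake", "sleep", "wake"))
  expect_equal(b300$duration_s[2], 300)
  expect_equal(b300$start_s[2], 60)
})

test_that("bouts tile the scored span with alternating states", {
  set.seed(10)
  runs <- sample(c(30, 400, 200, 700, 45, 310, 600), 7)
  act <- make_activity(runs)
  bouts <- score_bouts(act)
  expect_equal(sum(bouts$duration_s), sum(runs))
  expect_equal(bouts$start_s[-1], bouts$end_s[-nrow(bouts)])
  expect_true(all(bouts$duration_s > 0))
  if (nrow(bouts) > 1) {
    expect_true(all(bouts$state[-1] != bouts$state[-nrow(bouts)]))
  }
})

test_that("sleep bouts segment into the five labelled minutes", {
  bouts <- tibble::tibble(state = c("wake", "sleep"),
                          start_s = c(0, 600), end_s = c(600, 1200),
                          duration_s = c(600, 600))
  seg <- segment_bouts(bouts)
  sl <- seg[seg$state == "sleep", ]
  expect_setequal(sl$label, c("sleep_1st", "sleep_2nd", "mid_sleep",
                              "sleep_2nd_last", "sleep_last"))
  expect_equal(sl$start_s[sl$label == "sleep_1st"], 600)
  expect_equal(sl$end_s[sl$label == "sleep_1st"], 660)
  expect_equal(sl$start_s[sl$label == "sleep_last"], 1140)
  # 10 whole minutes: mid window starts at minute floor((10-1)/2)+1 = 5
  expect_equal(sl$start_s[sl$label == "mid_sleep"], 600 + 4 * 60)
  # wake segments come from the immediately preceding wake bout
  wk <- seg[seg$state == "wake", ]
  expect_setequal(wk$label, c("mid_wake", "last_wake"))
  expect_equal(wk$start_s[wk$label == "last_wake"], 540)
  # all windows inside their bouts and unique labels per bout
  expect_true(all(sl$start_s >= 600 & sl$end_s <= 1200))
  expect_equal(anyDuplicated(paste(seg$bout_index, seg$label)), 0)
})

test_that("short and odd-length sleep bouts follow the centering rule", {
  five <- tibble::tibble(state = "sleep", start_s = 0, end_s = 300,
                         duration_s = 300)
  seg5 <- segment_bouts(five)
  expect_equal(nrow(seg5), 5)
  expect_equal(sort(seg5$start_s), c(0, 60, 120, 180, 240))  # minutes 1..5

  six <- tibble::tibble(state = "sleep", start_s = 0, end_s = 360,
                        duration_s = 360)
  seg6 <- segment_bouts(six)
  expect_equal(seg6$start_s[seg6$label == "mid_sleep"], 120)  # minute 3

  t21 <- tibble::tibble(state = "sleep", start_s = 0, end_s = 21 * 60,
                        duration_s = 21 * 60)
  seg21 <- segment_bouts(t21)
  expect_equal(seg21$start_s[seg21$label == "mid_sleep"], 10 * 60) # minute 11

  # wake bouts shorter than two minutes yield no wake segments
  short_wake <- tibble::tibble(state = c("wake", "sleep"),
                               start_s = c(0, 100), end_s = c(100, 500),
                               duration_s = c(100, 400))
  segw <- segment_bouts(short_wake)
  expect_false(any(segw$state == "wake"))
})

test_that("proboscis events are detected, merged and classified", {
  fs <- 100
  expect_equal(nrow(detect_pe_events(rep(0, 1000), fs)), 0)

  # two crossings 50 ms apart merge into one event
  tr <- numeric(1000)
  tr[101:120] <- 1
  tr[126:145] <- 1
  ev <- detect_pe_events(tr, fs, merge_gap_s = 0.1)
  expect_equal(nrow(ev), 1)
  ev2 <- detect_pe_events(tr, fs, merge_gap_s = 0.01)
  expect_equal(nrow(ev2), 2)

  # five short events at 1 s spacing form one all-rhythmic spell
  tr2 <- numeric(10 * fs)
  for (k in 0:4) tr2[(k * fs + 1):(k * fs + 30)] <- 1
  ev3 <- detect_pe_events(tr2, fs)
  cls <- classify_pe(ev3)
  expect_equal(nrow(cls$spells), 1)
  expect_true(all(cls$events$kind == "rhythmic_extension"))

  # a single 3 s event is a reach; a single short event is unclassified
  tr3 <- numeric(10 * fs)
  tr3[101:400] <- 1
  r <- classify_pe(detect_pe_events(tr3, fs))
  expect_equal(r$events$kind, "reach")
  tr4 <- numeric(10 * fs)
  tr4[101:130] <- 1
  u <- classify_pe(detect_pe_events(tr4, fs))
  expect_equal(u$events$kind, "unclassified")
})

test_that("spells split at bout boundaries so their state context is unambiguous", {
  fs <- 100
  tr <- numeric(20 * fs)
  for (k in 0:5) tr[(k * fs + 401):(k * fs + 430)] <- 1  # events at 4..9 s
  ev <- detect_pe_events(tr, fs)
  bouts <- tibble::tibble(state = c("wake", "sleep"), start_s = c(0, 7),
                          end_s = c(7, 20), duration_s = c(7, 13))
  cls <- classify_pe(ev, bouts = bouts)
  expect_equal(nrow(cls$spells), 2)
  expect_setequal(cls$spells$state, c("wake", "sleep"))
})

test_that("inter-extension windows exclude the extensions and their guards", {
  ev <- tibble::tibble(start_s = c(1.0, 2.0), end_s = c(1.2, 2.2),
                       peak_time_s = c(1.1, 2.1), duration_s = 0.2,
                       amplitude = 1)
  win <- inter_pe_windows(ev, guard_s = 0.05)
  expect_equal(nrow(win), 1)
  expect_equal(win$start_s, 1.25)
  expect_equal(win$end_s, 1.95)
  expect_equal(win$end_s - win$start_s, 0.7)

  # back-to-back events leave no window
  ev2 <- tibble::tibble(start_s = c(1.0, 1.2), end_s = c(1.2, 1.4),
                        peak_time_s = c(1.1, 1.3), duration_s = 0.2,
                        amplitude = 1)
  expect_equal(nrow(inter_pe_windows(ev2)), 0)
  expect_error(inter_pe_windows(ev2[1, ]),
               class = "flyssvep_invalid_argument")
})
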