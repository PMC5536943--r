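test_that("default schedule has the six-block 210-trial structure", {
  sched <- session_schedule()
  expect_equal(nrow(sched$blocks), 6)
  expect_equal(sum(sched$blocks$n_trials), 210)
  expect_equal(sched$blocks$n_trials, c(20, 50, 20, 50, 20, 50))
  trials <- make_schedule(sched, seed = 1)
  expect_equal(nrow(trials), 210)
  validate_trials(trials, sched)
  paired <- !is.na(trials$us_onset_s)
  expect_equal(trials$us_onset_s[paired] - trials$cs_onset_s[paired],
               rep(0.6, sum(paired)))
  expect_true(all(diff(trials$cs_onset_s) > 0))
})

test_that("schedule constructor enforces its invariants", {
  expect_error(session_schedule(cs_duration_s = 0.2, trace_interval_s = 0.5),
               "0.600")
  expect_error(session_schedule(iti_min_s = 5, iti_max_s = 40), "9 s")
  expect_error(session_schedule(iti_min_s = 41, iti_max_s = 40), "iti_min")
  expect_error(
    block_specs(1:2, c("auditory", "auditory"), c(1, 1), c(TRUE, TRUE),
                c(20, 20)),
    "unique")
})

test_that("ITI draws are deterministic under a fixed seed and bounded", {
  sched <- small_schedule()
  t1 <- make_schedule(sched, seed = 7)
  t2 <- make_schedule(sched, seed = 7)
  expect_identical(t1, t2)
  ends <- c(0, us_equivalent_time(t1)[-nrow(t1)] + sched$us_duration_s)
  gaps <- t1$cs_onset_s - ends
  expect_true(all(gaps >= sched$iti_min_s - 1e-9))
  expect_true(all(gaps <= sched$iti_max_s + 1e-9))
})

test_that("a single-trial schedule lays out one trial", {
  sched <- session_schedule(
    block_specs(1, "auditory", 1, TRUE, 1))
  tr <- make_schedule(sched, seed = 3)
  expect_equal(nrow(tr), 1)
  expect_false(is.na(tr$us_onset_s))
})

test_that("session round-trips through write_session and read_session", {
  sched <- small_schedule(2, 3, emg_rate = 500)
  trials <- make_schedule(sched, seed = 5)
  dur <- session_duration(trials, sched)
  units <- data.frame(unit_id = c("a", "b", "c"), rat_id = "r1",
                      session_id = "s1",
                      layer = c("superficial", "deep", "unknown"))
  trains <- list(a = c(1.5, 20.25, dur - 2), b = numeric(0), c = c(0.5))
  spikes <- spike_train_set(units, trains, dur)
  emg <- emg_trace(sin(seq_len(200)), rate_hz = sched$emg_rate_hz)
  dir <- withr::local_tempdir()
  write_session(spikes, trials, emg, sched, dir)
  back <- read_session(dir)
  expect_equal(back$spikes$spikes$a, trains$a)
  expect_equal(back$spikes$spikes$b, numeric(0))
  expect_equal(back$trials$cs_onset_s, trials$cs_onset_s)
  expect_equal(back$schedule$blocks, sched$blocks)
  expect_equal(back$schedule$iti_min_s, sched$iti_min_s)
  expect_equal(back$emg$samples, emg$samples, tolerance = 1e-6)
  # bit-stability: writing the same objects twice gives identical files
  dir2 <- withr::local_tempdir()
  write_session(spikes, trials, emg, sched, dir2)
  for (f in c("spikes.csv", "trials.csv", "schedule.json"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})

test_that("read_session rejects inconsistent inputs", {
  sched <- small_schedule(2, 3, emg_rate = 500)
  trials <- make_schedule(sched, seed = 5)
  dur <- session_duration(trials, sched)
  units <- data.frame(unit_id = "a", rat_id = "r1", session_id = "s1",
                      layer = "deep")
  spikes <- spike_train_set(units, list(a = c(1, 2)), dur)
  dir <- withr::local_tempdir()
  write_session(spikes, trials, NULL, sched, dir)

  # US onset on a trial of an unpaired block
  tr <- utils::read.csv(file.path(dir, "trials.csv"))
  bad <- tr
  alone_row <- which(is.na(bad$us_onset_s))[1]
  bad$us_onset_s[alone_row] <- bad$cs_onset_s[alone_row] + 0.6
  utils::write.csv(bad, file.path(dir, "trials.csv"), row.names = FALSE)
  expect_error(read_session(dir), "unpaired")
  utils::write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)

  # missing column
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  utils::write.csv(sp[, -5], file.path(dir, "spikes.csv"), row.names = FALSE)
  expect_error(read_session(dir), "missing columns")
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)

  # unsorted spike times
  sp2 <- sp
  sp2$spike_time_s <- rev(sp2$spike_time_s)
  utils::write.csv(sp2, file.path(dir, "spikes.csv"), row.names = FALSE)
  expect_error(read_session(dir), "sorted")
})

test_that("write_session refuses non-finite EMG samples", {
  sched <- small_schedule(2, 3)
  trials <- make_schedule(sched, seed = 5)
  dur <- session_duration(trials, sched)
  units <- data.frame(unit_id = "a", rat_id = "r", session_id = "s",
                      layer = "deep")
  spikes <- spike_train_set(units, list(a = numeric(0)), dur)
  expect_error(emg_trace(c(1, NA, 3)), "finite")
  bad_emg <- emg_trace(c(1, 2, 3))
  bad_emg$samples[2] <- Inf
  expect_error(write_session(spikes, trials, bad_emg, sched,
                             withr::local_tempdir()),
               "finite")
})

test_that("analysis_config validates its fields", {
  expect_error(analysis_config(n_permutations = 0), "n_permutations")
  expect_error(analysis_config(alpha = 0), "alpha")
  expect_error(analysis_config(alpha = 1), "alpha")
  expect_equal(analysis_config()$n_permutations, 1000L)
  expect_equal(analysis_config()$iti_window_s, 9)
})

test_that("stage seeds are deterministic, distinct and below 2^31", {
  s <- vapply(c("schedule", "spikes", "behavior", "decoding"),
              function(st) stage_seed(42, st), integer(1))
  expect_equal(length(unique(s)), 4)
  expect_true(all(s > 0 & s < 2^31))
  expect_identical(stage_seed(42, "spikes"), stage_seed(42, "spikes"))
})
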