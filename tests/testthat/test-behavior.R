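test_that("Hilbert envelope recovers sinusoid amplitudes", {
  rate <- 10000
  tt <- seq(0, 0.5, by = 1 / rate)
  # in-band pure tone: envelope equals the amplitude away from the edges
  env <- emg_envelope(3 * sin(2 * pi * 1000 * tt), rate)
  interior <- env[500:(length(env) - 500)]
  expect_lt(max(abs(interior - 3)) / 3, 0.02)
  # all-zero trace
  expect_equal(emg_envelope(numeric(100), rate, bandpass = FALSE),
               numeric(100))
  expect_error(emg_envelope(numeric(0), rate), "empty")
  # amplitude-modulated tone: envelope tracks |A(t)|
  a_t <- 2 + sin(2 * pi * 4 * tt)
  env_am <- emg_envelope(a_t * sin(2 * pi * 1000 * tt), rate,
                         bandpass = FALSE)
  interior <- 500:(length(env_am) - 500)
  expect_lt(max(abs(env_am[interior] - a_t[interior]) / a_t[interior]), 0.05)
})

test_that("three-branch CR rule labels the canonical cases", {
  p <- cr_detection_params()
  expect_equal(score_trial(8, 12, 10, p), "CR")      # 12 > 1.1 * 10
  expect_equal(score_trial(8, 10.5, 10, p), "noCR")
  expect_equal(score_trial(14, 100, 10, p), "discarded")  # 14 > 13
  expect_equal(score_trial(12, 21, 10, p), "CR")     # 11 >= 5 * 2
  expect_equal(score_trial(12, 15, 10, p), "noCR")   # 5 < 10
  expect_error(cr_detection_params(hyper_factor = 0.9), "exceed 1")
})

test_that("CR labelling is monotone in the scoring values", {
  p <- cr_detection_params()
  thr <- 10
  for (pre in c(2, 8, 10, 11, 12.9)) {
    crs <- seq(0, 40, by = 0.5)
    labels <- vapply(crs, function(cv) score_trial(pre, cv, thr, p),
                     character(1))
    is_cr <- labels == "CR"
    # once CR, always CR as cr_value increases
    expect_true(all(diff(as.integer(is_cr)) >= 0))
  }
  # increasing pre_cs_value never rescues a discarded trial
  pres <- seq(0, 20, by = 0.25)
  lab <- vapply(pres, function(pv) score_trial(pv, 30, thr, p), character(1))
  first_disc <- match("discarded", lab)
  expect_true(all(lab[first_disc:length(lab)] == "discarded"))
})

test_that("session threshold is mean plus one population SD", {
  expect_equal(session_threshold(c(1, 1, 1, 1)), 1)
  expect_equal(session_threshold(c(0, 2)), 1 + 1)  # population SD of {0,2} = 1
  v <- stats::runif(20)
  expect_equal(session_threshold(v + 5), session_threshold(v) + 5)
  expect_error(session_threshold(1), "at least 2")
})

test_that("block CR stats compute percentages over valid trials", {
  scores <- data.frame(
    trial_index = 1:60, block_id = rep(1:2, each = 30),
    pre_cs_value = 1, cr_value = 1,
    label = c(rep("CR", 21), rep("noCR", 9),
              rep("discarded", 30)),
    pre_cr_label = "noCR")
  expect_warning(st <- block_cr_stats(scores), "zero valid")
  expect_equal(st$cr_percent[st$block_id == 1], 70)
  expect_equal(st$n_valid, c(30, 0))
  expect_true(is.na(st$cr_percent[st$block_id == 2]))
})

test_that("labels are invariant to rescaling the whole trace", {
  sched <- small_schedule(3, 4, emg_rate = 2000)
  sess <- fixture("emg_session", simulate_session(
    sched, population_config(n_cells = 2),
    cr_behavior_config(cr_probability = 0.5), seed = 60))
  s1 <- score_session(sess$emg, sess$trials, sess$schedule)
  scaled <- emg_trace(sess$emg$samples * 7.3, sess$emg$rate_hz)
  s2 <- score_session(scaled, sess$trials, sess$schedule)
  expect_identical(s1$scores$label, s2$scores$label)
  expect_equal(s2$threshold, s1$threshold * 7.3)
})

test_that("detector recovers ground-truth CRs from the generator", {
  sched <- small_schedule(5, 50, emg_rate = 2000)
  sess <- fixture("cr_session", simulate_session(
    sched, population_config(n_cells = 2),
    cr_behavior_config(cr_probability = 0.8, cr_burst_amplitude = 5),
    seed = 61))
  sc <- score_session(sess$emg, sess$trials, sess$schedule)
  truth <- sess$truth$cr
  det <- sc$scores$label == "CR"
  valid <- sc$scores$label != "discarded"
  expect_gte(sum(det & truth) / sum(truth & valid), 0.95)  # sensitivity
  expect_lte(mean(det[!truth & valid]), 0.15)              # false positives
  # recovered CR% tracks the realised ground truth within 5 points on the
  # 50-trial paired blocks
  st <- block_cr_stats(sc$scores)
  truth_pct <- 100 * tapply(truth, sess$trials$block_id, mean)
  paired_ids <- sess$schedule$blocks$block_id[sess$schedule$blocks$paired]
  k <- st$block_id %in% paired_ids
  expect_lt(max(abs(st$cr_percent[k] -
                      truth_pct[as.character(st$block_id[k])])), 5 + 1e-9)
})
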