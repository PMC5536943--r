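test_that("pearson_r matches hand-computed values and rejects degenerates", {
  x <- stats::runif(10)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("block-pair comparison emits 2 r values per category per repeat", {
  sess <- small_session()
  cfg <- quick_config()
  bp <- block_pair_comparison(sess, "trial", cfg, n_repeats = 5, seed = 30)
  counts <- table(bp$category)
  expect_setequal(names(counts),
                  c("All", "Environment", "Modality", "None", "Relationship"))
  expect_true(all(counts == 10))  # 2 pairs x 5 repeats
  expect_true(all(bp$r >= -1 & bp$r <= 1))
  bp_iti <- block_pair_comparison(sess, "iti", cfg, n_repeats = 2, seed = 31)
  expect_true(all(table(bp_iti$category) == 4))
})

test_that("modality-only coding orders the comparison categories", {
  sess <- fixture("mod_session",
                  single_category_session("M", n_cells = 30,
                                          effect_size = 2, seed = 40))
  bp <- block_pair_comparison(sess, "iti", quick_config(), n_repeats = 10,
                              seed = 41)
  m <- tapply(bp$r, bp$category, mean)
  expect_lt(m[["Modality"]], m[["Environment"]])
  expect_lt(m[["Modality"]], m[["None"]])
  expect_lt(m[["All"]], m[["Environment"]])
})

test_that("ITI correlation matrix is symmetric with unit diagonal", {
  sess <- small_session()
  m <- iti_correlation_matrix(sess, n_subsample_cells = 15,
                              config = quick_config(), seed = 50)
  expect_equal(dim(m), rep(nrow(sess$trials), 2))
  expect_equal(unname(diag(m)), rep(1, nrow(m)))
  expect_equal(m, t(m))
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
})

test_that("environment-keyed tonic rates produce a box-structured matrix", {
  sess <- fixture("env_session",
                  single_category_session("E", n_cells = 30,
                                          effect_size = 2, seed = 51,
                                          schedule = small_schedule(20, 20)))
  m <- iti_correlation_matrix(sess, n_subsample_cells = 30,
                              config = quick_config(), seed = 52)
  box <- trial_block_attr <- sess$schedule$blocks$box[
    match(sess$trials$block_id, sess$schedule$blocks$block_id)]
  same_box <- outer(box, box, "==")
  off_diag <- !diag(nrow(m))
  expect_gt(mean(m[same_box & off_diag]), mean(m[!same_box]))
})

test_that("similarity scores drop at environment but not contingency shifts", {
  sess <- fixture("env_session",
                  single_category_session("E", n_cells = 30,
                                          effect_size = 2, seed = 51,
                                          schedule = small_schedule(20, 20)))
  sc <- similarity_scores(sess, quick_config(), n_repeats = 4,
                          n_subsample_cells = 30, seed = 60)
  expect_equal(nrow(sc), 4 * 5)
  agg <- stats::aggregate(cbind(within, between) ~ type, sc, mean)
  e_rows <- agg$type %in% c("E", "E+M")
  expect_true(all(agg$within[e_rows] - agg$between[e_rows] > 0.1))
  r_row <- agg$type == "R"
  expect_lt(abs(agg$within[r_row] - agg$between[r_row]), 0.1)
})

test_that("normalisation is idempotent", {
  x <- matrix(stats::runif(40), 10, 4)
  n1 <- lecensemble:::max_normalise_cols(x)
  expect_equal(lecensemble:::max_normalise_cols(n1), n1)
  expect_equal(unname(apply(n1, 2, max)), rep(1, 4))
})

test_that("session-sliding trend detects a growing modality step", {
  sched <- small_schedule(20, 20)
  n_per_sess <- 6
  n_sess <- 5
  n <- n_per_sess * n_sess
  set.seed(70)
  r0 <- stats::runif(n, 1, 3)
  baseline <- matrix(r0, n, 6)
  # modality step grows with session order: later cells differentiate the
  # visual blocks (5, 6) more strongly; each cell prefers one modality
  sess_idx <- rep(seq_len(n_sess), each = n_per_sess)
  step <- 0.5 + 2.5 * (sess_idx - 1) / (n_sess - 1)
  prefers_visual <- rep_len(c(TRUE, FALSE), n)
  baseline[prefers_visual, 5:6] <-
    baseline[prefers_visual, 5:6] * (1 + step[prefers_visual])
  baseline[!prefers_visual, 1:4] <-
    baseline[!prefers_visual, 1:4] * (1 + step[!prefers_visual])
  sess <- manual_session(baseline, schedule = sched,
                         session_ids = sprintf("s%02d", sess_idx), seed = 71)
  tr <- session_sliding_trend(sess, quick_config(), window_cells = 12,
                              step_cells = 6)
  em <- tr$trend[tr$trend$type == "E+M", ]
  expect_gt(em$slope, 0)
  expect_gt(em$r_squared, 0.5)
  expect_true(all(tr$trend$r_squared >= 0 & tr$trend$r_squared <= 1))
})
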