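# independent brute-force oracles for the permutation nulls
enumerate_di_null <- function(x, na) {
  n <- length(x)
  idx <- utils::combn(n, na)
  apply(idx, 2, function(k) {
    m1 <- mean(x[k]); m2 <- mean(x[-k])
    abs(m1 - m2) / (m1 + m2)
  })
}

enumerate_signflip_null <- function(d) {
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(d))))
  abs(as.numeric(signs %*% d)) / length(d)
}

test_that("window rates use half-open windows", {
  expect_equal(window_rate(c(0.1, 0.2, 0.5), 0, 0.6), 5)
  expect_equal(window_rate(numeric(0), 0, 1), 0)
  expect_equal(window_rate(c(0.0, 0.3, 0.6), 0, 0.6), 2 / 0.6)  # end excluded
  expect_error(window_rate(1, 2, 2), "window")
})

test_that("differential index is bounded, symmetric and scale invariant", {
  expect_equal(differential_index(3, 1), 0.5)
  expect_equal(differential_index(5, 0), 1)
  expect_true(is.na(differential_index(0, 0)))
  for (i in 1:20) {
    a <- stats::runif(1, 0, 10); b <- stats::runif(1, 0, 10)
    k <- stats::runif(1, 0.1, 100)
    expect_equal(differential_index(a, b), differential_index(b, a))
    expect_equal(differential_index(k * a, k * b), differential_index(a, b))
    expect_equal(differential_index(a, a), 0)
    expect_true(differential_index(a, b) >= 0 && differential_index(a, b) <= 1)
  }
  expect_error(differential_index(-1, 2), "non-negative")
})

test_that("CS-responsiveness test behaves at the extremes", {
  r <- cs_responsive_test(rep(2, 10), rep(2, 10), n_perm = 500, seed = 1)
  expect_equal(r$statistic, 0)
  expect_false(r$significant)
  # large separation: 10 Hz vs 1 Hz Poisson over 50 trials
  set.seed(2)
  tr <- rpois(50, 10 * 0.6) / 0.6
  pre <- rpois(50, 1 * 1) / 1
  expect_true(cs_responsive_test(tr, pre, n_perm = 1000, seed = 3)$significant)
  expect_warning(cs_responsive_test(tr, pre, n_perm = 10, seed = 4),
                 "resolution")
})

test_that("permutation nulls match exhaustive enumeration at small n", {
  set.seed(5)
  x <- rpois(10, 3) + stats::runif(10) * 1e-6  # break ties
  a <- x[1:5]; b <- x[6:10]
  pkg <- shuffle_corrected_di(a, b, alpha = 0.05, exact = TRUE)
  null <- enumerate_di_null(x, 5)
  k <- ceiling(0.95 * length(null))
  expect_equal(pkg$null_quantile, sort(null)[k])
  expect_equal(pkg$di_raw, abs(mean(a) - mean(b)) / (mean(a) + mean(b)))
  expect_equal(pkg$di_corrected, pkg$di_raw - sort(null)[k])

  # compare against the independent sign-flip enumeration
  tr <- rnorm(8); pre <- rep(0, 8)
  pkg3 <- cs_responsive_test(tr, pre, exact = TRUE)
  null3 <- enumerate_signflip_null(tr - pre)
  expect_equal(pkg3$null_quantile,
               sort(null3)[ceiling(0.95 * length(null3))])
  # Monte Carlo quantile converges to the exact one
  mc <- cs_responsive_test(tr, pre, n_perm = 20000, seed = 6)
  expect_lt(abs(mc$null_quantile - pkg3$null_quantile),
            0.1 * max(pkg3$null_quantile, 0.05))
})

test_that("shuffle-corrected DI flags strong contrasts and not null ones", {
  set.seed(7)
  a <- rpois(20, 10 * 0.6) / 0.6
  b <- rpois(50, 1 * 0.6) / 0.6
  r <- shuffle_corrected_di(a, b, n_shuffles = 1000, seed = 8)
  expect_true(r$selective)
  expect_true(r$di_corrected <= r$di_raw)
  same <- rep(c(1, 2, 3), 5)
  r0 <- shuffle_corrected_di(same, same, n_shuffles = 500, seed = 9)
  expect_false(r0$selective)
  rz <- shuffle_corrected_di(rep(0, 10), rep(0, 10))
  expect_true(is.na(rz$selective))
  expect_true(is.na(rz$di_raw))
})

test_that("classification recovers generator ground truth per category", {
  cfg <- quick_config(n_perm = 499)
  for (cat in c("E", "R+M+E", "Non-S")) {
    sess <- fixture(paste0("cat_", cat),
                    single_category_session(cat, n_cells = 12,
                                            effect_size = 1.5,
                                            seed = 70 + nchar(cat)))
    tab <- selectivity_table(sess, cfg, periods = "iti")
    hits <- mean(tab$category == cat)
    if (cat == "Non-S") expect_gte(hits, 0.5) else expect_gte(hits, 0.75)
  }
})

test_that("bin partitions are consistent with the full-window test", {
  sess <- small_session()
  cfg <- quick_config(n_perm = 199)
  ids <- sess$spikes$units$unit_id[1:6]
  sweep <- bin_size_sweep(sess, partitions = c(1, 4), config = cfg,
                          units = ids, seed = 80)
  expect_setequal(unique(sweep$cells$partition), c(1, 4))
  expect_equal(sum(sweep$cells$partition == 1), 6)
  expect_equal(sum(sweep$cells$partition == 4), 24)
  # the 1-bin partition is the full 9 s window classification
  full <- vapply(ids, function(u) {
    rates <- trial_rates(sess$spikes$spikes[[u]], sess$trials, "iti")
    classify_selectivity(rates, sess$trials, sess$schedule,
                         n_shuffles = 199, seed = 81)$category != "Non-S"
  }, logical(1))
  p1 <- sweep$cells[sweep$cells$partition == 1, ]
  # same criterion applied to the same rates: proportions must agree closely
  expect_lt(abs(mean(p1$selective) - mean(full)), 0.34)
  expect_true(all(sweep$summary$prop_selective >= 0 &
                    sweep$summary$prop_selective <= 1))
})

test_that("CR-firing correlation requires 20 trials of each type", {
  sess <- small_session()
  labels <- rep("noCR", nrow(sess$trials))
  # block 2 has 20 paired trials: 19 CR -> not computable
  in_b2 <- sess$trials$block_id == 2
  labels[which(in_b2)[1:19]] <- "CR"
  cfg <- quick_config(n_perm = 99)
  res <- cr_correlation(sess, labels, cfg)
  expect_true(all(!res$computable[res$block_id == 2]))
  # exactly 20 CR and 20 non-CR -> computable, DI defined
  sess2 <- single_category_session("Non-S", n_cells = 3, seed = 90,
                                   schedule = small_schedule(5, 40))
  labels2 <- rep("noCR", nrow(sess2$trials))
  in_b2 <- which(sess2$trials$block_id == 2)
  labels2[in_b2[1:20]] <- "CR"
  res2 <- cr_correlation(sess2, labels2, cfg)
  b2 <- res2[res2$block_id == 2, ]
  expect_true(all(b2$computable))
  expect_true(all(is.finite(b2$di_raw) | is.na(b2$di_raw)))
  # firing independent of CR label: selective fraction near alpha
  expect_lte(mean(b2$selective, na.rm = TRUE), 0.35)
})
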