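#' Firing rate in a half-open window
#'
#' Spike count in `[start, end)` divided by the window length. A spike
#' exactly at `end` is excluded.
#'
#' @param spikes sorted spike times.
#' @param start,end window bounds, s (`end > start`).
#' @return rate in Hz.
#' @export
window_rate <- function(spikes, start, end) {
  stop_if_not(end > start, "zero-length or inverted window")
  count_in_windows(spikes, start, end) / (end - start)
}

#' Per-trial firing rates for an analysis period
#'
#' @param spikes sorted spike times of one unit.
#' @param trials trial table.
#' @param period `"trial"` (CS onset to US onset, 600 ms), `"pre_cs"` (1 s
#'   before CS onset) or `"iti"` (the 9 s tonic window before CS onset, or a
#'   sub-bin of it).
#' @param iti_window_s length of the tonic window (9 s).
#' @param bin optional `c(k, m)`: use the k-th of m equal sub-bins of the
#'   tonic window instead of the whole window.
#' @param offsets optional per-trial start offsets (s, within the tonic
#'   window) for a fixed-length 600 ms bin; used by the ensemble analyses.
#' @return numeric vector of rates (Hz), one per trial.
#' @export
trial_rates <- function(spikes, trials, period = c("trial", "pre_cs", "iti"),
                        iti_window_s = 9, bin = NULL, offsets = NULL) {
  period <- match.arg(period)
  cs <- trials$cs_onset_s
  if (period == "trial") {
    starts <- cs; ends <- cs + 0.6
  } else if (period == "pre_cs") {
    starts <- cs - 1; ends <- cs
  } else {
    starts <- cs - iti_window_s; ends <- cs
    if (!is.null(bin)) {
      w <- iti_window_s / bin[2]
      starts <- cs - iti_window_s + (bin[1] - 1) * w
      ends <- starts + w
    }
    if (!is.null(offsets)) {
      starts <- cs - iti_window_s + offsets
      ends <- starts + 0.6
    }
  }
  count_in_windows(spikes, starts, ends) / (ends - starts)
}

#' CS-responsiveness permutation test
#'
#' Tests whether the mean trial-window rate differs from the mean pre-CS
#' rate. The statistic is the absolute difference of means; the null is
#' built by randomly re-assigning, per trial, the two rates to the two
#' period labels (a within-trial swap). The test is significant when the
#' observed statistic exceeds the upper `1 - alpha` order-statistic quantile
#' of the null.
#'
#' @param trial_period_rates,pre_cs_rates paired per-trial rates (equal
#'   length >= 2).
#' @param n_perm number of random re-assignments (1000).
#' @param alpha significance level (0.05).
#' @param exact enumerate all `2^n` swap patterns instead of sampling
#'   (requires `n <= 20`); the Monte Carlo null converges to this.
#' @param seed optional integer seed.
#' @return list with `statistic`, `null_quantile`, `p_value` (add-one
#'   estimate) and `significant`.
#' @export
cs_responsive_test <- function(trial_period_rates, pre_cs_rates,
                               n_perm = 1000, alpha = 0.05, exact = FALSE,
                               seed = NULL) {
  n <- length(trial_period_rates)
  stop_if_not(n == length(pre_cs_rates), "rate vectors must be paired")
  stop_if_not(n >= 2, "need at least 2 trials")
  if (!exact && n_perm < 1 / alpha)
    warning("n_perm below 1/alpha: permutation resolution insufficient")
  d <- trial_period_rates - pre_cs_rates
  obs <- abs(mean(d))
  with_seed(seed, {
    if (exact) {
      stop_if_not(n <= 16, "exact enumeration limited to 16 trials")
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      null <- abs(as.numeric(signs %*% d)) / n
    } else {
      s <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
      null <- abs(colMeans(s * d))
    }
    q <- null_quantile(null, alpha)
    list(statistic = obs, null_quantile = q,
         p_value = (1 + sum(null >= obs)) / (1 + length(null)),
         significant = obs > q)
  })
}

#' Differential index between two mean rates
#'
#' `|Fr1 - Fr2| / (Fr1 + Fr2)`, bounded in `[0, 1]`. Undefined (NA) when
#' both rates are zero; callers exclude such cells from the contrast.
#'
#' @param fr1,fr2 non-negative mean firing rates.
#' @return the absolute differential index.
#' @export
differential_index <- function(fr1, fr2) {
  stop_if_not(all(fr1 >= 0) && all(fr2 >= 0), "rates must be non-negative")
  ifelse(fr1 + fr2 == 0, NA_real_, abs(fr1 - fr2) / (fr1 + fr2))
}

#' Shuffle-corrected differential index
#'
#' The chance-level index is estimated as the upper `1 - alpha` quantile
#' (the `ceil((1 - alpha) * n)`-th order statistic) of the differential
#' indices recomputed under random permutations of the trial labels, and
#' subtracted from the observed index. A unit is selective for the contrast
#' when the corrected index is greater than zero.
#'
#' @param rates_a,rates_b per-trial rates in the two conditions (non-empty).
#' @param n_shuffles label permutations (1000).
#' @param alpha significance level (0.05).
#' @param exact enumerate all distinct label assignments
#'   (`choose(nA + nB, nA)` subsets, capped at 2e5) instead of sampling.
#' @param seed optional integer seed.
#' @return list with `di_raw`, `di_corrected`, `selective`,
#'   `null_quantile`; all-`NA` (with `selective = NA`) when every rate is
#'   zero, in which case the cell is excluded from the contrast.
#' @export
shuffle_corrected_di <- function(rates_a, rates_b, n_shuffles = 1000,
                                 alpha = 0.05, exact = FALSE, seed = NULL) {
  na <- length(rates_a); nb <- length(rates_b)
  stop_if_not(na >= 1 && nb >= 1, "both conditions must be non-empty")
  x <- c(rates_a, rates_b)
  if (sum(x) == 0)
    return(list(di_raw = NA_real_, di_corrected = NA_real_,
                selective = NA, null_quantile = NA_real_))
  di_raw <- differential_index(mean(rates_a), mean(rates_b))
  n <- na + nb
  tot <- sum(x)
  with_seed(seed, {
    if (exact) {
      stop_if_not(choose(n, na) <= 2e5,
                  "exact enumeration too large; use Monte Carlo shuffles")
      idx <- utils::combn(n, na)
      sa <- colSums(matrix(x[idx], nrow = na))
    } else {
      sa <- vapply(seq_len(n_shuffles),
                   function(i) sum(x[sample.int(n, na)]), numeric(1))
    }
    ma <- sa / na
    mb <- (tot - sa) / nb
    null <- abs(ma - mb) / (ma + mb)
    q <- null_quantile(null, alpha)
    list(di_raw = di_raw, di_corrected = di_raw - q,
         selective = (di_raw - q) > 0, null_quantile = q)
  })
}

#' Trial sets defining the three task-variable contrasts
#'
#' Derives from the schedule which blocks enter each contrast: Relationship
#' (each CS-alone block against the paired block with the same CS and box),
#' Modality (pooled trials of the two CS types in the box that saw both),
#' and Environment (pooled trials of the CS modality presented in both
#' boxes).
#'
#' @param schedule a [session_schedule()].
#' @return list with `R` (list of `c(alone, paired)` block-id pairs), `M`
#'   and `E` (each a list of two block-id vectors), entries `NULL` when the
#'   schedule does not support the contrast.
#' @export
selectivity_contrasts <- function(schedule) {
  bl <- schedule$blocks
  r_pairs <- list()
  for (m in unique(bl$cs_modality)) for (bx in unique(bl$box)) {
    alone <- bl$block_id[bl$cs_modality == m & bl$box == bx & !bl$paired]
    paired <- bl$block_id[bl$cs_modality == m & bl$box == bx & bl$paired]
    if (length(alone) == 1 && length(paired) == 1)
      r_pairs[[length(r_pairs) + 1]] <- c(alone = alone, paired = paired)
  }
  m_contrast <- NULL
  for (bx in unique(bl$box)) {
    mods <- unique(bl$cs_modality[bl$box == bx])
    if (length(mods) == 2) {
      m_contrast <- list(
        a = bl$block_id[bl$box == bx & bl$cs_modality == "auditory"],
        b = bl$block_id[bl$box == bx & bl$cs_modality == "visual"])
      break
    }
  }
  e_contrast <- NULL
  for (m in unique(bl$cs_modality)) {
    boxes <- unique(bl$box[bl$cs_modality == m])
    if (length(boxes) == 2) {
      e_contrast <- list(a = bl$block_id[bl$cs_modality == m & bl$box == 1],
                         b = bl$block_id[bl$cs_modality == m & bl$box == 2])
      break
    }
  }
  list(R = if (length(r_pairs)) r_pairs else NULL,
       M = m_contrast, E = e_contrast)
}

#' Classify one unit's selectivity for the three task variables
#'
#' Runs the shuffle-corrected differential-index test on each Relationship
#' block pair and on the pooled Modality and Environment contrasts, and
#' combines the raised flags into one of the eight category labels
#' ([selectivity_categories()]). The Relationship flag is raised when any of
#' the alone/paired pairs is selective.
#'
#' @param rates per-trial rates of the unit for the analysis period (e.g.
#'   from [trial_rates()]).
#' @param trials trial table aligned with `rates`.
#' @param schedule session schedule.
#' @param n_shuffles,alpha permutation-test parameters.
#' @param seed optional integer seed.
#' @return list with `category`, `flags` (named logical R/M/E), and
#'   `contrasts`, a data.frame of per-contrast `di_raw`, `di_corrected`,
#'   `selective`.
#' @export
classify_selectivity <- function(rates, trials, schedule, n_shuffles = 1000,
                                 alpha = 0.05, seed = NULL) {
  ctr <- selectivity_contrasts(schedule)
  rows <- list()
  run <- function(blocks_a, blocks_b, name) {
    a <- rates[trials$block_id %in% blocks_a]
    b <- rates[trials$block_id %in% blocks_b]
    res <- shuffle_corrected_di(a, b, n_shuffles = n_shuffles, alpha = alpha)
    data.frame(contrast = name, di_raw = res$di_raw,
               di_corrected = res$di_corrected,
               selective = res$selective, stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    if (!is.null(ctr$R))
      for (i in seq_along(ctr$R))
        rows[[length(rows) + 1]] <-
          run(ctr$R[[i]][["alone"]], ctr$R[[i]][["paired"]],
              paste0("R", i))
    if (!is.null(ctr$M))
      rows[[length(rows) + 1]] <- run(ctr$M$a, ctr$M$b, "M")
    if (!is.null(ctr$E))
      rows[[length(rows) + 1]] <- run(ctr$E$a, ctr$E$b, "E")
    res <- do.call(rbind, rows)
    sel <- function(pat) {
      v <- res$selective[grepl(pat, res$contrast)]
      if (all(is.na(v))) NA else any(v, na.rm = TRUE)
    }
    flags <- c(R = sel("^R"), M = sel("^M$"), E = sel("^E$"))
    raised <- names(flags)[!is.na(flags) & flags]
    category <- if (length(raised) == 0) "Non-S" else
      paste(raised, collapse = "+")
    list(category = category, flags = flags, contrasts = res)
  })
}

#' Per-unit selectivity table for a whole session
#'
#' For every unit: the CS-responsiveness permutation test (trial window vs
#' 1 s pre-CS, significant in at least one block makes the unit
#' "CS-responding"), and the 8-way selectivity category for both the trial
#' period and the 9 s ITI period. This is the per-unit table from which the
#' category count breakdowns are tabulated.
#'
#' @param session a session list (`spikes`, `trials`, `schedule`, ...).
#' @param config an [analysis_config()].
#' @param periods which periods to classify (default both).
#' @param seed optional integer seed (defaults to the config's selectivity
#'   sub-stream).
#' @return data.frame with one row per unit x period.
#' @export
selectivity_table <- function(session, config = analysis_config(),
                              periods = c("trial", "iti"), seed = NULL) {
  if (is.null(seed)) seed <- stage_seed(config$rng_seed, "selectivity")
  spikes <- session$spikes; trials <- session$trials
  schedule <- session$schedule
  rows <- list()
  for (i in seq_len(n_units(spikes))) {
    uid <- spikes$units$unit_id[i]
    st <- spikes$spikes[[uid]]
    tr_rates <- trial_rates(st, trials, "trial")
    pre_rates <- trial_rates(st, trials, "pre_cs")
    resp_block <- with_seed(seed + i, {
      vapply(schedule$blocks$block_id, function(b) {
        k <- trials$block_id == b
        cs_responsive_test(tr_rates[k], pre_rates[k],
                           n_perm = config$n_permutations,
                           alpha = config$alpha)$significant
      }, logical(1))
    })
    responsive <- any(resp_block)
    for (p in periods) {
      rates <- if (p == "trial") tr_rates else
        trial_rates(st, trials, "iti", iti_window_s = config$iti_window_s)
      cl <- classify_selectivity(rates, trials, schedule,
                                 n_shuffles = config$n_permutations,
                                 alpha = config$alpha,
                                 seed = seed + 1000L + i)
      di <- function(pat, col) {
        v <- cl$contrasts[[col]][grepl(pat, cl$contrasts$contrast)]
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = uid, layer = spikes$units$layer[i], period = p,
        responsive = responsive, category = cl$category,
        flag_R = cl$flags[["R"]], flag_M = cl$flags[["M"]],
        flag_E = cl$flags[["E"]],
        di_corr_R = di("^R", "di_corrected"),
        di_corr_M = di("^M$", "di_corrected"),
        di_corr_E = di("^E$", "di_corrected"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Category count table (overall and by layer)
#'
#' Tabulates a [selectivity_table()] period slice into counts and
#' percentages per category, overall and split by cortical layer.
#'
#' @param sel_table output of [selectivity_table()].
#' @param period which period slice to tabulate.
#' @param responding optional filter: `TRUE` for CS-responding units only,
#'   `FALSE` for non-responding only, `NULL` for all.
#' @return data.frame of counts with one row per grouping.
#' @export
category_counts <- function(sel_table, period = "trial", responding = NULL) {
  s <- sel_table[sel_table$period == period, ]
  if (!is.null(responding)) s <- s[s$responsive == responding, ]
  groups <- c(list(Overall = s),
              split(s, paste0(s$layer, " layers")))
  out <- lapply(names(groups), function(g) {
    ss <- groups[[g]]
    counts <- table(factor(ss$category, levels = selectivity_categories()))
    data.frame(group = g, n = nrow(ss), t(as.matrix(counts)),
               check.names = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Selectivity as a function of ITI bin size
#'
#' Re-runs the full classification on tonic rates computed in sub-bins of
#' the 9 s ITI window: one 9 s bin, four 2.25 s bins, or eight 1.125 s bins.
#' The per-partition proportion of selective cells is the mean over that
#' partition's bins of the fraction of cells selective in the bin (so the
#' 1-bin partition equals the full-window classification).
#'
#' @param session a session list.
#' @param partitions numbers of bins (default `c(1, 4, 8)`).
#' @param config an [analysis_config()].
#' @param units optional subset of unit ids.
#' @param seed optional integer seed.
#' @return list with `cells` (long data.frame: partition, bin, unit_id,
#'   category, selective) and `summary` (per-partition proportion
#'   selective).
#' @export
bin_size_sweep <- function(session, partitions = c(1, 4, 8),
                           config = analysis_config(), units = NULL,
                           seed = NULL) {
  if (is.null(seed)) seed <- stage_seed(config$rng_seed, "selectivity") + 5000L
  spikes <- session$spikes; trials <- session$trials
  schedule <- session$schedule
  ids <- if (is.null(units)) spikes$units$unit_id else units
  rows <- list()
  k <- 0
  for (m in partitions) for (b in seq_len(m)) for (uid in ids) {
    k <- k + 1
    st <- spikes$spikes[[uid]]
    rates <- trial_rates(st, trials, "iti",
                         iti_window_s = config$iti_window_s, bin = c(b, m))
    cl <- classify_selectivity(rates, trials, schedule,
                               n_shuffles = config$n_permutations,
                               alpha = config$alpha, seed = seed + k)
    rows[[k]] <- data.frame(partition = m, bin = b, unit_id = uid,
                            category = cl$category,
                            selective = cl$category != "Non-S",
                            stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, rows)
  per_bin <- stats::aggregate(selective ~ partition + bin, cells, mean)
  summary <- stats::aggregate(selective ~ partition, per_bin, mean)
  names(summary)[2] <- "prop_selective"
  list(cells = cells, summary = summary)
}

#' Trial-by-trial correlation of firing with CR expression
#'
#' For each paired block in which the animal expressed the CR on at least 20
#' trials and withheld it on at least 20, 20 trials of each type are
#' randomly sampled and the shuffle-corrected differential index computed
#' between CR and non-CR trials, separately for the trial window and the
#' ITI window.
#'
#' @param session a session list.
#' @param cr_labels per-trial labels from [score_session()] (`"CR"`,
#'   `"noCR"`, `"discarded"`), aligned with `session$trials`.
#' @param config an [analysis_config()].
#' @param seed optional integer seed.
#' @return data.frame with one row per unit x paired block x period;
#'   `computable = FALSE` rows mark insufficient trial counts.
#' @export
cr_correlation <- function(session, cr_labels, config = analysis_config(),
                           seed = NULL) {
  if (is.null(seed)) seed <- stage_seed(config$rng_seed, "selectivity") + 9000L
  spikes <- session$spikes; trials <- session$trials
  schedule <- session$schedule
  paired_blocks <- schedule$blocks$block_id[schedule$blocks$paired]
  rows <- list()
  k <- 0
  for (b in paired_blocks) {
    in_block <- trials$block_id == b
    cr_idx <- which(in_block & cr_labels == "CR")
    non_idx <- which(in_block & cr_labels == "noCR")
    enough <- length(cr_idx) >= 20 && length(non_idx) >= 20
    for (i in seq_len(n_units(spikes))) {
      uid <- spikes$units$unit_id[i]
      for (p in c("trial", "iti")) {
        k <- k + 1
        if (!enough) {
          rows[[k]] <- data.frame(unit_id = uid, block_id = b, period = p,
                                  n_cr = length(cr_idx),
                                  n_noncr = length(non_idx),
                                  di_raw = NA_real_, di_corrected = NA_real_,
                                  selective = NA, computable = FALSE)
          next
        }
        res <- with_seed(seed + k, {
          sa <- sample(cr_idx, 20)
          sb <- sample(non_idx, 20)
          rates <- trial_rates(spikes$spikes[[uid]], trials, p,
                               iti_window_s = config$iti_window_s)
          shuffle_corrected_di(rates[sa], rates[sb],
                               n_shuffles = config$n_permutations,
                               alpha = config$alpha)
        })
        rows[[k]] <- data.frame(unit_id = uid, block_id = b, period = p,
                                n_cr = length(cr_idx),
                                n_noncr = length(non_idx),
                                di_raw = res$di_raw,
                                di_corrected = res$di_corrected,
                                selective = res$selective, computable = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
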