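#' Pearson product-moment correlation
#'
#' Thin validated wrapper: requires equal length of at least 3 and
#' non-constant vectors (a constant state vector has no defined
#' correlation).
#'
#' @param x,y numeric vectors.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stop_if_not(length(x) == length(y), "vectors must have equal length")
  stop_if_not(length(x) >= 3, "need at least 3 elements")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for a constant vector")
  stats::cor(x, y)
}

# cells x trials rate matrix for one analysis period; offsets (per trial, s)
# select a random 600 ms bin within the tonic window
rate_matrix <- function(session, period = c("trial", "iti"),
                        iti_window_s = 9, offsets = NULL, units = NULL) {
  period <- match.arg(period)
  spikes <- session$spikes
  ids <- if (is.null(units)) spikes$units$unit_id else units
  m <- t(vapply(ids, function(u) {
    trial_rates(spikes$spikes[[u]], session$trials, period,
                iti_window_s = iti_window_s, offsets = offsets)
  }, numeric(nrow(session$trials))))
  rownames(m) <- ids
  m
}

# look up the block id for a (modality, box, paired) condition
condition_block <- function(schedule, modality, box, paired) {
  bl <- schedule$blocks
  id <- bl$block_id[bl$cs_modality == modality & bl$box == box &
                      bl$paired == paired]
  stop_if_not(length(id) == 1,
              "schedule lacks the six-condition block structure")
  id
}

#' Block-pair state-vector correlations
#'
#' Per repeat: ten trials are randomly drawn from each block and their rate
#' vectors averaged into one state vector per block; each cell is then
#' normalised by its maximum across the six averaged vectors (all-zero
#' cells dropped for that repeat); Pearson r is computed for the block
#' pairs of each comparison category. Categories: Modality (auditory vs
#' visual CS in the shared box, alone and paired pairs), Environment (same
#' CS across boxes), Relationship (alone vs paired with the same CS and
#' box), None (odd- vs even-numbered trials within the same paired block,
#' the upper reference) and All (two block pairs sharing no task variable,
#' the lower reference). With the default 20 repeats each category yields
#' 40 r values (2 pairs x 20 repeats).
#'
#' For `period = "iti"` every trial contributes the rate in one 600 ms bin
#' drawn uniformly from its 9 s tonic window, re-drawn on every repeat.
#'
#' @param session a session list.
#' @param period `"trial"` or `"iti"`.
#' @param config an [analysis_config()].
#' @param n_repeats repeats (default from config, 20).
#' @param seed optional integer seed.
#' @return data.frame with columns `category`, `repeat_idx`, `pair`, `r`.
#' @export
block_pair_comparison <- function(session, period = c("trial", "iti"),
                                  config = analysis_config(),
                                  n_repeats = config$n_repeats, seed = NULL) {
  period <- match.arg(period)
  if (is.null(seed)) seed <- stage_seed(config$rng_seed, "ensemble")
  schedule <- session$schedule
  trials <- session$trials
  blk <- function(m, bx, p) condition_block(schedule, m, bx, p)
  a1a <- blk("auditory", 1, FALSE); a1p <- blk("auditory", 1, TRUE)
  a2a <- blk("auditory", 2, FALSE); a2p <- blk("auditory", 2, TRUE)
  v1a <- blk("visual", 1, FALSE);   v1p <- blk("visual", 1, TRUE)
  pairs <- list(
    Modality = list(c(a1a, v1a), c(a1p, v1p)),
    Environment = list(c(a1a, a2a), c(a1p, a2p)),
    Relationship = list(c(a1a, a1p), c(v1a, v1p)),
    All = list(c(a2a, v1p), c(a2p, v1a)))
  none_blocks <- c(a1p, v1p)
  counts <- table(trials$block_id)
  stop_if_not(all(counts >= 10), "every block needs at least 10 trials")
  stop_if_not(all(counts[as.character(none_blocks)] >= 20),
              "odd/even control blocks need at least 20 trials")
  block_ids <- schedule$blocks$block_id
  with_seed(seed, {
    rows <- list()
    for (rep_i in seq_len(n_repeats)) {
      offs <- if (period == "iti")
        stats::runif(nrow(trials), 0, config$iti_window_s - 0.6) else NULL
      rm <- rate_matrix(session, period, config$iti_window_s, offsets = offs)
      avg <- vapply(block_ids, function(b) {
        idx <- sample(which(trials$block_id == b), 10)
        rowMeans(rm[, idx, drop = FALSE])
      }, numeric(nrow(rm)))
      colnames(avg) <- block_ids
      cell_max <- apply(avg, 1, max)
      keep <- cell_max > 0
      norm <- avg[keep, , drop = FALSE] / cell_max[keep]
      for (cat in names(pairs)) for (pi in seq_along(pairs[[cat]])) {
        pr <- pairs[[cat]][[pi]]
        rows[[length(rows) + 1]] <- data.frame(
          category = cat, repeat_idx = rep_i, pair = pi,
          r = pearson_r(norm[, as.character(pr[1])],
                        norm[, as.character(pr[2])]))
      }
      for (pi in seq_along(none_blocks)) {
        idx <- which(trials$block_id == none_blocks[pi])
        pos <- seq_along(idx)
        odd <- sample(idx[pos %% 2 == 1], 10)
        even <- sample(idx[pos %% 2 == 0], 10)
        v_odd <- rowMeans(rm[keep, odd, drop = FALSE]) / cell_max[keep]
        v_even <- rowMeans(rm[keep, even, drop = FALSE]) / cell_max[keep]
        rows[[length(rows) + 1]] <- data.frame(
          category = "None", repeat_idx = rep_i, pair = pi,
          r = pearson_r(v_odd, v_even))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Trial-by-trial ITI state-vector correlation matrix
#'
#' Subsamples cells (default 100), builds one state vector per inter-trial
#' interval (the mean rate over the 9 s window before CS onset), normalises
#' each cell by its maximum across all ITIs (all-zero cells dropped with a
#' notice), and returns the full pairwise Pearson correlation matrix
#' (symmetric, unit diagonal); 210 x 210 for the default schedule.
#'
#' @param session a session list.
#' @param n_subsample_cells cells drawn without replacement (all cells if
#'   the population is smaller).
#' @param config an [analysis_config()].
#' @param units optional explicit unit ids (overrides subsampling).
#' @param seed optional integer seed.
#' @return correlation matrix with attribute `"units"` (the cell ids used).
#' @export
iti_correlation_matrix <- function(session,
                                   n_subsample_cells = 100,
                                   config = analysis_config(), units = NULL,
                                   seed = NULL) {
  with_seed(seed, {
    all_ids <- session$spikes$units$unit_id
    if (is.null(units)) {
      units <- if (length(all_ids) > n_subsample_cells)
        sample(all_ids, n_subsample_cells) else all_ids
    }
    rm <- rate_matrix(session, "iti", config$iti_window_s, units = units)
    cell_max <- apply(rm, 1, max)
    if (any(cell_max == 0))
      message(sprintf("iti_correlation_matrix: dropping %d silent cell(s)",
                      sum(cell_max == 0)))
    keep <- cell_max > 0
    norm <- rm[keep, , drop = FALSE] / cell_max[keep]
    m <- stats::cor(norm)
    dimnames(m) <- list(session$trials$trial_index, session$trials$trial_index)
    attr(m, "units") <- rownames(rm)[keep]
    m
  })
}

# label a block transition by which task variables change across it
transition_type <- function(schedule, i) {
  bl <- schedule$blocks
  box_chg <- bl$box[i] != bl$box[i + 1]
  mod_chg <- bl$cs_modality[i] != bl$cs_modality[i + 1]
  if (box_chg && mod_chg) "E+M" else if (box_chg) "E"
  else if (mod_chg) "M" else "R"
}

#' Similarity Scores across block transitions
#'
#' For each of the transitions between consecutive blocks, the template is
#' the ITI state vector of the last trial of the earlier block. The
#' Between-block score is the mean correlation of the template with the
#' first 19 ITIs of the following block; the Within-block score is its mean
#' correlation with the 19 ITIs immediately preceding it in its own block
#' (trials 1-19 of a 20-trial block, 31-49 of a 50-trial block). Repeats
#' resubsample the cell population.
#'
#' @param session a session list.
#' @param config an [analysis_config()].
#' @param n_repeats repeats (default from config).
#' @param n_subsample_cells cells per repeat (default from config, 100).
#' @param units optional explicit unit ids (fixes the population; repeats
#'   then differ only if fewer cells than requested are available).
#' @param seed optional integer seed.
#' @return data.frame with `repeat_idx`, `transition` (index), `type`
#'   (`"R"`, `"E"`, `"M"` or `"E+M"`), `within`, `between`.
#' @export
similarity_scores <- function(session, config = analysis_config(),
                              n_repeats = config$n_repeats,
                              n_subsample_cells =
                                config$n_subsample_cells_ensemble,
                              units = NULL, seed = NULL) {
  if (is.null(seed)) seed <- stage_seed(config$rng_seed, "ensemble") + 100L
  schedule <- session$schedule
  trials <- session$trials
  bl <- schedule$blocks
  stop_if_not(all(bl$n_trials >= 20), "every block needs at least 20 trials")
  block_last <- cumsum(bl$n_trials)
  rows <- list()
  for (rep_i in seq_len(n_repeats)) {
    m <- iti_correlation_matrix(session, n_subsample_cells, config,
                                units = units, seed = seed + rep_i)
    for (tr_i in seq_len(nrow(bl) - 1)) {
      tmpl <- block_last[tr_i]
      between_idx <- (tmpl + 1):(tmpl + 19)
      within_idx <- (tmpl - 19):(tmpl - 1)
      rows[[length(rows) + 1]] <- data.frame(
        repeat_idx = rep_i, transition = tr_i,
        type = transition_type(schedule, tr_i),
        within = mean(m[tmpl, within_idx]),
        between = mean(m[tmpl, between_idx]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Session-sliding trend of the ensemble transition
#'
#' Units are sorted by recording session; a sliding window of cells (49 by
#' default, advancing by 10) emulates a block of sessions advancing one
#' session at a time. Per window the Similarity Score analysis is run on
#' exactly the window's cells and the mean `within - between` difference
#' taken per transition type; an ordinary least-squares regression of that
#' difference against window index then tests for growth or decay of the
#' ensemble transition across the recording period.
#'
#' @param session a session list (unit metadata must carry `session_id`).
#' @param config an [analysis_config()].
#' @param window_cells,step_cells sliding-window size and increment.
#' @param seed optional integer seed.
#' @return list with `windows` (per window x type difference series) and
#'   `trend` (per type: `slope`, `r_squared`, `p_value`).
#' @export
session_sliding_trend <- function(session, config = analysis_config(),
                                  window_cells = 49, step_cells = 10,
                                  seed = NULL) {
  units <- session$spikes$units
  ord <- order(units$session_id, units$unit_id)
  ids <- units$unit_id[ord]
  stop_if_not(length(ids) >= window_cells,
              "fewer cells than one sliding window")
  starts <- seq(1, length(ids) - window_cells + 1, by = step_cells)
  rows <- list()
  for (w in seq_along(starts)) {
    sub <- ids[starts[w]:(starts[w] + window_cells - 1)]
    sc <- similarity_scores(session, config, n_repeats = 1,
                            n_subsample_cells = window_cells, units = sub,
                            seed = if (is.null(seed)) NULL else seed + w)
    agg <- stats::aggregate(cbind(within, between) ~ type, sc, mean)
    agg$difference <- agg$within - agg$between
    agg$window <- w
    rows[[w]] <- agg[, c("window", "type", "within", "between", "difference")]
  }
  windows <- do.call(rbind, rows)
  rownames(windows) <- NULL
  trend <- do.call(rbind, lapply(split(windows, windows$type), function(d) {
    if (stats::var(d$difference) == 0) {
      return(data.frame(type = d$type[1], slope = 0, r_squared = 0,
                        p_value = NA_real_))
    }
    fit <- stats::lm(difference ~ window, data = d)
    sm <- summary(fit)
    data.frame(type = d$type[1], slope = stats::coef(fit)[["window"]],
               r_squared = sm$r.squared,
               p_value = sm$coefficients["window", "Pr(>|t|)"])
  }))
  rownames(trend) <- NULL
  list(windows = windows, trend = trend)
}
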