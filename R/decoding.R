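#' Decoding specification
#'
#' @param n_cells_subsampled cells per run (200).
#' @param n_runs independent runs (20).
#' @param n_trials_per_block trials drawn per block for each train/test
#'   resample (20).
#' @param n_train trials per block used for training (10; the remaining
#'   `n_trials_per_block - n_train` are tested).
#' @param n_resamples train/test resamples per run (20), so one run scores
#'   `n_test x blocks x n_resamples` = 1200 predictions under defaults.
#' @param cost_grid,gamma_grid RBF-SVM hyperparameter grids searched before
#'   the resampled evaluation.
#' @param cv_folds stratified cross-validation folds for the grid search.
#' @param period `"trial"` or `"iti"` feature window.
#' @param collapse `"none"` for 6-way block decoding, or a binary collapse:
#'   `"modality"` (auditory vs visual CS), `"environment"` (Box 1 vs 2),
#'   `"relationship"` (CS-alone vs CS-US).
#' @return an object of class `decoding_spec`.
#' @export
decoding_spec <- function(n_cells_subsampled = 200, n_runs = 20,
                          n_trials_per_block = 20, n_train = 10,
                          n_resamples = 20,
                          cost_grid = 2^seq(-5, 15, by = 4),
                          gamma_grid = 2^seq(-15, 3, by = 4),
                          cv_folds = 5,
                          period = c("trial", "iti"),
                          collapse = c("none", "modality", "environment",
                                       "relationship")) {
  stop_if_not(n_train < n_trials_per_block,
              "n_train must leave trials for testing")
  structure(list(n_cells_subsampled = n_cells_subsampled, n_runs = n_runs,
                 n_trials_per_block = n_trials_per_block, n_train = n_train,
                 n_test = n_trials_per_block - n_train,
                 n_resamples = n_resamples, cost_grid = cost_grid,
                 gamma_grid = gamma_grid, cv_folds = cv_folds,
                 period = match.arg(period),
                 collapse = match.arg(collapse)),
            class = "decoding_spec")
}

# class label per trial under a collapse mode
collapse_labels <- function(trials, schedule, collapse) {
  switch(collapse,
         none = factor(trials$block_id),
         modality = factor(trial_block_attr(trials, schedule, "cs_modality")),
         environment = factor(trial_block_attr(trials, schedule, "box")),
         relationship = factor(ifelse(trial_block_attr(trials, schedule,
                                                       "paired"),
                                      "paired", "alone")))
}

# normalise columns (cells) of a trials x cells matrix by their max,
# dropping all-zero cells
max_normalise_cols <- function(x) {
  mx <- apply(x, 2, max)
  x[, mx > 0, drop = FALSE] / rep(mx[mx > 0], each = nrow(x))
}

#' Pseudo-population feature matrix for decoding
#'
#' Draws `n_trials_per_block` trials per block without replacement, builds
#' the trials x cells rate matrix for the requested period, and normalises
#' each cell by its maximum over the drawn trials (all-zero cells dropped).
#'
#' @param session a session list.
#' @param spec a [decoding_spec()].
#' @param config an [analysis_config()].
#' @param units unit ids to use (already subsampled).
#' @param iti_offsets per-trial 600 ms bin offsets for the ITI period.
#' @param seed optional integer seed for the trial draw.
#' @return list with `x` (features), `y` (labels) and `trial_idx`.
#' @export
build_feature_matrix <- function(session, spec, config = analysis_config(),
                                 units, iti_offsets = NULL, seed = NULL) {
  trials <- session$trials
  schedule <- session$schedule
  counts <- table(trials$block_id)
  stop_if_not(all(counts >= spec$n_trials_per_block),
              "insufficient trials per block")
  with_seed(seed, {
    idx <- unlist(lapply(schedule$blocks$block_id, function(b) {
      sample(which(trials$block_id == b), spec$n_trials_per_block)
    }))
    rm <- rate_matrix(session, spec$period, config$iti_window_s,
                      offsets = iti_offsets, units = units)
    x <- max_normalise_cols(t(rm[, idx, drop = FALSE]))
    y <- collapse_labels(trials, schedule, spec$collapse)[idx]
    list(x = x, y = droplevels(y), trial_idx = trials$trial_index[idx])
  })
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Stratified k-fold cross-validation over the cost x gamma grid; returns
#' the grid point with the highest mean CV accuracy, ties broken by the
#' smallest cost then the smallest gamma.
#'
#' @param x feature matrix (samples x features).
#' @param y class labels (factor, at least two classes).
#' @param cost_grid,gamma_grid candidate values.
#' @param cv_folds number of folds.
#' @param seed optional integer seed for fold assignment.
#' @return list with `cost`, `gamma`, `cv_accuracy` and the full `grid`
#'   data.frame.
#' @export
grid_search <- function(x, y, cost_grid = 2^seq(-5, 15, by = 4),
                        gamma_grid = 2^seq(-15, 3, by = 4), cv_folds = 5,
                        seed = NULL) {
  y <- droplevels(as.factor(y))
  stop_if_not(nlevels(y) >= 2, "grid search needs at least two classes")
  with_seed(seed, {
    folds <- integer(length(y))
    for (lv in levels(y)) {
      k <- which(y == lv)
      folds[k] <- sample(rep_len(seq_len(cv_folds), length(k)))
    }
    grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
    grid$accuracy <- vapply(seq_len(nrow(grid)), function(g) {
      correct <- 0
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        if (nlevels(droplevels(y[tr])) < 2) next
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = grid$cost[g], gamma = grid$gamma[g],
                          scale = FALSE)
        pred <- stats::predict(fit, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      correct / length(y)
    }, numeric(1))
    best <- grid[order(-grid$accuracy, grid$cost, grid$gamma), ][1, ]
    list(cost = best$cost, gamma = best$gamma, cv_accuracy = best$accuracy,
         grid = grid)
  })
}

#' Pseudo-population SVM decoding of trial identity
#'
#' Per run: subsample cells; fix the ITI feature bins for the run (if the
#' ITI period is used); grid-search cost and gamma on all available trials
#' (normalised per cell over all trials); then repeatedly draw 20 trials
#' per block, normalise per cell over those 120 trials, train an RBF SVM
#' (one-vs-one for the 6-way problem) on half and test on the other half.
#' Accuracy is the proportion of correct predictions over
#' `n_test x blocks x n_resamples` tests (1200 under defaults). Binary
#' collapses relabel the six blocks before training.
#'
#' @param session a session list.
#' @param spec a [decoding_spec()].
#' @param config an [analysis_config()].
#' @param seed optional integer seed.
#' @param shuffle_labels permute class labels before training (chance-level
#'   control).
#' @return list with `results` (per-run accuracy, chosen cost and gamma)
#'   and `confusion` (summed true x predicted count matrix across runs).
#' @export
decode <- function(session, spec = decoding_spec(),
                   config = analysis_config(), seed = NULL,
                   shuffle_labels = FALSE) {
  if (is.null(seed)) seed <- stage_seed(config$rng_seed, "decoding")
  trials <- session$trials
  schedule <- session$schedule
  all_units <- session$spikes$units$unit_id
  labels_all <- collapse_labels(trials, schedule, spec$collapse)
  classes <- levels(labels_all)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  rows <- list()
  for (run in seq_len(spec$n_runs)) {
    run_seed <- seed + 7919L * run
    res <- with_seed(run_seed, {
      units <- if (length(all_units) > spec$n_cells_subsampled)
        sample(all_units, spec$n_cells_subsampled) else all_units
      offs <- if (spec$period == "iti")
        stats::runif(nrow(trials), 0, config$iti_window_s - 0.6) else NULL
      rm <- rate_matrix(session, spec$period, config$iti_window_s,
                        offsets = offs, units = units)
      y_all <- labels_all
      if (shuffle_labels) y_all <- sample(y_all)
      x_all <- max_normalise_cols(t(rm))
      gs <- grid_search(x_all, y_all, spec$cost_grid, spec$gamma_grid,
                        spec$cv_folds)
      correct <- 0L
      total <- 0L
      conf <- confusion
      for (rs in seq_len(spec$n_resamples)) {
        idx <- unlist(lapply(schedule$blocks$block_id, function(b) {
          sample(which(trials$block_id == b), spec$n_trials_per_block)
        }))
        x <- max_normalise_cols(t(rm[, idx, drop = FALSE]))
        y <- droplevels(y_all[idx])
        train <- unlist(lapply(split(seq_along(idx),
                                     rep(schedule$blocks$block_id,
                                         each = spec$n_trials_per_block)),
                               function(k) sample(k, spec$n_train)))
        test <- setdiff(seq_along(idx), train)
        fit <- e1071::svm(x[train, , drop = FALSE], y[train],
                          kernel = "radial", cost = gs$cost,
                          gamma = gs$gamma, scale = FALSE)
        pred <- stats::predict(fit, x[test, , drop = FALSE])
        correct <- correct + sum(pred == y[test])
        total <- total + length(test)
        tb <- table(factor(y[test], classes), factor(pred, classes))
        conf <- conf + as.matrix(tb)
      }
      list(accuracy = correct / total, total = total,
           cost = gs$cost, gamma = gs$gamma, conf = conf)
    })
    confusion <- confusion + res$conf
    rows[[run]] <- data.frame(run = run, period = spec$period,
                              collapse = spec$collapse,
                              accuracy = res$accuracy, n_tests = res$total,
                              cost = res$cost, gamma = res$gamma)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, confusion = confusion,
       provenance = list(grid_cost = spec$cost_grid,
                         grid_gamma = spec$gamma_grid,
                         cv_folds = spec$cv_folds,
                         multiclass = "one-vs-one (libsvm)",
                         note = "grid ranges and CV scheme are package defaults"))
}
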