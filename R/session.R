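#' Spike-train container for a pooled pseudo-population
#'
#' @param units data.frame with columns `unit_id`, `rat_id`, `session_id`,
#'   `layer` (one of `"superficial"`, `"deep"`, `"unknown"`).
#' @param spikes named list of sorted, non-negative spike-time vectors, one
#'   per unit (names are `unit_id`s). Empty trains are allowed.
#' @param duration_s recording duration; all spikes must fall inside it.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(units, spikes, duration_s) {
  units$unit_id <- as.character(units$unit_id)
  stop_if_not(all(c("unit_id", "rat_id", "session_id", "layer") %in%
                    names(units)), "units table is missing required columns")
  stop_if_not(all(units$layer %in% c("superficial", "deep", "unknown")),
              "layer must be superficial, deep or unknown")
  stop_if_not(!anyDuplicated(units$unit_id), "unit_id must be unique")
  stop_if_not(setequal(names(spikes), units$unit_id),
              "spike list names must match unit ids")
  spikes <- spikes[units$unit_id]
  for (u in units$unit_id) {
    s <- spikes[[u]]
    stop_if_not(!is.unsorted(s), sprintf("spike times of unit %s unsorted", u))
    stop_if_not(length(s) == 0 || (min(s) >= 0 && max(s) <= duration_s),
                sprintf("spike times of unit %s outside [0, duration]", u))
  }
  structure(list(units = units, spikes = spikes, duration_s = duration_s),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("spike_train_set: %d units, %.1f s, %d spikes total\n",
              nrow(x$units), x$duration_s, sum(lengths(x$spikes))))
  invisible(x)
}

#' Number of units in a spike-train set
#' @param x a `spike_train_set`.
#' @export
n_units <- function(x) nrow(x$units)

#' Eyelid EMG trace
#'
#' @param samples numeric amplitudes (arbitrary units); must be finite.
#' @param rate_hz sampling rate, 10000 Hz in the study design.
#' @param t0_s session time of the first sample.
#' @return an object of class `emg_trace`.
#' @export
emg_trace <- function(samples, rate_hz = 10000, t0_s = 0) {
  stop_if_not(all(is.finite(samples)), "EMG samples must be finite")
  structure(list(rate_hz = rate_hz, samples = as.numeric(samples), t0_s = t0_s),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("emg_trace: %d samples @ %g Hz (%.1f s from t0 = %g s)\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz,
              x$t0_s))
  invisible(x)
}

#' Analysis configuration
#'
#' Collects the tunable statistical parameters shared across stages.
#'
#' @param n_permutations permutation/shuffle count for the selectivity tests
#'   (1000).
#' @param alpha significance level (0.05).
#' @param iti_window_s length of the pre-CS tonic analysis window (9 s).
#' @param n_subsample_cells_ensemble cells resampled per repeat in the
#'   state-vector analyses (100).
#' @param n_subsample_cells_svm cells resampled per decoding run (200).
#' @param n_repeats repeats for the resampled ensemble analyses (20).
#' @param rng_seed top-level seed; per-stage sub-streams are derived from it
#'   with [stage_seed()].
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(n_permutations = 1000, alpha = 0.05,
                            iti_window_s = 9,
                            n_subsample_cells_ensemble = 100,
                            n_subsample_cells_svm = 200,
                            n_repeats = 20, rng_seed = 1L) {
  stop_if_not(n_permutations >= 1, "n_permutations must be >= 1")
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stop_if_not(iti_window_s > 0, "iti_window_s must be positive")
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 iti_window_s = iti_window_s,
                 n_subsample_cells_ensemble = n_subsample_cells_ensemble,
                 n_subsample_cells_svm = n_subsample_cells_svm,
                 n_repeats = n_repeats, rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' Write a session to plain-text files
#'
#' Emits `spikes.csv` (`unit_id,rat_id,session_id,layer,spike_time_s`; units
#' with empty trains get a single row with a blank spike time),
#' `trials.csv`, `schedule.json`, and `emg.csv` (`t_s,amplitude`).
#'
#' @param spikes a [spike_train_set()].
#' @param trials a trial table from [make_schedule()].
#' @param emg an [emg_trace()], or `NULL` to skip.
#' @param schedule the [session_schedule()].
#' @param dir output directory (created if missing).
#' @return named character vector of the file paths written.
#' @export
write_session <- function(spikes, trials, emg, schedule, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spikes = file.path(dir, "spikes.csv"),
             trials = file.path(dir, "trials.csv"),
             schedule = file.path(dir, "schedule.json"))
  sp <- do.call(rbind, lapply(seq_len(nrow(spikes$units)), function(i) {
    u <- spikes$units[i, ]
    st <- spikes$spikes[[u$unit_id]]
    if (length(st) == 0) st <- NA_real_
    data.frame(unit_id = u$unit_id, rat_id = u$rat_id,
               session_id = u$session_id, layer = u$layer, spike_time_s = st)
  }))
  utils::write.csv(sp, paths[["spikes"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(trials), paths[["trials"]],
                   row.names = FALSE, quote = FALSE)
  sched <- list(blocks = schedule$blocks, iti_min_s = schedule$iti_min_s,
                iti_max_s = schedule$iti_max_s,
                cs_duration_s = schedule$cs_duration_s,
                trace_interval_s = schedule$trace_interval_s,
                us_duration_s = schedule$us_duration_s,
                emg_rate_hz = schedule$emg_rate_hz,
                duration_s = spikes$duration_s)
  writeLines(jsonlite::toJSON(sched, auto_unbox = TRUE, digits = NA),
             paths[["schedule"]])
  if (!is.null(emg)) {
    stop_if_not(all(is.finite(emg$samples)), "EMG samples must be finite")
    paths <- c(paths, emg = file.path(dir, "emg.csv"))
    t_s <- emg$t0_s + (seq_along(emg$samples) - 1) / emg$rate_hz
    utils::write.csv(data.frame(t_s = t_s, amplitude = emg$samples),
                     paths[["emg"]], row.names = FALSE, quote = FALSE)
  }
  paths
}

#' Read a session written by [write_session()]
#'
#' Validates column contracts and cross-consistency (sorted spike times,
#' US presence matching the paired flag, trials inside the recording span).
#'
#' @param dir directory containing `spikes.csv`, `trials.csv`,
#'   `schedule.json` and optionally `emg.csv`.
#' @return a list with elements `spikes`, `trials`, `emg` (or `NULL`) and
#'   `schedule`, the in-memory session object consumed by all analyses.
#' @export
read_session <- function(dir) {
  sched_js <- jsonlite::fromJSON(file.path(dir, "schedule.json"))
  schedule <- session_schedule(
    blocks = block_specs(sched_js$blocks$block_id, sched_js$blocks$cs_modality,
                         sched_js$blocks$box, sched_js$blocks$paired,
                         sched_js$blocks$n_trials),
    iti_min_s = sched_js$iti_min_s, iti_max_s = sched_js$iti_max_s,
    cs_duration_s = sched_js$cs_duration_s,
    trace_interval_s = sched_js$trace_interval_s,
    us_duration_s = sched_js$us_duration_s,
    emg_rate_hz = sched_js$emg_rate_hz)

  tr <- utils::read.csv(file.path(dir, "trials.csv"))
  need <- c("trial_index", "block_id", "cs_onset_s", "cs_offset_s", "us_onset_s")
  stop_if_not(all(need %in% names(tr)),
              sprintf("trials.csv missing columns: %s",
                      paste(setdiff(need, names(tr)), collapse = ", ")))
  if (is.null(tr$valid)) tr$valid <- TRUE
  class(tr) <- c("trial_table", "data.frame")
  validate_trials(tr, schedule)

  sp <- utils::read.csv(file.path(dir, "spikes.csv"),
                        colClasses = c(unit_id = "character"))
  need <- c("unit_id", "rat_id", "session_id", "layer", "spike_time_s")
  stop_if_not(all(need %in% names(sp)),
              sprintf("spikes.csv missing columns: %s",
                      paste(setdiff(need, names(sp)), collapse = ", ")))
  units <- unique(sp[, c("unit_id", "rat_id", "session_id", "layer")])
  trains <- lapply(split(sp$spike_time_s, sp$unit_id), function(v) {
    v <- v[!is.na(v)]
    stop_if_not(!is.unsorted(v), "spike times must be sorted within unit")
    v
  })
  duration <- sched_js$duration_s
  if (is.null(duration)) duration <- session_duration(tr, schedule)
  spikes <- spike_train_set(units, trains[units$unit_id], duration)

  emg <- NULL
  emg_path <- file.path(dir, "emg.csv")
  if (file.exists(emg_path)) {
    em <- utils::read.csv(emg_path)
    stop_if_not(all(c("t_s", "amplitude") %in% names(em)),
                "emg.csv must have columns t_s, amplitude")
    emg <- emg_trace(em$amplitude, schedule$emg_rate_hz, t0_s = em$t_s[1])
  }

  stop_if_not(max(trial_end_time(tr, schedule)) <= duration + 1e-6,
              "trial events extend beyond the recording span")
  list(spikes = spikes, trials = tr, emg = emg, schedule = schedule)
}
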