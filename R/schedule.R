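#' Block specification table for a conditioning session
#'
#' A session consists of an ordered sequence of trial blocks. In the default
#' design a rat first receives 20 auditory-CS-alone trials in Box 1, then 50
#' auditory CS-US pairings in Box 1, then the same alone/paired pair of blocks
#' with the auditory CS in Box 2, and finally a visual-CS alone/paired pair
#' back in Box 1 (210 trials in total).
#'
#' @param block_id integer block identifiers (1-based, session order).
#' @param cs_modality `"auditory"` or `"visual"` per block.
#' @param box conditioning environment, `1` or `2`.
#' @param paired logical; `TRUE` for CS-US blocks.
#' @param n_trials trials per block.
#' @return a validated `data.frame` of block specifications.
#' @export
block_specs <- function(block_id, cs_modality, box, paired, n_trials) {
  b <- data.frame(block_id = as.integer(block_id),
                  cs_modality = as.character(cs_modality),
                  box = as.integer(box),
                  paired = as.logical(paired),
                  n_trials = as.integer(n_trials),
                  stringsAsFactors = FALSE)
  stop_if_not(all(b$cs_modality %in% c("auditory", "visual")),
              "cs_modality must be 'auditory' or 'visual'")
  stop_if_not(all(b$box %in% 1:2), "box must be 1 or 2")
  stop_if_not(all(b$n_trials >= 1), "n_trials must be positive")
  stop_if_not(!anyDuplicated(b$block_id), "block_id must be unique")
  key <- paste(b$cs_modality, b$box, b$paired)
  stop_if_not(!anyDuplicated(key),
              "(cs_modality, box, paired) must be unique across blocks")
  b
}

#' Construct a session schedule
#'
#' @param blocks a block specification table from [block_specs()]; defaults to
#'   the six-block design (3 x 20 CS-alone + 3 x 50 CS-US trials).
#' @param iti_min_s,iti_max_s bounds of the uniform inter-trial interval,
#'   measured from the end of one trial (US offset, or its equivalent time on
#'   CS-alone trials) to the next CS onset. Defaults 20 and 40 s.
#' @param cs_duration_s CS duration (0.1 s).
#' @param trace_interval_s stimulus-free trace interval between CS offset and
#'   US onset (0.5 s). `cs_duration_s + trace_interval_s` must equal 0.6 s,
#'   the CS-onset-to-US-onset trial window used throughout the analyses.
#' @param us_duration_s US duration (0.1 s).
#' @param emg_rate_hz EMG sampling rate (10000 Hz).
#' @return an object of class `session_schedule`.
#' @export
session_schedule <- function(blocks = default_blocks(),
                             iti_min_s = 20, iti_max_s = 40,
                             cs_duration_s = 0.1, trace_interval_s = 0.5,
                             us_duration_s = 0.1, emg_rate_hz = 10000) {
  stop_if_not(iti_min_s <= iti_max_s, "iti_min_s must be <= iti_max_s")
  stop_if_not(abs(cs_duration_s + trace_interval_s - 0.6) < 1e-9,
              "cs_duration_s + trace_interval_s must equal 0.600 s")
  stop_if_not(iti_min_s >= 9 + cs_duration_s + trace_interval_s,
              "iti_min_s must be at least 9 s plus the trial window")
  s <- structure(list(blocks = blocks,
                      iti_min_s = iti_min_s, iti_max_s = iti_max_s,
                      cs_duration_s = cs_duration_s,
                      trace_interval_s = trace_interval_s,
                      us_duration_s = us_duration_s,
                      emg_rate_hz = emg_rate_hz),
                 class = "session_schedule")
  s
}

#' @rdname session_schedule
#' @export
default_blocks <- function() {
  block_specs(block_id = 1:6,
              cs_modality = c("auditory", "auditory", "auditory",
                              "auditory", "visual", "visual"),
              box = c(1, 1, 2, 2, 1, 1),
              paired = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
              n_trials = c(20, 50, 20, 50, 20, 50))
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("session_schedule: %d blocks, %d trials, ITI %g-%g s\n",
              nrow(x$blocks), sum(x$blocks$n_trials), x$iti_min_s, x$iti_max_s))
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Lay out trial event times for a schedule
#'
#' Draws inter-trial intervals uniformly from `[iti_min_s, iti_max_s]` and
#' places trials sequentially. The ITI is the stimulus-free gap from the end
#' of a trial to the next CS onset, so the 9 s pre-CS analysis window always
#' begins at least `iti_min_s - 9` seconds (11 s by default) after US offset.
#' On paired trials `us_onset_s = cs_onset_s + 0.6`; CS-alone trials have no
#' US (`us_onset_s = NA`) and analyses use the equivalent virtual time.
#'
#' @param schedule a [session_schedule()].
#' @param seed optional integer seed for the ITI draws.
#' @return a `trial_table` data.frame with columns `trial_index`, `block_id`,
#'   `cs_onset_s`, `cs_offset_s`, `us_onset_s`, `valid`.
#' @export
make_schedule <- function(schedule = session_schedule(), seed = NULL) {
  with_seed(seed, {
    bl <- schedule$blocks
    n_total <- sum(bl$n_trials)
    block_id <- rep(bl$block_id, bl$n_trials)
    paired <- rep(bl$paired, bl$n_trials)
    itis <- runif(n_total, schedule$iti_min_s, schedule$iti_max_s)
    trial_len <- 0.6 + schedule$us_duration_s  # CS onset -> US offset
    cs_onset <- numeric(n_total)
    t_cursor <- 0
    for (i in seq_len(n_total)) {
      cs_onset[i] <- t_cursor + itis[i]
      t_cursor <- cs_onset[i] + trial_len
    }
    trials <- data.frame(trial_index = seq_len(n_total),
                         block_id = block_id,
                         cs_onset_s = cs_onset,
                         cs_offset_s = cs_onset + schedule$cs_duration_s,
                         us_onset_s = ifelse(paired, cs_onset + 0.6, NA_real_),
                         valid = TRUE)
    class(trials) <- c("trial_table", "data.frame")
    trials
  })
}

#' Validate a trial table against its schedule
#' @param trials a trial table.
#' @param schedule the matching [session_schedule()].
#' @return `trials`, invisibly, after validation.
#' @export
validate_trials <- function(trials, schedule) {
  stop_if_not(all(diff(trials$cs_onset_s) > 0) &&
                all(diff(trials$trial_index) > 0),
              "trial_index must increase strictly with cs_onset_s")
  paired <- trial_paired(trials, schedule)
  stop_if_not(all(is.na(trials$us_onset_s[!paired])),
              "us_onset_s present on a trial of an unpaired block")
  stop_if_not(all(!is.na(trials$us_onset_s[paired])),
              "us_onset_s missing on a trial of a paired block")
  ok <- abs(trials$us_onset_s[paired] - trials$cs_onset_s[paired] - 0.6) < 1e-9
  stop_if_not(all(ok), "us_onset_s - cs_onset_s must equal 0.600 s")
  counts <- table(factor(trials$block_id, levels = schedule$blocks$block_id))
  stop_if_not(all(as.integer(counts) == schedule$blocks$n_trials),
              "trial counts per block do not match the schedule")
  invisible(trials)
}

# per-trial block attributes looked up from the schedule
trial_block_attr <- function(trials, schedule, field) {
  idx <- match(trials$block_id, schedule$blocks$block_id)
  schedule$blocks[[field]][idx]
}

trial_paired <- function(trials, schedule) trial_block_attr(trials, schedule, "paired")

#' US-equivalent event time for every trial
#'
#' Paired trials return the real US onset; CS-alone trials return the virtual
#' time `cs_onset_s + 0.6` ("the corresponding interval"), used for CR scoring
#' and for laying out inter-trial intervals.
#' @param trials a trial table.
#' @return numeric vector of times (s).
#' @export
us_equivalent_time <- function(trials) {
  ifelse(is.na(trials$us_onset_s), trials$cs_onset_s + 0.6, trials$us_onset_s)
}

# end-of-trial times (US offset or its CS-alone equivalent)
trial_end_time <- function(trials, schedule) {
  us_equivalent_time(trials) + schedule$us_duration_s
}

#' Total session duration implied by a trial table
#' @param trials a trial table.
#' @param schedule the session schedule.
#' @param tail_s extra recording time after the last trial (default 1 s).
#' @return duration in seconds.
#' @export
session_duration <- function(trials, schedule, tail_s = 1) {
  max(trial_end_time(trials, schedule)) + tail_s
}
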