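#' Ground-truth selectivity categories
#'
#' The eight labels combine selectivity flags for stimulus Relationship
#' (CS-alone vs CS-US), Modality (auditory vs visual CS) and Environment
#' (Box 1 vs Box 2).
#' @return character vector of the eight category labels.
#' @export
selectivity_categories <- function() {
  c("Non-S", "R", "M", "E", "R+M", "R+E", "M+E", "R+M+E")
}

# default category mixture: the empirical distribution of tonic (ITI period)
# selectivity across all 250 recorded cells in the study this generator
# emulates (combined responding + non-responding counts)
default_category_proportions <- function() {
  p <- c("Non-S" = 7, R = 21, M = 9, E = 3, "R+M" = 43, "R+E" = 35,
         "M+E" = 22, "R+M+E" = 110)
  p / sum(p)
}

#' Configuration of a synthetic cell population
#'
#' Cells are assigned a ground-truth selectivity category; their per-block
#' tonic rates are built so that exactly the contrasts implied by the label
#' differ, by the multiplicative factor `1 + effect_size`. Baseline rates are
#' log-normal with median below 2 Hz, matching the low-rate regime of the
#' recorded population.
#'
#' @param n_cells number of cells (default 250, the pooled population size).
#' @param category_proportions named fractions over
#'   [selectivity_categories()]; must sum to 1. Defaults to the empirical
#'   mixture of the recorded population.
#' @param responsive_fraction fraction of cells with a phasic CS response
#'   (default 0.452).
#' @param rate_meanlog,rate_sdlog log-normal baseline-rate parameters
#'   (median `exp(rate_meanlog)` = 0.8 Hz by default).
#' @param effect_size fractional rate difference for selective contrasts
#'   (default 1.0, i.e. a twofold rate step).
#' @param phasic_gain multiplicative rate factor during the 600 ms trial
#'   window for responsive cells (default 3).
#' @param layer_proportions named fractions for `superficial`/`deep`.
#' @param n_sessions synthetic recording sessions the cells are attributed to
#'   (in order), emulating a pseudo-population pooled across sessions.
#' @param within_block_drift optional fractional linear rate drift from the
#'   first to the last trial of each block (default 0, no drift).
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_cells = 250,
                              category_proportions = default_category_proportions(),
                              responsive_fraction = 0.452,
                              rate_meanlog = log(0.8), rate_sdlog = 0.6,
                              effect_size = 1.0, phasic_gain = 3,
                              layer_proportions = c(superficial = 0.44,
                                                    deep = 0.56),
                              n_sessions = 10, within_block_drift = 0) {
  stop_if_not(n_cells >= 1, "n_cells must be positive")
  stop_if_not(all(names(category_proportions) %in% selectivity_categories()),
              "unknown category label in category_proportions")
  stop_if_not(abs(sum(category_proportions) - 1) < 1e-8,
              "category_proportions must sum to 1")
  stop_if_not(effect_size > 0 || all(names(category_proportions) == "Non-S"),
              "effect_size must be positive when selective categories exist")
  structure(list(n_cells = as.integer(n_cells),
                 category_proportions = category_proportions,
                 responsive_fraction = responsive_fraction,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 effect_size = effect_size, phasic_gain = phasic_gain,
                 layer_proportions = layer_proportions,
                 n_sessions = n_sessions,
                 within_block_drift = within_block_drift),
            class = "population_config")
}

category_flags <- function(category) {
  parts <- strsplit(category, "+", fixed = TRUE)[[1]]
  c(R = "R" %in% parts, M = "M" %in% parts, E = "E" %in% parts)
}

#' Sample ground-truth cell parameters
#'
#' @param config a [population_config()].
#' @param schedule the [session_schedule()] whose block semantics the rates
#'   are keyed to.
#' @param seed optional integer seed.
#' @return an object of class `cell_population`: a `units` table (with
#'   ground-truth `category` and `responsive` columns), a `baseline` matrix
#'   (cells x blocks, tonic rates in Hz) and a `gain` matrix (cells x blocks,
#'   phasic trial-window rate factors).
#' @export
sample_population <- function(config = population_config(),
                              schedule = session_schedule(), seed = NULL) {
  with_seed(seed, {
    n <- config$n_cells
    bl <- schedule$blocks
    cats <- sample(names(config$category_proportions), n, replace = TRUE,
                   prob = config$category_proportions)
    responsive <- runif(n) < config$responsive_fraction
    layer <- sample(names(config$layer_proportions), n, replace = TRUE,
                    prob = config$layer_proportions)
    r0 <- stats::rlnorm(n, config$rate_meanlog, config$rate_sdlog)
    f <- 1 + config$effect_size
    baseline <- matrix(r0, n, nrow(bl))
    # each selective cell prefers one side of its contrast(s) at random,
    # mirroring the bidirectional rate differences of recorded cells; the
    # set of contrasts that differ is exactly the label's, either way
    for (i in seq_len(n)) {
      fl <- category_flags(cats[i])
      mult <- rep(1, nrow(bl))
      side <- runif(3) < 0.5
      if (fl[["R"]]) mult <- mult * ifelse(bl$paired == side[1], f, 1)
      if (fl[["M"]]) mult <- mult *
          ifelse((bl$cs_modality == "visual") == side[2], f, 1)
      if (fl[["E"]]) mult <- mult * ifelse((bl$box == 2) == side[3], f, 1)
      baseline[i, ] <- baseline[i, ] * mult
    }
    gain <- matrix(ifelse(responsive, config$phasic_gain, 1), n, nrow(bl))
    sess <- sort(rep_len(seq_len(config$n_sessions), n))
    units <- data.frame(
      unit_id = sprintf("u%03d", seq_len(n)), rat_id = "synthetic",
      session_id = sprintf("s%02d", sess), layer = layer,
      category = cats, responsive = responsive, stringsAsFactors = FALSE)
    structure(list(units = units, baseline = baseline, gain = gain,
                   config = config),
              class = "cell_population")
  })
}

#' Simulate one cell's spike train
#'
#' Piecewise-homogeneous Poisson process: the rate equals the cell's tonic
#' block rate outside trial windows and `baseline * gain` within the 600 ms
#' CS-onset-to-US-onset window. The tonic rate switches to a new block's
#' value at the end of the previous block's last trial (when the rat moves).
#'
#' @param baseline tonic rate (Hz) per block.
#' @param gain phasic trial-window rate factor per block.
#' @param trials trial table.
#' @param schedule session schedule.
#' @param duration_s recording duration.
#' @param within_block_drift fractional linear rate drift across each block.
#' @param seed optional integer seed.
#' @return sorted numeric vector of spike times.
#' @export
simulate_spikes <- function(baseline, gain, trials, schedule, duration_s,
                            within_block_drift = 0, seed = NULL) {
  stop_if_not(all(baseline >= 0) && all(gain >= 0),
              "rates and gains must be non-negative")
  with_seed(seed, {
    bidx <- match(trials$block_id, schedule$blocks$block_id)
    us_eq <- us_equivalent_time(trials)
    ends <- trial_end_time(trials, schedule)
    n <- nrow(trials)
    # within-block trial position in [0, 1] for the optional drift
    pos <- stats::ave(seq_len(n), trials$block_id, FUN = function(i) {
      if (length(i) == 1) 0 else (seq_along(i) - 1) / (length(i) - 1)
    })
    tonic <- baseline[bidx] * (1 + within_block_drift * pos)
    seg_start <- c(rbind(c(0, ends[-n]), trials$cs_onset_s, us_eq))
    seg_end <- c(rbind(trials$cs_onset_s, us_eq, ends))
    seg_rate <- c(rbind(tonic, tonic * gain[bidx], tonic))
    if (duration_s > ends[n]) {
      seg_start <- c(seg_start, ends[n])
      seg_end <- c(seg_end, duration_s)
      seg_rate <- c(seg_rate, tonic[n])
    }
    len <- seg_end - seg_start
    counts <- stats::rpois(length(len), seg_rate * len)
    tot <- sum(counts)
    if (tot == 0) return(numeric(0))
    sort(rep(seg_start, counts) + stats::runif(tot) * rep(len, counts))
  })
}

#' Conditioned-response behaviour configuration for the EMG generator
#'
#' @param cr_probability per-block probability that a trial carries a CR
#'   burst. Either a scalar, or a vector over blocks. The default mirrors
#'   well-trained performance: 0.7 on CS-US blocks, 0.15 on CS-alone blocks.
#' @param cr_burst_amplitude CR burst size as a multiple of the baseline EMG
#'   envelope (default 5). Values at or below 1 are undetectable by
#'   construction and trigger a warning.
#' @param cr_window burst window relative to (real or virtual) US onset, s.
#' @param baseline_sd standard deviation of the Gaussian noise floor before
#'   band-pass filtering (arbitrary units).
#' @return an object of class `cr_behavior_config`.
#' @export
cr_behavior_config <- function(cr_probability = NULL, cr_burst_amplitude = 5,
                               cr_window = c(-0.2, 0), baseline_sd = 1) {
  if (!is.null(cr_probability))
    stop_if_not(all(cr_probability >= 0 & cr_probability <= 1),
                "cr_probability must lie in [0, 1]")
  if (cr_burst_amplitude <= 1)
    warning("cr_burst_amplitude <= 1: CR bursts are undetectable by construction")
  structure(list(cr_probability = cr_probability,
                 cr_burst_amplitude = cr_burst_amplitude,
                 cr_window = cr_window, baseline_sd = baseline_sd),
            class = "cr_behavior_config")
}

cr_probability_per_block <- function(cr_config, schedule) {
  p <- cr_config$cr_probability
  if (is.null(p)) p <- ifelse(schedule$blocks$paired, 0.7, 0.15)
  rep_len(p, nrow(schedule$blocks))
}

#' Simulate the eyelid EMG trace
#'
#' Band-limited Gaussian noise (250 Hz high edge of the acquisition band,
#' applied with a zero-phase Butterworth filter) with amplitude bursts in the
#' 200 ms before (real or virtual) US onset on trials drawn as CR trials.
#'
#' @param trials trial table.
#' @param schedule session schedule.
#' @param cr_config a [cr_behavior_config()].
#' @param duration_s trace duration.
#' @param seed optional integer seed.
#' @return list with `emg` (an [emg_trace()]) and `cr_truth`, the logical
#'   ground-truth CR flag per trial for detector validation.
#' @export
simulate_emg <- function(trials, schedule, cr_config = cr_behavior_config(),
                         duration_s, seed = NULL) {
  with_seed(seed, {
    rate <- schedule$emg_rate_hz
    n <- ceiling(duration_s * rate)
    p <- cr_probability_per_block(cr_config, schedule)
    bidx <- match(trials$block_id, schedule$blocks$block_id)
    cr_truth <- stats::runif(nrow(trials)) < p[bidx]
    x <- stats::rnorm(n, sd = cr_config$baseline_sd)
    x <- emg_bandpass_filter(x, rate)
    us_eq <- us_equivalent_time(trials)
    for (i in which(cr_truth)) {
      i0 <- max(1, floor((us_eq[i] + cr_config$cr_window[1]) * rate) + 1)
      i1 <- min(n, ceiling((us_eq[i] + cr_config$cr_window[2]) * rate))
      x[i0:i1] <- x[i0:i1] * cr_config$cr_burst_amplitude
    }
    list(emg = emg_trace(x, rate), cr_truth = cr_truth)
  })
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper chaining [make_schedule()], [sample_population()],
#' [simulate_spikes()] and [simulate_emg()]. The defaults reproduce the
#' study design: 210 trials over six blocks, 20-40 s inter-trial intervals,
#' 250 low-rate cells with the empirical selectivity mixture.
#'
#' @param schedule a [session_schedule()].
#' @param pop_config a [population_config()].
#' @param cr_config a [cr_behavior_config()].
#' @param seed top-level integer seed; sub-streams are derived per component.
#' @param emg logical; set `FALSE` to skip the (large) EMG trace when only
#'   spike analyses are needed.
#' @return a list with `spikes`, `trials`, `emg`, `schedule`, plus `truth`
#'   (ground-truth categories and CR flags) and `population`.
#' @export
simulate_session <- function(schedule = session_schedule(),
                             pop_config = population_config(),
                             cr_config = cr_behavior_config(),
                             seed = 1L, emg = TRUE) {
  trials <- make_schedule(schedule, seed = stage_seed(seed, "schedule"))
  pop <- sample_population(pop_config, schedule,
                           seed = stage_seed(seed, "population"))
  duration <- session_duration(trials, schedule)
  trains <- with_seed(stage_seed(seed, "spikes"), {
    lapply(seq_len(nrow(pop$units)), function(i) {
      simulate_spikes(pop$baseline[i, ], pop$gain[i, ], trials, schedule,
                      duration,
                      within_block_drift = pop$config$within_block_drift)
    })
  })
  names(trains) <- pop$units$unit_id
  spikes <- spike_train_set(
    pop$units[, c("unit_id", "rat_id", "session_id", "layer")],
    trains, duration)
  emg_out <- NULL
  cr_truth <- NULL
  if (emg) {
    sim <- simulate_emg(trials, schedule, cr_config, duration,
                        seed = stage_seed(seed, "emg"))
    emg_out <- sim$emg
    cr_truth <- sim$cr_truth
  }
  list(spikes = spikes, trials = trials, emg = emg_out, schedule = schedule,
       truth = list(categories = pop$units[, c("unit_id", "category",
                                               "responsive")],
                    cr = cr_truth),
       population = pop)
}
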