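# Shared fixtures, built in code and memoised per test file.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(build), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# six-block structure with reduced trial counts (fast spike simulation)
small_schedule <- function(n_alone = 10, n_paired = 20, emg_rate = 2000) {
  session_schedule(
    block_specs(1:6,
                c("auditory", "auditory", "auditory", "auditory",
                  "visual", "visual"),
                c(1, 1, 2, 2, 1, 1),
                c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
                rep(c(n_alone, n_paired), 3)),
    emg_rate_hz = emg_rate)
}

quick_config <- function(n_perm = 199, seed = 1L) {
  analysis_config(n_permutations = n_perm, rng_seed = seed)
}

# small spike-only session with a strong, mixed-selectivity population
small_session <- function() {
  fixture("small_session", simulate_session(
    small_schedule(), population_config(n_cells = 25, effect_size = 1.5),
    seed = 101, emg = FALSE))
}

# population selective for a single task variable
single_category_session <- function(category, n_cells = 20,
                                    effect_size = 1.5, seed = 202,
                                    schedule = small_schedule()) {
  props <- stats::setNames(1, category)
  simulate_session(schedule,
                   population_config(n_cells = n_cells,
                                     category_proportions = props,
                                     effect_size = effect_size),
                   seed = seed, emg = FALSE)
}

# hand-built session from explicit per-cell baselines/gains; session_ids
# optionally attribute cells to ordered recording sessions
manual_session <- function(baseline, gain = NULL, schedule = small_schedule(),
                           session_ids = NULL, seed = 303) {
  n <- nrow(baseline)
  if (is.null(gain)) gain <- matrix(1, n, nrow(schedule$blocks))
  if (is.null(session_ids)) session_ids <- rep("s01", n)
  trials <- make_schedule(schedule, seed = seed)
  dur <- session_duration(trials, schedule)
  ids <- sprintf("u%03d", seq_len(n))
  trains <- with_seed(seed + 1, lapply(seq_len(n), function(i) {
    simulate_spikes(baseline[i, ], gain[i, ], trials, schedule, dur)
  }))
  names(trains) <- ids
  units <- data.frame(unit_id = ids, rat_id = "synthetic",
                      session_id = session_ids, layer = "unknown")
  list(spikes = spike_train_set(units, trains, dur), trials = trials,
       emg = NULL, schedule = schedule)
}
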