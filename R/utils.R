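#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `code`, and restores the
#' previous state on exit. With `seed = NULL` the expression simply uses the
#' current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Derive a reproducible per-stage seed from a top-level seed
#'
#' Each pipeline stage draws randomness from its own named sub-stream so that
#' stages can be re-run independently with identical results.
#'
#' @param seed top-level integer seed.
#' @param stage stage name, e.g. `"behavior"`.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  stages <- c(schedule = 1, population = 2, spikes = 3, emg = 4,
              behavior = 5, selectivity = 6, stability = 7,
              ensemble = 8, decoding = 9, misc = 10)
  off <- stages[[match.arg(stage, names(stages))]]
  as.integer((as.numeric(seed) + off * 1000003) %% 2147483646) + 1L
}

# count spikes in half-open windows [start, end) against a sorted spike vector;
# findInterval(x, v, left.open = TRUE) counts spikes strictly below x, so a
# spike exactly at `end` is excluded and one exactly at `start` included
count_in_windows <- function(spikes, starts, ends) {
  if (length(spikes) == 0) return(rep(0L, length(starts)))
  findInterval(ends, spikes, left.open = TRUE) -
    findInterval(starts, spikes, left.open = TRUE)
}

# order statistic used as the permutation-null upper-tail quantile:
# the ceil((1 - alpha) * n)-th smallest null value
null_quantile <- function(null_values, alpha) {
  n <- length(null_values)
  k <- ceiling((1 - alpha) * n)
  sort(null_values, partial = k)[k]
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
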