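#' Kullback-Leibler divergence in bits
#'
#' `sum(P * log2(P / Q))` with zero-probability terms of P contributing 0.
#' Q must be strictly positive.
#'
#' @param p,q probability vectors of equal length summing to 1.
#' @return divergence in bits (non-negative).
#' @export
kld <- function(p, q) {
  stop_if_not(length(p) == length(q), "P and Q must have equal length")
  stop_if_not(all(q > 0), "Q must be strictly positive")
  stop_if_not(all(p >= 0), "P must be non-negative")
  stop_if_not(abs(sum(p) - 1) < 1e-8 && abs(sum(q) - 1) < 1e-8,
              "P and Q must each sum to 1")
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Within- versus between-block firing-rate stability
#'
#' The 9 s ITI window is split into fifteen 600 ms bins and the rate in each
#' bin averaged across all trials of each block, giving a blocks x bins rate
#' profile. The within-block divergence is the median over blocks of the KLD
#' between the block's bin profile (normalised to sum 1) and the uniform
#' distribution over 15 bins; the between-block divergence is the median
#' over bins of the KLD between the bin's 6-block rate vector (normalised)
#' and the uniform distribution over blocks. A positive
#' `kld_difference = between - within` indicates tonic block coding that
#' exceeds within-block fluctuation. Blocks or bins with all-zero rates have
#' undefined KLD and are excluded from the medians with a notice.
#'
#' @param spikes sorted spike times of one unit.
#' @param trials trial table.
#' @param schedule session schedule.
#' @param iti_window_s tonic window length (9 s).
#' @param n_bins number of bins (15 x 600 ms).
#' @return list with `within_kld`, `between_kld`, `kld_difference` (bits)
#'   and the `profile` matrix (blocks x bins, Hz).
#' @export
stability_klds <- function(spikes, trials, schedule, iti_window_s = 9,
                           n_bins = 15) {
  blocks <- schedule$blocks$block_id
  prof <- matrix(NA_real_, length(blocks), n_bins,
                 dimnames = list(blocks, NULL))
  for (bi in seq_along(blocks)) {
    k <- trials$block_id == blocks[bi]
    for (j in seq_len(n_bins)) {
      prof[bi, j] <- mean(trial_rates(spikes, trials[k, , drop = FALSE],
                                      "iti", iti_window_s = iti_window_s,
                                      bin = c(j, n_bins)))
    }
  }
  q_bins <- rep(1 / n_bins, n_bins)
  within <- apply(prof, 1, function(v) {
    if (sum(v) == 0) NA_real_ else kld(v / sum(v), q_bins)
  })
  q_blocks <- rep(1 / length(blocks), length(blocks))
  between <- apply(prof, 2, function(v) {
    if (sum(v) == 0) NA_real_ else kld(v / sum(v), q_blocks)
  })
  if (anyNA(within) || anyNA(between))
    message("stability_klds: all-zero block(s)/bin(s) excluded from medians")
  w <- stats::median(within, na.rm = TRUE)
  b <- stats::median(between, na.rm = TRUE)
  list(within_kld = w, between_kld = b, kld_difference = b - w,
       profile = prof)
}

#' Stability table for all units of a session
#'
#' @param session a session list.
#' @param config an [analysis_config()].
#' @return data.frame with one row per unit: `within_kld`, `between_kld`,
#'   `kld_difference` (bits).
#' @export
stability_table <- function(session, config = analysis_config()) {
  spikes <- session$spikes
  rows <- lapply(seq_len(n_units(spikes)), function(i) {
    uid <- spikes$units$unit_id[i]
    r <- stability_klds(spikes$spikes[[uid]], session$trials,
                        session$schedule, iti_window_s = config$iti_window_s)
    data.frame(unit_id = uid, within_kld = r$within_kld,
               between_kld = r$between_kld,
               kld_difference = r$kld_difference)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
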