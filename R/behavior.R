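#' CR detection parameters
#'
#' The threshold rules operate on the session-wide envelope threshold T
#' (mean of all pre-CS values plus one SD): a trial is discarded if its
#' pre-CS value exceeds `hyper_factor` x T (hyperactivity); it is a CR if the
#' pre-CS value is at or below T and the CR value exceeds `cr_factor` x T;
#' in the intermediate band the CR value above T must exceed `ratio_factor`
#' times the pre-CS value above T.
#'
#' @param pre_cs_window averaging window relative to CS onset, s.
#' @param cr_window averaging window relative to (real or virtual) US onset.
#' @param pre_cr_window control window relative to CS onset used for the
#'   pre-CR% measure of CS-independent blinking.
#' @param hyper_factor,cr_factor,ratio_factor the 1.30 / 1.10 / 5.0 rule
#'   constants.
#' @param threshold_scope `"session"` (all trials pooled, the default) or
#'   `"block"` for a per-block threshold.
#' @param bandpass logical; band-pass filter the trace before the envelope
#'   (disable for pre-filtered input).
#' @return an object of class `cr_detection_params`.
#' @export
cr_detection_params <- function(pre_cs_window = c(-0.2, 0),
                                cr_window = c(-0.2, 0),
                                pre_cr_window = c(-0.48, -0.28),
                                hyper_factor = 1.30, cr_factor = 1.10,
                                ratio_factor = 5.0,
                                threshold_scope = c("session", "block"),
                                bandpass = TRUE) {
  stop_if_not(hyper_factor > 1 && cr_factor > 1 && ratio_factor > 0,
              "hyper_factor and cr_factor must exceed 1, ratio_factor 0")
  structure(list(pre_cs_window = pre_cs_window, cr_window = cr_window,
                 pre_cr_window = pre_cr_window, hyper_factor = hyper_factor,
                 cr_factor = cr_factor, ratio_factor = ratio_factor,
                 threshold_scope = match.arg(threshold_scope),
                 bandpass = bandpass),
            class = "cr_detection_params")
}

# zero-phase Butterworth band-pass approximating the 250-5000 Hz acquisition
# band (upper edge capped below Nyquist for realizability)
emg_bandpass_filter <- function(x, rate_hz, band = c(250, 4500)) {
  nyq <- rate_hz / 2
  hi <- min(band[2], 0.9 * nyq)
  stop_if_not(band[1] < hi, "band-pass edges invalid for this sampling rate")
  bf <- signal::butter(4, c(band[1], hi) / nyq, type = "pass")
  signal::filtfilt(bf, x)
}

# analytic signal via the standard FFT construction (positive frequencies
# doubled, negative zeroed); no installed package exposes this primitive
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous EMG amplitude (Hilbert envelope)
#'
#' Absolute value of the analytic signal of the (optionally band-passed)
#' EMG trace. Output is non-negative with the same length and timebase as
#' the input.
#'
#' @param trace an [emg_trace()] or a numeric vector.
#' @param rate_hz sampling rate (taken from the trace if omitted).
#' @param bandpass apply the 250 Hz-high-edge band-pass first.
#' @return numeric envelope.
#' @export
emg_envelope <- function(trace, rate_hz = NULL, bandpass = TRUE) {
  x <- if (inherits(trace, "emg_trace")) trace$samples else trace
  if (is.null(rate_hz))
    rate_hz <- if (inherits(trace, "emg_trace")) trace$rate_hz else
      stop("rate_hz required for a bare numeric trace")
  stop_if_not(length(x) > 0, "empty EMG trace")
  stop_if_not(all(is.finite(x)), "EMG trace contains non-finite samples")
  if (bandpass) x <- emg_bandpass_filter(x, rate_hz)
  Mod(analytic_signal(x))
}

#' Session-wide CR threshold
#'
#' Mean of all pre-CS envelope values plus one standard deviation
#' (population convention, ddof = 0).
#'
#' @param pre_cs_values numeric vector, one value per trial (length >= 2).
#' @return the threshold (arbitrary units).
#' @export
session_threshold <- function(pre_cs_values) {
  stop_if_not(length(pre_cs_values) >= 2,
              "need at least 2 pre-CS values for a threshold")
  m <- mean(pre_cs_values)
  m + sqrt(mean((pre_cs_values - m)^2))
}

#' Label one trial by the three-branch CR rule
#'
#' @param pre_cs_value averaged envelope in the 200 ms before CS onset.
#' @param cr_value averaged envelope in the 200 ms before US onset.
#' @param threshold session threshold from [session_threshold()].
#' @param params a [cr_detection_params()].
#' @return `"CR"`, `"noCR"` or `"discarded"`.
#' @export
score_trial <- function(pre_cs_value, cr_value, threshold,
                        params = cr_detection_params()) {
  if (pre_cs_value > params$hyper_factor * threshold) return("discarded")
  if (pre_cs_value <= threshold) {
    if (cr_value > params$cr_factor * threshold) return("CR") else return("noCR")
  }
  # threshold < pre <= hyper_factor * threshold
  if ((cr_value - threshold) >=
        params$ratio_factor * (pre_cs_value - threshold)) "CR" else "noCR"
}

# mean envelope of one trial-relative window, computed on a locally padded
# segment so the filter and Hilbert edge transients stay outside the window
trial_window_means <- function(emg, anchors, window, rate_hz, pad_s = 0.25,
                               bandpass = TRUE) {
  vapply(anchors, function(a) {
    t0 <- a + window[1] - pad_s
    t1 <- a + window[2] + pad_s
    i0 <- max(1, floor(t0 * rate_hz) + 1)
    i1 <- min(length(emg$samples), ceiling(t1 * rate_hz))
    stop_if_not(i1 > i0, "scoring window outside the EMG trace")
    env <- emg_envelope(emg$samples[i0:i1], rate_hz, bandpass = bandpass)
    tt <- (seq(i0, i1) - 1) / rate_hz
    sel <- tt >= a + window[1] & tt < a + window[2]
    stop_if_not(any(sel), "scoring window outside the EMG trace")
    mean(env[sel])
  }, numeric(1))
}

#' Score every trial of a session from the EMG trace
#'
#' Computes pre-CS and CR envelope values per trial (the envelope is
#' evaluated on padded per-trial segments so that filter edge transients do
#' not contaminate the scoring windows), derives the session threshold, and
#' applies the three-branch rule. The same machinery is rerun with the
#' pre-CR control window as scoring window to obtain pre-CR labels.
#'
#' @param emg an [emg_trace()].
#' @param trials trial table.
#' @param schedule session schedule.
#' @param params a [cr_detection_params()].
#' @return a list with `scores` (per-trial data.frame: `trial_index`,
#'   `block_id`, `pre_cs_value`, `cr_value`, `pre_cr_value`, `label`,
#'   `pre_cr_label`) and `threshold`.
#' @export
score_session <- function(emg, trials, schedule,
                          params = cr_detection_params()) {
  rate <- emg$rate_hz
  us_eq <- us_equivalent_time(trials)
  bp <- params$bandpass
  pre <- trial_window_means(emg, trials$cs_onset_s, params$pre_cs_window,
                            rate, bandpass = bp)
  crv <- trial_window_means(emg, us_eq, params$cr_window, rate, bandpass = bp)
  pcr <- trial_window_means(emg, trials$cs_onset_s, params$pre_cr_window,
                            rate, bandpass = bp)
  if (params$threshold_scope == "session") {
    thr <- rep(session_threshold(pre), nrow(trials))
  } else {
    thr_b <- tapply(pre, trials$block_id, session_threshold)
    thr <- as.numeric(thr_b[as.character(trials$block_id)])
  }
  lab <- mapply(score_trial, pre, crv, thr, MoreArgs = list(params = params))
  plab <- mapply(score_trial, pre, pcr, thr, MoreArgs = list(params = params))
  scores <- data.frame(trial_index = trials$trial_index,
                       block_id = trials$block_id,
                       pre_cs_value = pre, cr_value = crv, pre_cr_value = pcr,
                       label = lab, pre_cr_label = plab,
                       stringsAsFactors = FALSE)
  list(scores = scores, threshold = thr[1])
}

#' Per-block CR% and pre-CR%
#'
#' CR% is the percentage of CR trials among valid (non-discarded) trials;
#' pre-CR% applies the same rule to the pre-CR control window. Blocks with
#' no valid trials are flagged with `NA` percentages.
#'
#' @param scores the `scores` data.frame from [score_session()].
#' @return data.frame with `block_id`, `cr_percent`, `pre_cr_percent`,
#'   `n_valid`, `n_trials`.
#' @export
block_cr_stats <- function(scores) {
  out <- lapply(split(scores, scores$block_id), function(s) {
    valid <- s$label != "discarded"
    nv <- sum(valid)
    data.frame(block_id = s$block_id[1],
               cr_percent = if (nv > 0)
                 100 * sum(s$label[valid] == "CR") / nv else NA_real_,
               pre_cr_percent = if (nv > 0)
                 100 * sum(s$pre_cr_label[valid] == "CR") / nv else NA_real_,
               n_valid = nv, n_trials = nrow(s))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$block_id), ]
  rownames(res) <- NULL
  if (any(res$n_valid == 0))
    warning("block(s) with zero valid trials: CR% undefined")
  res
}
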