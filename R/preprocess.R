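# Raw EMG -> normalized linear envelope.
#
# Chain: 4th-order Butterworth high-pass at 20 Hz, run forward and backward
# (zero phase); demean; full-wave rectify; 4th-order Butterworth low-pass at
# 25 Hz, forward and backward; clip residual negative ringing to zero.
# Amplitude is then normalized per channel to the peak envelope value
# averaged across all strides.

# Zero-phase IIR filtering: odd-reflection padding of 3 filter lengths at
# each end plus steady-state initial conditions (filter memory preloaded as
# if the first sample had been applied forever), so no start/end transient
# leaks into the envelope. filt is a list(b =, a =) from signal::butter.
filtfilt_reflect <- function(filt, x) {
  b <- filt$b; a <- filt$a
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (length(x) <= npad)
    stop_data("signal too short for zero-phase filtering", "amap_data_error")
  dc_gain <- sum(b) / sum(a)
  one_pass <- function(v) {
    x0 <- v[1]
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(x0, length(b) - 1L),
                              init.y = rep(x0 * dc_gain, length(a) - 1L)))
  }
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  ext <- c(head_pad, x, tail_pad)
  y <- one_pass(ext)
  y <- rev(one_pass(rev(y)))
  y[(npad + 1):(npad + length(x))]
}

butter_or_fail <- function(order, cutoff_hz, rate_hz, type) {
  wn <- cutoff_hz / (rate_hz / 2)
  if (!is.finite(wn) || wn <= 0 || wn >= 1)
    stop_config(sprintf(
      "cannot design %s Butterworth at %g Hz for a %g Hz sampling rate",
      type, cutoff_hz, rate_hz))
  signal::butter(order, wn, type = type)
}

#' Linear-envelope extraction from raw EMG
#'
#' Applies, in order: zero-phase 4th-order Butterworth high-pass (20 Hz),
#' channel demeaning, full-wave rectification, zero-phase 4th-order
#' Butterworth low-pass (25 Hz), and clipping of residual negative filter
#' ringing to zero. Zero phase is realized by forward-backward filtering
#' with odd-reflection padding, so burst timing is not shifted.
#'
#' @param emg an [emg_recording].
#' @param highpass_hz high-pass cutoff, default 20.
#' @param lowpass_hz low-pass (smoothing) cutoff, default 25.
#' @param order filter order applied in each direction, default 4.
#' @return An `envelope_recording`: list with `envelopes` (samples x
#'   channels, nonnegative), `rate_hz`, `channel_names`, and
#'   `normalization_peaks` (NULL until [normalize_to_step_peaks()]).
#' @export
filter_chain <- function(emg, highpass_hz = 20, lowpass_hz = 25, order = 4) {
  stopifnot(inherits(emg, "emg_recording"))
  if (emg$rate_hz <= 2 * lowpass_hz)
    stop_config(sprintf(
      "sampling rate %g Hz too low for a %g Hz low-pass", emg$rate_hz,
      lowpass_hz))
  hp <- butter_or_fail(order, highpass_hz, emg$rate_hz, "high")
  lp <- butter_or_fail(order, lowpass_hz, emg$rate_hz, "low")
  env <- apply(emg$signals, 2, function(x) {
    y <- filtfilt_reflect(hp, x)
    y <- y - mean(y)
    y <- abs(y)
    y <- filtfilt_reflect(lp, y)
    pmax(y, 0)
  })
  envelope_recording(env, emg$rate_hz, emg$channel_names,
                     leg = emg$leg, subject_id = emg$subject_id)
}

#' Envelope recording constructor
#'
#' @param envelopes numeric matrix, samples x channels, nonnegative.
#' @param rate_hz sampling rate (Hz).
#' @param channel_names muscle labels.
#' @param normalization_peaks per-channel averaged stride peak used as the
#'   normalization divisor, or NULL if not yet normalized.
#' @param leg,subject_id carried metadata.
#' @return An object of class `envelope_recording`.
#' @export
envelope_recording <- function(envelopes, rate_hz,
                               channel_names = colnames(envelopes),
                               normalization_peaks = NULL,
                               leg = "left", subject_id = "anon") {
  envelopes <- as.matrix(envelopes)
  if (!is.numeric(envelopes) || anyNA(envelopes) || any(envelopes < 0))
    stop_data("envelopes must be numeric, nonnegative, no missing values")
  if (length(channel_names) != ncol(envelopes) ||
      anyDuplicated(channel_names))
    stop_data("channel_names must be unique, one per envelope column",
              "amap_schema_error")
  colnames(envelopes) <- channel_names
  structure(list(envelopes = envelopes, rate_hz = as.numeric(rate_hz),
                 channel_names = as.character(channel_names),
                 normalization_peaks = normalization_peaks,
                 leg = leg, subject_id = as.character(subject_id)),
            class = "envelope_recording")
}

#' Normalize envelopes to the averaged per-stride peak
#'
#' For each channel the divisor is the mean, across strides, of the maximum
#' envelope value within the stride; every sample is divided by it. This is
#' the walking-based alternative to maximum-voluntary-contraction
#' normalization, which is unreliable in populations with impaired
#' voluntary activation. Individual strides may exceed 1 after scaling.
#'
#' @param env an `envelope_recording`.
#' @param strides list of `gait_segmentation` objects from
#'   [segment_strides()]; at least one complete stride.
#' @param eps divisors at or below this are treated as flat channels.
#' @return The recording with scaled `envelopes` and `normalization_peaks`
#'   recording the divisors.
#' @export
normalize_to_step_peaks <- function(env, strides, eps = 1e-12) {
  stopifnot(inherits(env, "envelope_recording"))
  if (length(strides) < 1)
    stop_data("at least one complete stride is required",
              "amap_insufficient_data")
  t <- sample_times(nrow(env$envelopes), env$rate_hz)
  peaks <- sapply(env$channel_names, function(ch) {
    per_stride <- vapply(strides, function(s) {
      idx <- t >= s$boundaries[1] & t < s$boundaries[7]
      if (!any(idx)) return(NA_real_)
      max(env$envelopes[idx, ch])
    }, numeric(1))
    mean(per_stride, na.rm = TRUE)
  })
  flat <- names(peaks)[!is.finite(peaks) | peaks <= eps]
  if (length(flat))
    stop_data(sprintf("degenerate (flat) channel(s): %s",
                      paste(flat, collapse = ", ")),
              "amap_degenerate_channel")
  scaled <- sweep(env$envelopes, 2, peaks, "/")
  envelope_recording(scaled, env$rate_hz, env$channel_names,
                     normalization_peaks = peaks,
                     leg = env$leg, subject_id = env$subject_id)
}

# Times of the left edges of the half-open sample intervals.
sample_times <- function(n, rate_hz) (seq_len(n) - 1L) / rate_hz

#' @export
print.envelope_recording <- function(x, ...) {
  cat(sprintf(
    "<envelope_recording> %s: %d channels x %d samples @ %g Hz (%s)\n",
    x$subject_id, ncol(x$envelopes), nrow(x$envelopes), x$rate_hz,
    if (is.null(x$normalization_peaks)) "unnormalized" else "normalized"))
  invisible(x)
}
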