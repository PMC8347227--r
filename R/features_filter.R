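#' Zero-phase Butterworth band-pass filtering of a trial set
#'
#' Designs a Butterworth band-pass filter and applies it forward-backward
#' (`signal::filtfilt`) to every channel of every trial, so the output has no
#' group delay. The effective attenuation order is twice `order`.
#'
#' @param trials a [trial_set()].
#' @param band numeric pair `(low, high)` in Hz; default the 8-30 Hz
#'   sensorimotor range.
#' @param order Butterworth order (default 5).
#' @return A `trial_set` of identical shape, filtered.
#' @export
bandpass_filter <- function(trials, band = c(8, 30), order = 5) {
  stopifnot(inherits(trials, "trial_set"), length(band) == 2L, order >= 1)
  if (band[1] <= 0 || band[1] >= band[2])
    stop("invalid band: need 0 < low < high")
  if (band[2] >= trials$fs / 2)
    stop("band upper edge ", band[2], " Hz is at or above Nyquist (fs = ",
         trials$fs, " Hz)")
  if (!all(is.finite(trials$X))) stop("non-finite samples in EEG data")
  bf <- signal::butter(order, band / (trials$fs / 2), type = "pass")
  X <- trials$X
  d <- dim(X)
  for (n in seq_len(d[3])) {
    for (c in seq_len(d[1])) {
      X[c, , n] <- signal::filtfilt(bf, X[c, , n])
    }
  }
  out <- trials
  out$X <- X
  out
}

#' Magnitude response of the band-pass stage at given frequencies
#'
#' Utility for checking the designed filter: returns the zero-phase
#' (forward-backward, hence squared) magnitude response of the Butterworth
#' band-pass used by [bandpass_filter()].
#'
#' @param freqs_hz frequencies to evaluate, Hz.
#' @param fs sampling rate, Hz.
#' @inheritParams bandpass_filter
#' @return Numeric vector of gains.
#' @export
bandpass_gain <- function(freqs_hz, fs, band = c(8, 30), order = 5) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  w <- 2 * pi * freqs_hz / fs
  ejw <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  h <- as.vector(ejw %*% bf$b) / as.vector(ejw[, seq_along(bf$a)] %*% bf$a)
  Mod(h)^2
}

#' Cut a trial into sliding windows
#'
#' @param trial `C x T` numeric matrix.
#' @param fs sampling rate, Hz.
#' @param window_s window length tau in seconds (default 2).
#' @param step_s step size in seconds (default 1).
#' @param interval `(start_s, end_s)` analysis span within the trial,
#'   in seconds from trial onset; default the full trial.
#' @return List of `C x round(window_s * fs)` matrices ordered by onset; the
#'   count is `floor((interval_length - window_s) / step_s) + 1`.
#' @export
segment_trial <- function(trial, fs, window_s = 2, step_s = 1,
                          interval = NULL) {
  stopifnot(is.matrix(trial), fs > 0, window_s > 0, step_s > 0)
  Tn <- ncol(trial)
  if (is.null(interval)) interval <- c(0, Tn / fs)
  if (interval[1] < 0 || interval[2] * fs > Tn + 1e-9)
    stop("analysis interval does not fit inside the trial")
  len <- interval[2] - interval[1]
  if (window_s > len + 1e-9)
    stop("window (", window_s, " s) longer than the analysis interval (",
         len, " s)")
  n_seg <- floor((len - window_s) / step_s + 1e-9) + 1
  wlen <- round(window_s * fs)
  lapply(seq_len(n_seg), function(k) {
    start <- round((interval[1] + (k - 1) * step_s) * fs) + 1
    trial[, start:(start + wlen - 1), drop = FALSE]
  })
}

#' Sliding windows for every trial of a trial set
#'
#' @param trials a [trial_set()].
#' @inheritParams segment_trial
#' @return List over trials; each element a list of `C x L` segment matrices.
#' @export
segment_trials <- function(trials, window_s = 2, step_s = 1,
                           interval = NULL) {
  d <- dim(trials$X)
  lapply(seq_len(d[3]), function(n)
    segment_trial(trials$X[, , n], trials$fs, window_s, step_s, interval))
}
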