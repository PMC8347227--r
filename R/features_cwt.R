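#' Complex Morlet wavelet scales over a frequency range
#'
#' The continuous wavelet transform uses a complex Morlet atom
#' `psi(u) = (pi * B)^(-1/2) * exp(-u^2 / B) * exp(2i * pi * Cf * u)` with
#' bandwidth-times-centre-frequency product fixed at `B = Cf = 1`. A scale
#' `s` maps to the centre frequency `f = Cf * fs / s`; `n_scales` scales are
#' log-spaced so their centre frequencies span `freq_range`.
#'
#' @param fs sampling rate, Hz.
#' @param freq_range `(low, high)` Hz covered by the scale bank.
#' @param n_scales number of scales (default 32).
#' @return Data frame with columns `scale` and `freq_hz` (descending
#'   frequency order... ascending scale).
#' @export
morlet_scales <- function(fs, freq_range = c(8, 30), n_scales = 32) {
  stopifnot(freq_range[1] > 0, freq_range[2] > freq_range[1], n_scales >= 1)
  freqs <- exp(seq(log(freq_range[2]), log(freq_range[1]),
                   length.out = n_scales))
  data.frame(scale = fs / freqs, freq_hz = freqs)
}

# Frequency responses of the Morlet atoms at each scale: nfft x n_scales.
.morlet_bank <- function(fs, scales, nfft) {
  half <- floor(nfft / 2)
  bank <- matrix(0i, nfft, length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    # wavelet sampled on +-4 sigma support (sigma_u = sqrt(B/2) scale units)
    m <- min(half - 1L, ceiling(4 * s / sqrt(2)))
    u <- (-m:m) / s
    psi <- (pi)^(-0.5) * exp(-u^2) * exp(2i * pi * u) / sqrt(s)
    bank[, si] <- stats::fft(c(psi[(m + 1):(2 * m + 1)],
                               rep(0, nfft - (2 * m + 1)),
                               psi[1:m]))
  }
  bank
}

# CWT of a multi-channel segment at the given scales, via FFT convolution.
# Returns squared magnitudes averaged over time: C x n_scales matrix. The
# inverse transforms for all (channel, scale) pairs run in one mvfft call.
.cwt_power <- function(segment, fs, scales, bank = NULL) {
  C <- nrow(segment); L <- ncol(segment)
  nfft <- stats::nextn(2L * L, 2)
  if (is.null(bank)) bank <- .morlet_bank(fs, scales, nfft)
  ns <- length(scales)
  Xf <- stats::mvfft(rbind(t(segment), matrix(0, nfft - L, C)))  # nfft x C
  Wf <- matrix(0i, nfft, C * ns)
  for (si in seq_len(ns))
    Wf[, (si - 1L) * C + seq_len(C)] <- Xf * Conj(bank[, si])
  W <- stats::mvfft(Wf, inverse = TRUE) / nfft
  P <- colMeans(Mod(W[seq_len(L), , drop = FALSE])^2)
  matrix(P, C, ns)
}

#' Per-channel wavelet band energy of a segment
#'
#' Mean squared magnitude of the complex Morlet coefficients over the scales
#' whose centre frequencies fall inside `band`, averaged over the segment.
#'
#' @param segment `C x L` matrix.
#' @param fs sampling rate, Hz.
#' @param band `(low, high)` Hz; must lie within `freq_range`.
#' @param freq_range range spanned by the scale bank (default `c(8, 30)`).
#' @param n_scales number of log-spaced scales (default 32).
#' @param power optional precomputed `C x n_scales` power matrix from the
#'   same scale bank (lets callers share one CWT across bands).
#' @return Nonnegative numeric vector of length `C`.
#' @export
cwt_channel_features <- function(segment, fs, band,
                                 freq_range = c(8, 30), n_scales = 32,
                                 power = NULL) {
  sc <- morlet_scales(fs, freq_range, n_scales)
  in_band <- sc$freq_hz >= band[1] & sc$freq_hz <= band[2]
  if (!any(in_band))
    stop("no wavelet scale has a centre frequency inside [",
         band[1], ", ", band[2], "] Hz")
  if (is.null(power)) power <- .cwt_power(segment, fs, sc$scale)
  rowMeans(power[, in_band, drop = FALSE])
}
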