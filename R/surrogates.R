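#' Phase surrogate of a multichannel segment
#'
#' Per channel independently: Fourier transform, replace the phases of the
#' positive-frequency coefficients with i.i.d. uniform(0, 2*pi) draws while
#' enforcing Hermitian symmetry (DC and, for even lengths, the Nyquist
#' coefficient keep their phases), inverse transform. The output is real and
#' each channel's power spectrum — hence its autocorrelation — is preserved
#' exactly, while cross-channel phase relations are destroyed on average.
#'
#' @param segment channels x samples numeric matrix (>= 4 samples).
#' @return same-shape real matrix.
#' @export
phase_surrogate <- function(segment) {
  segment <- as.matrix(segment)
  T <- ncol(segment)
  if (T < 4L) stop("need at least 4 samples")
  half <- if (T %% 2 == 0) T %/% 2 - 1L else (T - 1L) %/% 2   # free coeffs
  out <- segment
  for (ch in seq_len(nrow(segment))) {
    F <- stats::fft(segment[ch, ])
    if (half >= 1L) {
      idx <- 2:(half + 1L)
      theta <- stats::runif(half, 0, 2 * pi)
      F[idx] <- Mod(F[idx]) * exp(1i * theta)
      F[T + 2L - idx] <- Conj(F[idx])
    }
    out[ch, ] <- Re(stats::fft(F, inverse = TRUE)) / T
  }
  out
}

#' Staggering surrogate: independent per-channel circular time shifts
#'
#' Each channel is shifted forward in time by an integer lag drawn uniformly
#' from `[0, width_s * fs)` samples, wrapping circularly (each channel's
#' sample multiset — and its periodogram — is preserved). Fresh lags are
#' drawn on every call, matching the protocol of re-staggering each time a
#' segment is selected.
#'
#' The default width `0.1 * sqrt(12)` s (~346 ms) gives the uniform shift
#' distribution a standard deviation of exactly 100 ms.
#'
#' @param segment channels x samples numeric matrix.
#' @param fs sampling frequency in Hz.
#' @param width_s width of the flat lag distribution in seconds; `NULL`
#'   gives the default.
#' @return same-shape matrix with per-channel circular shifts applied.
#' @export
stagger_surrogate <- function(segment, fs, width_s = NULL) {
  if (is.null(width_s)) width_s <- 0.1 * sqrt(12)
  segment <- as.matrix(segment)
  wn <- width_s * fs
  if (wn < 1) stop("width_s * fs must be >= 1 sample")
  lags <- floor(stats::runif(nrow(segment), 0, wn))
  apply_channel_lags(segment, lags)
}

#' Draw per-channel lags once for global staggering
#'
#' Global staggering uses one fixed lag per channel for every segment of an
#' experiment (default flat width 0.5 s), so the same desynchronization is
#' applied throughout; apply with [apply_channel_lags()].
#'
#' @param n_channels number of channels.
#' @param fs sampling frequency in Hz.
#' @param width_s flat-distribution width in seconds (default 0.5).
#' @param seed integer seed keying the experiment.
#' @return integer vector of lags in samples, in `[0, width_s * fs)`.
#' @export
global_stagger_lags <- function(n_channels, fs, width_s = 0.5, seed = 1L) {
  set.seed(seed)
  as.integer(floor(stats::runif(n_channels, 0, width_s * fs)))
}

#' Apply fixed per-channel circular forward shifts
#' @param segment channels x samples matrix.
#' @param lags integer vector of per-channel lags in samples.
#' @return shifted matrix: output sample `t` of channel `i` is input sample
#'   `t - lags[i]` (mod segment length).
#' @export
apply_channel_lags <- function(segment, lags) {
  segment <- as.matrix(segment)
  T <- ncol(segment)
  stopifnot(length(lags) == nrow(segment))
  out <- segment
  for (ch in seq_len(nrow(segment))) {
    l <- lags[ch] %% T
    if (l > 0) out[ch, ] <- segment[ch, c((T - l + 1L):T, 1L:(T - l))]
  }
  out
}
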