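#' Filter specification: notch combs plus bandpass edges
#'
#' @param notch_hz center frequencies (Hz) of line-noise notches; default the
#'   50 Hz mains fundamental and its first two harmonics.
#' @param notch_halfwidth_hz half-band (Hz) excluded around each notch center.
#' @param band_lo_hz,band_hi_hz passband edges in Hz.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(notch_hz = c(50, 100, 150), notch_halfwidth_hz = 1,
                        band_lo_hz = 5, band_hi_hz = 500) {
  if (!(band_lo_hz > 0 && band_lo_hz < band_hi_hz))
    stop("need 0 < band_lo_hz < band_hi_hz")
  if (notch_halfwidth_hz <= 0) stop("notch_halfwidth_hz must be > 0")
  structure(list(notch_hz = as.numeric(notch_hz),
                 notch_halfwidth_hz = notch_halfwidth_hz,
                 band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz),
            class = "filter_spec")
}

#' Zero-phase ideal (brick-wall) filtering of all channels
#'
#' Each channel is Fourier transformed, coefficients outside
#' `[band_lo_hz, band_hi_hz]` or inside any notch band are zeroed, retained
#' coefficients are left untouched, and the signal is inverse transformed.
#' The mask is a function of absolute frequency, so Hermitian symmetry is
#' preserved and the output is real with exactly zero phase shift. Applying
#' the same spec twice is a no-op (masking is a projection).
#'
#' No taper is applied; segments are assumed long relative to the lowest
#' passband period.
#'
#' @param rec a [recording()].
#' @param spec a [filter_spec()]; edges must respect `fs/2`.
#' @return filtered [recording()] of identical shape.
#' @examples
#' rec <- recording(matrix(sin(2 * pi * 20 * (0:999) / 1000), 1), fs = 1000)
#' filtered <- ideal_filter(rec, filter_spec())
#' @export
ideal_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "filter_spec"))
  T <- ncol(rec$data)
  if (T < 4L) stop("need at least 4 samples to filter")
  if (spec$band_hi_hz > rec$fs / 2 + 1e-9)
    stop("spec error: band_hi_hz exceeds Nyquist frequency ", rec$fs / 2)
  if (any(spec$notch_hz <= 0 | spec$notch_hz >= rec$fs / 2))
    stop("spec error: notch centers must lie in (0, fs/2)")
  freqs <- (0:(T - 1)) * rec$fs / T
  fa <- pmin(freqs, rec$fs - freqs)          # absolute (folded) frequency
  tol <- 1e-9
  keep <- fa >= spec$band_lo_hz - tol & fa <= spec$band_hi_hz + tol
  for (nc in spec$notch_hz)
    keep <- keep & abs(fa - nc) > spec$notch_halfwidth_hz - tol
  F <- stats::mvfft(t(rec$data))             # columns = channels
  F[!keep, ] <- 0
  out <- Re(t(stats::mvfft(F, inverse = TRUE))) / T
  recording(out, fs = rec$fs, channel_ids = rec$channel_ids, meta = rec$meta)
}
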