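#' Spectral (FFT) feature vector for one segment
#'
#' Per channel, the discrete Fourier power at frequencies strictly between 0
#' and 100 Hz (DC excluded, no taper); the logarithm is taken per channel
#' with a relative floor, and the vector is the mean of the per-channel
#' log-power across channels. The dimension is the number of Fourier bins
#' `k / Delta` Hz with `0 < k / Delta < 100`, so it depends only on the
#' segment duration and sampling rate.
#'
#' @param segment channels x samples numeric matrix (>= 4 samples).
#' @param fs sampling frequency in Hz.
#' @param floor_rel relative power floor: per channel, powers below
#'   `floor_rel * max(power)` are clamped before the log (guards all-zero
#'   channels; a warning is emitted when the floor engages).
#' @return object of class `fft_vector`: list with `values` (mean log-power),
#'   `freqs_hz`, `window_s`.
#' @examples
#' seg <- matrix(sin(2 * pi * 10 * (0:1999) / 1000), 1)
#' v <- make_fft_vector(seg, fs = 1000)
#' v$freqs_hz[which.max(v$values)]   # 10 Hz
#' @export
make_fft_vector <- function(segment, fs, floor_rel = 1e-20) {
  segment <- as.matrix(segment)
  T <- ncol(segment)
  if (T < 4L) stop("need at least 4 samples")
  delta_s <- T / fs
  kmax <- ceiling(100 * delta_s) - 1L          # largest k with k/Delta < 100
  kmax <- min(kmax, floor((T - 1) / 2))        # stay below Nyquist
  if (kmax < 1L) stop("segment too short: no Fourier bins below 100 Hz")
  F <- stats::mvfft(t(segment))                # columns = channels
  p <- Mod(F[2:(kmax + 1L), , drop = FALSE])^2 # DC excluded
  pmaxs <- apply(p, 2, max)
  floored <- FALSE
  for (j in seq_len(ncol(p))) {
    fl <- if (pmaxs[j] > 0) floor_rel * pmaxs[j] else .Machine$double.xmin
    if (any(p[, j] < fl)) floored <- TRUE
    p[, j] <- pmax(p[, j], fl)
  }
  if (floored) warning("power floor engaged for at least one channel")
  structure(list(values = rowMeans(log(p)),
                 freqs_hz = (1:kmax) / delta_s,
                 window_s = delta_s),
            class = "fft_vector")
}

#' @export
print.fft_vector <- function(x, ...) {
  cat(sprintf("<fft_vector> dim %d (%.2g-%.4g Hz, Delta = %g s)\n",
              length(x$values), x$freqs_hz[1], max(x$freqs_hz), x$window_s))
  invisible(x)
}

#' Build a labeled set of FFT vectors from a recording
#'
#' Spectral counterpart of [make_ds_vectors()]: same segment layout and
#' labeling, but each vector is the channel-averaged log-power below 100 Hz.
#'
#' @inheritParams make_ds_vectors
#' @return a [feature_set()] with `source = "fft"`.
#' @export
make_fft_vectors <- function(rec, intervals, window_s, n_per_interval = 500,
                             surrogate = c("none", "phase", "stagger",
                                           "global_stagger"),
                             seed = 1L, stagger_width_s = NULL) {
  surrogate <- match.arg(surrogate)
  stopifnot(inherits(rec, "recording"), inherits(intervals, "state_intervals"))
  set.seed(seed)
  lags <- NULL
  if (surrogate == "global_stagger")
    lags <- global_stagger_lags(nrow(rec$data), fs = rec$fs,
                                width_s = if (is.null(stagger_width_s)) 0.5
                                          else stagger_width_s,
                                seed = seed)
  tri <- trimmed_intervals(intervals)
  rows <- list(); labs <- character(0)
  for (i in seq_len(nrow(tri))) {
    starts <- extract_segment_starts(tri[i, ], window_s, n_per_interval)
    for (s in starts) {
      seg <- rec_segment(rec, s, window_s)
      seg <- switch(surrogate,
        none = seg,
        phase = phase_surrogate(seg),
        stagger = stagger_surrogate(seg, fs = rec$fs,
                                    width_s = stagger_width_s),
        global_stagger = apply_channel_lags(seg, lags))
      rows[[length(rows) + 1L]] <- make_fft_vector(seg, rec$fs)$values
      labs <- c(labs, tri$label[i])
    }
  }
  feature_set(do.call(rbind, rows), labs, window_s = window_s,
              source = "fft", surrogate = surrogate, seed = seed)
}
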