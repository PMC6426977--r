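#' Multichannel recording container
#'
#' A `recording` holds a channels-by-samples numeric matrix together with its
#' sampling rate and channel metadata. Sample `k` (0-based) covers time
#' `k * dt` seconds from recording start; all time intervals in this package
#' are half-open `[start_s, end_s)`.
#'
#' @param data numeric matrix, channels (rows) by samples (columns). A vector
#'   is treated as a single channel.
#' @param fs sampling frequency in Hz.
#' @param channel_ids optional character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param meta free-form named list of provenance information.
#'
#' @return An object of class `recording` with elements `data`, `fs`, `dt`
#'   (`= 1/fs`), `channel_ids` and `meta`.
#' @examples
#' rec <- recording(matrix(rnorm(4000), 4, 1000), fs = 1000)
#' rec
#' @export
recording <- function(data, fs, channel_ids = NULL, meta = list()) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 2L)
    stop("recording needs at least 1 channel and 2 samples")
  if (!all(is.finite(data)))
    stop("recording data contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data))
    stop("`channel_ids` length must equal the number of channels")
  structure(list(
    data = unname(data),
    fs = as.numeric(fs),
    dt = 1 / as.numeric(fs),
    channel_ids = as.character(channel_ids),
    meta = meta
  ), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) * x$dt))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @return length in seconds (`n_samples * dt`).
#' @export
rec_duration <- function(rec) ncol(rec$data) * rec$dt

#' Extract a time segment from a recording
#'
#' Returns the channels-by-samples submatrix covering the half-open time
#' window `[start_s, start_s + len_s)`.
#'
#' @param rec a [recording()].
#' @param start_s segment start in seconds from recording start.
#' @param len_s segment length in seconds.
#' @return numeric matrix, channels x `round(len_s * fs)` samples.
#' @export
rec_segment <- function(rec, start_s, len_s) {
  n <- round(len_s * rec$fs)
  i0 <- floor(start_s * rec$fs + 1e-9) + 1L   # 1-based first sample
  i1 <- i0 + n - 1L
  if (i0 < 1L || i1 > ncol(rec$data))
    stop(sprintf("segment [%g, %g) s outside recording of %g s",
                 start_s, start_s + len_s, rec_duration(rec)))
  rec$data[, i0:i1, drop = FALSE]
}

#' State-interval annotations
#'
#' Behavioral state labels attached to time intervals of a recording, with a
#' trim margin removed at each end before any vector is drawn (guards against
#' mislabeling near state transitions; 30 s in the original full-length
#' experiments).
#'
#' @param label character vector, each `"awake"` or `"anesthetized"`.
#' @param start_s,end_s interval bounds in seconds (half-open).
#' @param trim_s margin in seconds removed from each end (recycled).
#' @return a `state_intervals` data frame with columns `label`, `start_s`,
#'   `end_s`, `trim_s`.
#' @examples
#' state_intervals(c("awake", "anesthetized"), c(0, 500), c(400, 900), trim_s = 30)
#' @export
state_intervals <- function(label, start_s, end_s, trim_s = 30) {
  label <- match.arg(label, c("awake", "anesthetized"), several.ok = TRUE)
  df <- data.frame(label = label, start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   trim_s = rep_len(as.numeric(trim_s), length(label)),
                   stringsAsFactors = FALSE)
  bad <- df$start_s + df$trim_s >= df$end_s - df$trim_s
  if (any(bad))
    stop("interval(s) empty after trimming: ",
         paste(which(bad), collapse = ", "))
  # intervals of different labels must be disjoint after trimming
  a <- df$start_s + df$trim_s; b <- df$end_s - df$trim_s
  n <- nrow(df)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (df$label[i] != df$label[j] && a[i] < b[j] && a[j] < b[i])
      stop("trimmed intervals of different labels overlap")
  }
  class(df) <- c("state_intervals", "data.frame")
  df
}

#' Trimmed bounds of state intervals
#' @param intervals a [state_intervals()] object.
#' @return data frame with `label`, `start_s`, `end_s` after trim removal.
#' @export
trimmed_intervals <- function(intervals) {
  data.frame(label = intervals$label,
             start_s = intervals$start_s + intervals$trim_s,
             end_s = intervals$end_s - intervals$trim_s,
             stringsAsFactors = FALSE)
}

#' Equally spaced segment start times within a trimmed interval
#'
#' Places `n` segment start times so the first segment begins at the trimmed
#' interval start and the last segment ends exactly at the trimmed interval
#' end. Segments may overlap for large `n` or `window_s`.
#'
#' @param interval one row of [trimmed_intervals()] output, or any list with
#'   `start_s` and `end_s` (already trimmed).
#' @param window_s segment length Delta in seconds.
#' @param n number of segments (>= 1).
#' @return numeric vector of `n` start times in seconds.
#' @examples
#' extract_segment_starts(list(start_s = 30, end_s = 130), window_s = 2, n = 5)
#' @export
extract_segment_starts <- function(interval, window_s, n) {
  a <- interval$start_s; b <- interval$end_s
  if (n < 1L) stop("`n` must be >= 1")
  if (b - a < window_s)
    stop(sprintf("infeasible: trimmed interval length %g s < window %g s",
                 b - a, window_s))
  if (n == 1L) return(a)
  seq(a, b - window_s, length.out = n)
}
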