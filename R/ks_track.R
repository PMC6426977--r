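#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum gap between the two empirical cumulative distribution
#' functions, computed over the pooled sorted values. Only the statistic is
#' returned (no p-value); it is invariant under any common strictly
#' monotone transform of both samples.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return the KS distance, in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 2, 3, 4), c(3, 4, 5, 6))   # 0.5
#' @export
ks_statistic <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a); sample_b <- as.numeric(sample_b)
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be nonempty")
  pooled <- sort(c(sample_a, sample_b))
  # ECDF of each sample evaluated just after every pooled point
  Fa <- findInterval(pooled, sort(sample_a)) / length(sample_a)
  Fb <- findInterval(pooled, sort(sample_b)) / length(sample_b)
  max(abs(Fa - Fb))
}

#' Track dynamical stabilization over a recording
#'
#' Slides a pooling window over the recording: at each timestamp, the
#' damping-timescale (`tau`) values of `pool_fits` consecutive `delta_s`
#' VAR(1) fits are pooled and compared, via the two-sample KS statistic, with
#' the pooled `tau` distribution of an initial reference window (typically
#' the first stretch of verified awake data). A stationary system yields a
#' flat series at the finite-sample baseline; stabilization (e.g. anesthesia
#' induction) drives the statistic up.
#'
#' @param rec a [recording()].
#' @param reference_window numeric `c(start_s, len_s)` of the reference.
#' @param step_s timestamp spacing in seconds.
#' @param pool_fits number of consecutive `delta_s` fits pooled per
#'   timestamp (default 20, i.e. 10 s of data).
#' @param delta_s fit window length in seconds (default 0.5).
#' @param include_intercept passed to [fit_var1()].
#' @param drop_infinite drop `tau = -Inf` (nilpotent) values from the pooled
#'   samples (default `TRUE`).
#' @return object of class `ks_series`: list with `times_s` (window
#'   centers), `ks`, `reference` (the window spec), `tau_reference`.
#' @export
track_stability <- function(rec, reference_window, step_s, pool_fits = 20,
                            delta_s = 0.5, include_intercept = TRUE,
                            drop_infinite = TRUE) {
  stopifnot(inherits(rec, "recording"), length(reference_window) == 2L)
  dur <- rec_duration(rec)
  win_len <- pool_fits * delta_s
  if (dur < reference_window[1] + reference_window[2] + step_s)
    stop("recording shorter than reference window plus one step")
  pool_tau <- function(start_s, len_s) {
    k <- floor(len_s / delta_s)
    seg <- rec_segment(rec, start_s, k * delta_s)
    tau <- unlist(lapply(segment_modes(seg, rec$fs, delta_s, k,
                                       include_intercept),
                         function(m) m$tau), use.names = FALSE)
    if (drop_infinite) tau <- tau[is.finite(tau)]
    tau
  }
  ref_tau <- pool_tau(reference_window[1], reference_window[2])
  starts <- seq(0, dur - win_len, by = step_s)
  ks <- vapply(starts, function(s) {
    tau <- pool_tau(s, win_len)
    if (length(tau) == 0L) return(NA_real_)
    ks_statistic(ref_tau, tau)
  }, numeric(1))
  structure(list(times_s = starts + win_len / 2, ks = ks,
                 reference = reference_window, tau_reference = ref_tau,
                 pool_fits = pool_fits, delta_s = delta_s),
            class = "ks_series")
}

#' @export
print.ks_series <- function(x, ...) {
  cat(sprintf("<ks_series> %d timestamps, KS in [%.3f, %.3f]\n",
              length(x$ks), min(x$ks, na.rm = TRUE),
              max(x$ks, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.ks_series <- function(x, ...) {
  graphics::plot(x$times_s, x$ks, type = "l", xlab = "time (s)",
                 ylab = "KS statistic", ylim = c(0, 1), ...)
  graphics::abline(v = x$reference[1] + x$reference[2] / 2, lty = 3)
  invisible(x)
}
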