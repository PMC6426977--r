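#' Coarse-graining grid for dynamical-stability vectors
#'
#' A 20 x 20 histogram grid over the mode plane: growth rate `tau` binned
#' linearly over `[-250, 25]` 1/s, frequency binned logarithmically (base 2)
#' over `[4, 256]` Hz. Flattening is row-major over `tau` rows (frequency
#' varying fastest), yielding feature vectors of dimension 400. The ranges
#' bracket where awake and anesthetized mode distributions differ most;
#' roughly half of all fitted eigenvalues fall inside.
#'
#' @param tau_range growth-rate range in 1/s.
#' @param f_range frequency range in Hz.
#' @param n_tau_bins,n_f_bins bin counts.
#' @return object of class `ds_grid` with the bin edges and dimensions.
#' @export
ds_grid <- function(tau_range = c(-250, 25), f_range = c(4, 256),
                    n_tau_bins = 20, n_f_bins = 20) {
  stopifnot(tau_range[1] < tau_range[2], f_range[1] > 0,
            f_range[1] < f_range[2], n_tau_bins >= 1, n_f_bins >= 1)
  structure(list(
    tau_range = tau_range, f_range = f_range,
    n_tau_bins = n_tau_bins, n_f_bins = n_f_bins,
    tau_edges = seq(tau_range[1], tau_range[2], length.out = n_tau_bins + 1),
    log2f_edges = seq(log2(f_range[1]), log2(f_range[2]),
                      length.out = n_f_bins + 1),
    dim = n_tau_bins * n_f_bins
  ), class = "ds_grid")
}

# half-open [lo, hi) bins, final bin closed at the top; NA if out of range
bin_index <- function(x, edges) {
  n <- length(edges) - 1L
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[x < edges[1] | x > edges[n + 1L]] <- NA_integer_
  i[i == 0L] <- NA_integer_
  i
}

#' Bin pooled eigen-modes on a DS grid
#'
#' Each mode with `tau` and `f` inside the grid ranges increments exactly one
#' cell; the final bin in each direction is closed at the top edge so modes
#' exactly at the upper bound are kept. Out-of-range modes (including real
#' modes at `f = 0` and nilpotent `tau = -Inf` modes) are dropped and
#' counted.
#'
#' @param modes a `mode_set` from [eig_modes()], a data frame with `tau` and
#'   `f` columns, or a list of such objects (pooled).
#' @param grid a [ds_grid()].
#' @return object of class `ds_vector`: list with `counts` (length
#'   `grid$dim`, nonnegative integers), `n_modes_total`, `n_modes_in_range`.
#' @examples
#' m <- data.frame(tau = -100, f = 16)
#' which(bin_modes(m, ds_grid())$counts > 0)   # flat index 207 (1-based)
#' @export
bin_modes <- function(modes, grid = ds_grid()) {
  if (is.data.frame(modes)) modes <- list(modes)
  tau <- unlist(lapply(modes, function(m) m$tau), use.names = FALSE)
  f <- unlist(lapply(modes, function(m) m$f), use.names = FALSE)
  it <- bin_index(tau, grid$tau_edges)
  jf <- bin_index(log2(f), grid$log2f_edges)
  ok <- !is.na(it) & !is.na(jf)
  flat <- (it[ok] - 1L) * grid$n_f_bins + jf[ok]   # tau rows, f fastest
  counts <- tabulate(flat, nbins = grid$dim)
  structure(list(counts = counts,
                 n_modes_total = length(tau),
                 n_modes_in_range = sum(ok)),
            class = "ds_vector")
}

#' @export
print.ds_vector <- function(x, ...) {
  cat(sprintf("<ds_vector> dim %d, %d/%d modes in range\n",
              length(x$counts), x$n_modes_in_range, x$n_modes_total))
  invisible(x)
}

#' Equally spaced sub-window start times within a segment
#'
#' Places `k` sub-window starts from the segment start to
#' `segment_start + window_s - delta_s` inclusive. For `window_s < k *
#' delta_s` the sub-windows overlap; at `window_s = k * delta_s` they tile
#' the segment exactly; at `window_s = delta_s` all starts coincide
#' (degenerate but allowed).
#'
#' @param segment_start_s segment start (seconds).
#' @param window_s segment length Delta in seconds (`>= delta_s`).
#' @param delta_s sub-window (fit) length in seconds, default 0.5.
#' @param k number of sub-windows, default 10.
#' @return numeric vector of `k` start times.
#' @export
subwindow_starts <- function(segment_start_s, window_s, delta_s = 0.5,
                             k = 10) {
  if (window_s < delta_s)
    stop(sprintf("infeasible: window %g s shorter than sub-window %g s",
                 window_s, delta_s))
  if (k == 1L) return(segment_start_s)
  seq(segment_start_s, segment_start_s + window_s - delta_s, length.out = k)
}

#' Pooled mode sets from equally spaced sub-window fits of one segment
#'
#' Fits `k` VAR(1) models on equally spaced `delta_s` sub-windows of the
#' segment and returns their mode sets — the sampling step behind both DS
#' vectors and the KS stability track.
#'
#' @param seg channels x samples matrix.
#' @param fs sampling frequency in Hz.
#' @param delta_s,k sub-window length (s) and count.
#' @param include_intercept passed to [fit_var1()].
#' @return list of `k` [eig_modes()] mode sets.
#' @export
segment_modes <- function(seg, fs, delta_s = 0.5, k = 10,
                          include_intercept = TRUE) {
  n_sub <- round(delta_s * fs)
  offs <- subwindow_starts(0, ncol(seg) / fs, delta_s, k)
  lapply(offs, function(o) {
    i0 <- floor(o * fs + 1e-9) + 1L
    sub <- seg[, i0:(i0 + n_sub - 1L), drop = FALSE]
    eig_modes(fit_var1(sub, dt = 1 / fs,
                       include_intercept = include_intercept))
  })
}

#' Build a labeled set of DS vectors from a recording
#'
#' For each trimmed state interval, draws `n_per_interval` equally spaced
#' segments of length `window_s`; for each segment, pools the eigen-modes of
#' `k_fits` equally spaced VAR(1) fits on `delta_s` sub-windows and bins
#' them on `grid`. When `surrogate != "none"` the corresponding surrogate
#' transform is applied to each segment before fitting (global-stagger lags
#' are drawn once per call and reused for every segment).
#'
#' Vectors carry raw bin counts; set `normalize = TRUE` for per-vector L1
#' normalization (the classifier standardizes features, so scale is
#' absorbed either way).
#'
#' @param rec a [recording()].
#' @param intervals a [state_intervals()] object.
#' @param window_s segment length Delta in seconds.
#' @param n_per_interval vectors per interval (500 in the full-scale
#'   protocol; reducible for desk-scale runs).
#' @param surrogate one of `"none"`, `"phase"`, `"stagger"`,
#'   `"global_stagger"`.
#' @param seed integer seed controlling all surrogate randomness.
#' @param grid a [ds_grid()].
#' @param delta_s,k_fits sub-window length and count (defaults 0.5 s, 10).
#' @param include_intercept passed to [fit_var1()].
#' @param normalize L1-normalize each vector (default `FALSE`).
#' @param stagger_width_s override the surrogate shift-distribution width.
#' @return a [feature_set()] with `n_per_interval * nrow(intervals)` rows of
#'   dimension `grid$dim`.
#' @export
make_ds_vectors <- function(rec, intervals, window_s, n_per_interval = 500,
                            surrogate = c("none", "phase", "stagger",
                                          "global_stagger"),
                            seed = 1L, grid = ds_grid(), delta_s = 0.5,
                            k_fits = 10, include_intercept = TRUE,
                            normalize = FALSE, stagger_width_s = NULL) {
  surrogate <- match.arg(surrogate)
  stopifnot(inherits(rec, "recording"), inherits(intervals, "state_intervals"))
  set.seed(seed)
  N <- nrow(rec$data)
  lags <- NULL
  if (surrogate == "global_stagger")
    lags <- global_stagger_lags(N, fs = rec$fs,
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
      dv <- bin_modes(segment_modes(seg, rec$fs, delta_s, k_fits,
                                    include_intercept), grid)
      v <- dv$counts
      if (normalize && sum(v) > 0) v <- v / sum(v)
      rows[[length(rows) + 1L]] <- v
      labs <- c(labs, tri$label[i])
    }
  }
  feature_set(do.call(rbind, rows), labs, window_s = window_s, source = "ds",
              surrogate = surrogate, seed = seed,
              extra = list(delta_s = delta_s, k_fits = k_fits))
}
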