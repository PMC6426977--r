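# Independent brute-force oracles and tiny fixture builders.

# KS distance by direct ECDF evaluation at every pooled point
brute_ks <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# 2-D histogram by explicit double loop over cells ([lo, hi), last closed),
# flattened tau-row-major with frequency fastest
brute_bin <- function(tau, f, grid) {
  counts <- numeric(grid$dim)
  te <- grid$tau_edges; fe <- grid$log2f_edges
  lf <- log2(f)
  for (i in seq_len(grid$n_tau_bins)) for (j in seq_len(grid$n_f_bins)) {
    in_t <- tau >= te[i] & (tau < te[i + 1] |
                              (i == grid$n_tau_bins & tau == te[i + 1]))
    in_f <- lf >= fe[j] & (lf < fe[j + 1] |
                             (j == grid$n_f_bins & lf == fe[j + 1]))
    counts[(i - 1) * grid$n_f_bins + j] <- sum(in_t & in_f)
  }
  counts
}

# noiseless trajectory of y_{n+1} = A y_n from a given start
noiseless_traj <- function(A, y0, n) {
  Y <- matrix(0, length(y0), n)
  y <- y0
  for (i in seq_len(n)) { Y[, i] <- y; y <- A %*% y }
  Y
}

# small multichannel sine-mix recording for io/filter tests
toy_recording <- function(n_ch = 4, T = 1000, fs = 1000, seed = 42) {
  set.seed(seed)
  t <- (0:(T - 1)) / fs
  data <- t(sapply(seq_len(n_ch), function(i)
    sin(2 * pi * (5 * i) * t) + 0.1 * rnorm(T)))
  recording(data, fs = fs, meta = list(origin = "toy"))
}
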