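test_that("sub-window starts follow the equal-spacing rule", {
  expect_equal(subwindow_starts(0, 5, 0.5, 10), seq(0, 4.5, by = 0.5))
  expect_equal(subwindow_starts(0, 0.5, 0.5, 10), rep(0, 10))   # degenerate
  expect_equal(diff(subwindow_starts(0, 2, 0.5, 10))[1], 1.5 / 9)
  expect_equal(subwindow_starts(12, 2, 0.5, 10)[1], 12)
  expect_error(subwindow_starts(0, 0.4, 0.5, 10), "infeasible")
})

test_that("the DS grid has the documented geometry", {
  g <- ds_grid()
  expect_equal(g$dim, 400)
  expect_equal(length(g$tau_edges), 21)
  expect_true(all(diff(g$tau_edges) > 0))
  expect_equal(diff(g$tau_edges)[1], 13.75)
  expect_equal(g$log2f_edges, seq(2, 8, by = 0.3))
})

test_that("single-mode binning lands on the derived flat index", {
  dv <- bin_modes(data.frame(tau = -100, f = 16), ds_grid())
  expect_equal(which(dv$counts > 0), 207L)   # 0-based 206
  expect_equal(sum(dv$counts), 1)
})

test_that("binning conserves counts and matches a brute-force histogram", {
  g <- ds_grid()
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(c(10, 1000, 10000), 1)
    tau <- runif(n, -300, 50)
    f <- 2^runif(n, 1.5, 8.5)
    dv <- bin_modes(data.frame(tau = tau, f = f), g)
    expect_equal(dv$counts, brute_bin(tau, f, g))
    expect_equal(sum(dv$counts), dv$n_modes_in_range)
    expect_equal(dv$n_modes_total, n)
  }
  # boundary semantics: [lo, hi) except the final bin closed at the top
  edge <- bin_modes(data.frame(tau = c(-250, 25, -250), f = c(4, 256, 256)), g)
  expect_equal(sum(edge$counts), 3)
  expect_equal(bin_modes(data.frame(tau = 25 + 1e-9, f = 16), g)$n_modes_in_range, 0)
  expect_equal(bin_modes(data.frame(tau = numeric(0), f = numeric(0)),
                         g)$counts, rep(0, 400))
})

test_that("DS feature sets have the right shape, counts and determinism", {
  sr <- make_two_state_recording(durations_s = c(20, 20), seed = 6,
                                 n_channels = 8)
  fs <- make_ds_vectors(sr$recording, sr$intervals, window_s = 1,
                        n_per_interval = 4, seed = 2)
  expect_equal(dim(fs$vectors), c(8L, 400L))
  expect_equal(as.integer(table(fs$labels)), c(4L, 4L))
  # count conservation: k_fits x N modes per vector, minus out-of-range
  expect_true(all(rowSums(fs$vectors) <= 10 * 8))
  expect_true(all(rowSums(fs$vectors) > 0))

  fs2 <- make_ds_vectors(sr$recording, sr$intervals, window_s = 1,
                         n_per_interval = 4, seed = 2)
  expect_identical(fs$vectors, fs2$vectors)     # determinism

  sa <- make_ds_vectors(sr$recording, sr$intervals, 1, 4,
                        surrogate = "stagger", seed = 3)
  sb <- make_ds_vectors(sr$recording, sr$intervals, 1, 4,
                        surrogate = "stagger", seed = 4)
  expect_equal(dim(sa$vectors), dim(sb$vectors))
  expect_false(identical(sa$vectors, sb$vectors))  # fresh lags per seed
})

test_that("a uniform stabilization shift moves the count-weighted mean tau", {
  g <- ds_grid()
  sr <- make_two_state_recording(
    awake = awake_regime(8, tau_range = c(-60, -40), seed = 9),
    anesthetized = awake_regime(8, tau_range = c(-110, -90), seed = 9),
    durations_s = c(20, 20), seed = 9, n_channels = 8)
  fs <- make_ds_vectors(sr$recording, sr$intervals, 1, 6, seed = 5)
  centers <- (head(g$tau_edges, -1) + tail(g$tau_edges, -1)) / 2
  tau_cell <- rep(centers, each = g$n_f_bins)
  mean_tau <- apply(fs$vectors, 1, function(v) sum(v * tau_cell) / sum(v))
  m_aw <- mean(mean_tau[fs$labels == "awake"])
  m_an <- mean(mean_tau[fs$labels == "anesthetized"])
  expect_lt(m_an, m_aw - 25)   # designed -50 1/s shift, within bin resolution
})
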