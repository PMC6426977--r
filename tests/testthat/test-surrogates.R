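test_that("phase surrogation preserves each channel's power spectrum", {
  set.seed(21)
  for (T in c(128, 129)) {                      # even and odd lengths
    seg <- matrix(rnorm(3 * T), 3)
    out <- phase_surrogate(seg)
    expect_equal(dim(out), dim(seg))
    expect_true(is.numeric(out))
    for (ch in 1:3)
      expect_equal(Mod(fft(out[ch, ])), Mod(fft(seg[ch, ])),
                   tolerance = 1e-10)
  }
  expect_equal(phase_surrogate(matrix(0, 2, 64)), matrix(0, 2, 64))
})

test_that("a phase-surrogated tone stays a unit tone with shifted phase", {
  t <- (0:999) / 1000
  x <- sin(2 * pi * 10 * t)
  set.seed(5)
  y <- phase_surrogate(matrix(x, 1))[1, ]
  # single spectral line: output must be A*sin(2 pi 10 t + phi) with A = 1
  expect_equal(max(Mod(fft(y))), max(Mod(fft(x))), tolerance = 1e-8)
  expect_equal(sqrt(mean(y^2)), sqrt(mean(x^2)), tolerance = 1e-8)
  expect_gt(max(abs(y - x)), 1e-3)              # phase actually moved
})

test_that("phase surrogation decorrelates channels sharing a source", {
  set.seed(6)
  src <- as.numeric(stats::filter(rnorm(2064), rep(0.15, 4),
                                  "recursive"))[65:2064]
  seg <- rbind(src, src)                        # perfectly correlated pair
  cors <- vapply(1:40, function(i) {
    out <- phase_surrogate(seg)
    cor(out[1, ], out[2, ])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
  expect_equal(cor(seg[1, ], seg[2, ]), 1)
})

test_that("staggering is a per-channel circular permutation with bounded lags", {
  set.seed(9)
  seg <- matrix(rnorm(4 * 1000), 4)
  out <- stagger_surrogate(seg, fs = 1000)      # default width 0.1*sqrt(12) s
  for (ch in 1:4) {
    expect_equal(sort(out[ch, ]), sort(seg[ch, ]))          # multiset kept
    expect_equal(Mod(fft(out[ch, ])), Mod(fft(seg[ch, ])),  # spectrum kept
                 tolerance = 1e-9)
  }
  # identity under zero lag
  expect_identical(apply_channel_lags(seg, rep(0L, 4)), seg)
  # shift-forward convention: y[t] = x[t - lag]
  x <- matrix(1:10, 1)
  expect_equal(drop(apply_channel_lags(x, 3L)), c(8, 9, 10, 1:7))
})

test_that("stagger lags respect the flat-width arithmetic", {
  set.seed(10)
  lags <- replicate(500, {
    seg <- matrix(seq_len(400), 1)
    out <- stagger_surrogate(seg, fs = 1000)    # width 0.1*sqrt(12) s -> <347
    which(out[1, ] == 1) - 1L
  })
  expect_true(all(lags >= 0 & lags < ceiling(0.1 * sqrt(12) * 1000)))
  expect_gt(max(lags), 300)                     # actually spans the range
})

test_that("global stagger lags are drawn once, deterministically per seed", {
  l1 <- global_stagger_lags(16, fs = 1000, seed = 3)
  l2 <- global_stagger_lags(16, fs = 1000, seed = 3)
  l3 <- global_stagger_lags(16, fs = 1000, seed = 4)
  expect_identical(l1, l2)
  expect_false(identical(l1, l3))
  expect_true(all(l1 >= 0 & l1 < 500))          # 0.5 s at 1 kHz
})

test_that("surrogation perturbs DS distributions beyond resampling noise", {
  sr <- make_two_state_recording(durations_s = c(24, 20), seed = 13,
                                 n_channels = 8)
  seg <- rec_segment(sr$recording, 2, 10)
  tau_of <- function(m) unlist(lapply(m, function(x)
    x$tau[is.finite(x$tau)]))
  base <- tau_of(segment_modes(seg, 1000))
  resamp <- tau_of(segment_modes(rec_segment(sr$recording, 12, 10), 1000))
  set.seed(2)
  surr <- tau_of(segment_modes(stagger_surrogate(seg, 1000), 1000))
  expect_gt(ks_statistic(base, surr), ks_statistic(base, resamp))
})
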