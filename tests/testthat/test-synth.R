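test_that("generator spectrum equals the design exactly, mixed or not", {
  spec <- regime_spec(8, data.frame(f = c(10, 40, 80, 120),
                                    tau = c(0, -20, -60, -120)),
                      mixing = FALSE, seed = 1)
  dt <- 0.001
  A <- build_generator(spec, dt)
  target <- sort(exp((spec$modes$tau + 2i * pi * spec$modes$f) * dt))
  got <- eigen(A, only.values = TRUE)$values
  got <- sort(got[Im(got) > 0])
  expect_equal(got, target, tolerance = 1e-12)

  specm <- regime_spec(8, spec$modes, mixing = TRUE, seed = 2)
  Am <- build_generator(specm, dt)
  expect_equal(sort(Mod(eigen(Am)$values)), sort(Mod(eigen(A)$values)),
               tolerance = 1e-12)
  # single marginal pair at 10 Hz sits on the unit circle at angle 0.02*pi
  A1 <- build_generator(regime_spec(2, data.frame(f = 10, tau = 0),
                                    mixing = FALSE), dt)
  ev <- eigen(A1)$values
  expect_equal(Mod(ev), c(1, 1), tolerance = 1e-14)
  expect_equal(sort(Arg(ev)), c(-0.02 * pi, 0.02 * pi), tolerance = 1e-12)
  # tau = -250 -> radius exp(-0.25)
  A2 <- build_generator(regime_spec(2, data.frame(f = 10, tau = -250),
                                    mixing = FALSE), dt)
  expect_equal(Mod(eigen(A2)$values)[1], exp(-0.25), tolerance = 1e-14)
})

test_that("generator validates dimensions and frequency bounds", {
  expect_error(regime_spec(8, data.frame(f = 10, tau = 0)), "mode rows")
  expect_error(regime_spec(4, data.frame(f = c(1, 2), tau = c(100, 0))),
               "tau_max")
  spec <- regime_spec(2, data.frame(f = 600, tau = 0))
  expect_error(build_generator(spec, dt = 0.001), "Nyquist")
  # odd N carries one trailing real mode
  spec3 <- regime_spec(3, data.frame(f = c(10, 0), tau = c(-5, -50)))
  ev <- eigen(build_generator(spec3, 0.001))$values
  expect_equal(sum(abs(Im(ev)) < 1e-12), 1L)
})

test_that("simulation is seed-deterministic and decays noiselessly", {
  A <- build_generator(awake_regime(8, tau_range = c(-40, -10), seed = 3),
                       dt = 0.001)
  y1 <- simulate_system(A, 1, 500, seed = 4)
  y2 <- simulate_system(A, 1, 500, seed = 4)
  expect_identical(y1, y2)
  expect_false(identical(y1, simulate_system(A, 1, 500, seed = 5)))

  # noise-free flow contracts at the spectral radius
  set.seed(6)
  y <- simulate_system(A, 0, 2000, burn_in = 0, init = rnorm(8))
  rho_max <- max(Mod(eigen(A)$values))
  n0 <- sqrt(sum(y[, 100]^2)); n1 <- sqrt(sum(y[, 1100]^2))
  expect_equal(log(n1 / n0) / 1000, log(rho_max), tolerance = 5e-3)

  expect_error(simulate_system(matrix(1.05), 1, 2000, seed = 1), "diverged")
})

test_that("fitted modes recover the design targets from simulated data", {
  spec <- awake_regime(16, seed = 8)
  A <- build_generator(spec, dt = 0.001)
  y <- simulate_system(A, 1, 10000, seed = 8)
  fit <- fit_var1(y, dt = 0.001)
  m <- match_modes(eig_modes(fit), spec$modes)
  expect_lt(max(abs(m$dtau)), 5)
  expect_lt(max(abs(m$df)), 1)
})

test_that("two-state recordings carry consistent labels and bookkeeping", {
  sr <- make_two_state_recording(durations_s = c(20, 16), fs = 500,
                                 seed = 9, gap_s = 4, n_channels = 8)
  expect_equal(ncol(sr$recording$data), (20 + 4 + 16) * 500)
  expect_equal(sr$intervals$label, c("awake", "anesthetized"))
  expect_equal(sr$intervals$trim_s, 0.05 * c(20, 16))
  expect_equal(sort(Mod(eigen(sr$A_true$awake)$values)),
               sort(exp(sr$specs$awake$modes$tau[rep(1:4, each = 2)] / 500)),
               tolerance = 1e-12)

  # DS mean tau moves in the designed direction between intervals
  fs <- make_ds_vectors(sr$recording, sr$intervals, 1, 5, seed = 10)
  g <- ds_grid()
  centers <- (head(g$tau_edges, -1) + tail(g$tau_edges, -1)) / 2
  tau_cell <- rep(centers, each = g$n_f_bins)
  mt <- apply(fs$vectors, 1, function(v) sum(v * tau_cell) / sum(v))
  expect_lt(mean(mt[fs$labels == "anesthetized"]),
            mean(mt[fs$labels == "awake"]))
})

test_that("matched-spectra recordings hide the class from spectra", {
  sr <- make_two_state_recording(durations_s = c(20, 20), seed = 11,
                                 n_channels = 8, matched_spectra = TRUE)
  ff <- make_fft_vectors(sr$recording, sr$intervals, 1, 12, seed = 12)
  # per-dimension two-sample tests: essentially nothing significant
  pvals <- vapply(seq_len(ncol(ff$vectors)), function(j)
    suppressWarnings(stats::ks.test(
      ff$vectors[ff$labels == "awake", j],
      ff$vectors[ff$labels == "anesthetized", j])$p.value), numeric(1))
  expect_gt(mean(pvals > 0.01), 0.9)
})
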