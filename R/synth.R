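#' Regime specification for the synthetic generator
#'
#' A regime is a noise-driven linear system whose eigenvalues are placed at
#' chosen (frequency, growth-rate) coordinates: `floor(N/2)` conjugate pairs
#' (plus one real mode when `N` is odd). An "awake-like" regime puts its
#' modes near marginal stability (`tau` just below 0); an
#' "anesthetized-like" regime damps them strongly.
#'
#' @param n_channels system dimension `N`.
#' @param modes data frame with columns `f` (Hz) and `tau` (1/s), one row
#'   per conjugate pair (plus one trailing real mode, `f = 0`, if `N` odd).
#' @param noise_sd innovation standard deviation.
#' @param mixing conjugate the block-diagonal generator by a random
#'   orthogonal matrix so every channel mixes every mode (default `TRUE`).
#' @param seed integer seed (orthogonal mixing draw).
#' @param tau_max upper bound on design growth rates; mildly unstable modes
#'   are allowed but bounded so finite segments do not overflow.
#' @return object of class `regime_spec`.
#' @export
regime_spec <- function(n_channels, modes, noise_sd = 1, mixing = TRUE,
                        seed = 1L, tau_max = 10) {
  modes <- as.data.frame(modes)
  stopifnot(all(c("f", "tau") %in% names(modes)))
  n_pairs <- n_channels %/% 2L
  n_real <- n_channels %% 2L
  if (nrow(modes) != n_pairs + n_real)
    stop(sprintf("need %d mode rows for N = %d (%d pairs%s)",
                 n_pairs + n_real, n_channels, n_pairs,
                 if (n_real) " + 1 real" else ""))
  if (any(modes$tau > tau_max))
    stop("design tau exceeds tau_max = ", tau_max, " 1/s")
  if (n_real && modes$f[nrow(modes)] != 0)
    stop("the trailing real mode (odd N) must have f = 0")
  structure(list(n_channels = as.integer(n_channels), modes = modes,
                 noise_sd = noise_sd, mixing = mixing,
                 seed = as.integer(seed)),
            class = "regime_spec")
}

#' Awake-like and anesthetized-like default regimes
#'
#' Shared log-spaced frequency layout spanning the DS grid's band; the awake
#' regime spreads growth rates over `[-20, 0]` 1/s (near-marginal), the
#' anesthetized regime over `[-150, -40]` 1/s (strongly damped). Both use
#' the same mixing seed, so the two generators differ only in their damping.
#'
#' @param n_channels system dimension.
#' @param tau_range growth-rate range covered by the pairs.
#' @param seed mixing seed.
#' @return a [regime_spec()].
#' @export
awake_regime <- function(n_channels = 16, tau_range = c(-20, 0), seed = 1L) {
  n_pairs <- n_channels %/% 2L
  modes <- data.frame(f = 2^seq(2.5, 7.5, length.out = n_pairs),
                      tau = seq(tau_range[1], tau_range[2],
                                length.out = n_pairs))
  if (n_channels %% 2L) modes <- rbind(modes, data.frame(f = 0, tau = -50))
  regime_spec(n_channels, modes, seed = seed)
}

#' @rdname awake_regime
#' @export
anesthetized_regime <- function(n_channels = 16, tau_range = c(-150, -40),
                                seed = 1L) {
  awake_regime(n_channels, tau_range, seed)
}

# Haar-distributed random orthogonal matrix (QR with sign fix)
random_orthogonal <- function(n, seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(n * n), n))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), n)
}

#' Build a generator matrix with a designed spectrum
#'
#' Assembles a block-diagonal real matrix from 2 x 2 rotation-scaling blocks
#' with radius `rho = exp(tau * dt)` and angle `theta = 2 * pi * f * dt` per
#' design mode (plus a scalar block for a real mode), then optionally
#' conjugates by a seeded random orthogonal matrix. The spectrum equals the
#' design exactly, before and after mixing.
#'
#' @param spec a [regime_spec()].
#' @param dt sample period in seconds.
#' @return `N x N` real matrix whose eigenvalues are
#'   `exp((tau + 2i * pi * f) * dt)` and conjugates.
#' @export
build_generator <- function(spec, dt) {
  stopifnot(inherits(spec, "regime_spec"))
  nyq <- 1 / (2 * dt)
  if (any(spec$modes$f >= nyq))
    stop("spec error: design frequency at or above Nyquist (", nyq, " Hz)")
  N <- spec$n_channels
  A <- matrix(0, N, N)
  r <- 1L
  for (i in seq_len(nrow(spec$modes))) {
    rho <- exp(spec$modes$tau[i] * dt)
    theta <- 2 * pi * spec$modes$f[i] * dt
    if (r == N) {                      # trailing real mode (odd N)
      A[r, r] <- rho
      r <- r + 1L
    } else {
      A[r:(r + 1L), r:(r + 1L)] <-
        rho * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
      r <- r + 2L
    }
  }
  if (spec$mixing) {
    Q <- random_orthogonal(N, spec$seed)
    A <- Q %*% A %*% t(Q)
  }
  A
}

#' Simulate a noise-driven linear system
#'
#' Iterates `y_{n+1} = A y_n + c + u_n` with i.i.d. Gaussian innovations
#' from a zero initial state, discarding a burn-in so stable regimes forget
#' the initial condition.
#'
#' @param A transition matrix.
#' @param noise_sd innovation standard deviation (0 gives the deterministic
#'   flow).
#' @param t_samples number of samples returned.
#' @param seed optional integer seed.
#' @param burn_in samples discarded before recording starts (default 2000).
#' @param init initial state (default zero).
#' @param intercept optional constant drive `c`.
#' @return channels x `t_samples` matrix.
#' @export
simulate_system <- function(A, noise_sd, t_samples, seed = NULL,
                            burn_in = 2000L, init = NULL, intercept = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(A)
  if (t_samples < 2L) stop("t_samples must be >= 2")
  total <- burn_in + t_samples
  U <- if (noise_sd > 0) matrix(stats::rnorm(N * total, sd = noise_sd),
                                N, total)
       else matrix(0, N, total)
  if (!is.null(intercept)) U <- U + intercept
  y <- if (is.null(init)) numeric(N) else init
  Y <- matrix(0, N, total)
  for (i in seq_len(total)) {
    y <- A %*% y + U[, i]
    Y[, i] <- y
  }
  if (!all(is.finite(Y)) || max(abs(Y)) > 1e12)
    stop("simulation error: trajectory diverged (unstable design?)")
  Y[, (burn_in + 1L):total, drop = FALSE]
}

#' Generate a labeled two-state synthetic recording
#'
#' Concatenates an awake-regime stretch and an anesthetized-regime stretch
#' with a guard gap in between (the gap continues the awake simulation so no
#' artificial discontinuity of statistics other than the regime switch
#' exists at the anesthetized onset). State intervals are pre-trimmed by 5%
#' of their duration at each end — the 30 s margin of the full-scale
#' (~600 s-interval) protocol scaled to the simulated durations.
#'
#' With `matched_spectra = TRUE` the "anesthetized" interval is instead an
#' independent realization of the *awake* regime with fixed per-channel
#' circular time shifts (flat width `0.5` s): each channel's power spectrum
#' is preserved exactly, so the two classes are indistinguishable to purely
#' spectral features, while the cross-channel coupling — and hence the
#' fitted eigenstructure — differs.
#'
#' @param awake,anesthetized [regime_spec()]s sharing `n_channels`;
#'   defaults: [awake_regime()] / [anesthetized_regime()].
#' @param durations_s lengths of the two labeled stretches in seconds.
#' @param fs sampling frequency in Hz.
#' @param seed integer seed (innovations, shifts).
#' @param gap_s guard gap between the intervals in seconds.
#' @param n_channels system dimension used for the default regimes.
#' @param matched_spectra use the spectra-matched construction above.
#' @param burn_in samples discarded before each stretch.
#' @return object of class `synthetic_recording`: list with `recording`,
#'   `intervals` ([state_intervals()]), `A_true` (named list of generator
#'   matrices), `specs`, `seed`.
#' @export
make_two_state_recording <- function(awake = NULL, anesthetized = NULL,
                                     durations_s = c(60, 60), fs = 1000,
                                     seed = 1L, gap_s = 10,
                                     n_channels = 16,
                                     matched_spectra = FALSE,
                                     burn_in = 2000L) {
  if (is.null(awake)) awake <- awake_regime(n_channels, seed = seed)
  if (is.null(anesthetized))
    anesthetized <- if (matched_spectra) awake
                    else anesthetized_regime(n_channels, seed = seed)
  stopifnot(awake$n_channels == anesthetized$n_channels)
  dt <- 1 / fs
  A_aw <- build_generator(awake, dt)
  A_an <- build_generator(anesthetized, dt)
  n1 <- round((durations_s[1] + gap_s) * fs)
  n2 <- round(durations_s[2] * fs)
  y1 <- simulate_system(A_aw, awake$noise_sd, n1, seed = seed,
                        burn_in = burn_in)
  y2 <- simulate_system(A_an, anesthetized$noise_sd, n2,
                        seed = seed + 7919L, burn_in = burn_in)
  if (matched_spectra) {
    lags <- global_stagger_lags(awake$n_channels, fs, width_s = 0.5,
                                seed = seed + 104729L)
    y2 <- apply_channel_lags(y2, lags)
  }
  rec <- recording(cbind(y1, y2), fs = fs,
                   meta = list(generator = "two_state_synthetic",
                               matched_spectra = matched_spectra,
                               seed = seed))
  iv <- state_intervals(
    c("awake", "anesthetized"),
    start_s = c(0, durations_s[1] + gap_s),
    end_s = c(durations_s[1], durations_s[1] + gap_s + durations_s[2]),
    trim_s = 0.05 * durations_s)
  structure(list(recording = rec, intervals = iv,
                 A_true = list(awake = A_aw, anesthetized = A_an),
                 specs = list(awake = awake, anesthetized = anesthetized),
                 matched_spectra = matched_spectra, seed = seed),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat("<synthetic_recording>",
      if (x$matched_spectra) "(matched spectra)" else "", "\n")
  print(x$recording)
  print.data.frame(as.data.frame(unclass(x$intervals)))
  invisible(x)
}

#' Match fitted modes to design modes
#'
#' For each design `(f, tau)` pair, finds the fitted mode minimizing a
#' scaled distance in the mode plane and reports the frequency and
#' growth-rate discrepancies — the parameter-recovery diagnostic for the
#' synthetic generator.
#'
#' @param fitted a `mode_set` from [eig_modes()].
#' @param design data frame with `f` and `tau` columns (design targets).
#' @param tau_scale growth-rate units equivalent to 1 Hz in the matching
#'   metric (default 25, i.e. the DS grid aspect ratio).
#' @return data frame with design and matched fitted coordinates plus
#'   `df` and `dtau` errors.
#' @export
match_modes <- function(fitted, design, tau_scale = 25) {
  design <- as.data.frame(design)
  out <- lapply(seq_len(nrow(design)), function(i) {
    d <- (fitted$f - design$f[i])^2 +
         ((fitted$tau - design$tau[i]) / tau_scale)^2
    j <- which.min(d)
    data.frame(f_design = design$f[i], tau_design = design$tau[i],
               f_fit = fitted$f[j], tau_fit = fitted$tau[j],
               df = fitted$f[j] - design$f[i],
               dtau = fitted$tau[j] - design$tau[i])
  })
  do.call(rbind, out)
}
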