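#' Fit a first-order vector autoregression to a short window
#'
#' Estimates `A` (and optionally an intercept `c`) in the linear stochastic
#' recurrence
#' \deqn{y_{n+1} = A y_n + c + u_n}
#' by minimum-norm least squares over all sample-to-sample transitions in the
#' window: a segment of `T` samples yields `T - 1` regression equations. The
#' solution uses the SVD pseudoinverse of the regressor matrix (singular
#' values below `rcond` times the largest are treated as zero); a
#' rank-deficient regressor produces the minimum-norm solution together with
#' a degenerate-fit warning.
#'
#' The intercept is a nuisance parameter: stability analysis uses the
#' eigenvalues of `A` only. It is fitted by default so that a nonzero signal
#' mean does not bias `A`; disabling it and demeaning the window first is an
#' equivalent path.
#'
#' @param segment numeric matrix, channels `N` x samples `T` (`T >= N + 2`
#'   recommended so the system is overdetermined), all values finite.
#' @param dt sample period in seconds (stored for the mode mapping).
#' @param include_intercept fit a per-channel constant term (default `TRUE`).
#' @param rcond relative singular-value cutoff for rank decisions.
#' @param window_start_s optional provenance: window start time in seconds.
#' @return an object of class `var1` with elements `A` (`N x N`), `intercept`
#'   (length `N`; zeros when disabled), `dt`, `residuals`
#'   (`N x (T-1)`), `fitted`, `sigma` (residual standard deviation),
#'   `rank`, `n_samples_used`, `window_start_s`, `window_len_s`.
#' @examples
#' y <- 0.9^(0:19)                      # scalar geometric decay
#' fit <- fit_var1(matrix(y, 1), dt = 0.001, include_intercept = FALSE)
#' coef(fit)                            # exactly 0.9
#' @export
fit_var1 <- function(segment, dt, include_intercept = TRUE, rcond = 1e-10,
                     window_start_s = NA_real_) {
  segment <- as.matrix(segment)
  if (!all(is.finite(segment))) stop("segment contains non-finite values")
  N <- nrow(segment); T <- ncol(segment)
  if (T < 3L) stop("need at least 3 samples (2 transitions)")
  Y1 <- segment[, 2:T, drop = FALSE]           # N x (T-1) responses
  Y0 <- segment[, 1:(T - 1), drop = FALSE]     # N x (T-1) regressors
  Z <- if (include_intercept) rbind(Y0, 1) else Y0
  # B = Y1 %*% pinv(Z), pinv via SVD with relative cutoff
  sv <- svd(Z)
  d <- sv$d
  keep <- d > rcond * d[1]
  r <- sum(keep)
  full_rank <- r == nrow(Z)
  if (!full_rank)
    warning(sprintf("degenerate fit: regressor rank %d < %d; %s",
                    r, nrow(Z), "minimum-norm solution returned"))
  dinv <- ifelse(keep, 1 / d, 0)
  B <- Y1 %*% sv$v %*% (dinv * t(sv$u))
  if (include_intercept) {
    A <- B[, 1:N, drop = FALSE]
    intercept <- B[, N + 1L]
  } else {
    A <- B
    intercept <- numeric(N)
  }
  fitted <- A %*% Y0 + intercept
  res <- Y1 - fitted
  structure(list(
    A = A, intercept = intercept, dt = dt,
    residuals = res, fitted = fitted,
    sigma = sqrt(mean(res^2)),
    rank = r, full_rank = full_rank,
    include_intercept = include_intercept,
    n_samples_used = T,
    window_start_s = window_start_s,
    window_len_s = T * dt
  ), class = "var1")
}

#' @export
print.var1 <- function(x, ...) {
  N <- nrow(x$A)
  rho <- max(Mod(eigen(x$A, only.values = TRUE)$values))
  cat(sprintf(
    "<var1> N=%d, %d samples (%d transitions), dt=%g s%s\n",
    N, x$n_samples_used, x$n_samples_used - 1L, x$dt,
    if (x$include_intercept) ", intercept" else ""))
  cat(sprintf("  spectral radius %.4f  residual sd %.4g%s\n", rho, x$sigma,
              if (!x$full_rank) "  [degenerate fit]" else ""))
  invisible(x)
}

#' @export
coef.var1 <- function(object, ...) {
  A <- object$A
  if (object$include_intercept) attr(A, "intercept") <- object$intercept
  A
}

#' @export
residuals.var1 <- function(object, ...) object$residuals

#' One-step-ahead predictions from a fitted VAR(1)
#'
#' @param object a fitted `var1` model.
#' @param newdata channels x samples matrix; defaults to the training window.
#' @return matrix of one-step predictions `A y_n + c` for each column of
#'   `newdata` (one fewer column than the input when `newdata` is the
#'   training window is *not* assumed: predictions align with the inputs).
#' @export
predict.var1 <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  object$A %*% newdata + object$intercept
}

#' Simulate from a fitted VAR(1)
#'
#' Generates new trajectories from the estimated dynamics with Gaussian
#' innovations at the fitted residual scale.
#'
#' @param object a fitted `var1` model.
#' @param nsim number of samples (time points) to generate.
#' @param seed optional integer seed.
#' @param init initial state vector; defaults to zero.
#' @return channels x `nsim` matrix.
#' @export
simulate.var1 <- function(object, nsim = 1000, seed = NULL, init = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_system(object$A, noise_sd = object$sigma, t_samples = nsim,
                  burn_in = 0L, init = if (is.null(init))
                    numeric(nrow(object$A)) else init,
                  intercept = object$intercept)
}

#' @export
summary.var1 <- function(object, ...) {
  ms <- eig_modes(object)
  structure(list(fit = object, modes = ms,
                 spectral_radius = max(ms$rho)),
            class = "summary.var1")
}

#' @export
print.summary.var1 <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  modes: tau in [%.1f, %.1f] 1/s, f in [%.1f, %.1f] Hz\n",
              min(x$modes$tau), max(x$modes$tau),
              min(x$modes$f), max(x$modes$f)))
  invisible(x)
}
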