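#' Map VAR(1) eigenvalues to dynamical modes (frequency, growth rate)
#'
#' Writing each eigenvalue of the transition matrix as
#' \eqn{\lambda_j = \rho_j e^{i\varphi_j}}, the corresponding continuous-time
#' mode has frequency \eqn{f_j = |\varphi_j| / (2\pi\, dt)} in Hz and growth
#' rate (inverse damping timescale)
#' \eqn{\tau_j = \log(\rho_j) / dt} in 1/s (natural logarithm). Negative
#' `tau` means the mode is damped, zero marginal, positive unstable. The
#' absolute value of the argument folds each conjugate pair onto one
#' nonnegative frequency; both members are retained as separate modes with
#' equal `(f, tau)`.
#'
#' Eigenvalues at exactly zero (nilpotent directions) have no finite
#' timescale; they carry `tau = -Inf` and are excluded from all binned
#' distributions downstream.
#'
#' @param model a fitted [fit_var1()] model, or a square numeric matrix.
#' @param dt sample period in seconds; taken from the model when omitted.
#' @return a `mode_set`: data frame with one row per eigenvalue and columns
#'   `rho` (modulus), `phi` (argument, radians in (-pi, pi]), `f` (Hz),
#'   `tau` (1/s).
#' @examples
#' eig_modes(matrix(0.9), dt = 0.001)   # f = 0, tau = log(0.9)/0.001
#' @export
eig_modes <- function(model, dt = NULL) {
  if (inherits(model, "var1")) {
    A <- model$A
    if (is.null(dt)) dt <- model$dt
  } else {
    A <- as.matrix(model)
    if (is.null(dt)) stop("`dt` is required when passing a raw matrix")
  }
  if (nrow(A) != ncol(A)) stop("transition matrix must be square")
  ev <- eigen(A, only.values = TRUE)$values
  if (any(!is.finite(Re(ev)) | !is.finite(Im(ev))))
    stop("computation error: non-finite eigenvalues")
  rho <- Mod(ev)
  phi <- Arg(ev)
  out <- data.frame(
    rho = rho,
    phi = phi,
    f = abs(phi) / (2 * pi * dt),
    tau = ifelse(rho > 0, log(rho) / dt, -Inf)
  )
  attr(out, "dt") <- dt
  class(out) <- c("mode_set", "data.frame")
  out
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d modes (dt = %g s)\n", nrow(x), attr(x, "dt")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
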