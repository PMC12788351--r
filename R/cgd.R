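#' Conjugate-gradient analytical baseline
#'
#' Solves the Tikhonov-regularized normal equations
#' \eqn{(J^T J + \delta I)\,\chi = J^T M} with the conjugate-gradient method,
#' matrix-free (only products with J and J^T are formed), starting from
#' \eqn{\chi = 0} and stopping when the normal-equation residual norm falls
#' below `tol` times its initial value, or after `max_iters` iterations.
#'
#' The returned image is the raw (unclipped) CG iterate; reporting-side
#' normalization/clipping is done by [reconstruct_cgd()].
#'
#' @param J Sensitivity matrix (a [build_jacobian()] object or plain matrix),
#'   oriented so that `J %*% chi` predicts the measurement being fitted.
#' @param M_sub Measurement image to fit (matrix or vector, `nrow(J)` pixels).
#' @param delta Tikhonov weight (>= 0). Default: 1e-2 times the largest
#'   diagonal entry of J^T J.
#' @param max_iters,tol Iteration cap and relative residual tolerance.
#' @return The solution reshaped like `M_sub` when square-compatible, with
#'   attributes `converged` (logical) and `iterations`. Non-convergence at
#'   `max_iters` returns the current iterate with a warning.
#' @export
cgd_baseline <- function(J, M_sub, delta = NULL, max_iters = 200, tol = 1e-6) {
  Jm <- jacobian_entries(J)
  b_meas <- as.numeric(M_sub)
  if (length(b_meas) != nrow(Jm)) {
    stop("`M_sub` does not match the rows of J", call. = FALSE)
  }
  if (is.null(delta)) delta <- 1e-2 * max(colSums(Jm^2))
  if (delta < 0) stop("`delta` must be non-negative", call. = FALSE)

  Afun <- function(x) as.numeric(crossprod(Jm, Jm %*% x)) + delta * x
  b <- as.numeric(crossprod(Jm, b_meas))
  x <- numeric(ncol(Jm))
  r <- b
  p <- r
  rs <- sum(r^2)
  rs0 <- rs
  iters <- 0L
  converged <- rs0 == 0
  while (!converged && iters < max_iters) {
    Ap <- Afun(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) break # loss of positive definiteness in finite precision
    a <- rs / pAp
    x <- x + a * p
    r <- r - a * Ap
    rs_new <- sum(r^2)
    iters <- iters + 1L
    if (sqrt(rs_new) <= tol * sqrt(rs0)) {
      converged <- TRUE
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (!converged) {
    warning(sprintf("conjugate gradient stopped at %d iterations without reaching tol",
                    iters))
  }
  out <- if (is.matrix(M_sub) && length(x) == length(b_meas)) {
    matrix(x, nrow(M_sub), ncol(M_sub))
  } else if (is.matrix(M_sub) && sqrt(length(x)) %% 1 == 0) {
    n <- as.integer(sqrt(length(x)))
    matrix(x, n, n)
  } else {
    x
  }
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iters
  attr(out, "delta") <- delta
  out
}
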