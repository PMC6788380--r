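#' Block-tridiagonal symmetric positive-definite linear algebra
#'
#' Internal helpers for Gaussian inference on Markov chains. The negative
#' Hessian of a linear-dynamical-system log joint over a length-`T` latent
#' sequence is symmetric block-tridiagonal with `p x p` blocks; these routines
#' solve systems against it, accumulate its log-determinant, and recover the
#' diagonal and first off-diagonal blocks of its inverse (the posterior
#' marginal covariances and adjacent-time cross-covariances needed by EM) in
#' O(T p^3) via the forward Schur-complement factorisation.
#'
#' @param D list of `T` diagonal blocks (each `p x p`, symmetric).
#' @param U list of `T-1` upper off-diagonal blocks; `U[[t]]` is the
#'   `(t, t+1)` block of the matrix.
#' @param g `p x T` matrix of right-hand-side blocks.
#' @return `btd_solve` returns a list with `z` (`p x T` solution), `logdet`,
#'   and the forward Schur complements `Phi` (reused by `btd_inverse_blocks`).
#' @keywords internal
#' @noRd
btd_solve <- function(D, D_T = length(D), U, g = NULL) {
  Tn <- D_T
  p <- nrow(D[[1L]])
  Phi <- vector("list", Tn)
  Phi[[1L]] <- D[[1L]]
  cvec <- if (is.null(g)) NULL else matrix(0, p, Tn)
  logdet <- 0
  if (!is.null(g)) cvec[, 1L] <- g[, 1L]
  for (t in seq_len(Tn)) {
    if (t > 1L) {
      # Schur update: Phi_t = D_t - U_{t-1}' Phi_{t-1}^{-1} U_{t-1}
      M <- solve(Phi[[t - 1L]], U[[t - 1L]])
      Phi[[t]] <- D[[t]] - crossprod(U[[t - 1L]], M)
      if (!is.null(g)) {
        cvec[, t] <- g[, t] - crossprod(M, cvec[, t - 1L])
      }
    }
    ch <- chol(Phi[[t]])
    logdet <- logdet + 2 * sum(log(diag(ch)))
  }
  z <- NULL
  if (!is.null(g)) {
    z <- matrix(0, p, Tn)
    z[, Tn] <- solve(Phi[[Tn]], cvec[, Tn])
    if (Tn > 1L) {
      for (t in seq(Tn - 1L, 1L)) {
        z[, t] <- solve(Phi[[t]], cvec[, t] - U[[t]] %*% z[, t + 1L])
      }
    }
  }
  list(z = z, logdet = logdet, Phi = Phi)
}

#' Diagonal and first off-diagonal blocks of the inverse
#'
#' Given the forward Schur complements from [btd_solve()], returns
#' `Sigma[[t]] = (H^{-1})_{tt}` and `Cross[[t]] = (H^{-1})_{t,t+1}`.
#' @keywords internal
#' @noRd
btd_inverse_blocks <- function(Phi, U) {
  Tn <- length(Phi)
  Sigma <- vector("list", Tn)
  Cross <- if (Tn > 1L) vector("list", Tn - 1L) else list()
  Sigma[[Tn]] <- chol2inv(chol(Phi[[Tn]]))
  if (Tn > 1L) {
    for (t in seq(Tn - 1L, 1L)) {
      Phit_inv <- chol2inv(chol(Phi[[t]]))
      M <- Phit_inv %*% U[[t]]
      Cross[[t]] <- -M %*% Sigma[[t + 1L]]
      Sigma[[t]] <- Phit_inv + M %*% Sigma[[t + 1L]] %*% t(M)
      Sigma[[t]] <- (Sigma[[t]] + t(Sigma[[t]])) / 2
    }
  }
  list(Sigma = Sigma, Cross = Cross)
}
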