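#' Construct and validate Poisson linear dynamical system parameters
#'
#' The model is a latent linear-Gaussian Markov chain observed through a
#' Poisson count process with an exponential link:
#' \deqn{x_1 \sim N(x_0, Q_0), \quad x_{t+1} = A x_t + w_t, \; w_t \sim N(0, Q),}
#' \deqn{y_t \mid x_t \sim \mathrm{Poisson}(\exp(C x_t + d)) \text{ per 10 ms bin.}}
#'
#' @param A latent dynamics matrix (`p x p`).
#' @param Q state-noise covariance (`p x p`, symmetric positive definite).
#' @param C loading matrix (`n_units x p`).
#' @param d per-unit baseline log rate, in log(spikes/bin).
#' @param x0 initial-state mean (length `p`).
#' @param Q0 initial-state covariance (`p x p`, symmetric positive definite).
#' @return An object of class `plds_params`.
#' @examples
#' p <- plds_params(A = diag(2) * 0.9, Q = diag(2) * 0.1,
#'                  C = matrix(rnorm(10), 5, 2), d = rep(-2, 5))
#' @export
plds_params <- function(A, Q, C, d, x0 = rep(0, ncol(A)), Q0 = Q) {
  A <- as.matrix(A); Q <- as.matrix(Q); C <- as.matrix(C); Q0 <- as.matrix(Q0)
  d <- as.numeric(d); x0 <- as.numeric(x0)
  p <- ncol(A)
  stopifnot(nrow(A) == p, all(dim(Q) == p), ncol(C) == p,
            length(d) == nrow(C), length(x0) == p, all(dim(Q0) == p))
  check_spd(Q, "Q")
  check_spd(Q0, "Q0")
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (sr > 1 + 1e-8) {
    warning(sprintf("dynamics matrix A has spectral radius %.4f > 1 (unstable)", sr))
  }
  structure(list(A = A, Q = Q, C = C, d = d, x0 = x0, Q0 = Q0),
            class = "plds_params")
}

check_spd <- function(M, name) {
  if (max(abs(M - t(M))) > 1e-8 * (1 + max(abs(M)))) {
    stop(sprintf("%s must be symmetric", name))
  }
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop(sprintf("%s must be positive definite", name))
  invisible(TRUE)
}

#' @export
print.plds_params <- function(x, ...) {
  cat(sprintf("PLDS parameters: %d units, %d latent dimensions\n",
              nrow(x$C), ncol(x$A)))
  ev <- eigen(x$A, only.values = TRUE)$values
  cat("  |eig(A)|:", paste(sprintf("%.3f", Mod(ev)), collapse = " "), "\n")
  cat("  mean baseline rate:", sprintf("%.3f spikes/bin", mean(exp(x$d))), "\n")
  invisible(x)
}

#' Apply a similarity transform to PLDS parameters
#'
#' Latent bases are identifiable only up to an invertible linear map `M`;
#' transforming with `M` leaves predicted rates and the marginal likelihood
#' unchanged.
#' @param params a [plds_params()] object.
#' @param M invertible `p x p` matrix.
#' @export
plds_transform <- function(params, M) {
  Mi <- solve(M)
  plds_params(A = M %*% params$A %*% Mi,
              Q = M %*% params$Q %*% t(M),
              C = params$C %*% Mi,
              d = params$d,
              x0 = as.numeric(M %*% params$x0),
              Q0 = M %*% params$Q0 %*% t(M))
}

#' Simulate latents and spike counts from a PLDS model
#'
#' @param params a [plds_params()] object.
#' @param n_bins number of 10 ms bins to simulate.
#' @param seed integer seed; the draw is reproducible given `seed`.
#' @param rate_cap upper bound on the conditional mean count per bin; rates
#'   above it abort the simulation (guards `exp` overflow from runaway
#'   dynamics).
#' @return list with `latents` (`p x n_bins`) and `counts`
#'   (`n_units x n_bins`, non-negative integers).
#' @export
plds_simulate <- function(params, n_bins, seed = NULL, rate_cap = 50) {
  stopifnot(n_bins >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(params$A)
  n <- nrow(params$C)
  cQ <- chol(params$Q)
  cQ0 <- chol(params$Q0)
  x <- matrix(0, p, n_bins)
  x[, 1L] <- params$x0 + drop(crossprod(cQ0, rnorm(p)))
  if (n_bins > 1L) {
    for (t in 2:n_bins) {
      x[, t] <- params$A %*% x[, t - 1L] + drop(crossprod(cQ, rnorm(p)))
    }
  }
  eta <- params$C %*% x + params$d
  lam <- exp(eta)
  if (max(lam) > rate_cap) {
    stop(sprintf("simulated rate %.1f spikes/bin exceeds cap %g; check parameter scales",
                 max(lam), rate_cap))
  }
  counts <- matrix(stats::rpois(n * n_bins, as.vector(lam)), n, n_bins)
  list(latents = x, counts = counts)
}
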