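#' Kalman filter/smoother for a linear-Gaussian state-space model
#'
#' Fixed-interval (Rauch-Tung-Striebel) smoothing for
#' `x_1 ~ N(x0, Q0)`, `x_{t+1} = A x_t + w_t`, `y_t = C x_t + d + v_t`,
#' `v_t ~ N(0, R)`. This is the package's independent oracle for the Laplace
#' E-step: with Gaussian observations substituted, the Laplace posterior is
#' exact and must match the smoother.
#'
#' @param y `n_units x T` observation matrix.
#' @param params a [plds_params()] object (interpreted with Gaussian
#'   observations; `d` is the observation offset).
#' @param R observation noise covariance.
#' @return list with `mean` (`p x T` smoothed means), `Sigma` (list of
#'   smoothed covariances), `Cross` (list of `Cov(x_t, x_{t+1} | y)`),
#'   `loglik` (exact log marginal likelihood), plus the filtered moments.
#' @export
kalman_smooth <- function(y, params, R) {
  y <- as.matrix(y)
  Tn <- ncol(y); p <- ncol(params$A); n <- nrow(y)
  A <- params$A; C <- params$C; d <- params$d
  m_pred <- matrix(0, p, Tn); m_filt <- matrix(0, p, Tn)
  P_pred <- vector("list", Tn); P_filt <- vector("list", Tn)
  loglik <- 0
  for (t in seq_len(Tn)) {
    if (t == 1L) {
      m_pred[, t] <- params$x0
      P_pred[[t]] <- params$Q0
    } else {
      m_pred[, t] <- A %*% m_filt[, t - 1L]
      P_pred[[t]] <- A %*% P_filt[[t - 1L]] %*% t(A) + params$Q
    }
    S <- C %*% P_pred[[t]] %*% t(C) + R
    S <- (S + t(S)) / 2
    cS <- chol(S)
    innov <- y[, t] - C %*% m_pred[, t] - d
    loglik <- loglik - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(cS))) +
                                sum(backsolve(cS, innov, transpose = TRUE)^2))
    K <- P_pred[[t]] %*% t(C) %*% chol2inv(cS)
    m_filt[, t] <- m_pred[, t] + K %*% innov
    Pf <- (diag(p) - K %*% C) %*% P_pred[[t]]
    P_filt[[t]] <- (Pf + t(Pf)) / 2
  }
  m_sm <- m_filt
  P_sm <- P_filt
  Cross <- if (Tn > 1L) vector("list", Tn - 1L) else list()
  if (Tn > 1L) {
    for (t in seq(Tn - 1L, 1L)) {
      J <- P_filt[[t]] %*% t(A) %*% chol2inv(chol((P_pred[[t + 1L]] +
                                                     t(P_pred[[t + 1L]])) / 2))
      m_sm[, t] <- m_filt[, t] + J %*% (m_sm[, t + 1L] - m_pred[, t + 1L])
      Ps <- P_filt[[t]] + J %*% (P_sm[[t + 1L]] - P_pred[[t + 1L]]) %*% t(J)
      P_sm[[t]] <- (Ps + t(Ps)) / 2
      Cross[[t]] <- J %*% P_sm[[t + 1L]]
    }
  }
  list(mean = m_sm, Sigma = P_sm, Cross = Cross, loglik = loglik,
       filtered_mean = m_filt, filtered_cov = P_filt)
}

#' Exact EM for the Gaussian linear dynamical system
#'
#' Reference implementation used to validate the PLDS EM machinery: with
#' Gaussian observations the E-step (Kalman smoother) and the closed-form
#' M-step are exact, so the log likelihood is provably non-decreasing every
#' iteration — asserted in the acceptance suite.
#'
#' @param trials list of `n_units x T_i` observation matrices.
#' @param latent_dim latent dimensionality.
#' @param max_iter,tol EM iteration cap and relative log-likelihood change
#'   tolerance.
#' @param seed seed for the random initialisation.
#' @return list with `params`, `R`, `loglik_trace`, `iterations`.
#' @export
glds_em <- function(trials, latent_dim, max_iter = 50L, tol = 1e-8, seed = 1L) {
  stopifnot(length(trials) >= 1, latent_dim >= 1)
  n <- nrow(trials[[1L]])
  p <- latent_dim
  set.seed(seed)
  params <- plds_params(A = diag(p) * 0.9,
                        Q = diag(p) * 0.1,
                        C = matrix(stats::rnorm(n * p, sd = 0.5), n, p),
                        d = rowMeans(do.call(cbind, trials)),
                        x0 = rep(0, p), Q0 = diag(p))
  R <- diag(n) * stats::var(as.numeric(do.call(cbind, trials)))
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # E-step
    ll <- 0
    S11 <- matrix(0, p, p); Scc <- matrix(0, p, p); Spp <- matrix(0, p, p)
    Scp <- matrix(0, p, p)   # sum E[x_{t+1} x_t']
    Sxx <- matrix(0, p, p); Sx <- rep(0, p)
    Syx <- matrix(0, n, p); Sy <- rep(0, n); Syy <- matrix(0, n, n)
    x1s <- matrix(0, p, length(trials)); V1s <- matrix(0, p, p)
    n_trans <- 0; n_bins <- 0
    for (k in seq_along(trials)) {
      y <- trials[[k]]
      Tn <- ncol(y)
      sm <- kalman_smooth(y, params, R)
      ll <- ll + sm$loglik
      mu <- sm$mean
      Ext <- lapply(seq_len(Tn), function(t) sm$Sigma[[t]] + tcrossprod(mu[, t]))
      x1s[, k] <- mu[, 1L]
      V1s <- V1s + sm$Sigma[[1L]]
      for (t in seq_len(Tn)) {
        Sxx <- Sxx + Ext[[t]]
        Sx <- Sx + mu[, t]
      }
      Syx <- Syx + y %*% t(mu)
      Sy <- Sy + rowSums(y)
      Syy <- Syy + tcrossprod(y)
      if (Tn > 1L) {
        for (t in seq_len(Tn - 1L)) {
          Spp <- Spp + Ext[[t]]
          Scc <- Scc + Ext[[t + 1L]]
          Scp <- Scp + t(sm$Cross[[t]]) + tcrossprod(mu[, t + 1L], mu[, t])
        }
        n_trans <- n_trans + Tn - 1L
      }
      n_bins <- n_bins + Tn
    }
    trace <- c(trace, ll)
    if (iter > 1L && abs(diff(utils::tail(trace, 2))) <
          tol * max(1, abs(ll))) break
    # M-step
    K <- length(trials)
    x0 <- rowMeans(x1s)
    dev <- x1s - x0
    Q0 <- (V1s + tcrossprod(dev)) / K
    A <- Scp %*% chol2inv(chol(Spp))
    Q <- (Scc - A %*% t(Scp)) / n_trans
    Q <- (Q + t(Q)) / 2
    G <- rbind(cbind(Sxx, Sx), c(Sx, n_bins))
    Cd <- cbind(Syx, Sy) %*% chol2inv(chol(G))
    Cm <- Cd[, seq_len(p), drop = FALSE]
    dv <- Cd[, p + 1L]
    Rm <- (Syy - Cm %*% t(Syx) - tcrossprod(dv, Sy)) / n_bins
    Rm <- (Rm + t(Rm)) / 2
    params <- plds_params(A = A, Q = spd_repair(Q), C = Cm, d = dv,
                          x0 = x0, Q0 = spd_repair(Q0))
    R <- spd_repair(Rm)
  }
  list(params = params, R = R, loglik_trace = trace, iterations = length(trace))
}

# Symmetrise and eigenvalue-floor a covariance update (jitter repair).
spd_repair <- function(M, floor = 1e-9) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < floor) {
    M <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
    M <- (M + t(M)) / 2
  }
  M
}
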