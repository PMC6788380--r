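#' Laplace-approximated posterior over a latent trajectory
#'
#' Computes the posterior of the full latent sequence given one trial of
#' observations under a linear-Gaussian state-space prior. The posterior mode
#' is found by Newton's method on the log joint of the whole sequence; the
#' Hessian is symmetric block-tridiagonal and is factorised in O(T p^3) (see
#' `btd_solve`). The Laplace approximation takes the mode as the posterior
#' mean and blocks of the inverse Hessian as marginal covariances and
#' adjacent-bin cross-covariances; the approximate log marginal likelihood is
#' the Laplace evidence at the mode.
#'
#' With `family = "gaussian"` the observation term is replaced by a Gaussian
#' likelihood with covariance `R`, for which the log joint is exactly
#' quadratic: the "approximation" is then exact and must agree with a Kalman
#' smoother — the package's primary inference correctness check.
#'
#' @param y observation matrix (`n_units x T`); non-negative integer counts
#'   for the Poisson family.
#' @param params a [plds_params()] object.
#' @param family `"poisson"` (canonical exponential link, the model of
#'   record) or `"gaussian"` (test hook).
#' @param R Gaussian observation covariance (`n_units x n_units`), required
#'   for `family = "gaussian"`.
#' @param x_init optional `p x T` starting point for Newton; defaults to the
#'   noise-free prior mean path.
#' @param max_iter,grad_tol Newton iteration cap and gradient infinity-norm
#'   tolerance at the mode.
#' @param want_cov if `FALSE`, skip the covariance back-recursion (mode and
#'   evidence only).
#' @param engine `"cpp"` (compiled fast path, Poisson only) or `"r"`
#'   (reference implementation). Both compute the same quantities; agreement
#'   is asserted in the test-suite.
#' @return list of class `latent_posterior`: `mean` (`p x T`), `Sigma`
#'   (list of `T` `p x p` covariance blocks), `Cross` (list of `T-1`
#'   cross-covariance blocks `Cov(x_t, x_{t+1} | y)`), `loglik`
#'   (Laplace-approximate log marginal likelihood), `grad_norm`,
#'   `iterations`, `converged`.
#' @export
plds_laplace_estep <- function(y, params, family = c("poisson", "gaussian"),
                               R = NULL, x_init = NULL,
                               max_iter = 100L, grad_tol = 1e-8,
                               want_cov = TRUE, engine = c("cpp", "r")) {
  family <- match.arg(family)
  engine <- match.arg(engine)
  y <- as.matrix(y)
  Tn <- ncol(y)
  p <- ncol(params$A)
  if (Tn < 1L) stop("trial must contain at least one observation bin")
  if (nrow(y) != nrow(params$C)) stop("unit count mismatch between y and C")
  if (family == "poisson") {
    if (any(y < 0) || any(y != round(y))) {
      stop("Poisson family requires non-negative integer counts")
    }
  } else if (is.null(R)) {
    stop("family = 'gaussian' requires an observation covariance R")
  }
  if (is.null(x_init)) {
    x_init <- matrix(0, p, Tn)
    x_init[, 1L] <- params$x0
    if (Tn > 1L) {
      for (t in 2:Tn) x_init[, t] <- params$A %*% x_init[, t - 1L]
    }
  }
  if (family == "poisson" && engine == "cpp") {
    out <- plds_estep_cpp(y, params$A, params$Q, params$C, params$d,
                          params$x0, params$Q0, x_init,
                          as.integer(max_iter), grad_tol, want_cov)
    Sig <- if (want_cov) lapply(seq_len(Tn), function(t) out$Sigma[, , t]) else NULL
    Crs <- if (want_cov && Tn > 1L) {
      lapply(seq_len(Tn - 1L), function(t) out$Cross[, , t])
    } else list()
    res <- list(mean = out$mean, Sigma = Sig, Cross = Crs,
                loglik = out$loglik, grad_norm = out$grad_norm,
                iterations = out$iterations, converged = out$converged)
    class(res) <- "latent_posterior"
    if (!res$converged) {
      stop(sprintf("Laplace E-step did not converge in %d Newton iterations (|grad| = %.3g)",
                   max_iter, res$grad_norm))
    }
    return(res)
  }
  estep_reference(y, params, family, R, x_init, max_iter, grad_tol, want_cov)
}

# Pure-R Newton on the stacked log joint; shared by the Gaussian test hook.
estep_reference <- function(y, params, family, R, x, max_iter, grad_tol, want_cov) {
  Tn <- ncol(y); p <- ncol(params$A); n <- nrow(y)
  A <- params$A; C <- params$C; d <- params$d
  Qi <- chol2inv(chol(params$Q))
  Q0i <- chol2inv(chol(params$Q0))
  AQi <- crossprod(A, Qi)          # A' Q^{-1}
  AQiA <- AQi %*% A                # A' Q^{-1} A
  U <- rep(list(-AQi), max(Tn - 1L, 0L))
  ldQ <- 2 * sum(log(diag(chol(params$Q))))
  ldQ0 <- 2 * sum(log(diag(chol(params$Q0))))
  if (family == "gaussian") {
    Ri <- chol2inv(chol(R))
    CRC <- crossprod(C, Ri) %*% C
    ldR <- 2 * sum(log(diag(chol(R))))
    obs_const <- Tn * 0.5 * (ldR + n * log(2 * pi))
  } else {
    obs_const <- sum(lgamma(y + 1))
  }
  prior_const <- 0.5 * (ldQ0 + p * log(2 * pi)) +
    (Tn - 1L) * 0.5 * (ldQ + p * log(2 * pi))

  neg_logjoint <- function(x) {
    v1 <- x[, 1L] - params$x0
    f <- 0.5 * sum(v1 * (Q0i %*% v1))
    if (Tn > 1L) {
      dx <- x[, -1L, drop = FALSE] - A %*% x[, -Tn, drop = FALSE]
      f <- f + 0.5 * sum(dx * (Qi %*% dx))
    }
    eta <- C %*% x + d
    if (family == "poisson") {
      f <- f + sum(exp(pmin(eta, 30))) - sum(y * eta)
    } else {
      r <- y - eta
      f <- f + 0.5 * sum(r * (Ri %*% r))
    }
    f + prior_const + obs_const
  }

  grad_hess <- function(x) {
    eta <- C %*% x + d
    g <- matrix(0, p, Tn)
    D <- vector("list", Tn)
    if (family == "poisson") {
      lam <- exp(pmin(eta, 30))
      gobs <- crossprod(C, lam - y)
    } else {
      gobs <- crossprod(C, Ri %*% (eta - y))
    }
    for (t in seq_len(Tn)) {
      gp <- if (t == 1L) Q0i %*% (x[, 1L] - params$x0)
            else Qi %*% (x[, t] - A %*% x[, t - 1L])
      if (t < Tn) gp <- gp - AQi %*% (x[, t + 1L] - A %*% x[, t])
      g[, t] <- gp + gobs[, t]
      Dp <- if (t == 1L) Q0i else Qi
      if (t < Tn) Dp <- Dp + AQiA
      Wt <- if (family == "poisson") {
        crossprod(C, C * as.vector(lam[, t]))
      } else CRC
      D[[t]] <- Dp + Wt
    }
    list(g = g, D = D)
  }

  f <- neg_logjoint(x)
  converged <- FALSE
  gnorm <- Inf
  it <- 0L
  repeat {
    gh <- grad_hess(x)
    gnorm <- max(abs(gh$g))
    if (gnorm < grad_tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    it <- it + 1L
    sol <- btd_solve(gh$D, Tn, U, gh$g)
    step <- sol$z
    descent <- sum(gh$g * step)
    alpha <- 1
    repeat {
      x_new <- x - alpha * step
      f_new <- neg_logjoint(x_new)
      if (f_new <= f - 1e-4 * alpha * descent || alpha < 1e-10) break
      alpha <- alpha / 2
    }
    # line-search stall at the arithmetic floor: accept the mode if the
    # gradient is already far below any practical scale
    if (f - f_new < 1e-12 * (1 + abs(f)) && gnorm < 1e-5) {
      if (f_new < f) { x <- x_new; f <- f_new }
      converged <- TRUE
      break
    }
    x <- x_new
    f <- f_new
  }
  if (!converged) {
    stop(sprintf("Laplace E-step did not converge in %d Newton iterations (|grad| = %.3g)",
                 max_iter, gnorm))
  }
  gh <- grad_hess(x)
  fac <- btd_solve(gh$D, Tn, U, NULL)
  loglik <- -neg_logjoint(x) + 0.5 * p * Tn * log(2 * pi) - 0.5 * fac$logdet
  Sig <- NULL; Crs <- list()
  if (want_cov) {
    inv <- btd_inverse_blocks(fac$Phi, U)
    Sig <- inv$Sigma
    Crs <- inv$Cross
  }
  res <- list(mean = x, Sigma = Sig, Cross = Crs, loglik = loglik,
              grad_norm = gnorm, iterations = it, converged = converged)
  class(res) <- "latent_posterior"
  res
}

#' Causal (filtered) latent-state estimates
#'
#' One-sided counterpart to [plds_laplace_estep()]: a Gaussian approximate
#' filter that, at each bin, Newton-updates the predictive distribution with
#' the current count vector only (no future data). Offered for causal /
#' real-time decoding comparisons; the smoothed posterior mean remains the
#' default latent feature.
#'
#' @inheritParams plds_laplace_estep
#' @return `p x T` matrix of filtered means.
#' @export
plds_filter <- function(y, params, max_iter = 50L, grad_tol = 1e-9) {
  y <- as.matrix(y)
  Tn <- ncol(y); p <- ncol(params$A)
  A <- params$A; C <- params$C; d <- params$d
  m <- params$x0
  V <- params$Q0
  out <- matrix(0, p, Tn)
  for (t in seq_len(Tn)) {
    if (t > 1L) {
      m <- drop(A %*% m)
      V <- A %*% V %*% t(A) + params$Q
    }
    Vi <- chol2inv(chol((V + t(V)) / 2))
    x <- m
    for (it in seq_len(max_iter)) {
      lam <- exp(pmin(C %*% x + d, 30))
      g <- Vi %*% (x - m) + crossprod(C, lam - y[, t])
      if (max(abs(g)) < grad_tol) break
      H <- Vi + crossprod(C, C * as.vector(lam))
      x <- x - solve(H, g)
    }
    lam <- exp(pmin(C %*% x + d, 30))
    V <- chol2inv(chol(Vi + crossprod(C, C * as.vector(lam))))
    m <- drop(x)
    out[, t] <- m
  }
  out
}
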