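#' Fit a Poisson linear dynamical system by Laplace EM
#'
#' Alternates the Laplace E-step ([plds_laplace_estep()]) over all trials with
#' closed-form M-step updates for the dynamics (`A`, `Q`, `x0`, `Q0`) from the
#' posterior first/second moments, and Newton ascent on the expected Poisson
#' log likelihood for the loadings (`C`, `d`) using the log-normal moment
#' identity `E[exp(c'x)] = exp(c'mu + c'Sigma c / 2)`. Trials are treated as
#' independent sequences sharing parameters, each restarting from
#' `(x0, Q0)` — one trial is one gait cycle.
#'
#' Initialisation is seed-controlled: PCA on z-scored, square-root-transformed,
#' temporally smoothed counts gives initial latent scores; `C` and `d` come
#' from a per-unit log-linear regression on those scores, `A` from a
#' least-squares fit of successive scores, and `Q` from its residuals.
#'
#' Because the marginal likelihood is itself Laplace-approximated, the
#' objective trace is non-decreasing only up to the approximation error; the
#' fit records any decrease in `diagnostics`.
#'
#' @param trials list of `n_units x T_i` spike-count matrices (10 ms bins).
#' @param latent_dim number of latent dimensions (>= 1).
#' @param max_iter,tol EM iteration cap and relative change tolerance on the
#'   summed approximate log likelihood.
#' @param seed seed for initialisation.
#' @param cd_newton_iter Newton steps for the loading update per M-step.
#' @param verbose print the objective each iteration.
#' @return object of class `plds_fit`: `params` ([plds_params()]),
#'   `loglik_trace`, `iterations`, `converged`, `diagnostics` (largest
#'   per-iteration objective decrease, if any).
#' @export
plds_fit <- function(trials, latent_dim, max_iter = 100L, tol = 1e-6,
                     seed = 1L, cd_newton_iter = 3L, verbose = FALSE) {
  if (length(trials) < 2L) stop("EM requires at least two trials")
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  n <- nrow(trials[[1L]])
  if (latent_dim > n) stop("latent_dim cannot exceed the number of units")
  p <- latent_dim

  params <- plds_init(trials, p, seed)
  K <- length(trials)
  warm <- vector("list", K)
  trace <- numeric(0)
  worst_decrease <- 0
  converged <- FALSE
  n_halvings <- 0L

  eval_loglik <- function(prm, warm_in) {
    ll <- 0
    wm <- warm_in
    for (k in seq_len(K)) {
      post <- plds_laplace_estep(trials[[k]], prm, x_init = warm_in[[k]],
                                 want_cov = FALSE)
      wm[[k]] <- post$mean
      ll <- ll + post$loglik
    }
    list(ll = ll, warm = wm)
  }

  ll <- NULL
  for (iter in seq_len(max_iter)) {
    # --- E-step at the current (accepted) parameters, with covariances ---
    ll_full <- 0
    Spp <- matrix(0, p, p); Scc <- matrix(0, p, p); Scp <- matrix(0, p, p)
    x1s <- matrix(0, p, K); V1s <- matrix(0, p, p)
    n_trans <- 0
    mus <- vector("list", K); Sigs <- vector("list", K)
    for (k in seq_len(K)) {
      post <- plds_laplace_estep(trials[[k]], params, x_init = warm[[k]])
      warm[[k]] <- post$mean
      ll_full <- ll_full + post$loglik
      mu <- post$mean
      Tn <- ncol(mu)
      mus[[k]] <- mu
      Sigs[[k]] <- post$Sigma
      x1s[, k] <- mu[, 1L]
      V1s <- V1s + post$Sigma[[1L]]
      if (Tn > 1L) {
        for (t in seq_len(Tn - 1L)) {
          Spp <- Spp + post$Sigma[[t]] + tcrossprod(mu[, t])
          Scc <- Scc + post$Sigma[[t + 1L]] + tcrossprod(mu[, t + 1L])
          Scp <- Scp + t(post$Cross[[t]]) + tcrossprod(mu[, t + 1L], mu[, t])
        }
        n_trans <- n_trans + Tn - 1L
      }
    }
    ll <- ll_full
    trace <- c(trace, ll)
    if (verbose) message(sprintf("EM iter %3d: loglik_approx = %.4f", iter, ll))
    if (iter > 1L) {
      delta <- trace[iter] - trace[iter - 1L]
      if (delta < 0) worst_decrease <- max(worst_decrease, -delta)
      if (abs(delta) < tol * max(1, abs(ll))) { converged <- TRUE; break }
    }
    # --- M-step: dynamics (closed form) ---
    x0 <- rowMeans(x1s)
    dev <- x1s - x0
    Q0 <- spd_repair((V1s + tcrossprod(dev)) / K, 1e-8)
    A <- Scp %*% chol2inv(chol(Spp))
    Q <- spd_repair((Scc - A %*% t(Scp)) / n_trans, 1e-8)
    # --- M-step: loadings (per-unit Newton on expected Poisson loglik) ---
    cd <- update_loadings_cpp(do.call(cbind, trials), do.call(cbind, mus),
                              simplify2array(do.call(c, Sigs)),
                              params$C, params$d, as.integer(cd_newton_iter))
    cand <- plds_params(A = A, Q = Q, C = cd$C, d = cd$d, x0 = x0, Q0 = Q0)
    # --- ascent safeguard: the M-step maximises the EM surrogate, not the
    # Laplace evidence, so a full step can lower the objective; halve the
    # parameter step toward the current params until the evidence does not
    # decrease (generalized-EM step-size control) ---
    ev <- eval_loglik(cand, warm)
    halve <- 0L
    while (ev$ll < ll - 1e-9 * max(1, abs(ll)) && halve < 6L) {
      cand <- midpoint_params(params, cand)
      ev <- eval_loglik(cand, warm)
      halve <- halve + 1L
      n_halvings <- n_halvings + 1L
    }
    if (ev$ll < ll - 1e-9 * max(1, abs(ll))) {
      # no ascent direction left: local maximum of the approximate evidence
      converged <- TRUE
      break
    }
    params <- cand
    warm <- ev$warm
  }
  structure(list(params = params, loglik_trace = trace,
                 iterations = length(trace), converged = converged,
                 diagnostics = list(worst_decrease = worst_decrease,
                                    n_halvings = n_halvings)),
            class = "plds_fit")
}

# Halfway point between two parameter sets (covariances SPD-repaired).
midpoint_params <- function(a, b) {
  plds_params(A = (a$A + b$A) / 2,
              Q = spd_repair((a$Q + b$Q) / 2, 1e-9),
              C = (a$C + b$C) / 2,
              d = (a$d + b$d) / 2,
              x0 = (a$x0 + b$x0) / 2,
              Q0 = spd_repair((a$Q0 + b$Q0) / 2, 1e-9))
}

#' @export
print.plds_fit <- function(x, ...) {
  cat(sprintf("PLDS fit: %d latent dims, %d EM iterations (%s), loglik_approx %.2f\n",
              ncol(x$params$A), x$iterations,
              if (x$converged) "converged" else "iteration cap",
              utils::tail(x$loglik_trace, 1)))
  invisible(x)
}

# PCA-based seed-controlled initialisation on variance-stabilised counts.
plds_init <- function(trials, p, seed) {
  set.seed(seed)
  n <- nrow(trials[[1L]])
  kern <- stats::dnorm(-4:4, sd = 2)
  kern <- kern / sum(kern)
  smooth_sqrt <- function(y) {
    s <- sqrt(y)
    t(apply(s, 1L, function(r) {
      as.numeric(stats::filter(c(rep(r[1L], 4), r, rep(r[length(r)], 4)),
                               kern, sides = 2L))[5:(length(r) + 4L)]
    }))
  }
  sm <- lapply(trials, smooth_sqrt)
  allsm <- do.call(cbind, sm)
  mu <- rowMeans(allsm)
  sdv <- apply(allsm, 1L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  zs <- (allsm - mu) / sdv
  pc <- eigen(tcrossprod(zs) / ncol(zs), symmetric = TRUE)
  W <- pc$vectors[, seq_len(p), drop = FALSE]          # units x p
  scores <- crossprod(W, zs)                           # p x bins
  # unsmoothed scores in the same basis: their measurement noise is white, so
  # lagged regressions see the rotation angle without low-pass contamination
  raw <- do.call(cbind, lapply(trials, sqrt))
  scores_raw <- crossprod(W, (raw - rowMeans(raw)) / sdv)
  # per-unit log-linear regression of smoothed counts on scores -> C, d
  X <- cbind(t(scores), 1)
  lograte <- log(pmax(allsm^2, 1e-3))
  beta <- solve(crossprod(X), crossprod(X, t(lograte)))
  C <- t(beta[seq_len(p), , drop = FALSE])
  d <- beta[p + 1L, ]
  d <- pmin(pmax(d, -8), 2)
  # dynamics from lagged regressions of the scores within trials; the
  # two-lag ratio M2 M1^{-1} cancels the attenuation that measurement noise
  # induces on a single-lag AR fit (which otherwise biases rotation
  # frequencies toward zero)
  lens <- vapply(sm, ncol, 1L)
  idx_end <- cumsum(lens)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  X1 <- NULL; X2 <- NULL; Y1 <- NULL; Y2 <- NULL
  for (k in seq_along(lens)) {
    s <- scores_raw[, idx_start[k]:idx_end[k], drop = FALSE]
    if (ncol(s) > 1L) {
      X1 <- cbind(X1, s[, -ncol(s), drop = FALSE])
      X2 <- cbind(X2, s[, -1L, drop = FALSE])
    }
    if (ncol(s) > 2L) {
      Y1 <- cbind(Y1, s[, 1:(ncol(s) - 2L), drop = FALSE])
      Y2 <- cbind(Y2, s[, 3:ncol(s), drop = FALSE])
    }
  }
  G1 <- tcrossprod(X1) + diag(p) * 1e-6
  M1 <- tcrossprod(X2, X1) %*% chol2inv(chol(G1))
  A <- M1
  if (!is.null(Y1)) {
    M2 <- tcrossprod(Y2, Y1) %*%
      chol2inv(chol(tcrossprod(Y1) + diag(p) * 1e-6))
    A2 <- tryCatch(M2 %*% solve(M1), error = function(e) NULL)
    if (!is.null(A2) && all(is.finite(A2)) &&
          max(Mod(eigen(A2, only.values = TRUE)$values)) < 1.5) {
      A <- A2
    }
  }
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (sr > 0.99) A <- A * (0.99 / sr)
  res <- X2 - A %*% X1
  Q <- spd_repair(tcrossprod(res) / ncol(res), 1e-4)
  firsts <- scores[, idx_start, drop = FALSE]
  x0 <- rowMeans(firsts)
  Q0 <- spd_repair(stats::cov(t(firsts)) * (length(lens) - 1) / length(lens) +
                     diag(p) * 1e-3, 1e-4)
  plds_params(A = A, Q = Q, C = C, d = d, x0 = x0, Q0 = Q0)
}

# Newton ascent on the expected Poisson log likelihood, unit by unit.
# Pure-R reference for the compiled update_loadings_cpp (agreement is
# asserted in the test-suite).
update_loadings_r <- function(trials, mus, Sigs, C, d, n_iter) {
  p <- ncol(C)
  mu_all <- do.call(cbind, mus)                 # p x total_bins
  Tn <- ncol(mu_all)
  # stack covariances: Sflat (p^2 x T) for quadratic forms, Srows (T*p x p)
  Slist <- do.call(c, Sigs)
  Sflat <- vapply(Slist, as.numeric, numeric(p * p))
  Sflat <- matrix(Sflat, nrow = p * p)
  Srows <- do.call(rbind, Slist)                # (T*p) x p
  y_all <- do.call(cbind, trials)
  n <- nrow(C)
  for (u in seq_len(n)) {
    b <- c(C[u, ], d[u])
    yu <- y_all[u, ]
    y_mu <- as.numeric(mu_all %*% yu)
    y_sum <- sum(yu)
    f_cur <- expected_ll_unit(b, mu_all, Sflat, yu, p)
    for (it in seq_len(n_iter)) {
      cu <- b[seq_len(p)]
      quad <- as.numeric(crossprod(Sflat, as.numeric(tcrossprod(cu))))  # c'S_t c
      Sc <- matrix(Srows %*% cu, nrow = p)       # p x T, column t = S_t c
      eta <- as.numeric(crossprod(mu_all, cu)) + b[p + 1L] + 0.5 * quad
      rho <- exp(pmin(eta, 30))
      m_eff <- mu_all + Sc                       # p x T
      g <- c(y_mu - m_eff %*% rho, y_sum - sum(rho))
      if (max(abs(g)) < 1e-8) break
      W <- m_eff * rep(rho, each = p)
      Hcc <- tcrossprod(W, m_eff) + matrix(Sflat %*% rho, p, p)
      Hcd <- m_eff %*% rho
      H <- rbind(cbind(Hcc, Hcd), c(Hcd, sum(rho)))
      step <- tryCatch(solve(H + diag(p + 1L) * 1e-9, g),
                       error = function(e) g / (max(abs(diag(H))) + 1))
      alpha <- 1
      repeat {
        b_new <- b + alpha * step
        f_new <- expected_ll_unit(b_new, mu_all, Sflat, yu, p)
        if (f_new >= f_cur || alpha < 1e-6) break
        alpha <- alpha / 2
      }
      if (alpha >= 1e-6 && f_new >= f_cur) { b <- b_new; f_cur <- f_new }
      else break
    }
    C[u, ] <- b[seq_len(p)]
    d[u] <- b[p + 1L]
  }
  list(C = C, d = d)
}

expected_ll_unit <- function(b, mu_all, Sflat, yu, p) {
  cu <- b[seq_len(p)]
  quad <- as.numeric(crossprod(Sflat, as.numeric(tcrossprod(cu))))
  eta <- as.numeric(crossprod(mu_all, cu)) + b[p + 1L]
  sum(yu * eta) - sum(exp(pmin(eta + 0.5 * quad, 30)))
}

#' Decode latent trajectories for novel trials
#'
#' Applies the Laplace smoother with fixed, previously fitted parameters to
#' new spike counts and returns the posterior-mean latent time series — the
#' feature set consumed by the Wiener decoder. A causal (filtered) estimate is
#' available via `causal = TRUE` (see [plds_filter()]).
#'
#' @param fit a `plds_fit` object or bare [plds_params()].
#' @param y `n_units x T` spike counts for one trial.
#' @param causal use the causal point-process filter instead of the smoother.
#' @param want_cov return the full posterior (covariances) instead of just
#'   the mean.
#' @return `p x T` matrix of posterior means (or a `latent_posterior` when
#'   `want_cov = TRUE`).
#' @export
plds_decode <- function(fit, y, causal = FALSE, want_cov = FALSE) {
  params <- if (inherits(fit, "plds_fit")) fit$params else fit
  y <- as.matrix(y)
  if (ncol(y) < 1L) stop("empty trial: no observation bins to decode")
  if (causal) return(plds_filter(y, params))
  post <- plds_laplace_estep(y, params, want_cov = want_cov)
  if (want_cov) post else post$mean
}
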