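# Shared fixtures, built in code and memoized across test files.
.fixtures <- new.env(parent = emptyenv())

# Small treadmill session used by several modules (20 units, 36 trials).
small_session <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_session(gait_config(
      n_units = 20L, latent_dim = 4L, n_trials_per_condition = 12L,
      conditions = data.frame(task = "TRM", speed = c(2.4, 4.0, 6.4)),
      seed = 42L))
  }
  .fixtures$small
}

rot2x2 <- function(theta, mod = 1) {
  mod * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# Small PLDS ground truth for module tests.
toy_plds <- function(n = 10L, p = 2L, seed = 1L, theta = 0.25, mod = 0.97) {
  set.seed(seed)
  A <- diag(p) * 0.8
  A[1:2, 1:2] <- rot2x2(theta, mod)
  Cm <- matrix(rnorm(n * p, sd = 0.7), n, p)
  plds_params(A = A, Q = diag(p) * 0.03, C = Cm, d = runif(n, -3, -1),
              x0 = c(1, rep(0, p - 1L)), Q0 = diag(p) * 0.2)
}

# Parameter-recovery world: 30 units, 4 latent dims, sustained rotations at
# realistic M1 modulation depths (tuning-vector norms 0.6-1.4, baselines
# ~5-37 spikes/s).
recovery_params <- function(seed) {
  set.seed(seed)
  A <- matrix(0, 4, 4)
  A[1:2, 1:2] <- rot2x2(0.2, 0.99)
  A[3:4, 3:4] <- rot2x2(0.45, 0.97)
  Cm <- matrix(rnorm(30 * 4), 30, 4)
  Cm <- Cm * runif(30, 0.6, 1.4) / sqrt(rowSums(Cm^2))
  plds_params(A = A, Q = diag(4) * 0.02, C = Cm, d = runif(30, -3, -1),
              x0 = c(1, 0, 0.6, 0), Q0 = diag(4) * 0.1)
}

# Dense brute-force conditioning of the joint Gaussian (x_{1:T}, y_{1:T})
# on y: the from-first-principles oracle for smoothing, usable at small T.
brute_force_smoother <- function(y, params, R) {
  Tn <- ncol(y); p <- ncol(params$A); n <- nrow(y)
  A <- params$A
  mx <- matrix(0, p, Tn)
  mx[, 1L] <- params$x0
  if (Tn > 1L) for (t in 2:Tn) mx[, t] <- A %*% mx[, t - 1L]
  # joint covariance of the latent path by propagation
  Sxx <- matrix(0, p * Tn, p * Tn)
  blk <- function(t) ((t - 1L) * p + 1L):(t * p)
  Sxx[blk(1L), blk(1L)] <- params$Q0
  if (Tn > 1L) {
    for (t in 2:Tn) {
      Sxx[blk(t), blk(t)] <- A %*% Sxx[blk(t - 1L), blk(t - 1L)] %*% t(A) + params$Q
      for (s in 1:(t - 1L)) {
        Sxx[blk(t), blk(s)] <- A %*% Sxx[blk(t - 1L), blk(s)]
        Sxx[blk(s), blk(t)] <- t(Sxx[blk(t), blk(s)])
      }
    }
  }
  Cbig <- kronecker(diag(Tn), params$C)
  Rbig <- kronecker(diag(Tn), R)
  my <- as.numeric(params$C %*% mx + params$d)
  Syy <- Cbig %*% Sxx %*% t(Cbig) + Rbig
  Sxy <- Sxx %*% t(Cbig)
  K <- Sxy %*% solve(Syy)
  mpost <- as.numeric(mx) + K %*% (as.numeric(y) - my)
  Vpost <- Sxx - K %*% t(Sxy)
  list(mean = matrix(mpost, p, Tn),
       Sigma = lapply(seq_len(Tn), function(t) Vpost[blk(t), blk(t)]),
       Cross = if (Tn > 1L) lapply(seq_len(Tn - 1L), function(t) {
         Vpost[blk(t), blk(t + 1L)]
       }) else list())
}

# Exhaustive signed-rank oracle over all 2^n sign assignments.
signrank_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# Direct Benjamini-Hochberg step-up from its definition.
bh_enum <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k_set <- which(p[o] <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(k_set) > 0) rej[o[seq_len(max(k_set))]] <- TRUE
  rej
}

# Independent R^2: literal 1 - SSres/SStot.
r2_direct <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

max_block_diff <- function(a, b) max(mapply(function(x, y) max(abs(x - y)), a, b))
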