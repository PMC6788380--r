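#' Configuration for the synthetic locomotor-session generator
#'
#' The generator states a ground-truth world with the statistical structure
#' the analysis pipeline assumes: trials are single gait cycles of variable
#' duration, latent dynamics rotate once per cycle in a plane (with a
#' harmonic pair on higher dimensions), task/speed conditions shift the
#' latents along one axis, spike counts are conditionally Poisson given the
#' latents through an exponential link, and 100 Hz marker kinematics are
#' noisy affine readouts of the latents. Defaults mirror a treadmill session:
#' speeds from the training set (km/h), cycle periods around 0.6 s with 60%
#' stance, 18-80 units and mean counts well below one spike per 10 ms bin.
#'
#' @param n_units number of recorded units.
#' @param latent_dim latent dimensionality (>= 2; the rotation needs a plane).
#' @param n_trials_per_condition gait cycles per condition.
#' @param conditions data.frame with columns `task` and `speed` (km/h).
#' @param gait_period_range min/max cycle duration in seconds.
#' @param rotation_frequency latent rotations per gait cycle.
#' @param speed_offset_axis latent dimension carrying the speed offset.
#' @param speed_offset_gain latent units per km/h of speed difference.
#' @param base_log_rate_range per-unit baseline log rate range, log(spikes/bin).
#' @param loading_scale typical norm of a unit's latent tuning vector.
#' @param latent_noise_sd stationary SD of the AR(1) latent noise
#'   (inter-trial variability; the paper does not state a magnitude, so it is
#'   a knob).
#' @param kinematic_noise_sd marker position noise SD in meters.
#' @param missing_kinematics_fraction fraction of trials whose kinematics are
#'   flagged absent (video occlusion etc.).
#' @param seed integer seed; the session is fully reproducible given it.
#' @return a `gait_config` list.
#' @export
gait_config <- function(n_units = 40L,
                        latent_dim = 4L,
                        n_trials_per_condition = 15L,
                        conditions = data.frame(
                          task = "TRM",
                          speed = c(1.1, 1.6, 2.4, 3.2, 4.0, 4.8, 6.4)),
                        gait_period_range = c(0.5, 0.7),
                        rotation_frequency = 1,
                        speed_offset_axis = min(3L, latent_dim),
                        speed_offset_gain = 0.3,
                        base_log_rate_range = c(-3, -0.8),
                        loading_scale = 0.8,
                        latent_noise_sd = 0.12,
                        kinematic_noise_sd = 0.003,
                        missing_kinematics_fraction = 0.15,
                        seed = 1L) {
  cfg <- list(n_units = as.integer(n_units), latent_dim = as.integer(latent_dim),
              n_trials_per_condition = as.integer(n_trials_per_condition),
              conditions = conditions,
              gait_period_range = gait_period_range,
              rotation_frequency = rotation_frequency,
              speed_offset_axis = as.integer(speed_offset_axis),
              speed_offset_gain = speed_offset_gain,
              base_log_rate_range = base_log_rate_range,
              loading_scale = loading_scale,
              latent_noise_sd = latent_noise_sd,
              kinematic_noise_sd = kinematic_noise_sd,
              missing_kinematics_fraction = missing_kinematics_fraction,
              seed = as.integer(seed))
  validate_gait_config(cfg)
  structure(cfg, class = "gait_config")
}

validate_gait_config <- function(cfg) {
  stopifnot(cfg$n_units >= 1, cfg$n_trials_per_condition >= 1,
            nrow(cfg$conditions) >= 1,
            all(c("task", "speed") %in% names(cfg$conditions)),
            length(cfg$gait_period_range) == 2,
            cfg$gait_period_range[1] > 0,
            diff(cfg$gait_period_range) >= 0,
            cfg$speed_offset_axis >= 1,
            cfg$latent_noise_sd >= 0, cfg$kinematic_noise_sd >= 0)
  if (cfg$latent_dim < 2L) stop("latent_dim must be >= 2: the rotation needs a plane")
  if (cfg$speed_offset_axis > cfg$latent_dim) {
    stop("speed_offset_axis exceeds latent_dim")
  }
  if (cfg$missing_kinematics_fraction < 0 || cfg$missing_kinematics_fraction > 1) {
    stop("missing_kinematics_fraction must lie in [0, 1]")
  }
  invisible(cfg)
}

# Fixed hind-limb marker scaffold (meters, crest at the origin) and the
# latent-to-marker affine readout used by the generator.
marker_base_pose <- function() {
  c(crest_h = 0,     crest_v = 0,
    hip_h   = 0.02,  hip_v   = -0.04,
    knee_h  = 0.06,  knee_v  = -0.12,
    ankle_h = 0.01,  ankle_v = -0.20,
    meta_h  = 0.06,  meta_v  = -0.25,
    toe_h   = 0.095, toe_v   = -0.255)
}

marker_readout <- function(latent_dim) {
  # rows: the 10 non-crest coordinates; columns: latent dims.
  # Each coordinate is a phase-shifted mixture of the rotation pair (dims 1-2)
  # plus a small contribution from the harmonic/offset dims.
  nm <- setdiff(names(marker_base_pose()), c("crest_h", "crest_v"))
  amp <- c(hip_h = 0.020, hip_v = 0.012,
           knee_h = 0.030, knee_v = 0.015,
           ankle_h = 0.045, ankle_v = 0.020,
           meta_h = 0.055, meta_v = 0.025,
           toe_h = 0.060, toe_v = 0.028)
  phase <- c(hip_h = 0.0, hip_v = 1.2,
             knee_h = 0.3, knee_v = 1.6,
             ankle_h = 0.5, ankle_v = 2.0,
             meta_h = 0.7, meta_v = 2.4,
             toe_h = 0.8, toe_v = 2.6)
  G <- matrix(0, length(nm), latent_dim, dimnames = list(nm, NULL))
  G[, 1L] <- amp[nm] * cos(phase[nm])
  G[, 2L] <- amp[nm] * sin(phase[nm])
  if (latent_dim >= 3L) G[, 3L] <- amp[nm] * 0.2 * cos(phase[nm] + 0.7)
  if (latent_dim >= 4L) G[, 4L] <- amp[nm] * 0.2 * sin(phase[nm] + 0.7)
  G
}

#' Generate a ground-truth synthetic locomotor session
#'
#' Builds one continuous epoch of back-to-back gait cycles. The latent state
#' is a deterministic rotating mean (phase advances exactly one rotation per
#' gait cycle, continuous across trials, never reset) plus stationary AR(1)
#' noise; a per-condition constant offset proportional to speed (and a fixed
#' random offset per non-treadmill task) shifts the mean on
#' `speed_offset_axis`. Counts are drawn conditionally Poisson with rate
#' `exp(C x_t + d)` per 10 ms bin; marker positions are affine in the latents
#' plus i.i.d. Gaussian noise, sampled on frames aligned 1:1 with the bins.
#' Foot-strike and toe-off events sit at phase 0 and 60% of each cycle.
#'
#' @param config a [gait_config()].
#' @return object of class `gait_session`: `counts` (units x bins),
#'   `kinematics` (observed markers, NA for kinematics-absent trials),
#'   `kinematics_true` (noise-free markers), `latents_true`, `trials`
#'   (data.frame of single-cycle trials), `params_true` (mean-period
#'   [plds_params()] summary of the generative dynamics), `readout` (the
#'   latent-to-marker affine map), `config`.
#' @export
generate_session <- function(config) {
  validate_gait_config(config)
  set.seed(config$seed)
  p <- config$latent_dim
  n <- config$n_units

  conds <- config$conditions
  cond_idx <- rep(seq_len(nrow(conds)), each = config$n_trials_per_condition)
  cond_idx <- sample(cond_idx)            # interleave conditions
  n_tr <- length(cond_idx)
  speeds <- conds$speed[cond_idx]
  tasks <- as.character(conds$task[cond_idx])

  # fixed random task offsets (TRM = reference, offset 0) on the offset axis
  utask <- unique(as.character(conds$task))
  task_off <- stats::setNames(numeric(length(utask)), utask)
  extra <- setdiff(utask, "TRM")
  task_off[extra] <- stats::rnorm(length(extra), 0, 1.5)

  ref_speed <- mean(conds$speed, na.rm = TRUE)

  periods <- stats::runif(n_tr, config$gait_period_range[1], config$gait_period_range[2])
  T_bins <- pmax(20L, as.integer(round(periods / 0.01)))
  stance_bins <- as.integer(round(0.6 * T_bins))
  total <- sum(T_bins)

  # deterministic rotating mean + harmonic pair + condition offsets
  M <- matrix(0, p, total)
  offsets <- matrix(0, p, n_tr)
  pos <- 0L
  for (i in seq_len(n_tr)) {
    th <- 2 * pi * config$rotation_frequency * (seq_len(T_bins[i]) - 1L) / T_bins[i]
    idx <- pos + seq_len(T_bins[i])
    M[1L, idx] <- cos(th)
    M[2L, idx] <- sin(th)
    if (p >= 4L) {
      M[3L, idx] <- M[3L, idx] + 0.4 * cos(2 * th)
      M[4L, idx] <- 0.4 * sin(2 * th)
    }
    off <- numeric(p)
    spd <- if (is.na(speeds[i])) ref_speed else speeds[i]
    off[config$speed_offset_axis] <-
      config$speed_offset_gain * (spd - ref_speed) + task_off[tasks[i]]
    offsets[, i] <- off
    M[, idx] <- M[, idx] + off
    pos <- pos + T_bins[i]
  }

  # stationary AR(1) latent noise, continuous across the session
  a_noise <- 0.95
  sig <- config$latent_noise_sd
  eps <- matrix(0, p, total)
  eps[, 1L] <- stats::rnorm(p, 0, sig)
  innov_sd <- sig * sqrt(1 - a_noise^2)
  if (total > 1L) {
    w <- matrix(stats::rnorm(p * (total - 1L), 0, innov_sd), p)
    for (t in 2:total) eps[, t] <- a_noise * eps[, t - 1L] + w[, t - 1L]
  }
  X <- M + eps

  # Poisson observations
  Cload <- matrix(stats::rnorm(n * p), n, p)
  norms <- sqrt(rowSums(Cload^2))
  target_norm <- stats::runif(n, 0.5, 1.5) * config$loading_scale
  Cload <- Cload * target_norm / norms
  d <- stats::runif(n, config$base_log_rate_range[1], config$base_log_rate_range[2])
  lam <- exp(Cload %*% X + d)
  if (max(lam) > 20) {
    stop(sprintf("generative rate %.1f spikes/bin exceeds the 20/bin bound; lower loading_scale or base_log_rate_range", max(lam)))
  }
  counts <- matrix(stats::rpois(n * total, as.vector(lam)), n, total)

  # kinematics: affine readout of the latents + Gaussian noise, crest = origin
  base <- marker_base_pose()
  G <- marker_readout(p)
  kin_true <- matrix(rep(base, each = total), total, length(base),
                     dimnames = list(NULL, names(base)))
  kin_true[, rownames(G)] <- kin_true[, rownames(G)] + t(G %*% X)
  kin_obs <- kin_true
  nzc <- setdiff(colnames(kin_obs), c("crest_h", "crest_v"))
  kin_obs[, nzc] <- kin_obs[, nzc] +
    stats::rnorm(total * length(nzc), 0, config$kinematic_noise_sd)

  # trial table; events at bin edges (phase 0 and 60%)
  ends <- cumsum(T_bins)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  fs_t <- (starts - 1L) * 0.01
  to_t <- fs_t + stance_bins * 0.01
  nfs_t <- ends * 0.01
  miss <- stats::runif(n_tr) < config$missing_kinematics_fraction
  for (i in which(miss)) kin_obs[starts[i]:ends[i], nzc] <- NA_real_
  trials <- data.frame(trial = seq_len(n_tr),
                       bin_start = starts, bin_end = ends,
                       foot_strike_t = fs_t, toe_off_t = to_t,
                       next_foot_strike_t = nfs_t,
                       task = tasks, speed = speeds,
                       has_kinematics = !miss)

  # mean-period summary of the generative dynamics
  Tbar <- mean(T_bins)
  om <- 2 * pi * config$rotation_frequency / Tbar
  A <- diag(p) * a_noise
  A[1:2, 1:2] <- 0.995 * rot2(om)
  if (p >= 4L) A[3:4, 3:4] <- 0.995 * rot2(2 * om)
  Qd <- diag(p) * innov_sd^2 + diag(p) * 1e-8
  params_true <- plds_params(A = A, Q = Qd, C = Cload, d = d,
                             x0 = rowMeans(X[, starts, drop = FALSE]),
                             Q0 = spd_repair(stats::cov(t(X[, starts, drop = FALSE])), 1e-6))

  structure(list(counts = counts,
                 kinematics = as.data.frame(kin_obs),
                 kinematics_true = as.data.frame(kin_true),
                 latents_true = X,
                 trials = trials,
                 params_true = params_true,
                 readout = list(base = base, G = G),
                 config = config),
            class = "gait_session")
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("Synthetic locomotor session: %d units, %d bins (10 ms), %d trials\n",
              nrow(x$counts), ncol(x$counts), nrow(x$trials)))
  tb <- table(x$trials$task)
  cat("  trials per task:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  cat(sprintf("  kinematics available: %d/%d trials\n",
              sum(x$trials$has_kinematics), nrow(x$trials)))
  invisible(x)
}

#' Ideal decoding ceiling from the true latents
#'
#' Decodes the observed kinematic variables and gait phase from the
#' ground-truth latents with the same lag-10 Wiener decoder used on neural
#' features. Because no neural feature can carry more kinematic information
#' than the latents that generated the kinematics, the resulting per-variable
#' R-squared is the ceiling any neural decoder is compared against. Marker
#' positions are affine in the latents, so their noise-free ceiling is
#' exactly 1; trigonometric angle variables, leg extension and the phase ramp
#' are nonlinear readouts and plateau slightly below 1 even without noise.
#'
#' @param session a `gait_session`.
#' @param order Wiener filter order.
#' @return data.frame with per-variable mean R-squared across trials.
#' @export
ideal_decoding_ceiling <- function(session, order = 10L) {
  tr <- session$trials[session$trials$has_kinematics, , drop = FALSE]
  if (nrow(tr) == 0L) stop("session has no trials with kinematics")
  targets <- session_targets(session)
  feats <- lapply(seq_len(nrow(tr)), function(i) {
    t(session$latents_true[, tr$bin_start[i]:tr$bin_end[i], drop = FALSE])
  })
  ys <- lapply(seq_len(nrow(tr)), function(i) {
    as.matrix(targets[tr$bin_start[i]:tr$bin_end[i], , drop = FALSE])
  })
  wf <- wiener_fit(feats, ys, order = order)
  preds <- lapply(feats, function(f) wiener_predict(wf, f))
  sc <- r2_score(ys, preds)
  agg <- stats::aggregate(r_squared ~ variable, data = sc, FUN = mean)
  names(agg)[2L] <- "r_squared"
  agg
}

# Kinematic + gait-phase target matrix aligned with the session bins.
session_targets <- function(session) {
  kin <- derive_kinematics(session$kinematics)
  phase <- rep(NA_real_, ncol(session$counts))
  for (i in seq_len(nrow(session$trials))) {
    tr <- session$trials[i, ]
    idx <- tr$bin_start:tr$bin_end
    tt <- (idx - 1L) * 0.01
    phase[idx] <- gait_phase(tr, tt)
  }
  cbind(kin, gait_phase = phase)
}
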