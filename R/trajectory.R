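#' Time-normalize a single-trial latent trajectory to the gait cycle
#'
#' Resamples a trial's latent time series onto a 100-point grid of gait-cycle
#' percentages (1..100%) by linear interpolation of each latent dimension
#' against the within-trial gait phase: stance (foot-strike to toe-off) maps
#' to 0-60% and swing to 60-100%, so grid point 60 is the stance/swing
#' transition and grid point 100 the cycle end. Values beyond the last
#' sampled phase are held at the final bin (the cycle's last time point).
#'
#' @param latents `p x T` latent (or feature) matrix for one trial.
#' @param events list/data.frame row with `foot_strike_t`, `toe_off_t`,
#'   `next_foot_strike_t`.
#' @param t_bins bin start times (seconds), length `T`; defaults to 10 ms
#'   bins from `foot_strike_t`.
#' @return `normalized_trajectory`: `p x 100` matrix with columns named by
#'   grid percent.
#' @export
normalize_gait_cycle <- function(latents, events, t_bins = NULL) {
  latents <- as.matrix(latents)
  Tn <- ncol(latents)
  if (is.null(t_bins)) {
    t_bins <- events$foot_strike_t + 0.01 * (seq_len(Tn) - 1L)
  }
  if (length(t_bins) != Tn) stop("t_bins length must match the trial")
  ph <- gait_phase(events, t_bins)
  n_stance <- sum(ph < 60)
  if (n_stance < 2L || Tn - n_stance < 2L) {
    stop("trial needs at least two bins in each of stance and swing")
  }
  grid <- seq_len(100L)
  out <- t(apply(latents, 1L, function(v) {
    stats::approx(ph, v, xout = grid, rule = 2L)$y
  }))
  colnames(out) <- grid
  structure(out, class = c("normalized_trajectory", "matrix"),
            phase_grid = grid)
}

#' Pointwise average of time-normalized trajectories
#'
#' @param norm_list list of `p x 100` normalized trajectories from one
#'   condition.
#' @return list with `mean` (`p x 100`) and `sd` (`p x 100` pointwise
#'   dispersion across trials; NA with a single trial).
#' @export
average_trajectories <- function(norm_list) {
  stopifnot(length(norm_list) >= 1L)
  arr <- simplify2array(norm_list)          # p x 100 x n
  m <- apply(arr, c(1L, 2L), mean)
  s <- if (length(norm_list) > 1L) apply(arr, c(1L, 2L), stats::sd)
       else matrix(NA_real_, nrow(m), ncol(m))
  list(mean = m, sd = s, n = length(norm_list))
}

#' Mahalanobis distance profile of trials against a reference distribution
#'
#' At each of the 100 gait-cycle grid points, the reference trial type
#' defines a distribution (mean and covariance across reference trials of
#' the latent values at that point, in the full `dims`-dimensional space);
#' each comparison trial contributes the Mahalanobis distance of its value
#' to that distribution. The profile is the per-point mean across comparison
#' trials with its SEM, and the overall distance is the grand mean over
#' points and trials.
#'
#' With few reference trials the per-point covariance is singular; it is
#' shrunk toward its diagonal with intensity `alpha` (chosen automatically as
#' `p / (p + n_ref)` when `alpha = NULL` and the reference count is at most
#' `dims`, else 0), plus a tiny ridge.
#'
#' @param comparison list of normalized trajectories (`p x 100`) to score.
#' @param reference list of normalized reference trajectories (>= 2).
#' @param dims number of leading dimensions to use (default: all).
#' @param alpha shrinkage intensity in `[0, 1]` toward the diagonal, or
#'   `NULL` for automatic.
#' @return `distance_profile`: data.frame (`percent`, `mean_distance`,
#'   `sem`), plus attributes `overall_mean`, `alpha`, `distances`
#'   (trials x 100 matrix).
#' @export
mahalanobis_profile <- function(comparison, reference, dims = NULL, alpha = NULL) {
  stopifnot(length(reference) >= 2L, length(comparison) >= 1L)
  p_full <- nrow(reference[[1L]])
  if (is.null(dims)) dims <- p_full
  stopifnot(dims >= 1L, dims <= p_full)
  n_ref <- length(reference)
  if (is.null(alpha)) {
    alpha <- if (n_ref <= dims) dims / (dims + n_ref) else 0
  }
  ref_arr <- simplify2array(lapply(reference, function(m) m[seq_len(dims), , drop = FALSE]))
  cmp_arr <- simplify2array(lapply(comparison, function(m) m[seq_len(dims), , drop = FALSE]))
  n_cmp <- length(comparison)
  D <- matrix(0, n_cmp, 100L)
  for (g in seq_len(100L)) {
    refg <- matrix(ref_arr[, g, ], nrow = dims)      # dims x n_ref
    mu <- rowMeans(refg)
    S <- tcrossprod(refg - mu) / (n_ref - 1L)
    S <- (1 - alpha) * S + alpha * diag(diag(S), dims)
    S <- S + diag(dims) * 1e-10
    cS <- tryCatch(chol(S), error = function(e) {
      stop("singular reference covariance at grid point ", g,
           "; increase shrinkage (alpha)")
    })
    cmpg <- matrix(cmp_arr[, g, ], nrow = dims)
    wh <- backsolve(cS, cmpg - mu, transpose = TRUE)
    D[, g] <- sqrt(colSums(wh^2))
  }
  prof <- data.frame(percent = seq_len(100L),
                     mean_distance = colMeans(D),
                     sem = apply(D, 2L, stats::sd) / sqrt(n_cmp))
  structure(prof, class = c("distance_profile", "data.frame"),
            overall_mean = mean(D), alpha = alpha, distances = D)
}

#' Speed separation of latent trajectories
#'
#' Reports the Spearman rank correlation between the absolute speed
#' difference to a reference speed (default: the fastest) and the overall
#' mean Mahalanobis distance of each speed's trials to the reference-speed
#' distribution — the speed-separation signature of the latent space.
#'
#' @param norm_by_speed named list: speed value (km/h, as name) -> list of
#'   normalized trajectories for that speed.
#' @param reference_speed reference speed; defaults to the fastest.
#' @param dims,alpha forwarded to [mahalanobis_profile()].
#' @return list with `table` (speed, abs_dspeed, mean_distance) and
#'   `spearman` (NA with fewer than three non-reference speeds).
#' @export
speed_separation <- function(norm_by_speed, reference_speed = NULL,
                             dims = NULL, alpha = NULL) {
  speeds <- as.numeric(names(norm_by_speed))
  stopifnot(!anyNA(speeds))
  if (is.null(reference_speed)) reference_speed <- max(speeds)
  ref_key <- names(norm_by_speed)[which.min(abs(speeds - reference_speed))]
  reference <- norm_by_speed[[ref_key]]
  others <- setdiff(names(norm_by_speed), ref_key)
  tab <- do.call(rbind, lapply(others, function(k) {
    pr <- mahalanobis_profile(norm_by_speed[[k]], reference, dims = dims,
                              alpha = alpha)
    data.frame(speed = as.numeric(k),
               abs_dspeed = abs(as.numeric(k) - as.numeric(ref_key)),
               mean_distance = attr(pr, "overall_mean"))
  }))
  rho <- if (nrow(tab) >= 3L) {
    stats::cor(tab$abs_dspeed, tab$mean_distance, method = "spearman")
  } else NA_real_
  list(table = tab, spearman = rho, reference_speed = as.numeric(ref_key))
}
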