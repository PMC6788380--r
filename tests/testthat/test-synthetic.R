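# Ground-truth session generator: reproducibility, generative statistics,
# alignment invariants, and the ideal decoding ceiling.

test_that("sessions are bit-identical under one seed and differ across seeds", {
  cfg <- gait_config(n_units = 6L, latent_dim = 2L, n_trials_per_condition = 4L,
                     conditions = data.frame(task = "TRM", speed = 4.0),
                     seed = 5L)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$latents_true, s2$latents_true)
  expect_identical(s1$kinematics, s2$kinematics)
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(generate_session(cfg2)$counts, s1$counts))
})

test_that("config invariants are enforced", {
  expect_error(gait_config(latent_dim = 1L), "plane")
  expect_error(gait_config(missing_kinematics_fraction = 1.2), "0, 1")
  expect_error(gait_config(speed_offset_axis = 9L, latent_dim = 4L), "exceeds")
  # rate bound: overly strong baselines must be rejected
  expect_error(generate_session(gait_config(
    n_units = 5L, latent_dim = 2L, n_trials_per_condition = 2L,
    conditions = data.frame(task = "TRM", speed = 4.0),
    base_log_rate_range = c(3, 4), seed = 1L)), "bound")
})

test_that("bins, frames and trial structure are aligned by construction", {
  s <- small_session()
  expect_equal(nrow(s$kinematics), ncol(s$counts))     # 1:1 frames/bins
  expect_equal(ncol(s$latents_true), ncol(s$counts))
  expect_true(all(s$counts >= 0))
  expect_true(all(s$counts == round(s$counts)))
  tr <- s$trials
  # trials tile the session
  expect_equal(tr$bin_start, c(1L, utils::head(tr$bin_end, -1L) + 1L))
  # stance is ~60% of each cycle by construction
  stance_frac <- (tr$toe_off_t - tr$foot_strike_t) /
    (tr$next_foot_strike_t - tr$foot_strike_t)
  expect_true(all(abs(stance_frac - 0.6) < 0.02))
  # gait-phase round trip at event bins is exact
  for (i in c(1L, nrow(tr))) {
    expect_identical(gait_phase(tr[i, ], tr$foot_strike_t[i]), 0)
    expect_identical(gait_phase(tr[i, ], tr$toe_off_t[i]), 60)
    expect_identical(gait_phase(tr[i, ], tr$next_foot_strike_t[i]), 100)
  }
})

test_that("counts are conditionally Poisson with rate exp(Cx + d)", {
  s <- generate_session(gait_config(
    n_units = 30L, latent_dim = 4L, n_trials_per_condition = 100L,
    conditions = data.frame(task = "TRM", speed = 4.0), seed = 21L))
  lam <- exp(s$params_true$C %*% s$latents_true + s$params_true$d)
  # per-unit mean within 4 standard errors of the generative mean
  nb <- ncol(s$counts)
  se <- sqrt(rowSums(lam)) / nb
  expect_true(all(abs(rowMeans(s$counts) - rowMeans(lam)) < 4 * se))
  # Pearson residuals have unit variance under the conditional Poisson law
  pearson <- (s$counts - lam) / sqrt(lam)
  expect_equal(mean(pearson^2), 1, tolerance = 0.03)
})

test_that("noise-free kinematics are exactly affine in the latents", {
  s <- generate_session(gait_config(
    n_units = 10L, latent_dim = 4L, n_trials_per_condition = 6L,
    conditions = data.frame(task = "TRM", speed = 4.0),
    kinematic_noise_sd = 0, missing_kinematics_fraction = 0, seed = 9L))
  X <- cbind(1, t(s$latents_true))
  for (col in c("toe_h", "ankle_v", "knee_h")) {
    res <- stats::lm.fit(X, s$kinematics[[col]])$residuals
    expect_lt(max(abs(res)), 1e-10)
  }
})

test_that("zero speed-offset gain collapses the speed separation", {
  mk_cfg <- function(gain, seed) gait_config(
    n_units = 10L, latent_dim = 4L, n_trials_per_condition = 15L,
    conditions = data.frame(task = "TRM", speed = c(1.6, 4.0, 6.4)),
    speed_offset_gain = gain, seed = seed)
  mean_by_speed <- function(s) {
    tr <- s$trials
    vapply(split(seq_len(nrow(tr)), tr$speed), function(idx) {
      mean(s$latents_true[3L, unlist(lapply(idx, function(i) {
        tr$bin_start[i]:tr$bin_end[i]
      }))])
    }, numeric(1))
  }
  off0 <- mean_by_speed(generate_session(mk_cfg(0, 31L)))
  off1 <- mean_by_speed(generate_session(mk_cfg(0.3, 31L)))
  expect_lt(diff(range(off0)), 0.15)          # coincide up to sampling error
  expect_gt(diff(range(off1)), 1)             # separated by the offsets
  # offsets ordered with speed on the configured axis
  expect_true(all(diff(off1[order(as.numeric(names(off1)))]) > 0))
})

test_that("ideal ceiling is exact for affine variables and noise-bounded", {
  s0 <- generate_session(gait_config(
    n_units = 15L, latent_dim = 4L, n_trials_per_condition = 10L,
    conditions = data.frame(task = "TRM", speed = 4.0),
    kinematic_noise_sd = 0, missing_kinematics_fraction = 0, seed = 3L))
  ic0 <- ideal_decoding_ceiling(s0)
  pos_vars <- c(paste0(c("hip", "knee", "ankle", "meta", "toe"), "_h"),
                paste0(c("hip", "knee", "ankle", "meta", "toe"), "_v"))
  expect_true(all(abs(ic0$r_squared[ic0$variable %in% pos_vars] - 1) < 1e-6))
  expect_true(all(ic0$r_squared > 0.7))   # nonlinear readouts stay high

  # with noise every ceiling drops below 1, and doubling the noise lowers it
  mk <- function(sd_kin) generate_session(gait_config(
    n_units = 15L, latent_dim = 4L, n_trials_per_condition = 10L,
    conditions = data.frame(task = "TRM", speed = 4.0),
    kinematic_noise_sd = sd_kin, missing_kinematics_fraction = 0, seed = 3L))
  ic1 <- ideal_decoding_ceiling(mk(0.003))
  ic2 <- ideal_decoding_ceiling(mk(0.006))
  kin <- ic1$variable != "gait_phase"   # phase is untouched by marker noise
  expect_true(all(ic1$r_squared[kin] < 1))
  m <- merge(ic1[kin, ], ic2[kin, ], by = "variable", suffixes = c("_lo", "_hi"))
  expect_true(all(m$r_squared_hi < m$r_squared_lo))
})
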