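# Gait-cycle time normalization, trajectory averaging, Mahalanobis profiles.

grid_trial <- function(latents = NULL, Tn = 100L) {
  # cycle of 1 s with stance ending at 0.6 s: bin i (1-based) sits at phase i-1
  ev <- list(foot_strike_t = 0, toe_off_t = 0.6, next_foot_strike_t = 1.0)
  if (is.null(latents)) latents <- matrix(rnorm(2 * Tn), 2, Tn)
  list(latents = latents, ev = ev)
}

test_that("a trial sampled on the grid passes through unchanged", {
  tr <- grid_trial()
  nt <- normalize_gait_cycle(tr$latents, tr$ev)
  expect_equal(dim(nt), c(2L, 100L))
  # grid percent g corresponds to bin g+1 (bin 1 is phase 0); 100% holds the
  # final sample
  expect_equal(unclass(nt)[, 1:99], tr$latents[, 2:100], ignore_attr = TRUE)
  expect_equal(nt[, 100], tr$latents[, 100], ignore_attr = TRUE)
})

test_that("anchor phases are preserved exactly and ramps interpolate linearly", {
  Tn <- 100L
  ramp <- matrix(0, 1, Tn)
  ramp[1, 1:60] <- seq(0, 1, length.out = 60)   # rises over stance
  ramp[1, 61:Tn] <- 1
  tr <- grid_trial(ramp)
  nt <- normalize_gait_cycle(tr$latents, tr$ev)
  expect_equal(unname(nt[1, 60]), ramp[1, 61])  # point 60 = toe-off bin value
  expect_equal(unname(nt[1, 100]), 1)
  expect_true(all(abs(diff(nt[1, 1:59]) - diff(nt[1, 1:59])[1]) < 1e-9))
  expect_true(all(nt[1, 61:100] == 1))
  # constant latent -> constant trajectory
  cn <- normalize_gait_cycle(matrix(2.5, 1, 40),
                             list(foot_strike_t = 0, toe_off_t = 0.24,
                                  next_foot_strike_t = 0.4))
  expect_true(all(cn == 2.5))
  expect_error(normalize_gait_cycle(matrix(0, 1, 3),
                                    list(foot_strike_t = 0, toe_off_t = 0.02,
                                         next_foot_strike_t = 0.03)),
               "two bins")
})

test_that("averaging is pointwise with sensible edge cases", {
  tr <- grid_trial()
  nt <- normalize_gait_cycle(tr$latents, tr$ev)
  one <- average_trajectories(list(nt))
  expect_equal(one$mean, unclass(nt), ignore_attr = TRUE)
  expect_true(all(is.na(one$sd)))
  mirror <- average_trajectories(list(nt, -nt))
  expect_lt(max(abs(mirror$mean)), 1e-12)
  # law of large numbers toward the generative mean trajectory
  set.seed(8)
  base <- matrix(sin(seq(0, 2 * pi, length.out = 100)), 1)
  sims <- lapply(1:400, function(i) {
    normalize_gait_cycle(base + matrix(rnorm(100, sd = 0.5), 1), tr$ev)
  })
  avg <- average_trajectories(sims)
  expect_lt(max(abs(avg$mean - normalize_gait_cycle(base, tr$ev))), 0.15)
})

test_that("Mahalanobis profile has its closed-form behaviours", {
  set.seed(9)
  ev <- grid_trial()$ev
  ref <- lapply(1:400, function(i) {
    normalize_gait_cycle(rbind(rnorm(100, sd = 1), rnorm(100, sd = 2)), ev)
  })
  # reference mean against the reference distribution: distance ~ 0
  ref_mean <- average_trajectories(ref)$mean
  pr0 <- mahalanobis_profile(list(ref_mean), ref, alpha = 0)
  expect_lt(attr(pr0, "overall_mean"), 0.1)
  # diagonal covariance diag(1, 4): point (1, 2) sits sqrt(2) away
  pt <- rbind(rep(1, 100), rep(2, 100))
  pr1 <- mahalanobis_profile(list(pt), ref, alpha = 0)
  expect_equal(attr(pr1, "overall_mean"), sqrt(2), tolerance = 0.1)
  # identity covariance: Mahalanobis reduces to Euclidean distance
  ref_id <- lapply(1:500, function(i) {
    normalize_gait_cycle(matrix(rnorm(200), 2), ev)
  })
  pt2 <- rbind(rep(0.6, 100), rep(-0.8, 100))
  pr2 <- mahalanobis_profile(list(pt2), ref_id, alpha = 0)
  expect_equal(attr(pr2, "overall_mean"), 1, tolerance = 0.1)
  expect_true(all(pr2$mean_distance >= 0))
  expect_equal(nrow(pr2), 100L)
  expect_error(mahalanobis_profile(list(pt2), ref_id[1]), ">= 2")
})

test_that("profiles are invariant under joint affine maps (no shrinkage)", {
  set.seed(10)
  ev <- grid_trial()$ev
  ref <- lapply(1:60, function(i) normalize_gait_cycle(matrix(rnorm(300), 3), ev))
  cmp <- lapply(1:5, function(i) normalize_gait_cycle(matrix(rnorm(300), 3), ev))
  pr <- mahalanobis_profile(cmp, ref, alpha = 0)
  M <- matrix(rnorm(9), 3) + diag(3) * 2
  b <- rnorm(3)
  tf <- function(x) M %*% x + b
  pr_t <- mahalanobis_profile(lapply(cmp, tf), lapply(ref, tf), alpha = 0)
  expect_equal(attr(pr_t, "distances"), attr(pr, "distances"), tolerance = 1e-6)
})

test_that("shrinkage engages automatically for small reference sets", {
  set.seed(11)
  ev <- grid_trial()$ev
  ref_small <- lapply(1:6, function(i) normalize_gait_cycle(matrix(rnorm(1200), 12), ev))
  cmp <- list(normalize_gait_cycle(matrix(rnorm(1200), 12), ev))
  pr <- mahalanobis_profile(cmp, ref_small, dims = 12)
  expect_gt(attr(pr, "alpha"), 0)
  expect_true(all(is.finite(pr$mean_distance)))
})

test_that("speed separation reports Spearman rank structure", {
  set.seed(12)
  ev <- grid_trial()$ev
  mk_speed <- function(offset) {
    lapply(1:12, function(i) {
      normalize_gait_cycle(rbind(rnorm(100, sd = 0.3),
                                 rnorm(100, mean = offset, sd = 0.3)), ev)
    })
  }
  speeds <- c(1.6, 2.4, 4.0, 6.4)
  by_speed <- stats::setNames(lapply(speeds, function(v) mk_speed(0.8 * (6.4 - v))),
                              speeds)
  ss <- speed_separation(by_speed)
  expect_equal(ss$reference_speed, 6.4)
  expect_equal(ss$spearman, 1)
  # two speeds only: correlation undefined
  ss2 <- speed_separation(by_speed[c("1.6", "6.4")])
  expect_true(is.na(ss2$spearman))
})
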