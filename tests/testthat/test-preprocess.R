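# Spike binning, rate estimation, z-scoring, gait phase, kinematic
# derivation and trial segmentation.

test_that("bin_spikes uses half-open 10 ms bins aligned to the frame clock", {
  counts <- bin_spikes(list(c(0.005, 0.012, 0.019)), t0 = 0, t1 = 0.05)
  expect_equal(as.numeric(counts[1, ]), c(1, 2, 0, 0, 0))
  expect_equal(sum(counts), 3)

  # spike exactly on a bin edge belongs to the later bin
  edge <- bin_spikes(list(0.010), t0 = 0, t1 = 0.03)
  expect_equal(as.numeric(edge[1, ]), c(0, 1, 0))

  none <- bin_spikes(list(numeric(0), numeric(0)), t0 = 0, t1 = 0.04)
  expect_true(all(none == 0))
  expect_equal(dim(none), c(2L, 4L))

  expect_error(bin_spikes(list(c(0.02, 0.01)), 0, 0.05), "sorted")
  expect_error(bin_spikes(list(0.07), 0, 0.05), "outside")
})

test_that("estimate_rates is a 100 ms trailing sum in spikes/s with warm-up", {
  x <- matrix(1, 1, 20)
  r <- estimate_rates(x)
  expect_equal(as.numeric(r[1, 10:20]), rep(100, 11))
  # warm-up: partial window divided by its actual duration
  expect_equal(r[1, 1], 1 / 0.01)
  expect_equal(r[1, 5], 5 / 0.05)

  expect_true(all(estimate_rates(matrix(0, 3, 15)) == 0))

  y <- matrix(0, 1, 10); y[1, 10] <- 5
  expect_equal(estimate_rates(y)[1, 10], 50)
})

test_that("z-scoring uses training statistics only and handles degenerate units", {
  zs <- zscore_fit(matrix(c(2, 4, 6), 1))
  expect_equal(as.numeric(zscore_apply(matrix(c(2, 4, 6), 1), zs)),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  # already standardized input is unchanged
  x <- matrix(c(-1, 0, 1) * sqrt(3 / 2), 1)
  expect_equal(zscore_apply(x, zscore_fit(x)), x, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_warning(zsc <- zscore_fit(matrix(5, 1, 10)), "zero-variance")
  expect_true(all(zscore_apply(matrix(5, 1, 4), zsc) == 0))

  # test data normalised with training stats, not its own
  train <- matrix(rnorm(50, mean = 3, sd = 2), 1)
  zs2 <- zscore_fit(train, tag = "foldA")
  test <- matrix(rnorm(20, mean = 10), 1)
  expect_equal(as.numeric(zscore_apply(test, zs2)),
               as.numeric((test - zs2$mean) / zs2$sd))
  expect_identical(zs2$tag, "foldA")
})

test_that("gait phase is piecewise linear with exact 0/60/100 anchors", {
  ev <- list(foot_strike_t = 1.0, toe_off_t = 1.6, next_foot_strike_t = 2.0)
  expect_identical(gait_phase(ev, 1.0), 0)
  expect_identical(gait_phase(ev, 1.6), 60)
  expect_identical(gait_phase(ev, 2.0), 100)
  expect_equal(gait_phase(ev, 1.3), 30)            # stance midpoint
  expect_equal(gait_phase(ev, 1.6 + 0.75 * 0.4), 90)  # 75% through swing
  expect_error(gait_phase(ev, 2.1), "outside")
  expect_error(gait_phase(list(foot_strike_t = 1, toe_off_t = 0.5,
                               next_foot_strike_t = 2), 1), "events")
})

make_markers <- function(n = 1L) {
  base <- gaitdyn:::marker_base_pose()
  as.data.frame(matrix(rep(base, each = n), n, length(base),
                       dimnames = list(NULL, names(base))))
}

test_that("derive_kinematics computes inner angles and leg extension", {
  mk <- make_markers()
  # right angle at the knee: hip (0,0), knee (0,-1), ankle (1,-1)
  mk$hip_h <- 0; mk$hip_v <- 0
  mk$knee_h <- 0; mk$knee_v <- -1
  mk$ankle_h <- 1; mk$ankle_v <- -1
  kv <- derive_kinematics(mk)
  expect_equal(kv$sin_knee, 1, tolerance = 1e-12)
  expect_equal(kv$cos_knee, 0, tolerance = 1e-12)

  # collinear limb segments: inner angle 180 degrees
  mk$ankle_h <- 0; mk$ankle_v <- -2
  kv <- derive_kinematics(mk)
  expect_equal(kv$sin_knee, 0, tolerance = 1e-12)
  expect_equal(kv$cos_knee, -1, tolerance = 1e-12)

  # 3-4-5 triangle for leg extension
  mk <- make_markers()
  mk$crest_h <- 0; mk$crest_v <- 0
  mk$meta_h <- 0.3; mk$meta_v <- -0.4
  expect_equal(derive_kinematics(mk)$leg_extension, 0.5)

  # degenerate triplet flagged NA
  mk <- make_markers()
  mk$knee_h <- mk$hip_h; mk$knee_v <- mk$hip_v
  expect_true(is.na(derive_kinematics(mk)$sin_knee))

  # positions are crest-relative
  mk <- make_markers()
  mk[, ] <- mk[, ] + 0.37   # translate everything
  kv <- derive_kinematics(mk)
  base <- gaitdyn:::marker_base_pose()
  expect_equal(kv$toe_h, unname(base["toe_h"] - base["crest_h"]))
})

test_that("sin^2 + cos^2 = 1 for every angle on session kinematics", {
  s <- small_session()
  kv <- derive_kinematics(s$kinematics_true)
  for (ang in c("hip", "knee", "ankle", "meta")) {
    expect_equal(kv[[paste0("sin_", ang)]]^2 + kv[[paste0("cos_", ang)]]^2,
                 rep(1, nrow(kv)), tolerance = 1e-12)
  }
})

test_that("segment_trials forms one trial per cycle and applies the filters", {
  counts <- matrix(1L, 2, 30)
  ev <- data.frame(foot_strike_t = c(0, 0.1, 0.2), toe_off_t = c(0.06, 0.16, 0.26))
  tr <- segment_trials(counts, NULL, ev, task = "TRM", speed = 2.4)
  expect_equal(nrow(tr), 2L)   # 3 foot-strikes -> 2 trials
  expect_equal(tr$bin_start, c(1L, 11L))
  expect_equal(tr$bin_end, c(10L, 20L))
  expect_false(any(tr$has_kinematics))

  # a corrupt neural bin excludes the trial, with a log message
  counts_bad <- counts
  counts_bad[1, 5] <- NA
  expect_message(tr2 <- segment_trials(counts_bad, NULL, ev), "excluded 1")
  expect_equal(nrow(tr2), 1L)
  expect_equal(attr(tr2, "n_excluded_neural"), 1L)

  expect_error(segment_trials(counts, NULL,
                              data.frame(foot_strike_t = c(0, 0.1),
                                         toe_off_t = c(0.12, 0.16))),
               "inside")
})

test_that("missing-kinematics flagging matches the configured fraction", {
  s <- generate_session(gait_config(
    n_units = 8L, latent_dim = 2L, n_trials_per_condition = 100L,
    conditions = data.frame(task = "TRM", speed = 4.0),
    missing_kinematics_fraction = 0.2, seed = 7L))
  n_missing <- sum(!s$trials$has_kinematics)
  # binomial(100, 0.2) within 4 sd
  expect_gt(n_missing, 20 - 4 * sqrt(100 * 0.2 * 0.8))
  expect_lt(n_missing, 20 + 4 * sqrt(100 * 0.2 * 0.8))
})
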