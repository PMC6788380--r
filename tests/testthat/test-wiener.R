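# Wiener filtering, R^2 scoring, cross-validation design, dimension sweep.

test_that("an exact lagged linear system is recovered to machine precision", {
  set.seed(1)
  feats <- lapply(1:4, function(k) matrix(rnorm(80), 80, 1))
  targs <- lapply(feats, function(f) {
    y <- 2 * f[, 1]
    y[4:80] <- y[4:80] - f[1:77, 1]
    matrix(y, ncol = 1, dimnames = list(NULL, "y"))
  })
  wf <- wiener_fit(feats, targs, order = 10L)
  coefs <- vapply(wf$coefficients, function(m) m[1, 1], numeric(1))
  expect_equal(coefs, c(2, 0, 0, -1, rep(0, 6)), tolerance = 1e-8)
  expect_equal(wf$intercept, 0, tolerance = 1e-8, ignore_attr = TRUE)
  preds <- lapply(feats, function(f) wiener_predict(wf, f))
  sc <- r2_score(targs, preds)
  expect_true(all(abs(sc$r_squared - 1) < 1e-10))
})

test_that("zero inputs give a zero filter with the target mean as intercept", {
  feats <- list(matrix(0, 50, 2))
  targs <- list(matrix(c(rnorm(50, 3), rnorm(50, -1)), 50, 2))
  expect_warning(wf <- wiener_fit(feats, targs, order = 10L), "rank-deficient")
  expect_true(all(vapply(wf$coefficients, function(m) max(abs(m)), numeric(1)) < 1e-8))
  expect_equal(wf$intercept, colMeans(targs[[1]][10:50, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
  pr <- wiener_predict(wf, feats[[1]])
  expect_equal(pr[20, ], wf$intercept, ignore_attr = TRUE)
})

test_that("coefficients solve the normal equations", {
  set.seed(2)
  feats <- list(matrix(rnorm(60 * 2), 60, 2))
  targs <- list(matrix(rnorm(60 * 3), 60, 3))
  ord <- 4L
  wf <- wiener_fit(feats, targs, order = ord)
  X <- cbind(1, gaitdyn:::lag_design(feats[[1]], ord))
  Y <- targs[[1]][ord:60, ]
  B_oracle <- solve(crossprod(X), crossprod(X, Y))
  B_pkg <- rbind(wf$intercept, do.call(rbind, lapply(wf$coefficients, t)))
  expect_lt(max(abs(B_oracle - B_pkg)), 1e-8)
})

test_that("prediction is time-invariant and flags warm-up samples", {
  set.seed(3)
  f <- matrix(rnorm(40), 40, 1)
  wf <- wiener_fit(list(f), list(matrix(cumsum(f), 40, 1)), order = 6L)
  p1 <- wiener_predict(wf, f)
  expect_true(all(is.na(p1[1:5, ])))
  f_shift <- rbind(matrix(rnorm(1), 1, 1), f[-40, , drop = FALSE])
  p2 <- wiener_predict(wf, f_shift)
  expect_equal(p2[8:40, 1], p1[7:39, 1])       # shifted in, shifted out
  expect_error(wiener_predict(wf, matrix(0, 10, 2)), "mismatch")
})

test_that("r2_score implements the per-trial statistic exactly", {
  expect_equal(r2_score(matrix(0:3, 4, 1), matrix(c(0.5, 1.5, 1.5, 2.5), 4, 1))$r_squared,
               0.8)
  y <- matrix(rnorm(30), 30, 1)
  expect_equal(r2_score(y, y)$r_squared, 1)
  expect_equal(r2_score(y, matrix(mean(y), 30, 1))$r_squared, 0)
  # independent implementation on random vectors
  set.seed(4)
  for (i in 1:20) {
    yt <- rnorm(15); yp <- rnorm(15)
    expect_equal(r2_score(matrix(yt), matrix(yp))$r_squared,
                 r2_direct(yt, yp), tolerance = 1e-12)
  }
  expect_warning(out <- r2_score(matrix(1, 10, 1), matrix(rnorm(10))),
                 "constant")
  expect_equal(nrow(out), 0L)
})

test_that("cross-validation is deterministic and partitions the trials", {
  s <- small_session()
  cv1 <- cv_decode(s, "fp", folds = 6L, seed = 9L)
  cv2 <- cv_decode(s, "fp", folds = 6L, seed = 9L)
  expect_identical(cv1, cv2)
  ph <- cv1[cv1$variable == "gait_phase", ]
  expect_setequal(ph$trial, seq_len(nrow(s$trials)))   # every trial tested
  expect_equal(anyDuplicated(ph$trial), 0L)            # exactly once
  sizes <- table(unique(ph[, c("fold", "trial")])$fold)
  expect_lte(diff(range(sizes)), 1)                    # near-equal folds
  # kinematic variables scored only for trials with kinematics
  kin <- cv1[cv1$variable == "toe_h", ]
  expect_setequal(kin$trial, which(s$trials$has_kinematics))
  expect_error(cv_decode(s, "pca", folds = 6L), "dims")
})

test_that("dimension sweep reports a plateau near the true dimensionality", {
  s <- small_session()
  sw <- dim_sweep(s, "pca", dims = c(1:6), folds = 5L, seed = 2L)
  expect_equal(nrow(sw$table), 6L)
  expect_true(sw$plateau_dim %in% 3:6)
  # consistency with a direct run at one dimensionality
  cv4 <- cv_decode(s, "pca", dims = 4L, folds = 5L, seed = 2L)
  expect_equal(sw$table$mean_r2[sw$table$dims == 4], mean(cv4$r_squared))
  # single-dimensionality sweep: plateau undefined
  sw1 <- dim_sweep(s, "pca", dims = 3L, folds = 5L, seed = 2L)
  expect_true(is.na(sw1$plateau_dim))
})
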