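#' Fit a lagged linear (Wiener) decoder
#'
#' Solves the multi-output least-squares problem
#' `y[t] = b0 + sum_{n=0..order-1} A_n X[t-n]` on a design built within each
#' continuous trial; the first `order - 1` samples of every trial have
#' incomplete lag context and are excluded from both fitting and scoring.
#' Order 10 at 10 ms steps (a 100 ms history) is the analysis default.
#'
#' @param features list of `T_i x k` feature matrices, one per trial (rows =
#'   10 ms steps).
#' @param targets list of `T_i x m` target matrices, time-aligned with
#'   `features`.
#' @param order number of lags (0 .. order-1).
#' @return `wiener_filter` object: `coefficients` (list of `order` `m x k`
#'   lag matrices, lag 0 first), `intercept` (length `m`), `order`, `rank`.
#' @export
wiener_fit <- function(features, targets, order = 10L) {
  stopifnot(length(features) == length(targets), length(features) >= 1L)
  dm <- lapply(seq_along(features), function(i) {
    lag_design(as.matrix(features[[i]]), order)
  })
  X <- do.call(rbind, dm)
  Y <- do.call(rbind, lapply(seq_along(targets), function(i) {
    y <- as.matrix(targets[[i]])
    y[order:nrow(y), , drop = FALSE]
  }))
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  if (nrow(X) <= ncol(X)) {
    warning("fewer valid samples than coefficients; solution is not unique")
  }
  Xi <- cbind(1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    warning("rank-deficient Wiener design; returning the minimum-norm solution")
    sv <- svd(Xi)
    pos <- sv$d > sv$d[1L] * 1e-10
    B <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], Y)) / sv$d[pos])
  } else {
    B <- qr.coef(qr_x, Y)
  }
  k <- ncol(features[[1L]])
  m <- ncol(Y)
  coefs <- vector("list", order)
  for (l in seq_len(order)) {
    rows <- 1L + (l - 1L) * k + seq_len(k)
    coefs[[l]] <- t(B[rows, , drop = FALSE])   # m x k
  }
  structure(list(coefficients = coefs, intercept = as.numeric(B[1L, ]),
                 order = as.integer(order), n_features = k,
                 rank = qr_x$rank, fitted = TRUE,
                 target_names = colnames(Y)),
            class = "wiener_filter")
}

# rows t = order..T; columns blocked by lag (lag 0 block first)
lag_design <- function(f, order) {
  Tn <- nrow(f)
  if (Tn < order) return(matrix(numeric(0), 0L, ncol(f) * order))
  blocks <- lapply(seq_len(order) - 1L, function(l) {
    f[(order - l):(Tn - l), , drop = FALSE]
  })
  do.call(cbind, blocks)
}

#' Predict from a fitted Wiener filter
#'
#' @param filter a `wiener_filter`.
#' @param features `T x k` feature matrix for one trial.
#' @return `T x m` prediction matrix; the first `order - 1` rows (incomplete
#'   lag context) are NA and are skipped by [r2_score()].
#' @export
wiener_predict <- function(filter, features) {
  if (!isTRUE(filter$fitted)) stop("filter has not been fitted")
  f <- as.matrix(features)
  if (ncol(f) != filter$n_features) stop("feature-count mismatch")
  Tn <- nrow(f)
  m <- length(filter$intercept)
  out <- matrix(NA_real_, Tn, m)
  colnames(out) <- filter$target_names
  if (Tn < filter$order) return(out)
  D <- lag_design(f, filter$order)
  B <- do.call(rbind, lapply(filter$coefficients, t))  # (order*k) x m
  out[filter$order:Tn, ] <- sweep(D %*% B, 2L, filter$intercept, "+")
  out
}

#' Per-trial, per-variable coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)` with `ybar` the
#' per-trial mean of the variable; unbounded below, at most 1. Samples where
#' either series is NA (missing kinematics, lag warm-up) are skipped; trials
#' where a variable is constant have an undefined score and are skipped with
#' a warning.
#'
#' @param y_true,y_pred lists of time-aligned `T_i x m` matrices (or single
#'   matrices).
#' @return data.frame with columns `trial`, `variable`, `r_squared`.
#' @export
r2_score <- function(y_true, y_pred) {
  if (is.matrix(y_true) || is.data.frame(y_true)) y_true <- list(as.matrix(y_true))
  if (is.matrix(y_pred) || is.data.frame(y_pred)) y_pred <- list(as.matrix(y_pred))
  stopifnot(length(y_true) == length(y_pred))
  out <- list()
  warned <- FALSE
  for (i in seq_along(y_true)) {
    yt <- as.matrix(y_true[[i]]); yp <- as.matrix(y_pred[[i]])
    stopifnot(all(dim(yt) == dim(yp)))
    vn <- colnames(yt)
    if (is.null(vn)) vn <- paste0("V", seq_len(ncol(yt)))
    for (j in seq_len(ncol(yt))) {
      ok <- !is.na(yt[, j]) & !is.na(yp[, j])
      if (sum(ok) < 2L) next
      yy <- yt[ok, j]; pp <- yp[ok, j]
      sst <- sum((yy - mean(yy))^2)
      if (sst < 1e-300) {
        if (!warned) {
          warning("constant target in at least one trial; R^2 undefined, skipped")
          warned <- TRUE
        }
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        trial = i, variable = vn[j],
        r_squared = 1 - sum((yy - pp)^2) / sst)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(trial = integer(0), variable = character(0),
                      r_squared = numeric(0)))
  }
  do.call(rbind, out)
}
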