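#' Fit a PCA projection on concatenated, z-scored training rates
#'
#' Trials are concatenated across time, z-scored per unit, the covariance is
#' eigendecomposed, and the projection stacks the eigenvectors of the
#' `n_components` largest eigenvalues. The eigenvector sign is fixed
#' deterministically (largest-magnitude element positive) so serialized
#' projections are reproducible.
#'
#' @param rates `units x bins` training firing-rate matrix (concatenated
#'   training trials).
#' @param n_components number of components to retain.
#' @param tag provenance label forwarded to the z-scoring statistics.
#' @return `pca_projection` object: `W` (`n_components x units`, orthonormal
#'   rows), `eigenvalues` (all, descending), `zstats`, `n_components`.
#' @export
pca_fit <- function(rates, n_components, tag = NULL) {
  rates <- as.matrix(rates)
  n <- nrow(rates)
  if (n_components > n) stop("n_components cannot exceed the number of units")
  zs <- zscore_fit(rates, tag = tag)
  z <- zscore_apply(rates, zs)
  S <- tcrossprod(z) / ncol(z)
  e <- eigen(S, symmetric = TRUE)
  rk <- sum(e$values > max(e$values) * 1e-10)
  if (n_components > rk) {
    stop(sprintf("n_components = %d exceeds the training covariance rank %d",
                 n_components, rk))
  }
  W <- t(e$vectors[, seq_len(n_components), drop = FALSE])
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  structure(list(W = W, eigenvalues = e$values, zstats = zs,
                 n_components = as.integer(n_components)),
            class = "pca_projection")
}

#' Project rates onto fitted principal components
#'
#' @param projection a `pca_projection` from [pca_fit()].
#' @param rates `units x bins` matrix.
#' @return `n_components x bins` component time series.
#' @export
pca_project <- function(projection, rates) {
  rates <- as.matrix(rates)
  if (nrow(rates) != length(projection$zstats$mean)) {
    stop("unit count mismatch with the fitted projection")
  }
  projection$W %*% zscore_apply(rates, projection$zstats)
}

#' Greedy predictive subsampling of units
#'
#' Forward selection of `n` units: at each step the unit whose inclusion
#' maximises the mean validation R-squared (averaged over all target
#' variables) of a lag-`order` Wiener decoder trained on the current subset
#' is added; ties break to the lowest unit index. The criterion is evaluated
#' on an inner validation split of the training trials — test folds are
#' never touched.
#'
#' @param features list of `T_i x units` z-scored rate matrices (training
#'   trials only).
#' @param targets list of `T_i x m` target matrices.
#' @param n number of units to select (>= 1).
#' @param valid_fraction fraction of training trials held out as the inner
#'   validation split.
#' @param order Wiener filter order used in the criterion decoder.
#' @param seed seed for the inner split.
#' @return `pss_selection` object: `chosen_units` (ordered), and
#'   `criterion_trace` (validation mean R-squared after each addition).
#' @export
pss_select <- function(features, targets, n, valid_fraction = 0.2,
                       order = 10L, seed = 1L) {
  stopifnot(length(features) == length(targets))
  n_units <- ncol(features[[1L]])
  if (n < 1L) stop("n must be >= 1")
  if (n > n_units) stop("cannot select more units than are available")
  K <- length(features)
  set.seed(seed)
  n_val <- max(1L, round(valid_fraction * K))
  if (K - n_val < 1L) stop("too few trials for an inner validation split")
  val_idx <- sort(sample.int(K, n_val))
  tr_idx <- setdiff(seq_len(K), val_idx)

  crit <- function(units) {
    f_tr <- lapply(features[tr_idx], function(f) f[, units, drop = FALSE])
    f_va <- lapply(features[val_idx], function(f) f[, units, drop = FALSE])
    wf <- suppressWarnings(wiener_fit(f_tr, targets[tr_idx], order = order))
    preds <- lapply(f_va, function(f) wiener_predict(wf, f))
    sc <- suppressWarnings(r2_score(targets[val_idx], preds))
    if (nrow(sc) == 0L) return(-Inf)
    mean(sc$r_squared)
  }

  chosen <- integer(0)
  trace <- numeric(0)
  remaining <- seq_len(n_units)
  for (step in seq_len(n)) {
    vals <- vapply(remaining, function(u) crit(c(chosen, u)), numeric(1))
    best <- remaining[which.max(vals)]   # which.max: first max -> lowest index
    chosen <- c(chosen, best)
    trace <- c(trace, max(vals))
    remaining <- setdiff(remaining, best)
  }
  structure(list(chosen_units = chosen, criterion_trace = trace,
                 valid_trials = val_idx),
            class = "pss_selection")
}
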