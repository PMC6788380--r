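#' Cross-validated neural decoding of kinematics and gait phase
#'
#' The decoding design of record: all trials of all tasks are combined,
#' shuffled (seeded) and split into `folds` blocks of near-equal size (sizes
#' differ by at most one trial; remainders go to the earliest folds). Per
#' fold, the feature stage — z-scoring for the full population (`fp`), PCA,
#' greedy predictive subsampling (`pss`), or PLDS EM — and the lag-10 Wiener
#' filter are fitted on the nine training blocks only, then the held-out
#' block is decoded and scored per trial with [r2_score()]. Kinematic
#' variables are decoded only for trials with kinematics; gait phase is
#' decoded for every trial.
#'
#' Rate-based features (`fp`, `pca`, `pss`) use the 100 ms trailing-window
#' firing rates; the PLDS stage consumes the raw 10 ms spike counts and its
#' features are the smoothed posterior-mean latents.
#'
#' @param session a `gait_session`.
#' @param method feature set: `"fp"`, `"plds"`, `"pca"`, or `"pss"`.
#' @param dims latent dimensionality / component count / subset size
#'   (ignored for `fp`).
#' @param folds number of cross-validation blocks.
#' @param seed seed controlling the shuffle (and any stochastic feature
#'   stage).
#' @param order Wiener filter order.
#' @param plds_control list overriding [plds_fit()] settings
#'   (`max_iter`, `tol`).
#' @param keep_predictions if `TRUE`, attach per-trial predicted and true
#'   target series (used by the spectral comparison).
#' @return data.frame with columns `fold`, `trial`, `variable`,
#'   `r_squared`, plus attributes `method`, `dims`, and for PLDS the summed
#'   held-out approximate log likelihood (`test_loglik`).
#' @export
cv_decode <- function(session, method = c("fp", "plds", "pca", "pss"),
                      dims = NULL, folds = 10L, seed = 1L, order = 10L,
                      plds_control = list(), keep_predictions = FALSE) {
  method <- match.arg(method)
  trials <- session$trials
  n_tr <- nrow(trials)
  if (n_tr < folds) stop("need at least as many trials as folds")
  if (method != "fp" && is.null(dims)) stop("dims is required for this method")

  rates <- estimate_rates(session$counts)
  targets <- session_targets(session)
  kin_vars <- setdiff(colnames(targets), "gait_phase")

  slice_rows <- function(i) trials$bin_start[i]:trials$bin_end[i]
  targ_list <- lapply(seq_len(n_tr), function(i) {
    as.matrix(targets[slice_rows(i), , drop = FALSE])
  })
  counts_list <- lapply(seq_len(n_tr), function(i) {
    session$counts[, slice_rows(i), drop = FALSE]
  })

  set.seed(seed)
  perm <- sample.int(n_tr)
  sizes <- rep(n_tr %/% folds, folds)
  rem <- n_tr %% folds
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  fold_of <- integer(n_tr)
  fold_of[perm] <- rep(seq_len(folds), sizes)

  results <- list()
  test_ll <- 0
  pred_store <- list()

  for (f in seq_len(folds)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    tag <- sprintf("fold%02d-train", f)

    feats <- switch(method,
      fp = {
        zs <- zscore_fit(rates[, unlist(lapply(tr, slice_rows)), drop = FALSE],
                         tag = tag)
        lapply(seq_len(n_tr), function(i) t(zscore_apply(rates[, slice_rows(i), drop = FALSE], zs)))
      },
      pca = {
        pj <- pca_fit(rates[, unlist(lapply(tr, slice_rows)), drop = FALSE],
                      dims, tag = tag)
        lapply(seq_len(n_tr), function(i) t(pca_project(pj, rates[, slice_rows(i), drop = FALSE])))
      },
      pss = {
        zs <- zscore_fit(rates[, unlist(lapply(tr, slice_rows)), drop = FALSE],
                         tag = tag)
        zfeat <- lapply(seq_len(n_tr), function(i) t(zscore_apply(rates[, slice_rows(i), drop = FALSE], zs)))
        crit_tr <- tr[vapply(tr, function(i) trials$has_kinematics[i], logical(1))]
        if (length(crit_tr) < 5L) crit_tr <- tr
        sel <- pss_select(zfeat[crit_tr], targ_list[crit_tr], n = dims,
                          order = order, seed = seed + f)
        lapply(zfeat, function(z) z[, sel$chosen_units, drop = FALSE])
      },
      plds = {
        ctrl <- utils::modifyList(list(max_iter = 50L, tol = 1e-5), plds_control)
        fit <- plds_fit(counts_list[tr], latent_dim = dims,
                        max_iter = ctrl$max_iter, tol = ctrl$tol,
                        seed = seed + f)
        for (i in te) {
          post <- plds_laplace_estep(counts_list[[i]], fit$params, want_cov = FALSE)
          test_ll <- test_ll + post$loglik
        }
        lapply(counts_list, function(yc) t(plds_decode(fit, yc)))
      })

    tr_kin <- tr[trials$has_kinematics[tr]]
    wf_kin <- if (length(tr_kin) > 0L) {
      suppressWarnings(wiener_fit(feats[tr_kin],
                 lapply(targ_list[tr_kin], function(m) m[, kin_vars, drop = FALSE]),
                 order = order))
    } else NULL
    wf_phase <- suppressWarnings(wiener_fit(feats[tr],
                   lapply(targ_list[tr], function(m) m[, "gait_phase", drop = FALSE]),
                   order = order))

    te_kin <- te[trials$has_kinematics[te]]
    if (length(te_kin) > 0L && !is.null(wf_kin)) {
      preds <- lapply(feats[te_kin], function(ft) wiener_predict(wf_kin, ft))
      sc <- r2_score(lapply(targ_list[te_kin], function(m) m[, kin_vars, drop = FALSE]),
                     preds)
      if (nrow(sc) > 0L) {
        sc$trial <- te_kin[sc$trial]
        sc$fold <- f
        results[[length(results) + 1L]] <- sc
      }
      if (keep_predictions) {
        for (ii in seq_along(te_kin)) {
          pred_store[[length(pred_store) + 1L]] <-
            list(trial = te_kin[ii], pred = preds[[ii]],
                 true = targ_list[[te_kin[ii]]][, kin_vars, drop = FALSE])
        }
      }
    } else if (length(te_kin) == 0L) {
      message(sprintf("fold %d has no kinematic trials; kinematic scores absent", f))
    }
    preds_ph <- lapply(feats[te], function(ft) wiener_predict(wf_phase, ft))
    sc_ph <- r2_score(lapply(targ_list[te], function(m) m[, "gait_phase", drop = FALSE]),
                      preds_ph)
    if (nrow(sc_ph) > 0L) {
      sc_ph$trial <- te[sc_ph$trial]
      sc_ph$fold <- f
      results[[length(results) + 1L]] <- sc_ph
    }
  }

  out <- do.call(rbind, results)
  out <- out[, c("fold", "trial", "variable", "r_squared")]
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "dims") <- dims
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  if (method == "plds") attr(out, "test_loglik") <- test_ll
  if (keep_predictions) attr(out, "predictions") <- pred_store
  out
}

#' Decoder performance as a function of feature dimensionality
#'
#' Runs [cv_decode()] at each dimensionality and reports the mean R-squared
#' over all decoded variables (and, for PLDS, the held-out approximate log
#' likelihood). The plateau dimensionality is the first at which the
#' R-squared increment over the previous dimensionality drops below 0.001;
#' with fewer than two dimensionalities the plateau is undefined (NA).
#'
#' @param session a `gait_session`.
#' @param method `"plds"`, `"pca"`, or `"pss"`.
#' @param dims increasing vector of dimensionalities to evaluate.
#' @inheritParams cv_decode
#' @return list with `table` (data.frame: dims, mean_r2, test_loglik) and
#'   `plateau_dim`.
#' @export
dim_sweep <- function(session, method = c("plds", "pca", "pss"),
                      dims = 1:20, folds = 10L, seed = 1L, order = 10L,
                      plds_control = list()) {
  method <- match.arg(method)
  stopifnot(!is.unsorted(dims, strictly = TRUE))
  rows <- lapply(dims, function(k) {
    cv <- cv_decode(session, method = method, dims = k, folds = folds,
                    seed = seed, order = order, plds_control = plds_control)
    data.frame(dims = k, mean_r2 = mean(cv$r_squared),
               test_loglik = if (method == "plds") attr(cv, "test_loglik") else NA_real_)
  })
  tab <- do.call(rbind, rows)
  plateau <- NA_integer_
  if (nrow(tab) >= 2L) {
    inc <- diff(tab$mean_r2)
    hit <- which(inc < 0.001)
    if (length(hit) > 0L) plateau <- tab$dims[hit[1L] + 1L]
  }
  list(table = tab, plateau_dim = plateau)
}
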