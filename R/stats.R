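#' Two-tailed Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Paired test on `x - y` (or a single difference vector). Zero differences
#' are dropped (the standard convention); with `n <= 25` untied absolute
#' differences the exact null distribution of the positive-rank sum `W+` is
#' computed by dynamic programming over rank subsets, otherwise (or with
#' ties) the normal approximation with continuity and tie corrections is
#' used. `p = 2 min(P(W <= w), P(W >= w))`, capped at 1.
#'
#' @param x,y paired samples, or differences in `x` with `y = NULL`.
#' @return list: `statistic` (W+), `p_value`, `n` (non-zero pairs),
#'   `method` ("exact" or "normal").
#' @export
signed_rank_test <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !ties) {
    # exact: counts of subset rank-sums via DP (2^n equally likely sign vectors)
    cnt <- numeric(n * (n + 1) / 2 + 1)       # index s+1 holds count of sum s
    cnt[1L] <- 1
    for (k in seq_len(n)) {
      shifted <- c(rep(0, k), utils::head(cnt, length(cnt) - k))
      cnt <- cnt + shifted
    }
    total <- 2^n
    probs <- cnt / total
    lo <- sum(probs[seq_len(W + 1)])          # P(W <= w)
    hi <- sum(probs[(W + 1):length(probs)])   # P(W >= w)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' Benjamini-Hochberg step-up multiple-testing correction
#'
#' @param p vector of raw p-values.
#' @param fdr false discovery rate (default 0.10, the analysis convention).
#' @return logical rejection flags aligned with `p` (monotone in raw
#'   p-value order).
#' @export
bh_reject <- function(p, fdr = 0.10) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  o <- order(p)
  ps <- p[o]
  thresh <- fdr * seq_len(m) / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  rej <- logical(m)
  if (is.finite(k) && k >= 1L) rej[o[seq_len(k)]] <- TRUE
  rej
}

#' Compare decoders against the full-population baseline across sessions
#'
#' For each decoder and decoded variable, pairs per-session mean R-squared
#' values with the baseline decoder's, reports the mean change in R-squared,
#' a two-tailed Wilcoxon signed-rank p-value, and Benjamini-Hochberg
#' significance flags at the given FDR applied across variables within each
#' decoder. All-zero difference vectors get `p = 1` and are flagged
#' degenerate.
#'
#' @param scores data.frame with columns `session`, `decoder`, `variable`,
#'   `r_squared` (one row per session x decoder x variable; per-session
#'   means).
#' @param baseline decoder name used as reference (default `"fp"`).
#' @param fdr false discovery rate for the step-up correction.
#' @return data.frame: `decoder`, `variable`, `n_sessions`, `delta_r2`,
#'   `p_value`, `significant`, `degenerate`.
#' @export
compare_decoders <- function(scores, baseline = "fp", fdr = 0.10) {
  need <- c("session", "decoder", "variable", "r_squared")
  stopifnot(all(need %in% names(scores)))
  base <- scores[scores$decoder == baseline, , drop = FALSE]
  if (nrow(base) == 0L) stop("baseline decoder not present in scores")
  others <- setdiff(unique(scores$decoder), baseline)
  out <- list()
  for (dec in others) {
    cur <- scores[scores$decoder == dec, , drop = FALSE]
    for (v in unique(cur$variable)) {
      a <- cur[cur$variable == v, c("session", "r_squared")]
      b <- base[base$variable == v, c("session", "r_squared")]
      mm <- merge(a, b, by = "session", suffixes = c("_dec", "_base"))
      if (nrow(mm) < 2L) next
      diffs <- mm$r_squared_dec - mm$r_squared_base
      degen <- all(diffs == 0)
      tst <- signed_rank_test(diffs)
      out[[length(out) + 1L]] <- data.frame(
        decoder = dec, variable = v, n_sessions = nrow(mm),
        delta_r2 = mean(diffs), p_value = tst$p_value, degenerate = degen)
    }
  }
  res <- do.call(rbind, out)
  res$significant <- FALSE
  for (dec in unique(res$decoder)) {
    sel <- res$decoder == dec
    res$significant[sel] <- bh_reject(res$p_value[sel], fdr = fdr)
  }
  rownames(res) <- NULL
  res
}
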