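#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with half-bandwidth
#' parameter `nw` from the standard symmetric tridiagonal commuting-operator
#' formulation: the tapers are its eigenvectors, ordered by decreasing
#' spectral concentration. Tapers are unit-energy; the sign convention makes
#' the mean of each taper's leading half positive.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product (e.g. 4).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  i <- seq_len(n) - 1L
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- i[-1L] * (n - i[-1L]) / 2
  # symmetric tridiagonal eigenproblem; top-k eigenvectors
  M <- diag(diag_main)
  M[cbind(2:n, 1:(n - 1L))] <- off
  M[cbind(1:(n - 1L), 2:n)] <- off
  e <- eigen(M, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
    if (sum(V[seq_len(ceiling(n / 2)), j]) < 0) V[, j] <- -V[, j]
  }
  V
}

#' Thomson multitaper power spectral density of decoded trials
#'
#' Per-trial PSDs (mean over DPSS tapered periodograms, one-sided, mean
#' removed) are interpolated onto a common 0-50 Hz grid and averaged across
#' trials. With unit-energy tapers the PSD integrates to approximately the
#' signal variance (Parseval, within taper bias).
#'
#' @param trials list of numeric vectors (one decoded variable per trial) or
#'   a single vector.
#' @param fs sampling rate in Hz (100 for 10 ms steps).
#' @param nw time-bandwidth product; `k` tapers (default `2 nw - 1`).
#' @param grid common frequency grid (Hz) for averaging.
#' @return `psd_estimate`: data.frame `frequency`, `power`, with attributes
#'   `nw`, `k`, `n_trials`, `n_skipped`.
#' @export
multitaper_psd <- function(trials, fs = 100, nw = 4, k = 2 * nw - 1,
                           grid = seq(0, 50, by = 0.5)) {
  if (is.numeric(trials)) trials <- list(trials)
  stopifnot(max(grid) <= fs / 2)
  acc <- matrix(NA_real_, length(trials), length(grid))
  skipped <- 0L
  for (i in seq_along(trials)) {
    x <- as.numeric(trials[[i]])
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L * k) { skipped <- skipped + 1L; next }
    x <- x - mean(x)
    V <- dpss_tapers(n, nw, k)
    spec <- rowMeans(vapply(seq_len(k), function(j) {
      Mod(stats::fft(V[, j] * x))^2 / fs
    }, numeric(n)))
    nf <- floor(n / 2) + 1L
    freq <- (seq_len(nf) - 1L) * fs / n
    ps <- spec[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when n even)
    dbl <- rep(2, nf); dbl[1L] <- 1
    if (n %% 2L == 0L) dbl[nf] <- 1
    ps <- ps * dbl
    acc[i, ] <- stats::approx(freq, ps, xout = grid, rule = 2L)$y
  }
  if (skipped > 0L) {
    warning(sprintf("%d trial(s) shorter than 2 x tapers were skipped", skipped))
  }
  keep <- stats::complete.cases(acc)
  if (!any(keep)) stop("no trial long enough for the requested taper count")
  out <- data.frame(frequency = grid, power = colMeans(acc[keep, , drop = FALSE]))
  structure(out, class = c("psd_estimate", "data.frame"),
            nw = nw, k = k, n_trials = sum(keep), n_skipped = skipped)
}

#' High-frequency power fraction comparison across decoders
#'
#' Smoothness proxy: the fraction of total spectral power above `cutoff` Hz
#' for each decoder's output (and optionally the real kinematics), computed
#' on PSDs that share a frequency grid, with the decoders ordered from
#' smoothest (smallest ratio) up.
#'
#' @param psd_list named list of `psd_estimate` objects (one per decoder).
#' @param cutoff cutoff frequency in Hz.
#' @return data.frame `decoder`, `highfreq_fraction`, ordered ascending.
#' @export
smoothness_compare <- function(psd_list, cutoff = 10) {
  stopifnot(length(psd_list) >= 1L)
  f0 <- psd_list[[1L]]$frequency
  ratios <- vapply(psd_list, function(ps) {
    if (!isTRUE(all.equal(ps$frequency, f0))) {
      stop("PSDs must share a common frequency grid")
    }
    sum(ps$power[ps$frequency > cutoff]) / sum(ps$power)
  }, numeric(1))
  out <- data.frame(decoder = names(psd_list), highfreq_fraction = ratios)
  out[order(out$highfreq_fraction), , drop = FALSE]
}
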