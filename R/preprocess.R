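#' Bin spike times into 10 ms count bins
#'
#' Counts are aligned to the 100 Hz kinematic frame clock: bin `b` (1-based)
#' covers the half-open interval `[t0 + 0.01 (b-1), t0 + 0.01 b)` seconds, so
#' a spike landing exactly on a bin edge belongs to the later bin.
#'
#' @param spike_times list with one sorted numeric vector of spike times
#'   (seconds) per unit; all times must lie in `[t0, t1)`.
#' @param t0,t1 epoch bounds in seconds; `t1 - t0` must be a whole number of
#'   10 ms bins (it is rounded to the nearest bin).
#' @param bin_width bin width in seconds (fixed at 0.01 by the analysis; kept
#'   as an argument for unit tests only).
#' @return `spike_counts` object: integer matrix `units x bins` with
#'   attributes `t0` and `bin_width`.
#' @export
bin_spikes <- function(spike_times, t0, t1, bin_width = 0.01) {
  stopifnot(is.list(spike_times), t1 > t0)
  n_bins <- round((t1 - t0) / bin_width)
  counts <- t(vapply(spike_times, function(st) {
    if (length(st) == 0L) return(integer(n_bins))
    if (is.unsorted(st)) stop("spike times must be sorted within each unit")
    if (st[1L] < t0 || st[length(st)] >= t1) {
      stop("spike times outside [t0, t1)")
    }
    idx <- floor((st - t0) / bin_width) + 1L
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins)))
  structure(counts, t0 = t0, bin_width = bin_width, class = c("spike_counts", "matrix"))
}

#' Trailing-window firing-rate estimate
#'
#' 10 ms counts are too sparse to define a rate directly, so the rate at each
#' bin is the sum of the current and previous nine bins divided by 100 ms
#' (spikes/s). The window trails over the continuous recording; the first
#' nine bins of an epoch use the available partial window divided by its
#' actual duration, and trials are cut from the continuous stream afterwards
#' so within-trial rates always have full context.
#'
#' @param counts `units x bins` count matrix.
#' @param window number of trailing bins (10 = 100 ms).
#' @param bin_width bin width in seconds.
#' @return `units x bins` matrix of rates in spikes/s.
#' @export
estimate_rates <- function(counts, window = 10L, bin_width = 0.01) {
  counts <- as.matrix(counts)
  nb <- ncol(counts)
  cs <- cbind(0, t(apply(counts, 1L, cumsum)))
  idx <- seq_len(nb)
  lo <- pmax(idx - window, 0L)
  span <- (idx - lo) * bin_width
  rates <- (cs[, idx + 1L, drop = FALSE] - cs[, lo + 1L, drop = FALSE]) /
    rep(span, each = nrow(counts))
  dimnames(rates) <- dimnames(counts)
  rates
}

#' Fit and apply per-unit z-scoring
#'
#' Normalisation statistics must come from training data only; `zscore_fit`
#' records them (with a provenance tag) and `zscore_apply` applies them to any
#' data. Units with zero variance in the training data are mapped to zero and
#' flagged with a warning — they carry no information.
#'
#' @param x `units x bins` matrix (rates or counts) of training data.
#' @param tag free-form provenance label (e.g. the training-fold fingerprint)
#'   stored with the statistics.
#' @return `zscore_fit` returns a `zscore_stats` object; `zscore_apply`
#'   returns the normalised matrix.
#' @export
zscore_fit <- function(x, tag = NULL) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  # population SD (divide by N), matching covariance-of-concatenated-trials use
  sdv <- sqrt(rowMeans((x - mu)^2))
  zero <- sdv < 1e-12
  if (any(zero)) {
    warning(sprintf("%d zero-variance unit(s) will z-score to 0", sum(zero)))
    sdv[zero] <- 1
  }
  structure(list(mean = mu, sd = sdv, zero = zero, tag = tag),
            class = "zscore_stats")
}

#' @rdname zscore_fit
#' @param stats a `zscore_stats` object from `zscore_fit`.
#' @export
zscore_apply <- function(x, stats) {
  x <- as.matrix(x)
  if (nrow(x) != length(stats$mean)) stop("unit count mismatch")
  z <- (x - stats$mean) / stats$sd
  z[stats$zero, ] <- 0
  z
}

#' Piecewise-linear gait phase
#'
#' Foot-strike marks 0/100% and toe-off marks 60% of the gait cycle: phase
#' ramps linearly 0 to 60 over stance (foot-strike to toe-off) and 60 to 100
#' over swing (toe-off to the next foot-strike).
#'
#' @param events list or data.frame row with `foot_strike_t`, `toe_off_t`,
#'   `next_foot_strike_t` (seconds, strictly increasing).
#' @param query_t times at which to evaluate the phase; must lie within the
#'   cycle.
#' @return phase percentages in `[0, 100]`.
#' @export
gait_phase <- function(events, query_t) {
  fs <- events$foot_strike_t; to <- events$toe_off_t; nfs <- events$next_foot_strike_t
  if (!(fs < to && to < nfs)) stop("events must satisfy foot_strike < toe_off < next_foot_strike")
  if (any(query_t < fs - 1e-12) || any(query_t > nfs + 1e-12)) {
    stop("query time outside the gait cycle")
  }
  # ratio first: keeps the anchors (0, 60, 100) exact in floating point
  ifelse(query_t <= to,
         60 * ((query_t - fs) / (to - fs)),
         60 + 40 * ((query_t - to) / (nfs - to)))
}

#' Derive kinematic variables from hind-limb marker positions
#'
#' Re-references positions to the iliac crest (horizontal axis = walking
#' direction, vertical = height), computes the inner angle at each joint from
#' its marker triplet — hip (crest, hip, knee), knee (hip, knee, ankle),
#' ankle (knee, ankle, metatarsal), metatarsal (ankle, metatarsal, toe) — and
#' returns its sine and cosine (never the raw angle, whose circularity
#' confounds squared-error scores), plus the leg extension (Euclidean
#' crest-metatarsal distance).
#'
#' @param markers data.frame with columns `<marker>_h` and `<marker>_v`
#'   (meters) for markers `crest, hip, knee, ankle, meta, toe`, one row per
#'   100 Hz frame. Rows with missing markers yield NA outputs.
#' @param triplets named list mapping angle names to character triplets of
#'   marker names (middle marker = vertex); the anatomical default is used
#'   when omitted.
#' @return data.frame, one row per frame: `<marker>_h`, `<marker>_v`
#'   (crest-relative positions of the five distal markers), `sin_<angle>`,
#'   `cos_<angle>`, `leg_extension`. Frames with a degenerate (coincident)
#'   marker triplet are flagged NA for that angle.
#' @export
derive_kinematics <- function(markers, triplets = NULL) {
  mk <- c("crest", "hip", "knee", "ankle", "meta", "toe")
  need <- as.vector(outer(mk, c("_h", "_v"), paste0))
  if (!all(need %in% names(markers))) {
    stop("markers must contain columns ", paste(setdiff(need, names(markers)), collapse = ", "))
  }
  if (is.null(triplets)) {
    triplets <- list(hip = c("crest", "hip", "knee"),
                     knee = c("hip", "knee", "ankle"),
                     ankle = c("knee", "ankle", "meta"),
                     meta = c("ankle", "meta", "toe"))
  }
  nfr <- nrow(markers)
  gx <- function(m) markers[[paste0(m, "_h")]]
  gy <- function(m) markers[[paste0(m, "_v")]]
  out <- list()
  for (m in setdiff(mk, "crest")) {
    out[[paste0(m, "_h")]] <- gx(m) - gx("crest")
    out[[paste0(m, "_v")]] <- gy(m) - gy("crest")
  }
  for (ang in names(triplets)) {
    tr <- triplets[[ang]]
    ax <- gx(tr[1L]) - gx(tr[2L]); ay <- gy(tr[1L]) - gy(tr[2L])
    bx <- gx(tr[3L]) - gx(tr[2L]); by <- gy(tr[3L]) - gy(tr[2L])
    na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
    deg <- which(na < 1e-12 | nb < 1e-12)
    na[deg] <- NA_real_
    cosv <- (ax * bx + ay * by) / (na * nb)
    cosv <- pmin(pmax(cosv, -1), 1)
    sinv <- abs(ax * by - ay * bx) / (na * nb)   # inner angle in [0, 180]
    out[[paste0("sin_", ang)]] <- sinv
    out[[paste0("cos_", ang)]] <- cosv
  }
  out$leg_extension <- sqrt((gx("meta") - gx("crest"))^2 +
                              (gy("meta") - gy("crest"))^2)
  as.data.frame(out)
}

#' Segment a continuous epoch into single-gait-cycle trials
#'
#' One trial spans foot-strike to the next foot-strike. Trials whose neural
#' bins contain missing data are excluded (and counted in the returned
#' attribute `n_excluded_neural`); trials with missing kinematic frames are
#' retained with `has_kinematics = FALSE` so gait phase can still be decoded.
#'
#' @param counts `units x bins` count matrix for the epoch (NA bins mark
#'   corrupt neural data).
#' @param kinematics data.frame of marker positions, one row per bin-aligned
#'   frame, or `NULL`; NA rows mark frames without kinematics.
#' @param events data.frame with columns `foot_strike_t` and `toe_off_t`
#'   (seconds, one row per gait cycle, strictly ordered); the next row's
#'   foot-strike closes each cycle, so `n` rows yield `n - 1` trials.
#' @param task,speed per-cycle labels, recycled if scalar.
#' @param t0 epoch start time (seconds).
#' @return data.frame of trials: `bin_start`, `bin_end` (1-based, inclusive),
#'   event times, `task`, `speed`, `has_kinematics`.
#' @export
segment_trials <- function(counts, kinematics, events, task = "TRM",
                           speed = NA_real_, t0 = 0, bin_width = 0.01) {
  fs <- events$foot_strike_t
  to <- events$toe_off_t
  if (is.unsorted(fs, strictly = TRUE)) stop("foot-strike times must be strictly increasing")
  n_tr <- length(fs) - 1L
  if (n_tr < 1L) stop("need at least two foot-strikes to form a trial")
  if (any(to[seq_len(n_tr)] <= fs[seq_len(n_tr)]) ||
        any(to[seq_len(n_tr)] >= fs[-1L])) {
    stop("each toe-off must fall strictly inside its gait cycle")
  }
  task <- rep_len(task, n_tr)
  speed <- rep_len(speed, n_tr)
  bin_of <- function(t) as.integer(round((t - t0) / bin_width)) + 1L
  bs <- bin_of(fs[seq_len(n_tr)])
  be <- bin_of(fs[-1L]) - 1L
  keep <- logical(n_tr)
  haskin <- logical(n_tr)
  for (i in seq_len(n_tr)) {
    if (be[i] > ncol(counts)) { keep[i] <- FALSE; next }
    blk <- counts[, bs[i]:be[i], drop = FALSE]
    keep[i] <- !anyNA(blk)
    haskin[i] <- !is.null(kinematics) &&
      !anyNA(kinematics[bs[i]:be[i], , drop = FALSE])
  }
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message(sprintf("excluded %d trial(s) with missing neural data", n_excl))
  }
  out <- data.frame(trial = seq_len(n_tr),
                    bin_start = bs, bin_end = be,
                    foot_strike_t = fs[seq_len(n_tr)],
                    toe_off_t = to[seq_len(n_tr)],
                    next_foot_strike_t = fs[-1L],
                    task = task, speed = speed,
                    has_kinematics = haskin)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_neural") <- n_excl
  out
}
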