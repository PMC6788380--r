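#' Write a session to a plain-text container
#'
#' A session is stored as a directory of delimited text plus a JSON manifest
#' (schema-versioned): `counts.csv` (bins x units), `kinematics.csv` /
#' `kinematics_true.csv` (bins x markers), `latents_true.csv`,
#' `trials.csv`, and `manifest.json` carrying the generating configuration,
#' seeds and per-task trial counts. Plain text keeps sessions portable and
#' diffable; no binary container is required at these data sizes.
#'
#' @param session a `gait_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fw <- function(m, f) data.table::fwrite(as.data.frame(m), file.path(path, f))
  fw(t(session$counts), "counts.csv")
  fw(session$kinematics, "kinematics.csv")
  if (!is.null(session$kinematics_true)) fw(session$kinematics_true, "kinematics_true.csv")
  if (!is.null(session$latents_true)) fw(t(session$latents_true), "latents_true.csv")
  fw(session$trials, "trials.csv")
  manifest <- list(
    schema_version = 1L,
    session_id = paste0("synthetic-", session$config$seed),
    n_units = nrow(session$counts),
    n_bins = ncol(session$counts),
    task_trial_counts = as.list(table(session$trials$task)),
    task_kinematic_counts = as.list(tapply(session$trials$has_kinematics,
                                           session$trials$task, sum)),
    seeds = list(session = session$config$seed),
    provenance = "synthetic: gaitdyn generate_session",
    config = unclass(session$config))
  if (!is.null(session$params_true)) {
    manifest$params_true <- lapply(unclass(session$params_true), function(x) {
      if (is.matrix(x)) apply(x, 1L, identity, simplify = FALSE) else x
    })
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a session from its plain-text container
#'
#' Validates the schema version, the 1:1 bin/frame alignment, event ordering
#' and the manifest trial counts (recomputed on load) before returning the
#' in-memory session.
#'
#' @param path directory written by [write_session()].
#' @return a `gait_session`.
#' @export
load_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a session container: missing manifest.json")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$schema_version) || manifest$schema_version != 1L) {
    stop("unsupported session schema version")
  }
  fr <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) return(NULL)
    as.data.frame(data.table::fread(fp))
  }
  counts <- t(as.matrix(fr("counts.csv")))
  kin <- fr("kinematics.csv")
  kin_true <- fr("kinematics_true.csv")
  lat <- fr("latents_true.csv")
  trials <- fr("trials.csv")
  if (nrow(kin) != ncol(counts)) {
    stop("misaligned container: kinematic frames must match count bins 1:1")
  }
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("malformed counts: must be non-negative integers")
  }
  with(trials, {
    if (any(!(foot_strike_t < toe_off_t & toe_off_t < next_foot_strike_t))) {
      stop("malformed events: require foot_strike < toe_off < next_foot_strike")
    }
  })
  recount <- as.list(table(trials$task))
  stored <- manifest$task_trial_counts
  if (!identical(lapply(stored[names(recount)], as.integer),
                 lapply(recount, as.integer))) {
    stop("manifest trial counts disagree with trials.csv")
  }
  params_true <- NULL
  if (!is.null(manifest$params_true)) {
    pt <- manifest$params_true
    as_mat <- function(x) {
      if (is.list(x)) do.call(rbind, lapply(x, unlist)) else as.matrix(x)
    }
    params_true <- plds_params(A = as_mat(pt$A), Q = as_mat(pt$Q),
                               C = as_mat(pt$C), d = unlist(pt$d),
                               x0 = unlist(pt$x0), Q0 = as_mat(pt$Q0))
  }
  cfg <- manifest$config
  structure(list(counts = counts,
                 kinematics = kin,
                 kinematics_true = kin_true,
                 latents_true = if (is.null(lat)) NULL else t(as.matrix(lat)),
                 trials = trials,
                 params_true = params_true,
                 config = cfg,
                 manifest = manifest),
            class = "gait_session")
}

#' Session manifest summary
#'
#' @param session a `gait_session`.
#' @return data.frame mirroring the per-task trial bookkeeping: task, trial
#'   count, kinematics-available count.
#' @export
session_manifest <- function(session) {
  tr <- session$trials
  agg <- stats::aggregate(has_kinematics ~ task, data = tr,
                          FUN = function(x) c(n = length(x), kin = sum(x)))
  out <- data.frame(task = agg$task,
                    n_trials = agg$has_kinematics[, "n"],
                    n_with_kinematics = agg$has_kinematics[, "kin"])
  stopifnot(all(out$n_trials >= out$n_with_kinematics))
  out
}
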