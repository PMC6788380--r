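#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the full analysis on one session: (optionally) simulate a
#' synthetic session, cross-validated decoding for the requested feature
#' sets, the latent-trajectory distance analysis, and the decoder-comparison
#' report. Every artifact is stamped with the configuration hash and seeds so
#' two runs of the same configuration are identical.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{session}{a `gait_session`, a path to a session container, or
#'       `NULL` to simulate from `config$simulate` (a [gait_config()] or its
#'       argument list).}
#'     \item{decoders}{character subset of `c("fp","plds","pca","pss")`.}
#'     \item{dims}{feature dimensionality for the reduced decoders.}
#'     \item{folds, seed, order}{cross-validation settings.}
#'     \item{trajectories}{logical: run the Mahalanobis trajectory stage
#'       (needs a `plds` decode or true latents).}
#'     \item{out_dir}{optional directory for CSV exports.}
#'   }
#' @return list with `session`, `scores` (tidy per-trial R-squared table),
#'   `summary` (per-decoder per-variable means), `trajectories` (speed
#'   separation, if run), `provenance`.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(decoders = c("fp", "plds"), dims = 12L,
                                folds = 10L, seed = 1L, order = 10L,
                                trajectories = FALSE, out_dir = NULL,
                                plds_control = list()),
                           config)
  session <- cfg$session
  if (is.null(session)) {
    sim_cfg <- cfg$simulate
    if (!inherits(sim_cfg, "gait_config")) sim_cfg <- do.call(gait_config, as.list(sim_cfg))
    session <- generate_session(sim_cfg)
  } else if (is.character(session)) {
    session <- load_session(session)
  }

  scores <- list()
  for (dec in cfg$decoders) {
    message(sprintf("[decode] %s (dims=%s, folds=%d)", dec,
                    if (dec == "fp") "all" else cfg$dims, cfg$folds))
    cv <- cv_decode(session, method = dec,
                    dims = if (dec == "fp") NULL else cfg$dims,
                    folds = cfg$folds, seed = cfg$seed, order = cfg$order,
                    plds_control = cfg$plds_control)
    cv$decoder <- dec
    scores[[dec]] <- cv
  }
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL
  summary_tab <- stats::aggregate(r_squared ~ decoder + variable, data = scores,
                                  FUN = mean)

  traj <- NULL
  if (isTRUE(cfg$trajectories)) {
    traj <- trajectory_stage(session, dims = cfg$dims, seed = cfg$seed,
                             plds_control = cfg$plds_control)
  }

  prov <- list(config_hash = config_hash(cfg), seed = cfg$seed,
               timestamp = format(Sys.time(), tz = "UTC"))
  out <- list(session = session, scores = scores, summary = summary_tab,
              trajectories = traj, provenance = prov)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(scores, file.path(cfg$out_dir, "scores.csv"))
    data.table::fwrite(summary_tab, file.path(cfg$out_dir, "summary.csv"))
    if (!is.null(traj)) {
      data.table::fwrite(traj$table, file.path(cfg$out_dir, "speed_separation.csv"))
    }
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  out
}

# PLDS fit on all trials -> normalized trajectories by speed -> separation.
trajectory_stage <- function(session, dims, seed, plds_control = list()) {
  tr <- session$trials
  counts_list <- lapply(seq_len(nrow(tr)), function(i) {
    session$counts[, tr$bin_start[i]:tr$bin_end[i], drop = FALSE]
  })
  ctrl <- utils::modifyList(list(max_iter = 40L, tol = 1e-5), plds_control)
  fit <- plds_fit(counts_list, latent_dim = dims, max_iter = ctrl$max_iter,
                  tol = ctrl$tol, seed = seed)
  norm <- lapply(seq_len(nrow(tr)), function(i) {
    normalize_gait_cycle(plds_decode(fit, counts_list[[i]]), tr[i, ])
  })
  by_speed <- split(norm, tr$speed)
  if (length(by_speed) < 2L) return(NULL)
  speed_separation(by_speed)
}

config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), c("session", "out_dir"))]
  txt <- jsonlite::toJSON(keep, auto_unbox = TRUE, force = TRUE, digits = NA)
  # tiny stable FNV-1a style hash over the serialized config (no digest dep)
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Command-line entry point
#'
#' A thin driver around the package functions, installed at
#' `inst/cli/gaitdyn.R`. Verbs: `simulate`, `decode`, `sweep`,
#' `trajectories`, `report`, `run-all`. Flags are `--key value` pairs; see
#' the README for examples.
#'
#' @param argv character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
gaitdyn_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) < 1L) {
    cat("usage: gaitdyn <simulate|decode|sweep|trajectories|run-all> [--key value ...]\n")
    return(invisible(1L))
  }
  verb <- argv[1L]
  opts <- parse_cli_opts(argv[-1L])
  seed <- as.integer(opts$seed %||% 1L)
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  res <- switch(verb,
    simulate = {
      cfg <- if (!is.null(opts$config)) {
        do.call(gait_config, jsonlite::read_json(opts$config, simplifyVector = TRUE))
      } else gait_config(seed = seed)
      s <- generate_session(cfg)
      write_session(s, opts$out %||% "session")
      message("wrote session to ", opts$out %||% "session")
      0L
    },
    decode = {
      s <- load_session(opts$session)
      cv <- cv_decode(s, method = opts$decoder %||% "fp",
                      dims = if (is.null(opts$dims)) NULL else as.integer(opts$dims),
                      folds = as.integer(num(opts$folds, 10)), seed = seed)
      out <- opts$out %||% "scores.csv"
      data.table::fwrite(cv, out)
      message("wrote ", out)
      0L
    },
    sweep = {
      s <- load_session(opts$session)
      sw <- dim_sweep(s, method = opts$method %||% "pca",
                      dims = seq_len(as.integer(num(opts$max_dims, 12))),
                      folds = as.integer(num(opts$folds, 10)), seed = seed)
      out <- opts$out %||% "sweep.csv"
      data.table::fwrite(sw$table, out)
      message("plateau at ", sw$plateau_dim, " dims; wrote ", out)
      0L
    },
    trajectories = {
      s <- load_session(opts$session)
      ts <- trajectory_stage(s, dims = as.integer(num(opts$dims, 12)),
                             seed = seed)
      out <- opts$out %||% "speed_separation.csv"
      if (!is.null(ts)) data.table::fwrite(ts$table, out)
      message("wrote ", out)
      0L
    },
    `run-all` = {
      cfg <- if (!is.null(opts$config)) {
        jsonlite::read_json(opts$config, simplifyVector = TRUE)
      } else list()
      cfg$seed <- seed
      cfg$out_dir <- opts$out %||% "results"
      run_pipeline(cfg)
      message("wrote results to ", cfg$out_dir)
      0L
    },
    {
      cat("unknown verb: ", verb, "\n")
      1L
    })
  invisible(res)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L <= length(args)) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
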