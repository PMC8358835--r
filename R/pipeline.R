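#' Pipeline configuration
#'
#' Declarative configuration of the full analysis: recordings (or an
#' in-memory dataset) -> optional band decomposition -> per-target sparse
#' MVAR fits -> directed networks -> features -> evaluation. Unknown keys
#' are rejected to catch typos.
#'
#' @param trials either a character vector of file paths (delimited
#'   matrices, read with [read_recording()]) or a list of [recording()]s.
#' @param labels per-trial class labels (required for evaluation).
#' @param srate sampling rate used when reading files.
#' @param channels optional channel subset/order (applied with
#'   [select_channels()]).
#' @param bands optional list of [band_spec()]s; `NULL` analyses the
#'   broadband signal as a single band.
#' @param s MVAR lag order (default 3).
#' @param solver one of `"l2"`, `"lasso"`, `"lapps"`, `"scsga"`.
#' @param solver_cfg a [solver_config()].
#' @param select_lam `"fixed"` uses `solver_cfg$lam` as is;
#'   `"cv_first_trial"` runs [select_lambda_cv()] per target on the first
#'   trial and reuses the selected values for all trials (a cheap
#'   approximation of per-trial selection).
#' @param aggregate lag-aggregation mode for [aggregate_network()].
#' @param backend,eval_mode,folds,repeats,reg_strength evaluation settings;
#'   `eval_mode` is `"cv"` or `"holdout"`.
#' @param seed master seed for fold shuffles and lambda-selection CV.
#' @param out_dir optional output directory; when set, per-trial networks,
#'   the feature matrix, the evaluation report and a manifest are written.
#' @param orientation file orientation for [read_recording()].
#' @param verbose print one progress line per trial.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(trials, labels = NULL, srate = 200,
                            channels = NULL, bands = NULL, s = 3L,
                            solver = c("scsga", "l2", "lasso", "lapps"),
                            solver_cfg = solver_config(),
                            select_lam = c("fixed", "cv_first_trial"),
                            aggregate = "sum_abs",
                            backend = "logistic_l2",
                            eval_mode = c("cv", "holdout"),
                            folds = 5L, repeats = 100L, reg_strength = 1,
                            seed = 1L, out_dir = NULL,
                            orientation = "channels", verbose = FALSE) {
  solver <- match.arg(solver)
  eval_mode <- match.arg(eval_mode)
  select_lam <- match.arg(select_lam)
  if (is.character(trials)) {
    missing <- trials[!file.exists(trials)]
    if (length(missing) > 0L)
      stop("missing input file: ", paste(missing, collapse = ", "))
  } else if (!is.list(trials)) {
    stop("`trials` must be file paths or a list of recordings")
  }
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(trials = trials, labels = labels, srate = srate,
                 channels = channels, bands = bands, s = as.integer(s),
                 solver = solver, solver_cfg = solver_cfg,
                 select_lam = select_lam, aggregate = aggregate,
                 backend = backend, eval_mode = eval_mode,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 reg_strength = reg_strength, seed = as.integer(seed),
                 out_dir = out_dir, orientation = orientation,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Build a pipeline config from a JSON file
#'
#' Reads a declarative JSON config (keys as in [pipeline_config()]; bands
#' given as objects with `name`, `lo`, `hi`). Unknown keys are an error.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(pipeline_config)), "solver_cfg")
  solver_keys <- setdiff(names(formals(solver_config)), "")
  extra <- setdiff(names(raw), c(known, solver_keys))
  if (length(extra) > 0L)
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  scfg <- do.call(solver_config, raw[intersect(names(raw), solver_keys)])
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$bands))
    args$bands <- lapply(seq_len(nrow(args$bands)), function(i)
      band_spec(args$bands$name[i], args$bands$lo[i], args$bands$hi[i]))
  args$solver_cfg <- scfg
  do.call(pipeline_config, args)
}

solve_one <- function(ds, solver, cfg, E = NULL) {
  switch(solver,
         l2 = fit_l2(ds),
         lasso = fit_lasso(ds, cfg),
         lapps = fit_lapps(ds, cfg),
         scsga = fit_scsga(ds, E, cfg),
         stop("unknown solver: ", solver))
}

#' Fit the causality networks of one recording
#'
#' For each band (or broadband): zero-phase filter, center, compute the
#' sensor correlation matrix, fit the chosen MVAR estimator per target
#' channel, repack coefficients into a tensor and aggregate over lags into
#' a directed network.
#'
#' @param rec a [recording()].
#' @param s lag order.
#' @param solver `"l2"`, `"lasso"`, `"lapps"` or `"scsga"`.
#' @param cfg a [solver_config()]; `lam` may be a vector with one entry per
#'   target channel.
#' @param bands optional list of [band_spec()]s.
#' @param aggregate lag-aggregation mode.
#' @return named list of `causality_network`s, one per band (name
#'   `"broadband"` when `bands` is `NULL`).
#' @export
trial_networks <- function(rec, s, solver, cfg = solver_config(),
                           bands = NULL, aggregate = "sum_abs") {
  band_list <- if (is.null(bands)) list(broadband = NULL) else {
    stats::setNames(bands, vapply(bands, `[[`, character(1), "name"))
  }
  lams <- rep_len(cfg$lam, n_channels(rec))
  out <- lapply(band_list, function(band) {
    r <- if (is.null(band)) rec else bandpass_filter(rec, band)
    r <- center_recording(r)
    E <- if (solver == "scsga") correlation_matrix(r) else NULL
    fits <- lapply(seq_len(n_channels(r)), function(k) {
      cfg_k <- cfg; cfg_k$lam <- lams[k]
      solve_one(build_design(r, s, k), solver, cfg_k, E)
    })
    tensor <- coeffs_to_tensor(fits, n_channels(r), s)
    aggregate_network(tensor, r$channel_names, mode = aggregate)
  })
  out
}

load_trials <- function(cfg) {
  if (is.character(cfg$trials)) {
    lapply(cfg$trials, read_recording, srate = cfg$srate,
           orientation = cfg$orientation)
  } else cfg$trials
}

#' Run the full pipeline
#'
#' Loads/validates the trials, optionally restricts channels, extracts
#' per-band directed-network features with the configured solver, and
#' evaluates the configured classifier. With `out_dir` set, writes
#' per-trial network files, the feature matrix CSV, the report JSON and a
#' `manifest.json` (config echo, package version, seed) sufficient to
#' re-run the pipeline.
#'
#' @param cfg a [pipeline_config()].
#' @return a list with `report` (an `eval_report`), `features` (a
#'   [feature_set()]) and `networks` (per trial, per band).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  trials <- load_trials(cfg)
  if (!is.null(cfg$channels))
    trials <- lapply(trials, select_channels, keep = cfg$channels)
  scfg <- cfg$solver_cfg
  scfg$seed <- cfg$seed
  if (cfg$select_lam == "cv_first_trial" &&
      cfg$solver %in% c("lapps", "scsga")) {
    r1 <- center_recording(trials[[1L]])
    E1 <- if (cfg$solver == "scsga") correlation_matrix(r1) else NULL
    scfg$lam <- vapply(seq_len(n_channels(r1)), function(k)
      select_lambda_cv(build_design(r1, cfg$s, k), scfg, E = E1),
      numeric(1))
  }
  networks <- vector("list", length(trials))
  feats <- vector("list", length(trials))
  for (ti in seq_along(trials)) {
    res <- tryCatch(
      trial_networks(trials[[ti]], cfg$s, cfg$solver, scfg,
                     bands = cfg$bands, aggregate = cfg$aggregate),
      error = function(e) stop("trial ", ti, ": ", conditionMessage(e),
                               call. = FALSE))
    networks[[ti]] <- res
    feats[[ti]] <- network_features(res)
    if (cfg$verbose)
      message(sprintf("[trial %d/%d] solver=%s bands=%d",
                      ti, length(trials), cfg$solver, length(res)))
  }
  X <- do.call(rbind, feats)
  report <- NULL; fs <- NULL
  if (!is.null(cfg$labels)) {
    fs <- feature_set(X, cfg$labels)
    report <- if (cfg$eval_mode == "cv") {
      cross_validate(fs, backend = cfg$backend, folds = cfg$folds,
                     repeats = cfg$repeats, seed = cfg$seed,
                     reg_strength = cfg$reg_strength)
    } else {
      evaluate_holdout(fs, backend = cfg$backend, seed = cfg$seed,
                       reg_strength = cfg$reg_strength)
    }
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ti in seq_along(networks)) {
      for (bn in names(networks[[ti]])) {
        base <- file.path(cfg$out_dir, sprintf("trial%03d_%s", ti, bn))
        write_network(networks[[ti]][[bn]],
                      path_csv = paste0(base, "_network.csv"),
                      path_tsv = paste0(base, "_edges.tsv"))
      }
    }
    utils::write.csv(X, file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(report))
      write_report(report, file.path(cfg$out_dir, "report.json"))
    manifest <- list(
      package = "scsga",
      version = as.character(utils::packageVersion("scsga")),
      seed = cfg$seed,
      config = config_echo(cfg))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  list(report = report, features = fs, networks = networks)
}

config_echo <- function(cfg) {
  echo <- unclass(cfg)
  echo$solver_cfg <- unclass(cfg$solver_cfg)
  if (!is.character(echo$trials))
    echo$trials <- sprintf("<in-memory: %d recordings>", length(echo$trials))
  if (!is.null(echo$bands))
    echo$bands <- lapply(echo$bands, unclass)
  echo
}

#' Simulate a dataset and write it to disk
#'
#' Writes one delimited file per trial, a `labels.csv`, and per-class
#' ground-truth JSON files into `out_dir`.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (created if needed).
#' @return the `sim_dataset`, invisibly.
#' @export
cmd_simulate <- function(spec, out_dir) {
  ds <- make_dataset(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ti in seq_along(ds$trials))
    write_recording(ds$trials[[ti]],
                    file.path(out_dir, sprintf("trial%03d.csv", ti)))
  utils::write.csv(
    data.frame(trial = sprintf("trial%03d.csv", seq_along(ds$trials)),
               label = ds$labels),
    file.path(out_dir, "labels.csv"), row.names = FALSE)
  for (c in seq_along(ds$truths))
    write_ground_truth(ds$truths[[c]],
                       file.path(out_dir, sprintf("truth_class%d.json", c)))
  invisible(ds)
}

#' Fit and export the networks of a single trial file
#'
#' @param path delimited recording file.
#' @param out_dir output directory.
#' @inheritParams trial_networks
#' @param srate sampling rate of the file.
#' @param bands optional band list.
#' @return the list of networks, invisibly.
#' @export
cmd_fit <- function(path, out_dir, s = 3L, solver = "scsga",
                    cfg = solver_config(), srate = 200, bands = NULL) {
  rec <- read_recording(path, srate = srate)
  nets <- trial_networks(rec, s, solver, cfg, bands = bands)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- tools::file_path_sans_ext(basename(path))
  for (bn in names(nets))
    write_network(nets[[bn]],
                  path_csv = file.path(out_dir, sprintf("%s_%s_network.csv", base, bn)),
                  path_tsv = file.path(out_dir, sprintf("%s_%s_edges.tsv", base, bn)))
  invisible(nets)
}

#' Classify a saved feature matrix
#'
#' @param features_csv CSV with one row per trial (numeric features).
#' @param labels_csv CSV with a `label` column aligned with the rows.
#' @param out output path for the report JSON.
#' @inheritParams cross_validate
#' @return the `eval_report`, invisibly.
#' @export
cmd_classify <- function(features_csv, labels_csv, out,
                         backend = "logistic_l2", folds = 5L,
                         repeats = 100L, seed = 1L, reg_strength = 1) {
  X <- as.matrix(utils::read.csv(features_csv, check.names = FALSE))
  labels <- utils::read.csv(labels_csv)$label
  fs <- feature_set(X, labels)
  report <- cross_validate(fs, backend = backend, folds = folds,
                           repeats = repeats, seed = seed,
                           reg_strength = reg_strength)
  write_report(report, out)
  invisible(report)
}
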