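#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()].
#' Round-trips losslessly through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param seed master seed applied to every random stage.
#' @param simulate list: `mode` ("features" draws the feature table
#'   directly, "eeg" synthesises recordings and extracts features),
#'   `n_per_stratum` named AD/ASD/CON counts per age stratum, signal
#'   parameters for eeg mode, and injection lists for features mode.
#' @param stats list: `outlier_threshold`, `lrt_alpha`.
#' @param replicate list: `enabled`, `n_splits`, `threshold`.
#' @param samplesize list: `enabled`, `fractions`, `reps`, `threshold`.
#' @param subset optional number of registry variables to keep (prefix
#'   subset; NULL for the full registry).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            simulate = list(mode = "features",
                                            n_per_stratum = c(AD = 20, ASD = 10,
                                                              CON = 30),
                                            n_epochs = 20, sampling_rate = 250,
                                            epoch_length = 500,
                                            age_slope = list(),
                                            sex_shift = list(),
                                            diag_shift = list()),
                            stats = list(outlier_threshold = 3.5,
                                         lrt_alpha = 0.05),
                            replicate = list(enabled = TRUE, n_splits = 150,
                                             threshold = 0.035,
                                             rate_threshold = 0.64),
                            samplesize = list(enabled = FALSE,
                                              fractions = seq(0.1, 0.7, 0.1),
                                              reps = 100, threshold = 0.035),
                            subset = NULL) {
  cfg <- list(seed = seed, simulate = simulate, stats = stats,
              replicate = replicate, samplesize = samplesize, subset = subset)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config error: every random stage needs a seed")
  if (!cfg$simulate$mode %in% c("features", "eeg"))
    stop("config error: simulate$mode must be 'features' or 'eeg'")
  invisible(TRUE)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$simulate$n_per_stratum <- unlist(cfg$simulate$n_per_stratum)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  ## yaml drops names of atomic vectors; store named vectors as maps
  cfg$simulate$n_per_stratum <- as.list(cfg$simulate$n_per_stratum)
  for (f in c("age_slope", "sex_shift"))
    if (!is.null(cfg$simulate[[f]])) cfg$simulate[[f]] <- as.list(cfg$simulate[[f]])
  if (!is.null(cfg$simulate$diag_shift))
    cfg$simulate$diag_shift <- lapply(cfg$simulate$diag_shift, as.list)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order -- simulate, stats, replicate,
#' samplesize, report -- writing CSV/JSON outputs and a run manifest under
#' `out_dir`. Re-running with an unchanged configuration skips stages whose
#' outputs already exist (config-hash check in the manifest).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param verbose print stage progress.
#' @return the run manifest (invisibly): config hash, per-stage row counts
#'   and timings.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- digest::digest(unclass(config))
  man_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE) else list(stages = NULL)
  if (!identical(manifest$config_hash, hash))
    manifest <- list(config_hash = hash, stages = list())
  if (is.null(manifest$stages)) manifest$stages <- list()

  done <- function(stage, files)
    !is.null(manifest$stages[[stage]]) &&
      all(file.exists(file.path(out_dir, files)))
  record <- function(stage, rows, secs) {
    manifest$stages[[stage]] <<- list(rows = rows, seconds = round(secs, 2),
                                      completed = TRUE)
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  }
  say <- function(...) if (verbose) message(...)

  registry <- build_registry(default_layout())
  keys <- registry$key
  if (!is.null(config$subset)) keys <- keys[seq_len(config$subset)]

  ## ---- simulate ----
  if (!done("simulate", c("demographics.csv", "features.csv"))) {
    say("stage: simulate")
    t0 <- proc.time()[3]
    sim <- config$simulate
    dem <- generate_demographics(
      cohort_config(n_per_stratum = sim$n_per_stratum), seed = config$seed)
    if (sim$mode == "eeg") {
      eff <- default_effects()
      coh <- generate_cohort(dem, eff, default_layout(), seed = config$seed,
                             n_epochs = sim$n_epochs %||% 20,
                             sampling_rate = sim$sampling_rate %||% 250,
                             epoch_length = sim$epoch_length %||% 500)
      feats <- feature_table(coh$recordings, registry)
      feats <- feats[, c("participant_id", keys)]
    } else {
      feats <- simulate_features(dem, keys, seed = config$seed,
                                 age_slope = unlist(sim$age_slope),
                                 sex_shift = unlist(sim$sex_shift),
                                 diag_shift = lapply(sim$diag_shift, unlist))
    }
    utils::write.csv(dem, file.path(out_dir, "demographics.csv"),
                     row.names = FALSE)
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    record("simulate", nrow(dem), proc.time()[3] - t0)
  } else say("stage: simulate (cached)")

  dem <- utils::read.csv(file.path(out_dir, "demographics.csv"),
                         stringsAsFactors = FALSE)
  feats <- utils::read.csv(file.path(out_dir, "features.csv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  grouping <- assign_age_tertiles(dem)

  ## ---- stats ----
  if (!done("stats", "effects.csv")) {
    say("stage: stats")
    t0 <- proc.time()[3]
    eff <- effect_table(feats, dem, grouping,
                        outlier_threshold = config$stats$outlier_threshold,
                        lrt_alpha = config$stats$lrt_alpha)
    utils::write.csv(eff, file.path(out_dir, "effects.csv"), row.names = FALSE)
    record("stats", attr(eff, "n_fits"), proc.time()[3] - t0)
  } else say("stage: stats (cached)")
  eff <- utils::read.csv(file.path(out_dir, "effects.csv"),
                         stringsAsFactors = FALSE)

  ## ---- replicate ----
  if (isTRUE(config$replicate$enabled) && !done("replicate", "replication.csv")) {
    say("stage: replicate")
    t0 <- proc.time()[3]
    summ <- replication_summaries(eff, feats, dem, grouping,
                                  n_splits = config$replicate$n_splits,
                                  threshold = config$replicate$threshold,
                                  seed = config$seed)
    utils::write.csv(summ, file.path(out_dir, "replication.csv"),
                     row.names = FALSE)
    record("replicate", nrow(summ), proc.time()[3] - t0)
  } else if (isTRUE(config$replicate$enabled)) say("stage: replicate (cached)")

  ## ---- samplesize ----
  if (isTRUE(config$samplesize$enabled) && !done("samplesize",
                                                 c("subsample_runs.csv",
                                                   "subsample_nmi.csv"))) {
    say("stage: samplesize")
    t0 <- proc.time()[3]
    bc <- bootstrap_curve(feats, dem, grouping,
                          fractions = config$samplesize$fractions,
                          reps = config$samplesize$reps, seed = config$seed,
                          threshold = config$samplesize$threshold)
    utils::write.csv(bc$runs, file.path(out_dir, "subsample_runs.csv"),
                     row.names = FALSE)
    utils::write.csv(bc$nmi, file.path(out_dir, "subsample_nmi.csv"),
                     row.names = FALSE)
    record("samplesize", nrow(bc$runs), proc.time()[3] - t0)
  } else if (isTRUE(config$samplesize$enabled)) say("stage: samplesize (cached)")

  ## ---- report ----
  say("stage: report")
  t0 <- proc.time()[3]
  rep_path <- pipeline_report(out_dir,
                              threshold = config$replicate$threshold %||% 0.035,
                              rate_threshold = config$replicate$rate_threshold %||% 0.64)
  record("report", 1L, proc.time()[3] - t0)
  invisible(manifest)
}

#' Summarise a pipeline run
#'
#' Writes `report.md` (plus `proportion_matrix.csv` and `replicable.csv`)
#' from the stage outputs found in `out_dir`: the proportion of effects with
#' eta-squared above threshold per variable family, model term and age
#' group; the list of replicable effects; and sample-size curve summaries
#' when present. Missing stages are noted and skipped.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @param threshold,rate_threshold selection thresholds.
#' @return path of the written report (invisibly).
#' @export
pipeline_report <- function(out_dir, threshold = 0.035, rate_threshold = 0.64) {
  lines <- c("# Pipeline report", "")
  eff_path <- file.path(out_dir, "effects.csv")
  if (!file.exists(eff_path)) {
    lines <- c(lines, "stats stage missing: no effect table found.")
  } else {
    eff <- utils::read.csv(eff_path, stringsAsFactors = FALSE)
    eff$supra <- !is.na(eff$eta2) & eff$eta2 > threshold
    pm <- stats::aggregate(supra ~ family + term + age_group, eff, mean)
    utils::write.csv(pm, file.path(out_dir, "proportion_matrix.csv"),
                     row.names = FALSE)
    lines <- c(lines,
               sprintf("Model fits: %d records over %d variables.",
                       nrow(unique(eff[, c("variable", "age_group", "model")])),
                       length(unique(eff$variable))),
               sprintf("Proportion of effects with eta2 > %.3f by term:", threshold))
    by_term <- stats::aggregate(supra ~ term, eff, mean)
    lines <- c(lines, sprintf("  - %s: %.3f", by_term$term, by_term$supra), "")
  }
  rep_path <- file.path(out_dir, "replication.csv")
  if (file.exists(rep_path)) {
    summ <- utils::read.csv(rep_path, stringsAsFactors = FALSE)
    if (nrow(summ)) {
      repl <- select_replicable(summ, threshold, rate_threshold)
      utils::write.csv(repl, file.path(out_dir, "replicable.csv"),
                       row.names = FALSE)
      lines <- c(lines, sprintf(
        "Replication: %d supra-threshold effects tested; %d with rate >= %.2f.",
        nrow(summ), nrow(repl), rate_threshold), "")
    } else {
      lines <- c(lines, "Replication: no supra-threshold effects.", "")
    }
  } else lines <- c(lines, "replicate stage not run; section omitted.", "")
  run_path <- file.path(out_dir, "subsample_runs.csv")
  if (file.exists(run_path)) {
    runs <- utils::read.csv(run_path, stringsAsFactors = FALSE)
    agg <- stats::aggregate(prop_supra ~ fraction + term, runs, mean)
    lines <- c(lines, "Mean supra-threshold proportion by fraction and term:",
               sprintf("  - f=%.2f %s: %.3f", agg$fraction, agg$term,
                       agg$prop_supra))
  } else lines <- c(lines, "samplesize stage not run; section omitted.")
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `stats`, `replicate`, `samplesize`, `run-all`
#' (all driven by `--config <yaml> --out <dir> [--seed <int>]
#' [--subset <n>]`), and `report --out <dir>`. Returns exit status 0 on
#' success, 1 on configuration errors, 2 on stage failure.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (invisibly).
#' @export
eegstability_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: eegstability <simulate|stats|replicate|samplesize|run-all|report> ",
            "--config <yaml> --out <dir> [--seed <int>] [--subset <n>]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  out_dir <- opt("--out", "eegstability_out")
  cfg <- tryCatch({
    cfg_path <- opt("--config")
    cfg <- if (!is.null(cfg_path)) read_pipeline_config(cfg_path)
           else pipeline_config()
    seed <- opt("--seed"); subset <- opt("--subset")
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    if (!is.null(subset)) cfg$subset <- as.integer(subset)
    toggles <- list(simulate = c(FALSE, FALSE), stats = c(FALSE, FALSE),
                    replicate = c(TRUE, FALSE), samplesize = c(FALSE, TRUE),
                    `run-all` = c(TRUE, TRUE))
    if (cmd %in% names(toggles)) {
      cfg$replicate$enabled <- toggles[[cmd]][1]
      cfg$samplesize$enabled <- toggles[[cmd]][2]
    }
    cfg
  }, error = function(e) {
    message("config error: ", conditionMessage(e)); NULL
  })
  if (is.null(cfg) && cmd != "report") return(invisible(1L))
  status <- tryCatch({
    if (cmd == "report") pipeline_report(out_dir)
    else if (cmd %in% c("simulate", "stats", "replicate", "samplesize", "run-all"))
      run_pipeline(cfg, out_dir, verbose = TRUE)
    else { message("unknown subcommand: ", cmd); return(invisible(1L)) }
    0L
  }, error = function(e) {
    message("stage failure: ", conditionMessage(e)); 2L
  })
  invisible(status)
}
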