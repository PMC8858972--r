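#' Configuration for an end-to-end pipeline run
#'
#' @param mode Input mode: `"synthetic"` (simulate a cohort), `"table"`
#'   (read a cohort TSV) or `"spectra"` (quantify spot-spectrum files
#'   against a panel).
#' @param cohort_file Cohort TSV (mode `"table"`).
#' @param spectra_manifest TSV with columns `sample_id, group, stage,
#'   channel, path` pointing at spot-spectrum files in the simple tabular
#'   dialect (mode `"spectra"`).
#' @param panel_file Panel TSV (required for mode `"spectra"`).
#' @param synthetic A [synthetic_config()] (mode `"synthetic"`).
#' @param tol_ppm Peak-extraction half-window.
#' @param alpha ANOVA screen threshold.
#' @param min_features,delta,patience Elimination stopping rule.
#' @param ntree Trees for importance forests.
#' @param eval_reps,eval_ntree Elimination CV scoring settings.
#' @param cv_reps Repetitions of the repeated CV schemes in the final
#'   evaluation.
#' @param cv_schemes CV schemes evaluated.
#' @param target_spec Operating-point specificity.
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory (created if absent).
#' @return A `run_config` list (validated).
#' @export
run_config <- function(mode = c("synthetic", "table", "spectra"),
                       cohort_file = NULL, spectra_manifest = NULL,
                       panel_file = NULL, synthetic = synthetic_config(),
                       tol_ppm = 10, alpha = 0.05,
                       min_features = 5, delta = 2, patience = 2,
                       ntree = 500, eval_reps = 5, eval_ntree = 200,
                       cv_reps = 200, cv_schemes = CV_SCHEMES,
                       target_spec = 0.90, seed = 1L,
                       out_dir = "glycospot_run") {
  mode <- match.arg(mode)
  for (f in c(cohort_file, spectra_manifest, panel_file))
    if (!is.null(f) && !file.exists(f))
      stop("config error: file not found: ", f, call. = FALSE)
  if (mode == "table" && is.null(cohort_file))
    stop("config error: mode 'table' requires cohort_file", call. = FALSE)
  if (mode == "spectra" && (is.null(spectra_manifest) || is.null(panel_file)))
    stop("config error: mode 'spectra' requires spectra_manifest and panel_file",
         call. = FALSE)
  cv_schemes <- match.arg(cv_schemes, CV_SCHEMES, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline config from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `synthetic`
#' key may hold the arguments of [synthetic_config()] (with `planted` and
#' `decoys` as lists of records).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    for (k in c("planted", "decoys"))
      if (!is.null(s[[k]]))
        s[[k]] <- do.call(rbind, lapply(s[[k]], as.data.frame))
    if (!is.null(s$baseline)) s$baseline <- unlist(s$baseline)
    y$synthetic <- do.call(synthetic_config, s)
  }
  do.call(run_config, y)
}

cohort_from_manifest <- function(manifest_path, panel, tol_ppm) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group", "channel", "path") %in% names(man)))
  base <- dirname(manifest_path)
  samples <- lapply(split(man, man$sample_id), function(rows) {
    spots <- lapply(split(rows, rows$channel), function(r) {
      p <- r$path[1]
      if (!file.exists(p)) p <- file.path(base, r$path[1])
      read_spot_tsv(p)
    })
    list(group = rows$group[1],
         stage = if ("stage" %in% names(rows)) as.character(rows$stage[1])
                 else NA_character_,
         spots = spots)
  })
  build_cohort_table(samples, panel, tol_ppm)
}

#' Run the full analysis pipeline
#'
#' Stages: acquire a cohort table (simulate, read, or quantify spectra),
#' ANOVA-screen the features, prune the panel by iterative
#' similarity/importance elimination, and evaluate the final panel on all
#' pairwise group comparisons. All artifacts (cohort TSV, screen TSV,
#' selection trace JSON, evaluation JSON/TSV, run metadata) are written to
#' `cfg$out_dir`. A failed stage aborts with the stage name and leaves a
#' machine-readable `error.json` in the output directory.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `cohort`, `screen`, `selection`,
#'   `reports` and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rec <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(rec, file.path(cfg$out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  cohort <- stage("cohort", switch(
    cfg$mode,
    synthetic = {
      sim <- generate_cohort(cfg$synthetic, seed = cfg$seed)
      truth <- sim$truth
      write_truth(truth, file.path(cfg$out_dir, "truth.json"))
      sim$cohort
    },
    table = read_cohort_table(cfg$cohort_file),
    spectra = cohort_from_manifest(cfg$spectra_manifest,
                                   read_panel(cfg$panel_file), cfg$tol_ppm)
  ))
  write_cohort_table(cohort, file.path(cfg$out_dir, "cohort.tsv"))
  message(sprintf("cohort: %d samples x %d features",
                  nrow(cohort), length(cohort_features(cohort))))

  screen <- stage("anova_screen", filter_features(cohort, alpha = cfg$alpha))
  write_anova_results(screen, file.path(cfg$out_dir, "anova_results.tsv"))
  message(sprintf("ANOVA screen: %d of %d features retained at alpha=%g",
                  length(screen$retained),
                  length(cohort_features(cohort)), cfg$alpha))

  selection <- stage("feature_selection", iterative_elimination(
    cohort_matrix(cohort, screen$retained), cohort$group,
    min_features = cfg$min_features, delta = cfg$delta,
    patience = cfg$patience, ntree = cfg$ntree,
    eval_reps = cfg$eval_reps, eval_ntree = cfg$eval_ntree,
    seed = cfg$seed))
  write_selection_trace(selection, file.path(cfg$out_dir,
                                             "selection_trace.json"))
  message(sprintf("selection: %d features retained (%d eliminated)",
                  length(selection$panel), nrow(selection$trace)))

  reports <- stage("evaluation", evaluate_groupings(
    cohort, selection$panel, schemes = cfg$cv_schemes, reps = cfg$cv_reps,
    ntree = cfg$eval_ntree, target_spec = cfg$target_spec, seed = cfg$seed))
  write_eval_reports(reports,
                     json_path = file.path(cfg$out_dir, "eval_reports.json"),
                     tsv_path = file.path(cfg$out_dir, "eval_summary.tsv"))

  info <- list(
    package = "glycospot",
    version = as.character(utils::packageVersion("glycospot")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "synthetic")],
    config_hash = config_hash(cfg),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(info, file.path(cfg$out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(cohort = cohort, truth = truth, screen = screen,
                 selection = selection, reports = reports,
                 out_dir = cfg$out_dir))
}

# md5 of the serialized config; ties every artifact to the exact settings
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp)
  unname(tools::md5sum(tmp))
}
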