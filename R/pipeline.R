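#' Run configuration for the end-to-end pipeline
#'
#' Bundles every tunable of the simulate - reconstruct - featurize -
#' analyze - compare chain into one serializable object, so a run is fully
#' described by its configuration and seed.
#'
#' @param seed Integer seed driving all randomness.
#' @param cohort A [cohort_spec()]; its own seed is overridden by `seed`.
#' @param optical An [optical_config()] for reconstruction.
#' @param smooth_width Feature-extraction smoothing width (frames, odd).
#' @param saturation_hold_s Saturation-call hold time in seconds.
#' @param bonferroni_m Bonferroni multiplier for the Welch tests.
#' @param cor_threshold Spearman redundancy threshold.
#' @param cutoffs Modality [cutoff_rule()]s.
#' @param out_dir Optional default output directory.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1,
                       cohort = cohort_spec(),
                       optical = optical_config(),
                       smooth_width = 5,
                       saturation_hold_s = 5,
                       bonferroni_m = 3,
                       cor_threshold = 0.75,
                       cutoffs = default_cutoff_rules(),
                       out_dir = NULL) {
  if (!is_scalar_number(seed)) abort_config("`seed` must be a single integer")
  if (!inherits(cohort, "cohort_spec")) abort_config("`cohort` must be a cohort_spec")
  if (!inherits(optical, "optical_config")) abort_config("`optical` must be an optical_config")
  cohort$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), cohort = cohort, optical = optical,
         smooth_width = smooth_width, saturation_hold_s = saturation_hold_s,
         bonferroni_m = bonferroni_m, cor_threshold = cor_threshold,
         cutoffs = cutoffs, out_dir = out_dir),
    class = "run_config"
  )
}

# Named atomic vectors serialize to JSON arrays (losing names); convert them
# to named lists so group parameters survive the round trip.
as_jsonable <- function(x) {
  if (is.data.frame(x)) x
  else if (is.list(x)) lapply(x, as_jsonable)
  else if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else x
}

config_to_list <- function(config) {
  list(
    seed = config$seed,
    cohort = as_jsonable(unclass(config$cohort)),
    optical = list(
      detector = config$optical$detector,
      distance_cm = config$optical$distance_cm,
      dpf = as.list(config$optical$dpf),
      baseline_window_s = config$optical$baseline_window_s,
      extinction = config$optical$extinction
    ),
    smooth_width = config$smooth_width,
    saturation_hold_s = config$saturation_hold_s,
    bonferroni_m = config$bonferroni_m,
    cor_threshold = config$cor_threshold,
    cutoffs = as.data.frame(config$cutoffs),
    out_dir = config$out_dir
  )
}

#' Write / read a run configuration as JSON
#'
#' The JSON document is the single source of truth for a run; unknown keys
#' are rejected on read rather than silently ignored.
#'
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "cohort", "optical", "smooth_width", "saturation_hold_s",
             "bonferroni_m", "cor_threshold", "cutoffs", "out_dir")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort_config(sprintf("unknown configuration key(s): %s", paste(extra, collapse = ", ")))
  }
  coh <- raw$cohort
  cohort <- cohort_spec(
    n_positive = coh$n_positive, n_negative = coh$n_negative,
    diff_mean_s = unlist(coh$diff_mean_s), diff_sd_s = unlist(coh$diff_sd_s),
    pre_pt_mean_s = coh$pre_pt_mean_s, pre_pt_sd_s = coh$pre_pt_sd_s,
    post_pt_mean_s = unlist(coh$post_pt_mean_s), post_pt_sd_s = coh$post_pt_sd_s,
    patch_offset_sd_s = coh$patch_offset_sd_s,
    patch_counts = coh$patch_counts,
    amplitude_uM = coh$amplitude_uM, noise_sd = coh$noise_sd,
    seed = coh$seed,
    panel = rapply(coh$panel, unlist, how = "list")
  )
  optical <- optical_config(
    detector = raw$optical$detector,
    distance_cm = raw$optical$distance_cm,
    dpf = unlist(raw$optical$dpf),
    baseline_window_s = raw$optical$baseline_window_s,
    extinction = tibble::as_tibble(raw$optical$extinction)
  )
  run_config(
    seed = raw$seed, cohort = cohort, optical = optical,
    smooth_width = raw$smooth_width, saturation_hold_s = raw$saturation_hold_s,
    bonferroni_m = raw$bonferroni_m, cor_threshold = raw$cor_threshold,
    cutoffs = tibble::as_tibble(raw$cutoffs), out_dir = raw$out_dir
  )
}

#' Run the full analysis pipeline
#'
#' Generates the seeded synthetic cohort, reconstructs every recording,
#' extracts the per-patient feature table, runs the statistical layer
#' (redundancy screen, Welch tests, ROC/Youden cutoff, confusion metrics),
#' builds the modality truth table and scores all modalities. When an output
#' directory is given, the configuration, feature table, truth table,
#' statistics JSON and a plain-text report are written, each stamped with
#' the configuration hash and seed; identical configurations produce
#' identical bundles.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (overrides `config$out_dir`); `NULL`
#'   keeps everything in memory.
#' @return A `dvos_run` list: `cohort`, `features`, `analysis`,
#'   `truth_table`, `modality_scores`, `provenance`.
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(seed = 7,
#'   cohort = cohort_spec(n_positive = 3, n_negative = 2, patch_counts = 4)))
#' run$analysis$tests
#' }
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) abort_config("`config` must be a run_config")
  out_dir <- out_dir %||% config$out_dir

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "dvospt_stage_error", parent = e)
    })
  }

  cohort <- stage("simulate", generate_cohort(config$cohort))
  features <- stage("featurize", patient_features(
    cohort, config$optical,
    smooth_width = config$smooth_width,
    saturation_hold_s = config$saturation_hold_s))
  analysis <- stage("analyze", analyze_features(
    features, bonferroni_m = config$bonferroni_m,
    cor_threshold = config$cor_threshold))
  tt <- stage("compare", truth_table_from_cohort(cohort, features, config$cutoffs))
  scores <- stage("compare", score_modalities(tt))

  cfg_json <- jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                               digits = NA, null = "null", pretty = TRUE)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  provenance <- list(
    config_hash = cfg_hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("dvospt")),
    r_version = R.version.string
  )
  run <- structure(
    list(cohort = cohort, features = features, analysis = analysis,
         truth_table = tt, modality_scores = scores, provenance = provenance),
    class = "dvos_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(cfg_json, file.path(out_dir, "config.json"))
    stamp <- sprintf("# config_hash: %s seed: %d", cfg_hash, config$seed)
    write_stamped_csv(features, file.path(out_dir, "features.csv"), stamp)
    write_stamped_csv(tibble::as_tibble(tt), file.path(out_dir, "truth_table.csv"), stamp)
    stats_doc <- list(
      provenance = provenance,
      tests = analysis$tests,
      screen = tibble::as_tibble(analysis$screen),
      roc = list(auc = analysis$roc$auc, cutoff = analysis$roc$cutoff,
                 curve = analysis$roc$curve),
      confusion = tidy(analysis$confusion),
      modality_scores = scores
    )
    jsonlite::write_json(stats_doc, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    writeLines(report_text(run), file.path(out_dir, "report.txt"))
  }
  run
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

report_text <- function(run) {
  an <- run$analysis
  cm <- an$confusion
  c(
    sprintf("dvospt run report (config %s, seed %d, package %s)",
            run$provenance$config_hash, run$provenance$seed,
            run$provenance$package_version),
    "",
    sprintf("cohort: %d patients (%d positive / %d negative outcome)",
            nrow(run$features), sum(run$features$outcome == 1),
            sum(run$features$outcome == 0)),
    "",
    "Welch tests (negative - positive), Bonferroni-adjusted:",
    sprintf("  %-12s t = %6.2f  df = %5.1f  p = %.4g  p_adj = %.4g",
            an$tests$feature, an$tests$statistic, an$tests$df,
            an$tests$p_value, an$tests$p_adjusted),
    "",
    sprintf("ROC on %s: AUC = %.3f; Youden cutoff = %.2f s (predict worsening below it)",
            an$roc_feature, an$roc$auc, an$roc$cutoff),
    sprintf("  Se %g%%  Sp %g%%  PPV %g%%  NPV %g%%  (%d misclassified of %d)",
            cm$se_pct, cm$sp_pct, cm$ppv_pct, cm$npv_pct, cm$misclassified, cm$n),
    "",
    "Modality comparison (available patients):",
    sprintf("  %-9s n = %2d  misclassified = %2d  Se %3s%%  Sp %3s%%",
            run$modality_scores$modality, run$modality_scores$n_available,
            run$modality_scores$n_misclassified,
            format(run$modality_scores$se_pct), format(run$modality_scores$sp_pct))
  )
}

#' @export
print.dvos_run <- function(x, ...) {
  cat(paste(report_text(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Modality comparison report from a truth-table fixture
#'
#' Fixture-only mode: scores the packaged (or a user-supplied) clinical
#' truth table without any simulation, reporting per-modality confusion
#' metrics and availability.
#'
#' @param path Truth-table CSV; `NULL` uses the packaged table.
#' @return A `fixture_report` list: `table`, `scores`, `availability`.
#' @examples
#' fixture_report()
#' @export
fixture_report <- function(path = NULL) {
  table <- read_truth_table(path)
  structure(
    list(table = table, scores = score_modalities(table),
         availability = availability_counts(table)),
    class = "fixture_report"
  )
}

#' @export
print.fixture_report <- function(x, ...) {
  av <- x$availability
  cat(sprintf("<fixture_report> %d patients (%d positive / %d negative clinical outcome)\n",
              nrow(x$table), av$n_positive, av$n_negative))
  print(x$scores[, c("modality", "n_available", "n_misclassified",
                     "se_pct", "sp_pct", "ppv_pct", "npv_pct")])
  invisible(x)
}
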