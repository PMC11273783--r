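#' Pipeline configuration
#'
#' One serializable object holding every stage parameter. Unknown keys are
#' rejected.
#'
#' @param synthetic A [cohort_spec()] describing the synthetic cohort to
#'   analyze (the supported input source; pre-exported tiles can be
#'   assembled into the same cohort shape by the caller).
#' @param output_dir Directory for stage artifacts; `NULL` disables disk
#'   output.
#' @param tissue_min_fraction Tile tissue filter threshold. Default 0.5.
#' @param stain_matrix 2 x 3 stain matrix.
#' @param seg_params,feat_params Stage overrides; see [segment_tile()],
#'   [extract_tile_features()].
#' @param selection A [selection_config()].
#' @param svm An [svm_config()].
#' @param seed Global seed; seeds for cohort synthesis, MI jitter and fold
#'   shuffling are all derived from it.
#' @param paper_faithful Convenience switch: selects features once on the
#'   whole dataset (`selection_scope = "whole_dataset"`) as in the original
#'   protocol rather than per training fold.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = cohort_spec(),
                            output_dir = NULL,
                            tissue_min_fraction = 0.5,
                            stain_matrix = he_stain_matrix(),
                            seg_params = list(),
                            feat_params = list(),
                            selection = selection_config(),
                            svm = svm_config(),
                            seed = 1L,
                            paper_faithful = FALSE) {
  cfg <- list(
    synthetic = synthetic, output_dir = output_dir,
    tissue_min_fraction = tissue_min_fraction,
    stain_matrix = stain_matrix,
    seg_params = seg_params, feat_params = feat_params,
    selection = selection, svm = svm,
    seed = as.integer(seed), paper_faithful = isTRUE(paper_faithful)
  )
  check_that(is_prob(cfg$tissue_min_fraction),
    "tissue_min_fraction must be in [0, 1]",
    class = "pathomics_config_error"
  )
  cfg$synthetic$seed <- derive_seed(cfg$seed, "cohort")
  cfg$selection$seed <- derive_seed(cfg$seed, "mi")
  cfg$svm$seed <- derive_seed(cfg$seed, "folds")
  if (cfg$paper_faithful) cfg$svm$selection_scope <- "whole_dataset"
  structure(cfg, class = "pipeline_config")
}

stage_path <- function(cfg, name) {
  if (is.null(cfg$output_dir)) {
    return(NULL)
  }
  file.path(cfg$output_dir, name)
}

config_hash <- function(cfg) {
  rlang::hash(cfg[setdiff(names(cfg), "output_dir")])
}

#' Run the whole pipeline
#'
#' Generates (or reuses) the synthetic cohort, filters tiles by tissue
#' content, deconvolves stains, segments the three compartments, extracts
#' and aggregates features, prunes the case matrix, and fits the nested-CV
#' SVM. When `output_dir` is set, the case matrix and report are cached on
#' disk together with a provenance manifest (config hash, seed, package
#' version) and a rerun with an unchanged config reuses the cached matrix,
#' reproducing the identical report.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-stage progress? Default TRUE.
#' @return List: `report` (a `model_report`), `case_matrix` (pruned),
#'   `prune_report`, `labels`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(config)
  cache <- stage_path(config, "case_matrix.csv")
  manifest_path <- stage_path(config, "manifest.json")

  case_matrix <- NULL
  if (!is.null(cache) && file.exists(cache) && file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path)
    if (identical(man$config_hash, hash)) {
      say("pipeline: reusing cached case matrix (%s)", cache)
      case_matrix <- readr::read_csv(cache, show_col_types = FALSE)
    }
  }

  if (is.null(case_matrix)) {
    say("pipeline: generating synthetic cohort (seed %d)", config$synthetic$seed)
    cohort <- generate_cohort(config$synthetic)

    say("pipeline: filtering tiles at %.0f%% tissue", 100 * config$tissue_min_fraction)
    for (cid in names(cohort$tiles)) {
      fr <- vapply(cohort$tiles[[cid]], tissue_fraction, numeric(1))
      keep <- fr >= config$tissue_min_fraction
      if (!any(keep)) keep[which.max(fr)] <- TRUE # a case keeps >= 1 tile
      cohort$tiles[[cid]] <- cohort$tiles[[cid]][keep]
      cohort$truth[[cid]] <- cohort$truth[[cid]][keep]
    }

    say("pipeline: segmenting and extracting features for %d cases", length(cohort$tiles))
    case_matrix <- aggregate_cohort(
      cohort,
      seg_params = config$seg_params,
      feat_params = config$feat_params,
      stain_matrix = config$stain_matrix
    )
    if (!is.null(cache)) {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(case_matrix, cache)
    }
  }

  say("pipeline: pruning %d feature columns", ncol(case_matrix) - 2L)
  pruned <- prune_features(case_matrix)

  say(
    "pipeline: nested %d-fold CV (%s kernel, %s selection)",
    config$svm$outer_folds, config$svm$kernel, config$svm$selection_scope
  )
  report <- nested_cv(pruned$matrix, svm = config$svm, sel = config$selection)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(pruned$report, stage_path(config, "prune_report.csv"))
    readr::write_csv(report$predictions, stage_path(config, "predictions.csv"))
    jsonlite::write_json(
      list(
        config_hash = hash, seed = config$seed,
        package_version = as.character(utils::packageVersion("pathomics")),
        files = c(
          "case_matrix.csv", "prune_report.csv", "predictions.csv",
          "metrics.csv"
        ),
        glance = as.list(glance(report))
      ),
      manifest_path,
      auto_unbox = TRUE, pretty = TRUE
    )
    readr::write_csv(glance(report), stage_path(config, "metrics.csv"))
  }
  list(
    report = report, case_matrix = pruned$matrix,
    prune_report = pruned$report,
    labels = case_matrix[, c("case_id", "label")]
  )
}

#' Export figures and tables for a model report
#'
#' Writes the ROC curve, confusion-matrix figure, a metric table (AUC,
#' accuracy, precision, recall, F-score), ROC points CSV, and — when a case
#' matrix is supplied — the feature-correlation heatmap.
#'
#' @param report A `model_report` or named list of them.
#' @param outdir Output directory.
#' @param case_matrix Optional pruned case matrix for the heatmap.
#' @return Invisibly, the metric table.
#' @export
make_report <- function(report, outdir, case_matrix = NULL) {
  reports <- if (inherits(report, "model_report")) {
    setNames(list(report), report$kernel)
  } else {
    report
  }
  check_that(length(reports) > 0L, "no model reports supplied")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  metrics <- dplyr::bind_rows(lapply(reports, glance), .id = "model")
  metrics_out <- dplyr::mutate(
    dplyr::select(
      metrics, "model",
      AUC = "mean_auc", Accuracy = "accuracy", Precision = "precision",
      Recall = "recall", `F-Score` = "f_score"
    ),
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, 4))
  )
  readr::write_csv(metrics_out, file.path(outdir, "metrics_table.csv"))
  ggplot2::ggsave(file.path(outdir, "roc.png"), plot_roc(reports),
    width = 6, height = 5, dpi = 150
  )
  for (nm in names(reports)) {
    ggplot2::ggsave(
      file.path(outdir, paste0("confusion_", nm, ".png")),
      plot_confusion(reports[[nm]]),
      width = 4.5, height = 4, dpi = 150
    )
    readr::write_csv(
      roc_points(
        reports[[nm]]$predictions$label,
        reports[[nm]]$predictions$score
      ),
      file.path(outdir, paste0("roc_points_", nm, ".csv"))
    )
  }
  if (!is.null(case_matrix)) {
    cr <- feature_correlation_report(case_matrix)
    ggplot2::ggsave(
      file.path(outdir, "correlation_heatmap.png"),
      plot_correlation_heatmap(cr),
      width = 6, height = 5.5, dpi = 150
    )
    readr::write_csv(cr$families, file.path(outdir, "correlation_families.csv"))
  }
  invisible(metrics_out)
}
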