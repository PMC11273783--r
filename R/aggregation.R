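#' Default aggregation statistics
#'
#' Mean, median, standard deviation, and the nine interior deciles (10th to
#' 90th percentile, linear-interpolation quantiles) — 12 statistics per
#' feature. The decile definition is R's default type-7 quantile.
#'
#' @return Named list of functions mapping a numeric vector to a scalar.
#' @export
aggregation_stats <- function() {
  out <- list(
    mean = mean,
    median = median,
    sd = function(v) if (length(v) > 1L) sd(v) else 0
  )
  for (d in 1:9) {
    out[[paste0("d", d * 10)]] <- local({
      p <- d / 10
      function(v) unname(quantile(v, p))
    })
  }
  out
}

#' Aggregate a case's feature tables into one case-level vector
#'
#' Per-object tables are pooled across all of a case's tiles before any
#' statistic is computed (a nucleus contributes identically regardless of
#' which tile it came from), as are the per-tile image rows. For each unique
#' feature, each statistic in `stats` is emitted as
#' `<feature>_<stat>`; the output length is `length(stats)` times the
#' number of unique features (plus one `<compartment>_missing` flag per
#' object compartment). A compartment with zero objects across the whole
#' case gets zero-valued aggregates and a raised flag. The result is
#' invariant to tile order.
#'
#' @param tables List with elements `image` (tibble of per-tile rows),
#'   `nuclei` and `cytoplasm` (pooled or per-tile object tibbles); as
#'   produced by row-binding [extract_tile_features()] outputs of a case.
#' @param stats Named list of summary functions; default
#'   [aggregation_stats()].
#' @param reference_columns Optional named list of character vectors
#'   (`image`, `nuclei`, `cytoplasm`) fixing the expected feature columns,
#'   used when a compartment is empty for this case.
#' @return One-row tibble of aggregated features.
#' @export
aggregate_case <- function(tables, stats = aggregation_stats(),
                           reference_columns = NULL) {
  drop_cols <- c("case_id", "grid_row", "grid_col", "label")
  out <- list()
  for (compartment in c("image", "nuclei", "cytoplasm")) {
    tab <- tables[[compartment]]
    cols <- if (!is.null(tab) && ncol(tab) > 0L) {
      setdiff(names(tab), drop_cols)
    } else {
      character(0)
    }
    if (length(cols) == 0L && !is.null(reference_columns)) {
      cols <- reference_columns[[compartment]]
    }
    empty <- is.null(tab) || nrow(tab) == 0L
    if (compartment != "image") {
      out[[paste0(compartment, "_missing")]] <- as.numeric(empty)
    } else {
      check_that(!empty, "a case must have at least one tile",
        class = "pathomics_error"
      )
    }
    if (length(cols) == 0L) next
    vals <- vapply(cols, function(col) {
      if (empty) {
        return(numeric(length(stats)))
      }
      v <- tab[[col]]
      vapply(stats, function(f) f(v), numeric(1))
    }, numeric(length(stats)))
    flat <- as.numeric(vals) # stats vary fastest within each feature
    names(flat) <- paste(
      compartment,
      rep(cols, each = length(stats)),
      rep(names(stats), times = length(cols)),
      sep = "_"
    )
    out <- c(out, as.list(flat))
  }
  tibble::as_tibble(out)
}

#' Build the cases-by-features matrix for a cohort
#'
#' Runs deconvolution, segmentation, feature extraction and [aggregate_case()]
#' for every case of a [generate_cohort()] result (or an externally
#' assembled list with the same shape), returning the case-level matrix that
#' feeds [prune_features()] and [nested_cv()].
#'
#' @param cohort A `synthetic_cohort` (see [generate_cohort()]).
#' @param seg_params,feat_params Parameter overrides passed to
#'   [segment_tile()] and [extract_tile_features()].
#' @param stats Aggregation statistics; default [aggregation_stats()].
#' @param stain_matrix Stain matrix for deconvolution.
#' @return Tibble: `case_id`, `label`, then aggregated feature columns
#'   (identical column set for every case).
#' @export
aggregate_cohort <- function(cohort, seg_params = list(),
                             feat_params = list(),
                             stats = aggregation_stats(),
                             stain_matrix = he_stain_matrix()) {
  per_case <- lapply(names(cohort$tiles), function(cid) {
    tabs <- lapply(cohort$tiles[[cid]], function(tile) {
      pair <- deconvolve(rgb_to_od(tile), stain_matrix)
      masks <- segment_tile(pair, seg_params)
      extract_tile_features(tile, pair, masks, feat_params)
    })
    list(
      image = dplyr::bind_rows(lapply(tabs, `[[`, "image")),
      nuclei = dplyr::bind_rows(lapply(tabs, `[[`, "nuclei")),
      cytoplasm = dplyr::bind_rows(lapply(tabs, `[[`, "cytoplasm"))
    )
  })
  names(per_case) <- names(cohort$tiles)
  # fix the column universe so empty compartments still emit all columns
  ref_cols <- list(
    image = unique(unlist(lapply(per_case, function(x) names(x$image)))),
    nuclei = unique(unlist(lapply(per_case, function(x) names(x$nuclei)))),
    cytoplasm = unique(unlist(lapply(per_case, function(x) names(x$cytoplasm))))
  )
  ref_cols <- lapply(ref_cols, function(cl) {
    setdiff(cl, c("case_id", "grid_row", "grid_col", "label"))
  })
  rows <- lapply(names(per_case), function(cid) {
    dplyr::bind_cols(
      tibble::tibble(case_id = cid),
      aggregate_case(per_case[[cid]], stats, reference_columns = ref_cols)
    )
  })
  dplyr::left_join(cohort$labels, dplyr::bind_rows(rows), by = "case_id")
}

#' Drop duplicate and low-variance feature columns
#'
#' Exact duplicate columns are dropped (the first by column order is kept),
#' as are columns whose variance after median scaling (division by the
#' median absolute value, when nonzero) falls below `var_tol`. The report
#' lists every dropped column and the reason.
#'
#' @param matrix Tibble/data frame of cases x features; non-feature columns
#'   (`case_id`, `label`) are passed through untouched.
#' @param var_tol Variance threshold after scaling. Default 1e-10.
#' @return List: `matrix` (reduced), `report` (tibble `column`, `reason`).
#' @export
prune_features <- function(matrix, var_tol = 1e-10) {
  meta_cols <- intersect(c("case_id", "label"), names(matrix))
  feat_cols <- setdiff(names(matrix), meta_cols)
  check_that(nrow(matrix) >= 2L, "pruning needs at least 2 cases")
  drop_col <- character(0)
  drop_reason <- character(0)
  keep <- character(0)
  seen <- new.env(parent = emptyenv())
  for (col in feat_cols) {
    v <- matrix[[col]]
    med <- median(abs(v))
    s <- if (med > 0) v / med else v
    if (!all(is.finite(s)) || var(s) < var_tol) {
      drop_col <- c(drop_col, col)
      drop_reason <- c(drop_reason, "low_variance")
      next
    }
    key <- rlang::hash(v)
    first <- get0(key, envir = seen)
    if (!is.null(first)) {
      drop_col <- c(drop_col, col)
      drop_reason <- c(drop_reason, paste0("duplicate_of:", first))
      next
    }
    assign(key, col, envir = seen)
    keep <- c(keep, col)
  }
  dropped <- tibble::tibble(column = drop_col, reason = drop_reason)
  check_that(length(keep) > 0L, "all feature columns were dropped",
    class = "pathomics_error"
  )
  list(
    matrix = matrix[, c(meta_cols, keep)],
    report = dropped
  )
}

#' Pairwise feature correlations with per-family summaries
#'
#' Pearson correlation between every pair of feature columns, columns
#' ordered image, nuclei, cytoplasm (then by name), plus the distribution
#' of off-diagonal correlations within each compartment/family group.
#'
#' @param matrix Pruned cases x features tibble (see [prune_features()]).
#' @return List: `cor` (correlation matrix), `families` (tibble with
#'   `compartment`, `family`, `n_pairs`, `mean_abs_cor`, `q25`, `median`,
#'   `q75` of the absolute off-diagonal correlations).
#' @export
feature_correlation_report <- function(matrix) {
  feat_cols <- setdiff(names(matrix), c("case_id", "label"))
  compartment <- vapply(
    strsplit(feat_cols, "_"), `[[`, character(1), 1L
  )
  ord <- order(match(compartment, c("image", "nuclei", "cytoplasm")), feat_cols)
  feat_cols <- feat_cols[ord]
  cm <- cor(as.matrix(matrix[, feat_cols]))
  fam <- vapply(strsplit(feat_cols, "_"), function(s) {
    paste(s[1:min(2L, length(s))], collapse = "_")
  }, character(1))
  families <- dplyr::bind_rows(lapply(unique(fam), function(f) {
    idx <- which(fam == f)
    if (length(idx) < 2L) {
      return(tibble::tibble())
    }
    sub <- cm[idx, idx]
    vals <- abs(sub[upper.tri(sub)])
    tibble::tibble(
      compartment = strsplit(f, "_")[[1]][1],
      family = f, n_pairs = length(vals),
      mean_abs_cor = mean(vals),
      q25 = unname(quantile(vals, 0.25)),
      median = median(vals),
      q75 = unname(quantile(vals, 0.75))
    )
  }))
  list(cor = cm, families = families)
}
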