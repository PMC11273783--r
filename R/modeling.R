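#' k-nearest-neighbor mutual information between features and a binary label
#'
#' The Ross (2014) estimator for mutual information between a continuous
#' variable and a discrete label: for each sample, the distance to its k-th
#' nearest neighbor within the same class defines a radius; counting how
#' many samples of any class fall inside gives
#' `MI = psi(N) - mean(psi(n_y)) + psi(k) - mean(psi(m_i))` (nats), clamped
#' at 0. A tiny seeded jitter (identical across columns, scaled per column)
#' breaks ties, so duplicated columns receive equal scores and the result
#' is deterministic given the seed.
#'
#' @param X Cases x features data frame or matrix (numeric columns).
#' @param y Binary labels (0/1), at least 2 cases per class.
#' @param knn_k Neighbor count `k`. Default 3 (clamped to the smallest
#'   class size minus 1).
#' @param seed Seed for the jitter. Default 1.
#' @return Named numeric vector of non-negative scores, one per feature
#'   column.
#' @export
mi_scores <- function(X, y, knn_k = 3L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  check_that(length(unique(y)) == 2L, "y must contain both classes",
    class = "pathomics_error"
  )
  n <- length(y)
  counts <- table(y)
  check_that(all(counts >= 2L), "need at least 2 cases per class",
    class = "pathomics_error"
  )
  k <- max(1L, min(knn_k, min(counts) - 1L))
  jit <- with_seed(seed, rnorm(n))
  n_y <- as.numeric(counts[as.character(y)])
  scores <- apply(X, 2L, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      return(0)
    }
    xx <- x + s * 1e-10 * jit
    d <- abs(outer(xx, xx, `-`))
    diag(d) <- Inf
    radius <- vapply(seq_len(n), function(i) {
      same <- which(y == y[i])
      sort(d[i, same])[k]
    }, numeric(1))
    # points strictly inside the radius, plus the point itself
    m <- vapply(seq_len(n), function(i) sum(d[i, ] < radius[i]), numeric(1)) + 1
    max(0, digamma(n) - mean(digamma(n_y)) + digamma(k) - mean(digamma(m)))
  })
  scores
}

#' Feature-selection configuration
#'
#' Exactly one mode is active: `threshold` keeps every feature whose MI
#' score is `>= mi_threshold` (inclusive); `top_k` keeps the `top_k`
#' highest-scoring features (ties broken by column order).
#'
#' @param mode `"top_k"` or `"threshold"`.
#' @param mi_threshold Score cut for threshold mode. Default 0.29.
#' @param top_k Count for top-k mode. Default 100.
#' @param knn_k MI estimator neighbor count. Default 3.
#' @param seed Seed for the MI jitter. Default 1.
#' @return A `selection_config` list.
#' @export
selection_config <- function(mode = c("top_k", "threshold"),
                             mi_threshold = 0.29, top_k = 100L,
                             knn_k = 3L, seed = 1L) {
  mode <- match.arg(mode)
  check_that(mi_threshold >= 0, "mi_threshold must be >= 0",
    class = "pathomics_config_error"
  )
  check_that(is_count(top_k) && top_k >= 1, "top_k must be a positive count",
    class = "pathomics_config_error"
  )
  structure(
    list(
      mode = mode, mi_threshold = mi_threshold,
      top_k = as.integer(top_k), knn_k = as.integer(knn_k),
      seed = as.integer(seed)
    ),
    class = "selection_config"
  )
}

#' Select features from MI scores
#'
#' @param scores Named score vector from [mi_scores()].
#' @param config A [selection_config()].
#' @return Character vector of selected feature names, ordered by
#'   descending score (ties by original column order).
#' @export
select_features <- function(scores, config = selection_config()) {
  if (config$mode == "threshold") {
    keep <- which(scores >= config$mi_threshold)
  } else {
    k <- min(config$top_k, length(scores))
    keep <- head(order(-scores), k)
  }
  check_that(length(keep) > 0L,
    "no features selected; lower mi_threshold or use top_k mode",
    class = "pathomics_error"
  )
  keep <- keep[order(-scores[keep], keep)]
  names(scores)[keep]
}

#' SVM / cross-validation configuration
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C_grid Grid of regularization constants searched in the inner
#'   folds. Default `c(0.01, 0.1, 1, 10, 100)`.
#' @param gamma_grid RBF bandwidth grid, or `NULL` for the scale heuristic
#'   `1 / (d * mean(Var(X)))` alone.
#' @param outer_folds,inner_folds Stratified fold counts. Default 5 each.
#' @param selection_scope `"per_training_fold"` (leakage-free, default) or
#'   `"whole_dataset"` (select once on all cases before the outer loop —
#'   the historical protocol this pipeline can also reproduce).
#' @param seed Seed controlling fold shuffling and MI jitter.
#' @return An `svm_config` list.
#' @export
svm_config <- function(kernel = c("linear", "rbf"),
                       C_grid = c(0.01, 0.1, 1, 10, 100),
                       gamma_grid = NULL,
                       outer_folds = 5L, inner_folds = 5L,
                       selection_scope = c("per_training_fold", "whole_dataset"),
                       seed = 1L) {
  kernel <- match.arg(kernel)
  selection_scope <- match.arg(selection_scope)
  check_that(length(C_grid) >= 1L && all(C_grid > 0),
    "C_grid must be positive",
    class = "pathomics_config_error"
  )
  check_that(outer_folds >= 2L && inner_folds >= 2L,
    "fold counts must be >= 2",
    class = "pathomics_config_error"
  )
  structure(
    list(
      kernel = kernel, C_grid = C_grid, gamma_grid = gamma_grid,
      outer_folds = as.integer(outer_folds),
      inner_folds = as.integer(inner_folds),
      selection_scope = selection_scope, seed = as.integer(seed)
    ),
    class = "svm_config"
  )
}

# stratified fold assignment: within each class, seeded shuffle then
# round-robin; returns integer fold per case
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      check_that(length(idx) >= k,
        "too few cases in a class for stratified folds",
        class = "pathomics_stratification_error"
      )
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# fit an SVM and return decision scores oriented so higher = positive class
svm_decision <- function(X_train, y_train, X_test, kernel, C, gamma) {
  fit <- e1071::svm(
    x = X_train, y = factor(y_train, levels = c(0, 1)),
    kernel = if (kernel == "rbf") "radial" else "linear",
    cost = C, gamma = gamma %||% 1 / ncol(X_train),
    scale = FALSE
  )
  pr <- predict(fit, X_test, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sign_flip <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
  list(score = as.numeric(dv[, 1]) * sign_flip, pred = as.integer(as.character(pr)))
}

# z-score columns by training statistics; constant columns pass through
scale_by_train <- function(X_train, X_test) {
  mu <- colMeans(X_train)
  sg <- apply(X_train, 2L, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(
    train = sweep(sweep(X_train, 2L, mu), 2L, sg, "/"),
    test = sweep(sweep(X_test, 2L, mu), 2L, sg, "/")
  )
}

#' Nested cross-validated SVM classification
#'
#' Outer loop: stratified k-fold split of the cases. Per outer fold:
#' feature standardization and (when `selection_scope = "per_training_fold"`)
#' MI feature selection are computed on the training cases only; an inner
#' stratified k-fold grid search over `C` (and `gamma` for the RBF kernel)
#' picks the hyperparameters maximizing mean inner-fold AUC; the model is
#' refit on the whole outer training fold and decision scores are recorded
#' for the held-out cases. Every case is scored exactly once. The report
#' carries per-fold AUCs (mean +/- sd), the pooled confusion matrix at
#' decision threshold 0, and the pooled-score AUC.
#'
#' @param data Tibble with `case_id`, `label` (0/1) and numeric feature
#'   columns — e.g. the pruned output of [aggregate_cohort()].
#' @param svm An [svm_config()].
#' @param sel A [selection_config()].
#' @return A `model_report`; see [tidy.model_report()],
#'   [glance.model_report()], [autoplot.model_report()].
#' @export
nested_cv <- function(data, svm = svm_config(), sel = selection_config()) {
  feat_cols <- setdiff(names(data), c("case_id", "label"))
  X <- as.matrix(data[, feat_cols])
  y <- as.integer(data$label)
  case_id <- if ("case_id" %in% names(data)) {
    data$case_id
  } else {
    sprintf("case%03d", seq_along(y))
  }
  check_that(all(y %in% 0:1), "label must be binary 0/1")

  global_selected <- NULL
  if (identical(svm$selection_scope, "whole_dataset")) {
    global_selected <- select_features(
      mi_scores(X, y, knn_k = sel$knn_k, seed = sel$seed), sel
    )
  }

  folds <- stratified_folds(y, svm$outer_folds, svm$seed)
  per_fold <- list()
  predictions <- list()
  for (f in seq_len(svm$outer_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    selected <- global_selected %||% select_features(
      mi_scores(X[tr, , drop = FALSE], y[tr],
        knn_k = sel$knn_k, seed = sel$seed
      ), sel
    )
    Xtr <- X[tr, selected, drop = FALSE]
    Xte <- X[te, selected, drop = FALSE]
    sc <- scale_by_train(Xtr, Xte)

    gamma_grid <- if (svm$kernel == "rbf") {
      heur <- 1 / (ncol(sc$train) * max(mean(apply(sc$train, 2L, var)), 1e-12))
      unique(c(heur, svm$gamma_grid))
    } else {
      NA_real_
    }
    grid <- expand.grid(C = svm$C_grid, gamma = gamma_grid)
    inner <- stratified_folds(y[tr], svm$inner_folds,
      seed = derive_seed(svm$seed, "inner", f)
    )
    grid_auc <- vapply(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(seq_len(svm$inner_folds), function(i) {
        itr <- which(inner != i)
        ite <- which(inner == i)
        if (length(unique(y[tr][ite])) < 2L) {
          return(NA_real_)
        }
        isc <- scale_by_train(
          sc$train[itr, , drop = FALSE],
          sc$train[ite, , drop = FALSE]
        )
        out <- svm_decision(
          isc$train, y[tr][itr], isc$test, svm$kernel,
          grid$C[g], if (is.na(grid$gamma[g])) NULL else grid$gamma[g]
        )
        auc_rank(y[tr][ite], out$score)
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(grid_auc) # ties: first in grid order
    out <- svm_decision(
      sc$train, y[tr], sc$test, svm$kernel,
      grid$C[best], if (is.na(grid$gamma[best])) NULL else grid$gamma[best]
    )
    per_fold[[f]] <- tibble::tibble(
      fold = f,
      auc = auc_rank(y[te], out$score),
      C = grid$C[best],
      gamma = if (is.na(grid$gamma[best])) NA_real_ else grid$gamma[best],
      n_features = length(selected),
      features = list(selected)
    )
    predictions[[f]] <- tibble::tibble(
      case_id = case_id[te], label = y[te],
      score = out$score, pred = as.integer(out$score > 0), fold = f
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  predictions <- dplyr::bind_rows(predictions)
  conf <- with(
    predictions,
    c(
      tp = sum(pred == 1L & label == 1L), fp = sum(pred == 1L & label == 0L),
      tn = sum(pred == 0L & label == 0L), fn = sum(pred == 0L & label == 1L)
    )
  )
  structure(
    list(
      per_fold = per_fold,
      predictions = predictions,
      mean_auc = mean(per_fold$auc, na.rm = TRUE),
      sd_auc = sd(per_fold$auc),
      pooled_auc = auc_rank(predictions$label, predictions$score),
      confusion = as.list(conf),
      metrics = evaluate_confusion(conf["tp"], conf["fp"], conf["tn"], conf["fn"]),
      kernel = svm$kernel,
      config = list(svm = svm, selection = sel)
    ),
    class = "model_report"
  )
}

#' Metrics from a binary confusion matrix
#'
#' Accuracy, precision (= PPV), recall (sensitivity), F-score, and NPV,
#' with predicted-positive/-negative denominators (`precision = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)`). Undefined ratios (zero denominator) are reported as
#' 0 and flagged.
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts, not all zero.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`, `precision`,
#'   `recall`, `f_score`, `ppv`, `npv`, `undefined` (comma-separated flags).
#' @export
evaluate_confusion <- function(tp, fp, tn, fn) {
  vals <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  check_that(all(vals >= 0) && sum(vals) > 0 && all(vals == round(vals)),
    "confusion cells must be non-negative integers, not all zero"
  )
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f_score <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    undefined <- c(undefined, "f_score")
    0
  }
  tibble::tibble(
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    accuracy = (tp + tn) / sum(vals),
    precision = precision,
    recall = recall,
    f_score = f_score,
    ppv = precision,
    npv = ratio(tn, tn + fn, "npv"),
    undefined = paste(undefined, collapse = ",")
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> ", x$kernel, " SVM, ",
    nrow(x$per_fold), " outer folds\n",
    sep = ""
  )
  cat(sprintf(
    "  AUC %.4f +/- %.4f (per-fold), pooled %.4f\n",
    x$mean_auc, x$sd_auc, x$pooled_auc
  ))
  m <- x$metrics
  cat(sprintf(
    "  accuracy %.4f | precision %.4f | recall %.4f | F %.4f | NPV %.4f\n",
    m$accuracy, m$precision, m$recall, m$f_score, m$npv
  ))
  cat(sprintf(
    "  confusion: TP %d FP %d TN %d FN %d\n",
    m$tp, m$fp, m$tn, m$fn
  ))
  invisible(x)
}
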