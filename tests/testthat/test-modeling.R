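test_that("MI scores: independence, near-determinism, duplicates, errors", {
  set.seed(1)
  y <- rep(0:1, each = 250)
  X <- cbind(
    indep = rnorm(500),
    det = y + rnorm(500, 0, 1e-4)
  )
  X <- cbind(X, dup = X[, "det"])
  s <- mi_scores(X, y, seed = 5)
  expect_lt(s["indep"], 0.05)
  # oracle: discrete MI of the binned near-deterministic feature = H(y)
  want <- oracle_discrete_mi(X[, "det"], y, breaks = 2)
  expect_equal(unname(s["det"]), want, tolerance = 0.05)
  expect_equal(unname(s["det"]), unname(s["dup"]))
  expect_true(all(s >= 0))
  expect_error(mi_scores(X, rep(1, 500)), class = "pathomics_error")
})

test_that("MI of an independent pair shrinks with sample size", {
  set.seed(2)
  est <- vapply(c(100, 1000), function(n) {
    y <- rep(0:1, each = n / 2)
    mi_scores(cbind(x = rnorm(n)), y, seed = 3)
  }, numeric(1))
  expect_lt(est[2], 0.02)
  expect_lte(est[2], est[1] + 0.01)
})

test_that("feature selection honors threshold inclusivity and top-k ordering", {
  scores <- c(a = 0.5, b = 0.29, c = 0.1)
  keep <- select_features(scores, selection_config(mode = "threshold", mi_threshold = 0.29))
  expect_equal(keep, c("a", "b")) # boundary score kept, ordered by score
  all_of <- select_features(scores, selection_config(mode = "top_k", top_k = 3))
  expect_setequal(all_of, names(scores))
  set.seed(4)
  rs <- setNames(runif(50), sprintf("f%02d", 1:50))
  got <- select_features(rs, selection_config(mode = "top_k", top_k = 10))
  expect_setequal(got, names(sort(rs, decreasing = TRUE))[1:10])
  expect_error(
    select_features(c(a = 0.1), selection_config(mode = "threshold", mi_threshold = 1)),
    class = "pathomics_error"
  )
})

test_that("nested CV separates two distant Gaussians almost perfectly", {
  data <- make_gaussian_data(n = 80, sep = 6)
  rep <- nested_cv(
    data,
    svm_config(seed = 7),
    selection_config(mode = "top_k", top_k = 5, seed = 7)
  )
  expect_gte(rep$metrics$accuracy, 0.95)
  expect_gte(rep$mean_auc, 0.99)
})

test_that("nested CV on permuted labels stays in the null band", {
  base <- make_gaussian_data(n = 40, sep = 6, p_noise = 4)
  aucs <- vapply(1:20, function(i) {
    d <- base
    d$label <- withr::with_seed(1000 + i, sample(d$label))
    r <- nested_cv(
      d,
      svm_config(seed = i),
      selection_config(mode = "top_k", top_k = 3, seed = i)
    )
    r$mean_auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("nested CV is deterministic and partitions cases exactly once", {
  data <- make_gaussian_data(n = 40, sep = 2, p_noise = 4)
  r1 <- nested_cv(data, svm_config(seed = 11), selection_config(top_k = 4, seed = 11))
  r2 <- nested_cv(data, svm_config(seed = 11), selection_config(top_k = 4, seed = 11))
  expect_identical(r1, r2)
  expect_setequal(r1$predictions$case_id, data$case_id)
  expect_equal(nrow(r1$predictions), nrow(data)) # each case scored once
  expect_equal(
    with(r1$confusion, tp + fp + tn + fn),
    nrow(data)
  )
})

test_that("AUC is invariant under strictly monotone score transforms and matches pROC", {
  set.seed(12)
  labels <- rep(0:1, 25)
  scores <- rnorm(50) + labels
  a1 <- pathomics:::auc_rank(labels, scores)
  expect_equal(a1, pathomics:::auc_rank(labels, exp(scores)))
  expect_equal(a1, pathomics:::auc_rank(labels, 5 * scores - 3))
  expect_equal(
    a1,
    as.numeric(pROC::auc(pROC::roc(labels, scores,
      quiet = TRUE,
      direction = "<", levels = c(0, 1)
    )))
  )
})

test_that("whole-dataset selection scope reuses one feature list across folds", {
  data <- make_gaussian_data(n = 40, sep = 3, p_noise = 4)
  r <- nested_cv(
    data,
    svm_config(seed = 13, selection_scope = "whole_dataset"),
    selection_config(top_k = 3, seed = 13)
  )
  lists <- unique(r$per_fold$features)
  expect_length(lists, 1L)
})

test_that("confusion metrics reproduce their identities and handle zeros", {
  m <- evaluate_confusion(37, 10, 25, 7)
  expect_equal(m$precision * (m$tp + m$fp), m$tp)
  expect_equal(m$recall * (m$tp + m$fn), m$tp)
  expect_equal(m$npv * (m$tn + m$fn), m$tn)
  sym <- evaluate_confusion(25, 25, 25, 25)
  expect_equal(sym$accuracy, 0.5)
  expect_equal(sym$precision, 0.5)
  expect_equal(sym$recall, 0.5)
  z <- evaluate_confusion(0, 0, 5, 5)
  expect_equal(z$precision, 0)
  expect_match(z$undefined, "precision")
  expect_error(evaluate_confusion(0, 0, 0, 0))
})

test_that("tidiers return the documented shapes", {
  data <- make_gaussian_data(n = 40, sep = 4, p_noise = 4)
  r <- nested_cv(data, svm_config(seed = 15), selection_config(top_k = 3, seed = 15))
  td <- tidy(r)
  expect_named(td, c("fold", "auc", "C", "gamma", "n_features"))
  expect_equal(nrow(td), 5L)
  gl <- glance(r)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("kernel", "mean_auc", "accuracy", "f_score") %in% names(gl)))
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})

test_that("the RBF kernel trains and reports like the linear one", {
  data <- make_gaussian_data(n = 40, sep = 5, p_noise = 4)
  r <- nested_cv(
    data,
    svm_config(kernel = "rbf", seed = 17, gamma_grid = c(0.01, 0.1)),
    selection_config(top_k = 4, seed = 17)
  )
  expect_s3_class(r, "model_report")
  expect_gte(r$mean_auc, 0.9)
  expect_false(any(is.na(r$per_fold$gamma)))
})
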