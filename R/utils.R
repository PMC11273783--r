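# internal helpers shared across modules

# stopifnot-style check with a typed, readable message
check_that <- function(ok, msg, class = "pathomics_error") {
  if (!isTRUE(ok)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# luminance of an H x W x 3 array in [0, 255], returned in [0, 1]
rgb_luminance <- function(px) {
  (0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]) / 255
}

# raster-order (row-major) relabeling of a label matrix: object ids become
# 1..n ordered by the first raster position at which each label appears
relabel_raster <- function(labels) {
  if (all(labels == 0L)) {
    return(matrix(0L, nrow(labels), ncol(labels)))
  }
  idx_rowmajor <- order(row(labels), col(labels))
  flat <- as.integer(labels)[idx_rowmajor]
  first_seen <- unique(flat[flat > 0L])
  lut <- integer(max(labels))
  lut[first_seen] <- seq_along(first_seen)
  out <- labels
  out[labels > 0L] <- lut[labels[labels > 0L]]
  storage.mode(out) <- "integer"
  out
}

# rank-based AUC (Mann-Whitney), ties handled by midranks; labels in {0,1}
auc_rank <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic seed stream: derive child seeds from a parent seed
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  raw <- utils::tail(utils::head(strtoi(substring(rlang::hash(key), 1:7, 1:7), 16L), 7), 7)
  s <- sum(raw * 16^(0:6)) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
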