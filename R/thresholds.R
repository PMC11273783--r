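#' Otsu threshold of a grayscale image
#'
#' Histogram threshold maximizing between-class variance, computed on a
#' 256-bin histogram over the value range of `x` (or over `range` if given).
#'
#' @param x Numeric matrix or vector.
#' @param levels Number of histogram bins. Default 256.
#' @param range Optional length-2 value range; defaults to `range(x)`.
#' @return Threshold value on the scale of `x`. `Inf` when `x` is (near)
#'   constant, so that `x > otsu_threshold(x)` is empty.
#' @export
otsu_threshold <- function(x, levels = 256L, range = NULL) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range %||% base::range(v)
  if (diff(rng) < .Machine$double.eps^0.5) {
    return(Inf)
  }
  h <- tabulate(
    pmin(levels, pmax(1L, floor((v - rng[1]) / diff(rng) * levels) + 1L)),
    nbins = levels
  )
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(levels) - 0.5) * diff(rng) / levels
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  rng[1] + k * diff(rng) / levels
}

#' Minimum cross-entropy (Li) threshold
#'
#' Li & Lee's iterative minimum cross-entropy threshold: starting from the
#' image mean, iterate `t <- (mu_b - mu_f) / (log(mu_b) - log(mu_f))` where
#' `mu_b`, `mu_f` are the means of values below/above `t`, until convergence.
#' Values are shifted to be strictly positive before iterating.
#'
#' On a degenerate (near-constant) histogram the threshold is defined as
#' `Inf`: no pixel exceeds it and downstream foreground/fold masks are empty.
#'
#' @param x Numeric matrix or vector.
#' @param tol Convergence tolerance on the threshold. Default 1e-4 of range.
#' @param max_iter Iteration cap. Default 100.
#' @return Threshold on the scale of `x`, or `Inf` for near-constant input.
#' @export
li_threshold <- function(x, tol = NULL, max_iter = 100L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps^0.5) {
    return(Inf)
  }
  tol <- tol %||% (diff(rng) * 1e-4)
  # shift so all values > 0 (log-mean is undefined at 0)
  shift <- if (rng[1] <= 0) -rng[1] + diff(rng) * 1e-3 else 0
  v <- v + shift
  t_cur <- mean(v)
  for (i in seq_len(max_iter)) {
    back <- v[v <= t_cur]
    fore <- v[v > t_cur]
    if (length(back) == 0L || length(fore) == 0L) break
    mu_b <- mean(back)
    mu_f <- mean(fore)
    t_new <- (mu_b - mu_f) / (log(mu_b) - log(mu_f))
    if (!is.finite(t_new)) break
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur - shift
}
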