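# Tile-level feature families.

#' Granularity spectrum of a grayscale image
#'
#' Morphological size distribution: element `i` is the percentage of image
#' volume (sum of intensities) removed between grayscale openings with disc
#' structuring elements of radius `i - 1` and `i`, normalized by the
#' original volume. Elements are non-negative (openings are anti-extensive
#' and decreasing in radius) and sum to at most 100.
#'
#' @param image Non-negative numeric matrix (e.g. a stain OD channel).
#' @param n_scales Number of radii probed. Default 16.
#' @return Numeric vector `granularity_1 .. granularity_<n_scales>`.
#' @export
granularity_spectrum <- function(image, n_scales = 16L) {
  vol0 <- sum(image)
  out <- setNames(numeric(n_scales), paste0("granularity_", seq_len(n_scales)))
  if (vol0 <= 0) {
    return(out)
  }
  # EBImage grayscale morphology operates on [0, 1]; rescale around it
  scale_max <- max(image, 1e-12)
  prev <- image
  for (i in seq_len(n_scales)) {
    brush <- EBImage::makeBrush(2L * i + 1L, shape = "disc")
    opened <- scale_max * as.matrix(EBImage::opening(image / scale_max, brush))
    out[i] <- 100 * (sum(prev) - sum(opened)) / vol0
    prev <- opened
  }
  out
}

#' Stain colocalization metrics
#'
#' Pearson correlation, overlap coefficient, and Manders M1/M2 between the
#' hematoxylin and eosin channels over tissue pixels. Manders thresholds are
#' automatic (Otsu on each channel over the evaluated pixels). A
#' zero-variance channel yields a correlation of 0 by convention.
#'
#' @param h_channel,e_channel Equal-shape OD matrices.
#' @param tissue Optional logical mask restricting the evaluation; default
#'   is pixels with positive total OD.
#' @return Named numeric vector `coloc_pearson`, `coloc_overlap`,
#'   `coloc_manders_m1`, `coloc_manders_m2`.
#' @export
colocalization <- function(h_channel, e_channel, tissue = NULL) {
  check_that(all(dim(h_channel) == dim(e_channel)), "channel shapes differ")
  tissue <- tissue %||% (h_channel + e_channel > 0)
  h <- h_channel[tissue]
  e <- e_channel[tissue]
  if (length(h) < 2L || sd(h) == 0 || sd(e) == 0) {
    r <- 0
  } else {
    r <- cor(h, e)
  }
  denom <- sqrt(sum(h^2) * sum(e^2))
  overlap <- if (denom > 0) sum(h * e) / denom else 0
  th <- otsu_threshold(h)
  te <- otsu_threshold(e)
  m1 <- if (sum(h) > 0 && is.finite(te)) sum(h[e > te]) / sum(h) else 0
  m2 <- if (sum(e) > 0 && is.finite(th)) sum(e[h > th]) / sum(e) else 0
  c(
    coloc_pearson = r, coloc_overlap = overlap,
    coloc_manders_m1 = m1, coloc_manders_m2 = m2
  )
}

#' Whole-tile image quality metrics
#'
#' Focus score: the slope of the radially averaged log10 power spectrum of
#' the luminance against log10 spatial frequency (blur removes high
#' frequencies, making the slope more negative, so sharper images score
#' higher). Plus the percentage of saturated (luminance >= 254) and minimal
#' (<= 1) pixels.
#'
#' @param tile An [rgb_tile()] or H x W x 3 array in `[0, 255]`.
#' @return Named numeric vector `quality_focus_score`,
#'   `quality_pct_saturated`, `quality_pct_minimal`.
#' @export
image_quality <- function(tile) {
  px <- if (inherits(tile, "rgb_tile")) tile$pixels else tile
  gray <- rgb_luminance(px) * 255
  nr <- nrow(gray)
  nc <- ncol(gray)
  p <- Mod(fft(gray - mean(gray)))^2
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  f <- sqrt(outer(fr^2, fc^2, `+`))
  fmax <- sqrt(0.5) # corner of the 2-d frequency plane
  keep <- f > 0 & f <= fmax
  bins <- cut(f[keep], breaks = seq(0, fmax, length.out = 21L))
  pw <- tapply(p[keep], bins, mean)
  fm <- tapply(f[keep], bins, mean)
  ok <- is.finite(pw) & pw >= 0 & is.finite(fm)
  slope <- 0
  if (sum(ok) >= 3L) {
    slope <- unname(coef(lm(log10(pw[ok] + 1e-12) ~ log10(fm[ok])))[2])
  }
  c(
    quality_focus_score = slope,
    quality_pct_saturated = 100 * mean(gray >= 254),
    quality_pct_minimal = 100 * mean(gray <= 1)
  )
}

# intensity summary of one channel over tissue pixels, for tile-level rows
channel_summary <- function(x, tissue) {
  v <- x[tissue]
  if (length(v) == 0L) v <- 0
  q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
  c(
    intensity_mean = mean(v), intensity_median = q[2],
    intensity_sd = if (length(v) > 1L) sd(v) else 0,
    intensity_q25 = q[1], intensity_q75 = q[3],
    intensity_max = max(v)
  )
}
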