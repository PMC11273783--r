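#' Standard H&E stain matrix
#'
#' Returns a 2 x 3 matrix of unit-norm stain absorption vectors (rows:
#' hematoxylin, eosin; columns: R, G, B optical density). Defaults are the
#' widely used Ruifrok–Johnston H&E values.
#'
#' @param h,e Length-3 numeric absorption vectors for hematoxylin and eosin.
#'   They are normalized to unit Euclidean norm.
#' @return A 2 x 3 numeric matrix with rownames `c("h", "e")`.
#' @export
#' @examples
#' he_stain_matrix()
he_stain_matrix <- function(h = c(0.650, 0.704, 0.286),
                            e = c(0.072, 0.990, 0.105)) {
  check_that(length(h) == 3L && length(e) == 3L && all(is.finite(c(h, e))),
    "stain vectors must be finite length-3 numerics",
    class = "pathomics_config_error"
  )
  m <- rbind(h = h / sqrt(sum(h^2)), e = e / sqrt(sum(e^2)))
  colnames(m) <- c("r", "g", "b")
  m
}

#' Convert RGB intensities to optical density
#'
#' Beer–Lambert conversion `od = -log10((I + eps) / i0)` applied per channel,
#' clamped at zero. The small `eps` guards `log(0)` on saturated black pixels
#' of 8-bit input; set `eps = 0` for exact inversion of float renders.
#'
#' @param rgb An H x W x 3 array (or H x W matrix) of intensities in
#'   `[0, i0]`, or an [rgb_tile].
#' @param i0 Incident (white) intensity. Default 255.
#' @param eps Additive guard in intensity units. Default 1.
#' @return Array of the same shape with non-negative optical densities.
#' @seealso [od_to_rgb()], [deconvolve()]
#' @export
rgb_to_od <- function(rgb, i0 = 255, eps = 1) {
  if (inherits(rgb, "rgb_tile")) rgb <- rgb$pixels
  od <- -log10((rgb + eps) / i0)
  od[od < 0] <- 0
  od
}

#' Invert optical density back to intensities
#'
#' @param od Non-negative optical density array.
#' @inheritParams rgb_to_od
#' @return Intensity array in `[0, i0]`.
#' @export
od_to_rgb <- function(od, i0 = 255, eps = 1) {
  x <- i0 * 10^(-od) - eps
  x[x < 0] <- 0
  x[x > i0] <- i0
  x
}

#' Unmix an optical-density image into hematoxylin and eosin channels
#'
#' Per-pixel least-squares projection of the 3-vector OD onto the two stain
#' vectors via the Moore–Penrose pseudoinverse of the stain matrix (the
#' Ruifrok–Johnston color deconvolution scheme restricted to two stains; the
#' residual channel is discarded). Negative concentrations are clamped to 0
#' unless `clamp = FALSE`.
#'
#' @param od H x W x 3 optical-density array (see [rgb_to_od()]).
#' @param stain_matrix 2 x 3 stain matrix, rows linearly independent; see
#'   [he_stain_matrix()].
#' @param clamp Clamp negative recovered concentrations at 0? Default TRUE.
#' @return A `stain_pair`: list with matrices `h` and `e` (same H x W shape,
#'   non-negative when clamped) and the `stain_matrix` used.
#' @export
deconvolve <- function(od, stain_matrix = he_stain_matrix(), clamp = TRUE) {
  check_that(is.matrix(stain_matrix) && all(dim(stain_matrix) == c(2L, 3L)),
    "stain_matrix must be 2 x 3",
    class = "pathomics_config_error"
  )
  check_that(qr(stain_matrix)$rank == 2L,
    "stain_matrix rows must be linearly independent",
    class = "pathomics_config_error"
  )
  d <- dim(od)
  check_that(length(d) == 3L && d[3] == 3L, "od must be H x W x 3")
  # pinv = S^T (S S^T)^{-1}; concentrations c = OD . pinv  (pixels x 2)
  pinv <- t(stain_matrix) %*% solve(stain_matrix %*% t(stain_matrix))
  flat <- matrix(od, nrow = d[1] * d[2], ncol = 3L)
  conc <- flat %*% pinv
  if (clamp) conc[conc < 0] <- 0
  out <- list(
    h = matrix(conc[, 1], d[1], d[2]),
    e = matrix(conc[, 2], d[1], d[2]),
    stain_matrix = stain_matrix
  )
  class(out) <- "stain_pair"
  out
}

#' @export
print.stain_pair <- function(x, ...) {
  cat(
    "<stain_pair> ", nrow(x$h), "x", ncol(x$h),
    " | H od range [", sprintf("%.3f", min(x$h)), ", ",
    sprintf("%.3f", max(x$h)), "]",
    " | E od range [", sprintf("%.3f", min(x$e)), ", ",
    sprintf("%.3f", max(x$e)), "]\n",
    sep = ""
  )
  invisible(x)
}
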