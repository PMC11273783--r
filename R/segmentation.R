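#' Detect tissue-fold artifacts
#'
#' Tissue folds are double-thickness slide artifacts: macro-scale regions
#' whose staining is disproportionately heavy in both channels. The
#' detector first applies a grayscale morphological opening at nucleus
#' scale (`opening_radius`) to the total optical density `h + e`, which
#' erases nucleus-sized dark peaks while leaving macro-scale fold plateaus
#' (and their boundaries) intact. The fold threshold is then the larger of
#' (i) the minimum-cross-entropy (Li) threshold of the opened OD over
#' stained pixels — the adaptive split between ordinary tissue and the
#' heavy class — and (ii) `fold_factor` times the median opened stained OD,
#' which anchors "disproportionate" to the tile's typical staining so that
#' ordinary cytoplasm-vs-stroma contrast is never flagged. Flagged pixels
#' are kept only as connected components of at least `min_fold_area`
#' pixels. On a degenerate (near-constant) OD histogram no pixel can exceed
#' the threshold and the mask is empty.
#'
#' @param pair A [deconvolve()] `stain_pair`.
#' @param min_fold_area Minimum component area in px; default 0.25% of the
#'   tile area (2500 px for a 1000 x 1000 tile).
#' @param fold_factor Multiplier on the median stained OD that the fold
#'   class must exceed. Default 2 (double-thickness tissue doubles the typical OD).
#' @param opening_radius Disc radius in px of the nucleus-scale opening.
#'   Default 8.
#' @param od_floor Pixels with total OD below this are background and ignored
#'   when estimating the threshold. Default 0.05.
#' @return Logical matrix, `TRUE` on fold pixels (possibly empty).
#' @export
detect_folds <- function(pair, min_fold_area = NULL, fold_factor = 2,
                         opening_radius = 8L, od_floor = 0.05) {
  total <- pair$h + pair$e
  min_fold_area <- min_fold_area %||% max(1, round(0.0025 * length(total)))
  # EBImage grayscale morphology operates on [0, 1]; rescale around it
  scale_max <- max(total, 1e-12)
  opened <- scale_max * as.matrix(EBImage::opening(
    total / scale_max,
    EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
  ))
  stained <- opened > od_floor
  if (!any(stained)) {
    return(matrix(FALSE, nrow(total), ncol(total)))
  }
  li <- li_threshold(opened[stained])
  thr <- max(li, fold_factor * median(opened[stained]))
  if (!is.finite(thr)) {
    return(matrix(FALSE, nrow(total), ncol(total)))
  }
  mask <- opened > thr
  comp <- matrix(
    as.integer(EBImage::bwlabel(mask)),
    nrow(total), ncol(total)
  )
  areas <- tabulate(comp[comp > 0L])
  keep <- which(areas >= min_fold_area)
  out <- matrix(FALSE, nrow(total), ncol(total))
  out[comp %in% keep & comp > 0L] <- TRUE
  out
}

#' Segment cell nuclei from the hematoxylin channel
#'
#' Otsu threshold on the hematoxylin OD channel (fold pixels excluded), hole
#' filling, distance-transform watershed declumping of touching nuclei
#' (h-minima suppression via the watershed `tolerance`), and a size filter
#' keeping objects with equivalent diameter in `[min_diameter, max_diameter]`
#' (defaults 8–60 px, typical nuclear sizes at 20x / 0.5 um per px). Labels
#' are canonicalized to raster order.
#'
#' @param h_channel Hematoxylin OD matrix.
#' @param fold_mask Optional logical fold mask; fold pixels are removed from
#'   the foreground.
#' @param min_diameter,max_diameter Equivalent-diameter bounds in px.
#' @param declump_tolerance h-minima depth for watershed declumping.
#'   Default 2.
#' @return Integer label matrix (`0` background, objects `1..n`), possibly
#'   empty.
#' @export
segment_nuclei <- function(h_channel, fold_mask = NULL,
                           min_diameter = 8, max_diameter = 60,
                           declump_tolerance = 2) {
  x <- h_channel
  if (!is.null(fold_mask)) x[fold_mask] <- 0
  thr <- otsu_threshold(x)
  fg <- is.finite(thr) & x > thr
  if (!is.null(fold_mask)) fg[fold_mask] <- FALSE
  if (!any(fg)) {
    return(matrix(0L, nrow(x), ncol(x)))
  }
  fg <- EBImage::fillHull(fg)
  dm <- EBImage::distmap(fg)
  labels <- EBImage::watershed(dm, tolerance = declump_tolerance, ext = 1)
  labels <- matrix(as.integer(labels), nrow(x), ncol(x))
  # equivalent-diameter size filter
  areas <- tabulate(labels[labels > 0])
  dia <- 2 * sqrt(areas / pi)
  drop <- which(dia < min_diameter | dia > max_diameter)
  labels[labels %in% drop] <- 0L
  relabel_raster(labels)
}

#' Grow whole cells from nuclear seeds by shortest-path propagation
#'
#' The foreground domain is the set of pixels whose guide value (total OD)
#' exceeds its minimum-cross-entropy (Li) threshold, plus the seed pixels.
#' Each foreground pixel is assigned to the seed reachable at minimal
#' accumulated cost, with step cost
#' `sqrt((g(p) - g(q))^2 + lambda^2)` between 4-adjacent pixels (Dijkstra
#' order). Large `lambda` makes the spatial term dominate, approaching a
#' nearest-seed Voronoi partition; small `lambda` lets image gradients steer
#' the boundary. Nucleus pixels keep their seed label, so every cell label
#' matches its seed nucleus label.
#'
#' @param nuclei Integer label matrix of seeds (see [segment_nuclei()]).
#' @param guide Numeric guide image (total OD) of the same shape.
#' @param lambda_reg Regularization `lambda >= 0`. Default 0.05.
#' @param fold_mask Optional logical mask excluded from the foreground.
#' @param foreground Optional logical foreground override; when `NULL` it is
#'   computed by Li thresholding `guide`.
#' @return Integer label matrix of cells; `cells(k)` is a superset of
#'   `nuclei(k)`.
#' @export
propagate_cells <- function(nuclei, guide, lambda_reg = 0.05,
                            fold_mask = NULL, foreground = NULL) {
  check_that(is.numeric(lambda_reg) && length(lambda_reg) == 1L &&
    lambda_reg >= 0, "lambda_reg must be >= 0",
  class = "pathomics_config_error"
  )
  check_that(all(dim(nuclei) == dim(guide)), "nuclei and guide shapes differ")
  if (is.null(foreground)) {
    thr <- li_threshold(guide)
    foreground <- is.finite(thr) & guide > thr
  }
  foreground <- foreground | nuclei > 0L
  if (!is.null(fold_mask)) foreground[fold_mask & nuclei == 0L] <- FALSE
  storage.mode(nuclei) <- "integer"
  propagate_labels_cpp(nuclei, guide, foreground, lambda_reg)
}

#' Derive cytoplasm by subtracting nuclei from their cells
#'
#' `cytoplasm(k) = cells(k) \ nuclei(k)`, labels preserved. Objects whose
#' cytoplasm is empty simply have no cytoplasm pixels (they are dropped from
#' cytoplasm feature tables downstream but stay in nuclei tables).
#'
#' @param cells,nuclei Co-registered label matrices with matching label sets
#'   (every nucleus label must appear in `cells` and contain its nucleus).
#' @return Integer cytoplasm label matrix.
#' @export
derive_cytoplasm <- function(cells, nuclei) {
  check_that(all(dim(cells) == dim(nuclei)), "mask shapes differ")
  nuc_labels <- sort(unique(nuclei[nuclei > 0L]))
  cell_labels <- sort(unique(cells[cells > 0L]))
  check_that(identical(nuc_labels, cell_labels),
    "nuclei and cell label sets do not match",
    class = "pathomics_integrity_error"
  )
  check_that(all(cells[nuclei > 0L] == nuclei[nuclei > 0L]),
    "a nucleus pixel carries a different cell label",
    class = "pathomics_integrity_error"
  )
  cyto <- cells
  cyto[nuclei > 0L] <- 0L
  cyto
}

#' Segment one tile into nuclei, cells, and cytoplasm
#'
#' Convenience wrapper running [detect_folds()], [segment_nuclei()],
#' [propagate_cells()] and [derive_cytoplasm()] with shared parameters.
#'
#' @param pair A [deconvolve()] `stain_pair`.
#' @param params Named list of overrides: `min_fold_area`, `fold_factor`,
#'   `opening_radius`, `min_diameter`, `max_diameter`, `declump_tolerance`,
#'   `lambda_reg`.
#' @return List with `fold_mask`, `nuclei`, `cells`, `cytoplasm`.
#' @export
segment_tile <- function(pair, params = list()) {
  p <- utils::modifyList(
    list(
      min_fold_area = NULL, fold_factor = 2, opening_radius = 8L,
      min_diameter = 8, max_diameter = 60,
      declump_tolerance = 2, lambda_reg = 0.05
    ),
    params
  )
  folds <- detect_folds(pair,
    min_fold_area = p$min_fold_area,
    fold_factor = p$fold_factor,
    opening_radius = p$opening_radius
  )
  nuclei <- segment_nuclei(pair$h,
    fold_mask = folds,
    min_diameter = p$min_diameter, max_diameter = p$max_diameter,
    declump_tolerance = p$declump_tolerance
  )
  cells <- propagate_cells(nuclei, pair$h + pair$e,
    lambda_reg = p$lambda_reg,
    fold_mask = folds
  )
  cyto <- derive_cytoplasm(cells, nuclei)
  list(fold_mask = folds, nuclei = nuclei, cells = cells, cytoplasm = cyto)
}
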