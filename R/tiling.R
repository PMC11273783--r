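#' Split an RGB image into non-overlapping fixed-size tiles
#'
#' The image is cut into a `floor(H/s) x floor(W/s)` grid of `s x s` tiles;
#' partial border strips are discarded. Tile `(r, c)` (0-based, row-major)
#' holds pixels `image[r*s + 1 .. (r+1)*s, c*s + 1 .. (c+1)*s, ]`, so no
#' pixel appears in two tiles.
#'
#' @param image H x W x 3 numeric array of intensities in `[0, 255]`.
#' @param tile_size Tile side `s` in pixels. Default 1000.
#' @param case_id Case identifier stamped on every tile.
#' @return List of [rgb_tile()] objects in row-major grid order; empty (with
#'   a warning) when the image is smaller than one tile.
#' @export
tile_image <- function(image, tile_size = 1000L, case_id = "case") {
  d <- dim(image)
  check_that(length(d) == 3L && d[3] == 3L, "image must be H x W x 3")
  nr <- d[1] %/% tile_size
  nc <- d[2] %/% tile_size
  if (nr == 0L || nc == 0L) {
    rlang::warn("image is smaller than one tile; returning no tiles")
    return(list())
  }
  tiles <- vector("list", nr * nc)
  i <- 1L
  for (r in seq_len(nr) - 1L) {
    for (c in seq_len(nc) - 1L) {
      px <- image[
        r * tile_size + seq_len(tile_size),
        c * tile_size + seq_len(tile_size), ,
        drop = FALSE
      ]
      tiles[[i]] <- rgb_tile(px, grid_row = r, grid_col = c, case_id = case_id)
      i <- i + 1L
    }
  }
  tiles
}

#' Fraction of tile pixels classified as tissue
#'
#' A pixel is tissue when it is either colorful or dark: HSV saturation
#' `> sat_threshold` or luminance `< gray_threshold` (in `[0, 1]`). This is
#' the standard whitespace rule for H&E slides: stained tissue is saturated
#' (pink/purple) or dark, background glass is near-white.
#'
#' @param tile An [rgb_tile()] or H x W x 3 array.
#' @param sat_threshold Saturation cut. Default 0.05.
#' @param gray_threshold Luminance cut. Default 220/255.
#' @return Fraction in `[0, 1]`.
#' @export
tissue_fraction <- function(tile, sat_threshold = 0.05,
                            gray_threshold = 220 / 255) {
  px <- if (inherits(tile, "rgb_tile")) tile$pixels else tile
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3]) / 255
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3]) / 255
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  gray <- rgb_luminance(px)
  mean(sat > sat_threshold | gray < gray_threshold)
}

#' Keep tiles with enough tissue
#'
#' @param tiles List of [rgb_tile()]s.
#' @param min_fraction Minimum tissue fraction; a tile is kept iff its
#'   [tissue_fraction()] is `>= min_fraction` (inclusive). Default 0.5.
#' @param fractions Optional pre-computed tissue fractions (recycled against
#'   `tiles`); computed when `NULL`.
#' @return The kept tiles, order preserved, with the computed fractions in
#'   attribute `"fractions"` (for the kept tiles).
#' @export
filter_tiles <- function(tiles, min_fraction = 0.5, fractions = NULL) {
  check_that(is_prob(min_fraction), "min_fraction must be in [0, 1]",
    class = "pathomics_config_error"
  )
  fr <- fractions %||% vapply(tiles, tissue_fraction, numeric(1))
  keep <- fr >= min_fraction
  out <- tiles[keep]
  attr(out, "fractions") <- fr[keep]
  out
}

#' Tile manifest table
#'
#' @param tiles List of [rgb_tile()]s.
#' @param min_fraction Threshold used for the `kept` column. Default 0.5.
#' @return Tibble with `case_id`, `grid_row`, `grid_col`, `tissue_fraction`,
#'   `kept`.
#' @export
tile_manifest <- function(tiles, min_fraction = 0.5) {
  fr <- vapply(tiles, tissue_fraction, numeric(1))
  tibble::tibble(
    case_id = vapply(tiles, function(t) t$case_id, character(1)),
    grid_row = vapply(tiles, function(t) t$grid_row, integer(1)),
    grid_col = vapply(tiles, function(t) t$grid_col, integer(1)),
    tissue_fraction = fr,
    kept = fr >= min_fraction
  )
}
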