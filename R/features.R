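#' Extract all feature families from one segmented tile
#'
#' Runs the per-object extractors ([intensity_features()],
#' [radial_distribution()], [haralick_features()], [zernike_shape()],
#' [shape_features()], [neighbor_features()]) on the nuclei and cytoplasm
#' compartments and the tile-level extractors ([haralick_features()] per
#' stain, [granularity_spectrum()], [colocalization()], [image_quality()],
#' channel intensity summaries, object counts) on the whole tile. Texture
#' and intensity are measured on the stain OD channels: nuclei against
#' hematoxylin, cytoplasm against eosin. Fold pixels never reach this stage
#' (they are excluded during segmentation).
#'
#' Column names follow `<compartment>_<family>_<measure>`; the image row is
#' prefixed `image_`.
#'
#' @param tile An [rgb_tile()].
#' @param pair The tile's [deconvolve()] `stain_pair`.
#' @param masks Segmentation result from [segment_tile()] (needs `nuclei`
#'   and `cytoplasm`).
#' @param params Named list of overrides: `haralick_levels` (8), `n_rings`
#'   (4), `zernike_degree` (9), `neighbor_distance` (5),
#'   `granularity_scales` (16).
#' @return List of tibbles `image` (1 row), `nuclei`, `cytoplasm` (one row
#'   per object; zero rows when a compartment is empty). Every tibble
#'   carries `case_id`, `grid_row`, `grid_col` columns.
#' @export
extract_tile_features <- function(tile, pair, masks, params = list()) {
  p <- utils::modifyList(
    list(
      haralick_levels = 8L, n_rings = 4L, zernike_degree = 9L,
      neighbor_distance = 5, granularity_scales = 16L
    ),
    params
  )
  ref <- tibble::tibble(
    case_id = tile$case_id, grid_row = tile$grid_row,
    grid_col = tile$grid_col
  )

  object_table <- function(mask, channel, with_neighbors) {
    if (!any(mask > 0L)) {
      return(tibble::tibble())
    }
    tabs <- list(
      intensity_features(mask, channel),
      radial_distribution(mask, channel, n_rings = p$n_rings),
      haralick_features(channel, mask, levels = p$haralick_levels),
      zernike_shape(mask, max_degree = p$zernike_degree),
      shape_features(mask)
    )
    if (with_neighbors) {
      tabs <- c(tabs, list(neighbor_features(mask, p$neighbor_distance)))
    }
    out <- Reduce(function(a, b) dplyr::inner_join(a, b, by = "label"), tabs)
    dplyr::bind_cols(ref[rep(1L, nrow(out)), ], out)
  }

  nuclei_tab <- object_table(masks$nuclei, pair$h, with_neighbors = TRUE)
  cyto_tab <- object_table(masks$cytoplasm, pair$e, with_neighbors = FALSE)

  tissue <- pair$h + pair$e > 0
  img_har_h <- haralick_features(pair$h, levels = p$haralick_levels)
  img_har_e <- haralick_features(pair$e, levels = p$haralick_levels)
  image_row <- dplyr::bind_cols(
    ref,
    setNames(img_har_h, paste0("h_", names(img_har_h))),
    setNames(img_har_e, paste0("e_", names(img_har_e))),
    tibble::as_tibble(as.list(c(
      setNames(
        granularity_spectrum(pair$h, p$granularity_scales),
        paste0("h_granularity_", seq_len(p$granularity_scales))
      ),
      setNames(
        granularity_spectrum(pair$e, p$granularity_scales),
        paste0("e_granularity_", seq_len(p$granularity_scales))
      ),
      colocalization(pair$h, pair$e, tissue),
      image_quality(tile),
      setNames(
        channel_summary(pair$h, tissue),
        paste0("h_", names(channel_summary(matrix(0, 2, 1), matrix(TRUE, 2, 1))))
      ),
      setNames(
        channel_summary(pair$e, tissue),
        paste0("e_", names(channel_summary(matrix(0, 2, 1), matrix(TRUE, 2, 1))))
      ),
      count_nuclei = max(0L, length(unique(masks$nuclei[masks$nuclei > 0L]))),
      count_cytoplasm = max(0L, length(unique(masks$cytoplasm[masks$cytoplasm > 0L]))),
      tissue_fraction = mean(tissue)
    )))
  )
  list(image = image_row, nuclei = nuclei_tab, cytoplasm = cyto_tab)
}

#' Feature manifest
#'
#' Describes every feature column a compartment table can contain: the
#' compartment, family, and measure parsed from the stable
#' `family_measure` naming scheme.
#'
#' @param tables A list as returned by [extract_tile_features()] (or the
#'   pooled per-case version).
#' @return Tibble with `compartment`, `column`, `family`.
#' @export
feature_manifest <- function(tables) {
  one <- function(tab, compartment) {
    cols <- setdiff(
      names(tab),
      c("case_id", "grid_row", "grid_col", "label")
    )
    if (length(cols) == 0L) {
      return(tibble::tibble())
    }
    tibble::tibble(
      compartment = compartment,
      column = cols,
      family = vapply(
        strsplit(cols, "_"),
        function(s) s[[min(2L, length(s))]], character(1)
      )
    )
  }
  dplyr::bind_rows(
    one(tables$image, "image"),
    one(tables$nuclei, "nuclei"),
    one(tables$cytoplasm, "cytoplasm")
  )
}
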