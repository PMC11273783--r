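#' Specification of a synthetic H&E cohort
#'
#' Describes a two-class (responder / non-responder) cohort of synthetic
#' H&E tiles with ground-truth masks. Class-dependent parameters
#' (`nucleus_radius_mean`, `nucleus_eccentricity`, `texture_noise_sd`) may be
#' scalars (identical classes, zero effect size) or length-2 vectors ordered
#' `c(responder, nonresponder)`.
#'
#' Tiles are rendered by Beer–Lambert stain mixing: per-pixel hematoxylin and
#' eosin concentration fields (high hematoxylin in nuclei, high eosin in
#' cytoplasm, light eosin stroma elsewhere in tissue) are mixed through the
#' stain matrix into optical density and exponentiated to RGB. Tissue-fold
#' artifacts double both concentrations in a blob covering
#' `fold_area_fraction` of the tile.
#'
#' @param n_responders,n_nonresponders Number of cases per class. Defaults
#'   44 and 35, the cohort split this pipeline is calibrated around.
#' @param tiles_per_case Tiles rendered per case. Default 2.
#' @param tile_size Tile side in pixels. Default 1000.
#' @param nuclei_per_tile Nuclei per tile. Default 50.
#' @param nucleus_radius_mean Mean equivalent nucleus radius in pixels, per
#'   class (at 20x, ~0.5 um/px a 6–9 px radius is realistic). Default
#'   `c(9, 7)`.
#' @param nucleus_radius_sd Relative s.d. of nucleus radii. Default 0.08.
#' @param nucleus_eccentricity Nucleus ellipse eccentricity in `[0, 1)`, per
#'   class. Default 0.6.
#' @param texture_noise_sd Per-pixel Gaussian OD concentration noise, per
#'   class. Default 0.02.
#' @param modulation_amplitude Amplitude of the low-frequency multiplicative
#'   texture field (0 disables). Default 0.15.
#' @param fold_probability Probability that a tile contains a fold artifact.
#'   Default 0.05.
#' @param fold_area_fraction Area fraction of a fold blob. Default 0.05.
#' @param background_fraction Fraction of the tile that is whitespace (no
#'   tissue). Default 0.3.
#' @param cell_scale Ratio of cell to nucleus ellipse axes. Default 1.8.
#' @param nucleus_min_gap Minimum gap between nucleus boundaries, px.
#'   Default 2.
#' @param blur_sigma Optional Gaussian defocus sigma in px (0 = none).
#' @param concentrations Named list of stain concentrations for the three
#'   tissue compartments; see defaults in the function signature.
#' @param stain_matrix 2 x 3 stain matrix used for mixing; see
#'   [he_stain_matrix()].
#' @param i0 White level. Default 255.
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A `cohort_spec` list.
#' @seealso [render_tile()], [generate_cohort()]
#' @export
cohort_spec <- function(n_responders = 44L,
                        n_nonresponders = 35L,
                        tiles_per_case = 2L,
                        tile_size = 1000L,
                        nuclei_per_tile = 50L,
                        nucleus_radius_mean = c(9, 7),
                        nucleus_radius_sd = 0.08,
                        nucleus_eccentricity = 0.6,
                        texture_noise_sd = 0.02,
                        modulation_amplitude = 0.15,
                        fold_probability = 0.05,
                        fold_area_fraction = 0.05,
                        background_fraction = 0.3,
                        cell_scale = 1.8,
                        nucleus_min_gap = 2,
                        blur_sigma = 0,
                        concentrations = list(
                          nucleus = c(h = 1.00, e = 0.25),
                          cytoplasm = c(h = 0.12, e = 0.80),
                          stroma = c(h = 0.08, e = 0.55)
                        ),
                        stain_matrix = he_stain_matrix(),
                        i0 = 255,
                        seed = 1L) {
  spec <- list(
    n_responders = n_responders, n_nonresponders = n_nonresponders,
    tiles_per_case = tiles_per_case, tile_size = tile_size,
    nuclei_per_tile = nuclei_per_tile,
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    nucleus_eccentricity = nucleus_eccentricity,
    texture_noise_sd = texture_noise_sd,
    modulation_amplitude = modulation_amplitude,
    fold_probability = fold_probability,
    fold_area_fraction = fold_area_fraction,
    background_fraction = background_fraction,
    cell_scale = cell_scale, nucleus_min_gap = nucleus_min_gap,
    blur_sigma = blur_sigma, concentrations = concentrations,
    stain_matrix = stain_matrix, i0 = i0, seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  for (f in c(
    "n_responders", "n_nonresponders", "tiles_per_case",
    "tile_size", "nuclei_per_tile"
  )) {
    check_that(is_count(spec[[f]]), paste0(f, " must be a non-negative count"),
      class = "pathomics_config_error"
    )
  }
  for (f in c("fold_probability", "background_fraction")) {
    check_that(is_prob(spec[[f]]), paste0(f, " must be in [0, 1]"),
      class = "pathomics_config_error"
    )
  }
  check_that(all(spec$nucleus_radius_mean > 0), "nucleus radii must be > 0",
    class = "pathomics_config_error"
  )
  check_that(
    all(spec$nucleus_eccentricity >= 0 & spec$nucleus_eccentricity < 1),
    "eccentricity must be in [0, 1)",
    class = "pathomics_config_error"
  )
  check_that(all(spec$texture_noise_sd >= 0), "texture_noise_sd must be >= 0",
    class = "pathomics_config_error"
  )
  invisible(spec)
}

# class-dependent parameter lookup: scalar = both classes, length-2 =
# c(responder, nonresponder)
class_param <- function(value, class_label) {
  if (length(value) == 1L) {
    return(unname(value))
  }
  if (!is.null(names(value)) && class_label %in% names(value)) {
    return(unname(value[[class_label]]))
  }
  unname(value[[if (class_label == "responder") 1L else 2L]])
}

#' Construct an RGB tile object
#'
#' @param pixels H x W x 3 array of intensities in `[0, 255]`.
#' @param grid_row,grid_col 0-based tile grid indices.
#' @param case_id Parent case identifier.
#' @return An `rgb_tile`.
#' @export
rgb_tile <- function(pixels, grid_row = 0L, grid_col = 0L, case_id = "case") {
  check_that(length(dim(pixels)) == 3L && dim(pixels)[3] == 3L,
    "pixels must be H x W x 3"
  )
  structure(
    list(
      pixels = pixels, grid_row = as.integer(grid_row),
      grid_col = as.integer(grid_col), case_id = case_id
    ),
    class = "rgb_tile"
  )
}

#' @export
print.rgb_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(
    "<rgb_tile> ", x$case_id, " (", x$grid_row, ",", x$grid_col, ") ",
    d[1], "x", d[2], "\n",
    sep = ""
  )
  invisible(x)
}

# smooth zero-mean unit-sd random field (low-frequency texture / tissue blobs)
smooth_field <- function(size, sigma) {
  f <- matrix(rnorm(size * size), size, size)
  f <- as.matrix(EBImage::gblur(f, sigma = sigma))
  (f - mean(f)) / max(sd(f), 1e-12)
}

# rasterize an ellipse; returns integer pixel indices into a size x size tile
ellipse_pixels <- function(size, r0, c0, a, b, theta) {
  rad <- ceiling(max(a, b))
  rr <- max(1L, floor(r0 - rad)):min(size, ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(size, ceiling(c0 + rad))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  inside <- which(u^2 + v^2 <= 1)
  cbind(
    row = rep(rr, times = length(cc))[inside],
    col = rep(cc, each = length(rr))[inside]
  )
}

#' Render one synthetic H&E tile with ground truth
#'
#' Places non-overlapping elliptical nuclei on a smooth tissue region, grows
#' a surrounding cell ellipse per nucleus (contested pixels go to the nearest
#' nucleus center), builds hematoxylin/eosin concentration fields, and renders
#' `I = i0 * 10^-(cH*sH + cE*sE)` per channel. Fold artifacts double the
#' concentrations inside a blob. Ground-truth masks are exact.
#'
#' @param spec A [cohort_spec()].
#' @param class_label `"responder"` or `"nonresponder"`.
#' @param seed Optional integer; when given, rendering is reproducible on its
#'   own. When `NULL` the current RNG stream is used (as in
#'   [generate_cohort()]).
#' @param quantize Round intensities to 8-bit integers? Default TRUE. Use
#'   FALSE for exact float renders (e.g. when checking unmixing identities).
#' @param case_id,grid_row,grid_col Tile annotation.
#' @return List with `tile` (an [rgb_tile()]) and `truth` (a `ground_truth`
#'   list: `nuclei_mask`, `cell_mask`, `fold_mask`, `tissue_fraction`,
#'   `case_label`).
#' @export
render_tile <- function(spec, class_label = "responder", seed = NULL,
                        quantize = TRUE, case_id = "case",
                        grid_row = 0L, grid_col = 0L) {
  validate_cohort_spec(spec)
  check_that(class_label %in% c("responder", "nonresponder"),
    "class_label must be responder or nonresponder"
  )
  if (!is.null(seed)) {
    return(with_seed(seed, render_tile(spec, class_label,
      seed = NULL,
      quantize = quantize, case_id = case_id,
      grid_row = grid_row, grid_col = grid_col
    )))
  }
  s <- spec$tile_size
  r_mean <- class_param(spec$nucleus_radius_mean, class_label)
  ecc <- class_param(spec$nucleus_eccentricity, class_label)
  noise_sd <- class_param(spec$texture_noise_sd, class_label)

  # tissue region: threshold a smooth field at the background quantile so the
  # tissue fraction is exact
  if (spec$background_fraction >= 1) {
    tissue <- matrix(FALSE, s, s)
  } else if (spec$background_fraction <= 0) {
    tissue <- matrix(TRUE, s, s)
  } else {
    f <- smooth_field(s, sigma = max(2, s / 8))
    tissue <- f >= quantile(f, spec$background_fraction)
  }

  # nucleus placement: rejection sampling, overlap forbidden
  n <- spec$nuclei_per_tile
  centers <- matrix(numeric(0), 0, 2)
  axes <- matrix(numeric(0), 0, 2)
  thetas <- numeric(0)
  reach <- numeric(0) # cell-level semi-major axis, for overlap checks
  tissue_idx <- which(tissue)
  if (n > 0L) {
    check_that(length(tissue_idx) > 0L,
      "no tissue area available to place nuclei",
      class = "pathomics_generation_error"
    )
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        r <- max(1.5, rnorm(1, r_mean, spec$nucleus_radius_sd * r_mean))
        # semi-axes with eccentricity ecc and area pi * r^2
        shape <- (1 - ecc^2)^0.25
        a <- r / shape
        b <- r * shape
        idx <- tissue_idx[sample.int(length(tissue_idx), 1L)]
        r0 <- ((idx - 1L) %% s) + 1L
        c0 <- ((idx - 1L) %/% s) + 1L
        if (r0 - a < 1 || r0 + a > s || c0 - a < 1 || c0 + a > s) next
        if (nrow(centers) > 0L) {
          d <- sqrt((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2)
          if (any(d < axes[, 1] + a + spec$nucleus_min_gap)) next
        }
        centers <- rbind(centers, c(r0, c0))
        axes <- rbind(axes, c(a, b))
        thetas <- c(thetas, runif(1, 0, pi))
        reach <- c(reach, a * spec$cell_scale)
        placed <- TRUE
        break
      }
      check_that(placed,
        paste0(
          "could not place nucleus ", k, " of ", n,
          " without overlap within the retry budget"
        ),
        class = "pathomics_generation_error"
      )
    }
  }

  # ground-truth masks; contested cell pixels resolved by nearest center
  nuclei_mask <- matrix(0L, s, s)
  cell_mask <- matrix(0L, s, s)
  cell_dist <- matrix(Inf, s, s)
  for (k in seq_len(nrow(centers))) {
    px <- ellipse_pixels(
      s, centers[k, 1], centers[k, 2],
      axes[k, 1] * spec$cell_scale, axes[k, 2] * spec$cell_scale, thetas[k]
    )
    d2 <- (px[, 1] - centers[k, 1])^2 + (px[, 2] - centers[k, 2])^2
    lin <- px[, 1] + (px[, 2] - 1L) * s
    closer <- d2 < cell_dist[lin]
    cell_mask[lin[closer]] <- k
    cell_dist[lin[closer]] <- d2[closer]
  }
  for (k in seq_len(nrow(centers))) {
    px <- ellipse_pixels(
      s, centers[k, 1], centers[k, 2],
      axes[k, 1], axes[k, 2], thetas[k]
    )
    lin <- px[, 1] + (px[, 2] - 1L) * s
    nuclei_mask[lin] <- k
    cell_mask[lin] <- k # a nucleus pixel always belongs to its own cell
  }
  tissue <- tissue | cell_mask > 0L

  # concentration fields
  co <- spec$concentrations
  ch <- matrix(0, s, s)
  ce <- matrix(0, s, s)
  ch[tissue] <- co$stroma[["h"]]
  ce[tissue] <- co$stroma[["e"]]
  cyto <- cell_mask > 0L & nuclei_mask == 0L
  ch[cyto] <- co$cytoplasm[["h"]]
  ce[cyto] <- co$cytoplasm[["e"]]
  ch[nuclei_mask > 0L] <- co$nucleus[["h"]]
  ce[nuclei_mask > 0L] <- co$nucleus[["e"]]

  if (spec$modulation_amplitude > 0 && any(tissue)) {
    m <- 1 + spec$modulation_amplitude * smooth_field(s, sigma = max(2, s / 10))
    ch[tissue] <- ch[tissue] * m[tissue]
    ce[tissue] <- ce[tissue] * m[tissue]
  }
  if (noise_sd > 0 && any(tissue)) {
    ch[tissue] <- ch[tissue] + rnorm(sum(tissue), 0, noise_sd)
    ce[tissue] <- ce[tissue] + rnorm(sum(tissue), 0, noise_sd)
  }
  ch[ch < 0] <- 0
  ce[ce < 0] <- 0

  # fold artifact: double-thickness tissue in an elliptical blob. The folded
  # flap covers the whole region, so any background/stroma pixel inside it
  # carries at least a cytoplasm-level layer before doubling.
  fold_mask <- matrix(FALSE, s, s)
  if (spec$fold_probability > 0 && runif(1) < spec$fold_probability) {
    fa <- spec$fold_area_fraction * s^2
    fr <- sqrt(fa / pi)
    px <- ellipse_pixels(
      s, runif(1, fr, s - fr), runif(1, fr, s - fr),
      fr * 1.3, fr / 1.3, runif(1, 0, pi)
    )
    lin <- px[, 1] + (px[, 2] - 1L) * s
    fold_mask[lin] <- TRUE
    ch[lin] <- 2 * pmax(ch[lin], co$cytoplasm[["h"]])
    ce[lin] <- 2 * pmax(ce[lin], co$cytoplasm[["e"]])
    tissue[lin] <- TRUE
  }

  # Beer-Lambert mixing to RGB
  sm <- spec$stain_matrix
  px <- array(0, dim = c(s, s, 3))
  for (j in 1:3) {
    od <- ch * sm["h", j] + ce * sm["e", j]
    px[, , j] <- spec$i0 * 10^(-od)
  }
  if (spec$blur_sigma > 0) {
    px <- as.array(EBImage::gblur(px, sigma = spec$blur_sigma))
  }
  if (quantize) {
    px <- round(px)
    px[px < 0] <- 0
    px[px > spec$i0] <- spec$i0
  }

  truth <- structure(
    list(
      nuclei_mask = nuclei_mask, cell_mask = cell_mask,
      fold_mask = fold_mask, tissue_fraction = mean(tissue),
      case_label = class_label
    ),
    class = "ground_truth"
  )
  list(
    tile = rgb_tile(px, grid_row, grid_col, case_id),
    truth = truth
  )
}

#' Generate a seeded synthetic cohort
#'
#' Renders `tiles_per_case` tiles for each case of both classes. The whole
#' cohort is a deterministic function of the spec (including its seed):
#' identical inputs give bitwise-identical output.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `tiles` (per-case list of
#'   [rgb_tile()]s), `truth` (matching `ground_truth`s), `labels` (tibble
#'   `case_id`, `label` with 1 = responder/effective, 0 = nonresponder), and
#'   the `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  check_that(
    !(xor(spec$n_responders == 0L, spec$n_nonresponders == 0L)),
    "both classes must be populated (or both empty)",
    class = "pathomics_generation_error"
  )
  case_ids <- c(
    sprintf("R%03d", seq_len(spec$n_responders)),
    sprintf("N%03d", seq_len(spec$n_nonresponders))
  )
  classes <- rep(
    c("responder", "nonresponder"),
    c(spec$n_responders, spec$n_nonresponders)
  )
  tiles <- list()
  truth <- list()
  with_seed(spec$seed, {
    for (i in seq_along(case_ids)) {
      tl <- vector("list", spec$tiles_per_case)
      tr <- vector("list", spec$tiles_per_case)
      for (t in seq_len(spec$tiles_per_case)) {
        out <- render_tile(spec, classes[i],
          case_id = case_ids[i],
          grid_row = t - 1L, grid_col = 0L
        )
        tl[[t]] <- out$tile
        tr[[t]] <- out$truth
      }
      tiles[[case_ids[i]]] <- tl
      truth[[case_ids[i]]] <- tr
    }
  })
  structure(
    list(
      tiles = tiles, truth = truth,
      labels = tibble::tibble(
        case_id = case_ids,
        label = as.integer(classes == "responder")
      ),
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort> ", length(x$tiles), " cases (",
    sum(x$labels$label == 1L), " responders / ",
    sum(x$labels$label == 0L), " non-responders), ",
    x$spec$tiles_per_case, " tile(s) of ", x$spec$tile_size, " px each\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Tiles as PNG, ground-truth label masks as 16-bit TIFF, the label table as
#' CSV (`case_id,label`), and a JSON manifest tying them together.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (cid in names(cohort$tiles)) {
    for (t in seq_along(cohort$tiles[[cid]])) {
      tile <- cohort$tiles[[cid]][[t]]
      tr <- cohort$truth[[cid]][[t]]
      base <- sprintf("%s_tile%02d", cid, t - 1L)
      img_path <- file.path(dir, paste0(base, ".png"))
      EBImage::writeImage(
        EBImage::Image(aperm(tile$pixels / 255, c(2, 1, 3)),
          colormode = "Color"
        ),
        img_path
      )
      for (m in c("nuclei_mask", "cell_mask")) {
        EBImage::writeImage(
          EBImage::Image(t(tr[[m]]) / 65535),
          file.path(dir, paste0(base, "_", m, ".tiff")),
          type = "tiff", bits.per.sample = 16L
        )
      }
      entries[[length(entries) + 1L]] <- list(
        case_id = cid, grid_row = tile$grid_row, grid_col = tile$grid_col,
        image = basename(img_path), tissue_fraction = tr$tissue_fraction
      )
    }
  }
  readr::write_csv(cohort$labels, file.path(dir, "labels.csv"))
  manifest <- list(
    seed = cohort$spec$seed, n_cases = length(cohort$tiles),
    tile_size = cohort$spec$tile_size, tiles = entries
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
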