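# Per-object feature families. Each extractor takes a label mask (integer
# matrix, 0 = background) plus an intensity image (typically one stain OD
# channel) and returns a tibble with one row per object, first column
# `label`. Feature columns are named family_measure; the tile orchestrator
# prefixes the compartment.

# linear pixel indices per object label
object_pixels <- function(mask) {
  idx <- which(mask > 0L)
  split(idx, mask[idx])
}

# boundary pixels: object pixels with a 4-neighbor of a different label
# (or at the image border)
boundary_mask <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up <- pad[1:nr, 2:(nc + 1L)]
  down <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  ctr > 0L & (up != ctr | down != ctr | left != ctr | right != ctr)
}

#' Per-object intensity statistics
#'
#' Integrated, mean, median, standard deviation, median absolute deviation
#' (raw, unscaled), min, max, lower/upper quartile, and mean intensity of the
#' object's boundary pixels.
#'
#' @param mask Integer label matrix (0 = background).
#' @param image Co-registered numeric intensity image (e.g. a stain OD
#'   channel).
#' @return Tibble, one row per object; columns `label`,
#'   `intensity_integrated`, `intensity_mean`, `intensity_median`,
#'   `intensity_sd`, `intensity_mad`, `intensity_min`, `intensity_max`,
#'   `intensity_q25`, `intensity_q75`, `intensity_edge_mean`.
#' @export
intensity_features <- function(mask, image) {
  px <- object_pixels(mask)
  bnd <- boundary_mask(mask)
  rows <- lapply(names(px), function(lab) {
    v <- image[px[[lab]]]
    q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
    edge_idx <- px[[lab]][bnd[px[[lab]]]]
    tibble::tibble(
      label = as.integer(lab),
      intensity_integrated = sum(v),
      intensity_mean = mean(v),
      intensity_median = q[2],
      intensity_sd = if (length(v) > 1L) sd(v) else 0,
      intensity_mad = median(abs(v - q[2])),
      intensity_min = min(v),
      intensity_max = max(v),
      intensity_q25 = q[1],
      intensity_q75 = q[3],
      intensity_edge_mean = if (length(edge_idx)) mean(image[edge_idx]) else mean(v)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-object radial intensity distribution
#'
#' Object pixels are binned into `n_rings` equal-width bands of normalized
#' distance from the intensity-free centroid to the farthest object pixel.
#' For each ring: `FracAtD` is the ring's share of total object intensity;
#' `MeanFrac` is `FracAtD` normalized by the ring's share of pixels (1 for a
#' uniform object); `RadialCV` is the coefficient of variation of mean
#' intensity over `n_wedges` angular wedges within the ring (0 when fewer
#' than two wedges are populated or the mean is 0).
#'
#' @inheritParams intensity_features
#' @param n_rings Number of radial bands. Default 4.
#' @param n_wedges Number of angular wedges for `RadialCV`. Default 8.
#' @return Tibble with columns `label`, `radial_fracatd_<k>`,
#'   `radial_meanfrac_<k>`, `radial_cv_<k>` for `k = 1..n_rings`.
#' @export
radial_distribution <- function(mask, image, n_rings = 4L, n_wedges = 8L) {
  check_that(n_rings >= 1L, "n_rings must be >= 1")
  px <- object_pixels(mask)
  nr <- nrow(mask)
  rows <- lapply(names(px), function(lab) {
    idx <- px[[lab]]
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    v <- image[idx]
    r0 <- mean(r)
    c0 <- mean(c)
    d <- sqrt((r - r0)^2 + (c - c0)^2)
    dmax <- max(d)
    rel <- if (dmax > 0) d / dmax else rep(0, length(d))
    ring <- pmin(n_rings, floor(rel * n_rings) + 1L)
    wedge <- pmin(
      n_wedges,
      floor((atan2(c - c0, r - r0) + pi) / (2 * pi) * n_wedges) + 1L
    )
    total <- sum(v)
    out <- list(label = as.integer(lab))
    for (k in seq_len(n_rings)) {
      in_ring <- ring == k
      frac <- if (total != 0) sum(v[in_ring]) / total else 0
      pixfrac <- sum(in_ring) / length(idx)
      out[[paste0("radial_fracatd_", k)]] <- frac
      out[[paste0("radial_meanfrac_", k)]] <-
        if (pixfrac > 0) frac / pixfrac else 0
      cv <- 0
      if (any(in_ring)) {
        wm <- tapply(v[in_ring], wedge[in_ring], mean)
        if (length(wm) >= 2L && abs(mean(wm)) > 1e-12) {
          cv <- sd(wm) / abs(mean(wm))
        }
      }
      out[[paste0("radial_cv_", k)]] <- cv
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

# ---- Haralick texture ------------------------------------------------------

haralick_offsets <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

haralick_names <- c(
  "texture_asm", "texture_contrast", "texture_correlation",
  "texture_variance", "texture_idm", "texture_sumaverage",
  "texture_sumvariance", "texture_sumentropy", "texture_entropy",
  "texture_diffvariance", "texture_diffentropy",
  "texture_infomeas1", "texture_infomeas2"
)

# co-occurrence counts of a quantized matrix (NA outside the region) for one
# (dr, dc) offset; returned unsymmetrized
glcm_counts <- function(q, dr, dc, levels) {
  nr <- nrow(q)
  nc <- ncol(q)
  rs <- seq_len(nr - abs(dr))
  cs <- if (dc >= 0) seq_len(nc - dc) else (1L - dc):nc
  a <- q[rs + max(0L, -dr), cs, drop = FALSE]
  b <- q[rs + max(0L, dr), cs + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    return(matrix(0, levels, levels))
  }
  matrix(
    tabulate(a[ok] + levels * (b[ok] - 1L), nbins = levels * levels),
    levels, levels
  )
}

# the 13 Haralick (1973) statistics of one symmetric normalized GLCM;
# natural logarithms
haralick_from_glcm <- function(p) {
  levels <- nrow(p)
  i <- row(p)
  j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sigma2 <- sum((i - mu)^2 * p)
  ent_terms <- function(x) -sum(x[x > 0] * log(x[x > 0]))
  # p_{x+y}(k), k = 2..2L ; p_{x-y}(k), k = 0..L-1
  psum <- vapply(2:(2 * levels), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(levels - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  sum_avg <- sum((2:(2 * levels)) * psum)
  diff_avg <- sum((0:(levels - 1)) * pdiff)
  hx <- ent_terms(px)
  hxy <- ent_terms(p)
  # joint entropies against the product of (equal) marginals
  pxy <- outer(px, px)
  sel <- p > 0 & pxy > 0
  hxy1 <- -sum(p[sel] * log(pxy[sel]))
  hxy2 <- ent_terms(pxy)
  im1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  im2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 0
  c(
    texture_asm = sum(p^2),
    texture_contrast = sum((i - j)^2 * p),
    texture_correlation = corr,
    texture_variance = sigma2,
    texture_idm = sum(p / (1 + (i - j)^2)),
    texture_sumaverage = sum_avg,
    texture_sumvariance = sum(((2:(2 * levels)) - sum_avg)^2 * psum),
    texture_sumentropy = ent_terms(psum),
    texture_entropy = hxy,
    texture_diffvariance = sum(((0:(levels - 1)) - diff_avg)^2 * pdiff),
    texture_diffentropy = ent_terms(pdiff),
    texture_infomeas1 = im1,
    texture_infomeas2 = im2
  )
}

# quantize values linearly over [mn, mx] into `levels` bins (1-based)
quantize_levels <- function(x, mn, mx, levels) {
  pmin.int(levels, pmax.int(1L, floor((x - mn) / (mx - mn) * levels) + 1L))
}

haralick_region <- function(qsub, levels) {
  per_dir <- lapply(haralick_offsets, function(off) {
    cnt <- glcm_counts(qsub, off[1], off[2], levels)
    cnt <- cnt + t(cnt)
    tot <- sum(cnt)
    if (tot == 0) {
      return(NULL)
    }
    haralick_from_glcm(cnt / tot)
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  if (length(per_dir) == 0L) {
    return(setNames(rep(0, 13L), haralick_names))
  }
  colMeans(do.call(rbind, per_dir))
}

#' Haralick texture features
#'
#' Gray-level co-occurrence texture: region intensities are linearly
#' quantized to `levels` bins over the region's min–max range, a symmetric
#' normalized GLCM is built for 1-pixel offsets in 4 directions, and the 13
#' Haralick (1973) statistics (angular second moment, contrast, correlation,
#' variance, inverse difference moment, sum average/variance/entropy,
#' entropy, difference variance/entropy, and the two information measures of
#' correlation) are averaged over the directions. Natural logarithms are
#' used. A constant region has all features defined as 0.
#'
#' @param image Numeric intensity image.
#' @param mask Integer label matrix for per-object features, or `NULL` to
#'   treat the whole image as one region (returns a single row without a
#'   `label` column).
#' @param levels Number of gray levels. Default 8.
#' @return Tibble of the 13 `texture_*` columns (plus `label` when `mask`
#'   is given).
#' @export
haralick_features <- function(image, mask = NULL, levels = 8L) {
  if (is.null(mask)) {
    mn <- min(image)
    mx <- max(image)
    if (mx - mn < .Machine$double.eps^0.5) {
      return(tibble::as_tibble(as.list(setNames(rep(0, 13L), haralick_names))))
    }
    q <- matrix(
      quantize_levels(image, mn, mx, levels),
      nrow(image), ncol(image)
    )
    return(tibble::as_tibble(as.list(haralick_region(q, levels))))
  }
  px <- object_pixels(mask)
  nr <- nrow(mask)
  rows <- lapply(names(px), function(lab) {
    idx <- px[[lab]]
    v <- image[idx]
    mn <- min(v)
    mx <- max(v)
    feats <- if (mx - mn < .Machine$double.eps^0.5 || length(idx) < 2L) {
      setNames(rep(0, 13L), haralick_names)
    } else {
      r <- ((idx - 1L) %% nr) + 1L
      c <- ((idx - 1L) %/% nr) + 1L
      rsub <- r - min(r) + 1L
      csub <- c - min(c) + 1L
      q <- matrix(NA_integer_, max(rsub), max(csub))
      q[cbind(rsub, csub)] <- quantize_levels(v, mn, mx, levels)
      haralick_region(q, levels)
    }
    tibble::as_tibble(c(list(label = as.integer(lab)), as.list(feats)))
  })
  dplyr::bind_rows(rows)
}

# ---- Zernike shape moments -------------------------------------------------

zernike_nm_pairs <- function(max_degree) {
  out <- list()
  for (n in 0:max_degree) {
    for (m in seq(n %% 2, n, by = 2)) {
      out[[length(out) + 1L]] <- c(n, m)
    }
  }
  out
}

zernike_radial <- function(n, m, rho) {
  s_max <- (n - m) / 2
  acc <- numeric(length(rho))
  for (s in 0:s_max) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    acc <- acc + coef * rho^(n - 2 * s)
  }
  acc
}

#' Zernike shape moment magnitudes
#'
#' Each binary object is mapped onto the unit disk via its minimum enclosing
#' circle (centroid center, radius = farthest pixel distance), and
#' the magnitudes of the Zernike moments `|Z_nm|`,
#' `Z_nm = (n+1)/pi * sum_px f * conj(V_nm)`, are computed for all
#' `n <= max_degree`, `m >= 0`, `n - m` even (30 values at degree 9). The
#' indicator is normalized to unit mass (`f = 1/area`), so magnitudes are
#' scale-comparable across objects; they are invariant to object rotation.
#'
#' @param mask Integer label matrix.
#' @param max_degree Maximum polynomial degree. Default 9.
#' @return Tibble with `label` and `zernike_<n>_<m>` columns.
#' @export
zernike_shape <- function(mask, max_degree = 9L) {
  pairs <- zernike_nm_pairs(max_degree)
  px <- object_pixels(mask)
  nr <- nrow(mask)
  rows <- lapply(names(px), function(lab) {
    idx <- px[[lab]]
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    r0 <- mean(r)
    c0 <- mean(c)
    rad <- max(sqrt((r - r0)^2 + (c - c0)^2), 1)
    x <- (c - c0) / rad
    y <- (r - r0) / rad
    rho <- sqrt(x^2 + y^2)
    theta <- atan2(y, x)
    f <- 1 / length(idx)
    out <- list(label = as.integer(lab))
    for (p in pairs) {
      n <- p[1]
      m <- p[2]
      v <- zernike_radial(n, m, rho) * exp(complex(imaginary = -m * theta))
      out[[sprintf("zernike_%d_%d", n, m)]] <-
        Mod((n + 1) / pi * sum(f * v))
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

# ---- geometry --------------------------------------------------------------

# contour-based perimeter with the Vossepoel-Smeulders corner correction:
# P = 0.980 * N_axial + 1.406 * N_diagonal - 0.091 * N_corners
perimeter_vs <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) {
    return(4)
  }
  steps <- rbind(diff(contour), contour[1, ] - contour[n, ])
  diag_step <- steps[, 1] != 0 & steps[, 2] != 0
  dirs <- atan2(steps[, 2], steps[, 1])
  corners <- sum(dirs != c(dirs[-1], dirs[1]))
  0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * corners
}

# lattice-point count of the convex hull of pixel centers (Pick's theorem),
# used as the hull area on the pixel-count scale
hull_pixel_area <- function(r, c) {
  pts <- unique(cbind(r, c))
  if (nrow(pts) <= 2L) {
    return(nrow(pts))
  }
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  x <- hp[, 1]
  y <- hp[, 2]
  area2 <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
  bpts <- sum(vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    gcd2(abs(x[j] - x[i]), abs(y[j] - y[i]))
  }, numeric(1)))
  area2 / 2 + bpts / 2 + 1 # interior + boundary lattice points
}

gcd2 <- function(a, b) {
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  max(a, 1)
}

#' Per-object geometry features
#'
#' Area (pixel count), contour perimeter (corner-corrected chain length),
#' form factor `4*pi*A/P^2` (clamped to 1), extent (area / bounding-box
#' area), solidity (area / convex-hull pixel count), eccentricity,
#' major/minor axis lengths and orientation from second central moments, and
#' maximum/minimum Feret diameters (rotating projections of the convex
#' hull).
#'
#' @param mask Integer label matrix.
#' @return Tibble with `label` and `shape_*` columns.
#' @export
shape_features <- function(mask) {
  px <- object_pixels(mask)
  nr <- nrow(mask)
  rows <- lapply(names(px), function(lab) {
    idx <- px[[lab]]
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    area <- length(idx)
    # outer contour of this object alone, on its cropped bounding box
    sub <- matrix(0L, diff(range(r)) + 3L, diff(range(c)) + 3L)
    sub[cbind(r - min(r) + 2L, c - min(c) + 2L)] <- 1L
    ct <- EBImage::ocontour(sub)
    per <- if (length(ct) >= 1L) {
      sum(vapply(ct, perimeter_vs, numeric(1))) # fragments: sum their outlines
    } else {
      4
    }
    mu20 <- mean((r - mean(r))^2)
    mu02 <- mean((c - mean(c))^2)
    mu11 <- mean((r - mean(r)) * (c - mean(c)))
    half <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    l1 <- (mu20 + mu02) / 2 + half
    l2 <- (mu20 + mu02) / 2 - half
    ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
    hull_area <- hull_pixel_area(r, c)
    # Feret diameters over the convex hull
    pts <- unique(cbind(r, c))
    hp <- if (nrow(pts) > 2L) pts[grDevices::chull(pts), , drop = FALSE] else pts
    ang <- seq(0, pi, length.out = 91L)[-91L]
    proj_range <- vapply(ang, function(a) {
      pr <- hp[, 1] * cos(a) + hp[, 2] * sin(a)
      diff(range(pr)) + 1
    }, numeric(1))
    tibble::tibble(
      label = as.integer(lab),
      shape_area = area,
      shape_perimeter = per,
      shape_form_factor = min(1, 4 * pi * area / per^2),
      shape_extent = area / (diff(range(r)) + 1) / (diff(range(c)) + 1),
      shape_solidity = min(1, area / hull_area),
      shape_eccentricity = ecc,
      shape_major_axis = 4 * sqrt(l1),
      shape_minor_axis = 4 * sqrt(pmax(0, l2)),
      shape_orientation = 0.5 * atan2(2 * mu11, mu20 - mu02),
      shape_feret_max = max(proj_range),
      shape_feret_min = min(proj_range)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-object neighborhood features
#'
#' For each object, the number of distinct other labels with any pixel
#' within `expand_distance` (Euclidean) of the object's boundary, and the
#' fraction of boundary pixels lying within `expand_distance` of another
#' object ("percent touching").
#'
#' @param mask Integer label matrix (typically nuclei).
#' @param expand_distance Neighborhood radius in px. Default 5.
#' @return Tibble with `label`, `neighbors_count`, `neighbors_pct_touching`.
#' @export
neighbor_features <- function(mask, expand_distance = 5) {
  labs <- sort(unique(mask[mask > 0L]))
  bnd <- boundary_mask(mask)
  rows <- lapply(labs, function(k) {
    others <- mask > 0L & mask != k
    bk <- bnd & mask == k
    if (!any(others)) {
      return(tibble::tibble(
        label = k, neighbors_count = 0L,
        neighbors_pct_touching = 0
      ))
    }
    # distance of every pixel to the nearest other-object pixel
    d_other <- as.matrix(EBImage::distmap(matrix(
      as.numeric(!others),
      nrow(mask), ncol(mask)
    )))
    pct <- mean(d_other[bk] <= expand_distance)
    # distance of every pixel to this object's boundary
    d_bnd <- as.matrix(EBImage::distmap(matrix(
      as.numeric(!bk),
      nrow(mask), ncol(mask)
    )))
    near <- d_bnd <= expand_distance & others
    tibble::tibble(
      label = k,
      neighbors_count = length(setdiff(unique(mask[near]), c(0L, k))),
      neighbors_pct_touching = pct
    )
  })
  dplyr::bind_rows(rows)
}
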