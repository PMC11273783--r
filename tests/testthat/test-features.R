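test_that("intensity statistics match closed forms and a brute-force recount", {
  mask <- matrix(0L, 10, 10)
  mask[3:6, 3:7] <- 1L
  img <- matrix(0.5, 10, 10)
  f <- intensity_features(mask, img)
  expect_equal(f$intensity_integrated, 0.5 * 20)
  expect_equal(f$intensity_sd, 0)
  expect_equal(f$intensity_mad, 0)
  # two-pixel object
  mask2 <- matrix(0L, 4, 4)
  mask2[2, 2:3] <- 1L
  img2 <- matrix(0, 4, 4)
  img2[2, 2] <- 0.2
  img2[2, 3] <- 0.4
  f2 <- intensity_features(mask2, img2)
  expect_equal(f2$intensity_mean, 0.3)
  expect_equal(f2$intensity_min, 0.2)
  expect_equal(f2$intensity_max, 0.4)
  # random object against naive per-pixel statistics
  set.seed(5)
  mask3 <- draw_disk(20, 10, 11, 6)
  img3 <- matrix(runif(400), 20, 20)
  f3 <- intensity_features(mask3, img3)
  v <- img3[mask3 == 1L]
  expect_equal(f3$intensity_integrated, sum(v), tolerance = 1e-9)
  expect_equal(f3$intensity_mean, mean(v), tolerance = 1e-9)
  expect_equal(f3$intensity_median, median(v), tolerance = 1e-9)
  expect_equal(f3$intensity_sd, sd(v), tolerance = 1e-9)
  expect_equal(f3$intensity_q25, unname(quantile(v, 0.25)), tolerance = 1e-9)
  expect_equal(f3$intensity_q75, unname(quantile(v, 0.75)), tolerance = 1e-9)
})

test_that("radial distribution: uniform disk, point mass, and oracle equivalence", {
  mask <- draw_disk(41, 21, 21, 15)
  img <- matrix(1, 41, 41)
  f <- radial_distribution(mask, img)
  expect_equal(unlist(f[1, paste0("radial_meanfrac_", 1:4)]),
    rep(1, 4),
    ignore_attr = TRUE, tolerance = 1e-9
  )
  expect_equal(unlist(f[1, paste0("radial_cv_", 1:4)]),
    rep(0, 4),
    ignore_attr = TRUE, tolerance = 1e-9
  )
  # all intensity at the centroid pixel
  img2 <- matrix(0, 41, 41)
  img2[21, 21] <- 5
  f2 <- radial_distribution(mask, img2)
  expect_equal(f2$radial_fracatd_1, 1)
  expect_equal(f2$radial_fracatd_4, 0)
  # eccentric blob vs the per-pixel oracle
  set.seed(9)
  mask3 <- matrix(0L, 30, 30)
  mask3[5:25, 8:20] <- 1L
  mask3[20:25, 8:12] <- 0L # notch makes it eccentric
  img3 <- matrix(runif(900), 30, 30)
  got <- unlist(radial_distribution(mask3, img3)[1, -1])
  want <- oracle_radial(mask3, img3, 1L)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("Haralick: degenerate conventions, checkerboard pairs, oracle equivalence", {
  # constant region: all features 0 by convention
  mask <- matrix(1L, 6, 6)
  f <- haralick_features(matrix(2, 6, 6), mask)
  expect_equal(unlist(f[1, -1]), setNames(rep(0, 13), names(f)[-1]),
    ignore_attr = TRUE
  )
  # 2x2 checkerboard, 2 levels: the horizontal GLCM is purely off-diagonal
  q <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  counts <- pathomics:::glcm_counts(q, 0L, 1L, 2L)
  p <- (counts + t(counts)) / sum(counts + t(counts))
  expect_equal(p[1, 1] + p[2, 2], 0)
  expect_equal(p[1, 2] + p[2, 1], 1)
  stats <- pathomics:::haralick_from_glcm(p)
  expect_equal(unname(stats["texture_contrast"]), 1)
  # random 16x16 region vs the literature-formula oracle
  set.seed(12)
  for (rep in 1:3) {
    img <- matrix(runif(256), 16, 16)
    m <- matrix(FALSE, 16, 16)
    m[sample(256, 180)] <- TRUE
    mask <- matrix(0L, 16, 16)
    mask[m] <- 1L
    got <- unlist(haralick_features(img, mask)[1, -1])
    want <- oracle_haralick(img, m)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("Zernike magnitudes: disk orthogonality, rotation invariance, quadrature", {
  disk <- draw_disk(220, 110, 110, 100)
  z <- unlist(zernike_shape(disk)[1, -1])
  expect_equal(unname(z["zernike_0_0"]), 1 / pi, tolerance = 1e-3)
  expect_lt(max(z[names(z) != "zernike_0_0"]), 3e-3)
  expect_length(z, 30L) # degree-9 expansion
  # 90-degree rotation leaves magnitudes unchanged
  el <- matrix(0L, 80, 80)
  for (r in 1:80) {
    for (c in 1:80) {
      if (((r - 40) / 25)^2 + ((c - 40) / 12)^2 <= 1) el[r, c] <- 1L
    }
  }
  el90 <- t(el)[, 80:1, drop = FALSE]
  storage.mode(el90) <- "integer"
  expect_equal(
    unlist(zernike_shape(el)[1, -1]),
    unlist(zernike_shape(el90)[1, -1]),
    tolerance = 1e-12
  )
  # supersampled quadrature of the same inner product (finer rasterization)
  el2 <- matrix(0L, 92, 92)
  for (r in 1:92) {
    for (c in 1:92) {
      if (((r - 46) / 36)^2 + ((c - 46) / 24)^2 <= 1) el2[r, c] <- 1L
    }
  }
  sub <- 4L
  big <- matrix(0L, 92 * sub, 92 * sub)
  for (r in seq_len(92 * sub)) {
    for (c in seq_len(92 * sub)) {
      rr <- (r - 0.5) / sub + 0.5
      cc <- (c - 0.5) / sub + 0.5
      if (((rr - 46) / 36)^2 + ((cc - 46) / 24)^2 <= 1) big[r, c] <- 1L
    }
  }
  expect_lt(
    max(abs(
      unlist(zernike_shape(el2)[1, -1]) - unlist(zernike_shape(big)[1, -1])
    )),
    0.01
  )
})

test_that("geometry features match their definitions", {
  sq <- matrix(0L, 14, 14)
  sq[3:12, 3:12] <- 1L
  f <- shape_features(sq)
  expect_equal(f$shape_area, 100)
  expect_equal(f$shape_extent, 1.0)
  expect_equal(f$shape_solidity, 1.0, tolerance = 0.02)
  expect_equal(f$shape_eccentricity, 0, tolerance = 1e-9)
  # rasterized circle: near-unit form factor, solidity ~ 1
  circle <- draw_disk(110, 55, 55, 50)
  fc <- shape_features(circle)
  expect_gt(fc$shape_form_factor, 0.95)
  expect_equal(fc$shape_perimeter, 2 * pi * 50, tolerance = 0.02)
  expect_equal(fc$shape_solidity, 1.0, tolerance = 0.02)
  expect_equal(fc$shape_feret_max, 101, tolerance = 0.02)
  expect_equal(fc$shape_major_axis, 100, tolerance = 0.03)
  expect_equal(fc$shape_minor_axis, 100, tolerance = 0.03)
})

test_that("neighbor features: isolated, constructed pair, and oracle equivalence", {
  lone <- draw_disk(20, 10, 10, 4)
  f <- neighbor_features(lone)
  expect_equal(f$neighbors_count, 0L)
  expect_equal(f$neighbors_pct_touching, 0)
  # two squares 3 px apart with distance 5: mutual neighbors
  m <- matrix(0L, 20, 20)
  m[8:12, 3:7] <- 1L
  m[8:12, 11:15] <- 2L
  f2 <- neighbor_features(m, expand_distance = 5)
  expect_equal(f2$neighbors_count, c(1L, 1L))
  # random constellation vs the O(n^2) oracle
  set.seed(14)
  m3 <- matrix(0L, 40, 40)
  m3 <- draw_disk(40, 8, 9, 4, 1L, into = m3)
  m3 <- draw_disk(40, 14, 20, 3, 2L, into = m3)
  m3 <- draw_disk(40, 30, 30, 5, 3L, into = m3)
  m3 <- draw_disk(40, 33, 10, 3, 4L, into = m3)
  got <- neighbor_features(m3, expand_distance = 5)
  want <- oracle_neighbors(m3, expand_distance = 5)
  for (i in seq_len(nrow(got))) {
    w <- want[[as.character(got$label[i])]]
    expect_equal(got$neighbors_count[i], unname(w["count"]))
    expect_equal(got$neighbors_pct_touching[i], unname(w["pct"]), tolerance = 1e-12)
  }
})

test_that("granularity spectrum: blank image, disk scale, oracle equivalence", {
  expect_equal(
    unname(granularity_spectrum(matrix(0, 20, 20), 4)),
    rep(0, 4)
  )
  img <- matrix(0, 40, 40)
  img <- draw_disk(40, 10, 10, 3, 1, into = img) * 1.0
  img <- draw_disk(40, 28, 30, 3, 1, into = img) + img
  img[img > 1] <- 1
  g <- granularity_spectrum(img, 6)
  expect_true(which.max(g) %in% 3:4) # mass concentrated near radius 3
  expect_true(all(g >= 0))
  expect_lte(sum(g), 100 + 1e-9)
  # exact match with the brute-force opening oracle
  set.seed(16)
  img2 <- matrix(runif(24 * 24), 24, 24)
  expect_equal(
    unname(granularity_spectrum(img2, 3)),
    oracle_granularity(img2, 3),
    tolerance = 1e-9
  )
})

test_that("colocalization: identity, independence, and a hand example", {
  h <- matrix(runif(100, 0.1, 1), 10, 10)
  f <- colocalization(h, h)
  expect_equal(unname(f["coloc_pearson"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(f["coloc_overlap"]), 1.0, tolerance = 1e-12)
  set.seed(18)
  a <- matrix(runif(300 * 300, 0.01, 1), 300, 300)
  b <- matrix(runif(300 * 300, 0.01, 1), 300, 300)
  expect_lt(abs(colocalization(a, b)["coloc_pearson"]), 0.05)
  # five-pixel hand computation
  hv <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  ev <- c(0.5, 0.4, 0.3, 0.2, 0.1)
  pair <- colocalization(matrix(hv, 1), matrix(ev, 1))
  n <- 5
  r_hand <- (sum(hv * ev) - n * mean(hv) * mean(ev)) /
    ((n - 1) * sd(hv) * sd(ev))
  expect_equal(unname(pair["coloc_pearson"]), r_hand, tolerance = 1e-12)
  expect_equal(
    unname(pair["coloc_overlap"]),
    sum(hv * ev) / sqrt(sum(hv^2) * sum(ev^2)),
    tolerance = 1e-12
  )
  # zero-variance convention
  expect_equal(
    unname(colocalization(matrix(1, 2, 2), matrix(runif(4), 2, 2))["coloc_pearson"]),
    0
  )
})

test_that("image quality: blur lowers focus, saturation percentages are exact", {
  spec <- small_spec(nuclei_per_tile = 10L)
  out <- render_tile(spec, "responder", seed = 19)
  q1 <- image_quality(out$tile)
  blurred <- out$tile
  blurred$pixels <- as.array(EBImage::gblur(out$tile$pixels, sigma = 5))
  q2 <- image_quality(blurred)
  expect_lt(q2["quality_focus_score"], q1["quality_focus_score"])
  white <- array(255, c(16, 16, 3))
  expect_equal(unname(image_quality(white)["quality_pct_saturated"]), 100)
  # checkerboard outscores a constant tile
  ch_mat <- outer(1:16, 1:16, function(r, c) ((r + c) %% 2) * 255)
  ch <- array(rep(ch_mat, 3), c(16, 16, 3))
  q_const <- image_quality(array(128, c(16, 16, 3)))
  q_check <- image_quality(ch)
  expect_gt(q_check["quality_focus_score"], q_const["quality_focus_score"])
})

test_that("per-object features are translation invariant and tables finite", {
  spec <- small_spec(tile_size = 96L, nuclei_per_tile = 6L)
  out <- render_tile(spec, "responder", seed = 20)
  pair <- deconvolve(rgb_to_od(out$tile))
  masks <- segment_tile(pair)
  ft <- extract_tile_features(out$tile, pair, masks)
  for (tab in ft) {
    expect_true(all(vapply(tab, function(col) {
      !is.numeric(col) || all(is.finite(col))
    }, logical(1))))
  }
  # translate mask and image by (3, 5): identical per-object features
  shift <- function(m, dr, dc) {
    out <- m * 0
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  mask <- draw_disk(40, 15, 14, 6)
  mask[14:16, 10:12] <- 1L # asymmetric appendage
  set.seed(22)
  img <- matrix(runif(1600), 40, 40)
  f1 <- list(
    intensity_features(mask, img),
    shape_features(mask),
    zernike_shape(mask),
    haralick_features(img, mask),
    radial_distribution(mask, img)
  )
  mask_t <- shift(mask, 3L, 5L)
  storage.mode(mask_t) <- "integer"
  img_t <- shift(img, 3L, 5L)
  f2 <- list(
    intensity_features(mask_t, img_t),
    shape_features(mask_t),
    zernike_shape(mask_t),
    haralick_features(img_t, mask_t),
    radial_distribution(mask_t, img_t)
  )
  for (i in seq_along(f1)) {
    expect_equal(f1[[i]], f2[[i]], tolerance = 1e-9)
  }
})

test_that("rotation by 90 degrees preserves the invariant feature families", {
  mask <- draw_disk(40, 18, 20, 7)
  mask[10:13, 18:22] <- 1L
  set.seed(23)
  img <- matrix(runif(1600), 40, 40)
  rot90 <- function(m) {
    out <- t(m)[, nrow(m):1, drop = FALSE]
    out
  }
  mask_r <- rot90(mask)
  storage.mode(mask_r) <- "integer"
  img_r <- rot90(img)
  s1 <- shape_features(mask)
  s2 <- shape_features(mask_r)
  expect_equal(s1$shape_area, s2$shape_area)
  expect_equal(s1$shape_solidity, s2$shape_solidity, tolerance = 1e-9)
  expect_equal(
    unlist(zernike_shape(mask)[1, -1]),
    unlist(zernike_shape(mask_r)[1, -1]),
    tolerance = 1e-9
  )
  expect_equal(
    unlist(haralick_features(img, mask)[1, -1]),
    unlist(haralick_features(img_r, mask_r)[1, -1]),
    tolerance = 1e-9
  )
})

test_that("the feature manifest names every emitted column with its family", {
  spec <- small_spec(tile_size = 96L, nuclei_per_tile = 5L)
  out <- render_tile(spec, "responder", seed = 25)
  pair <- deconvolve(rgb_to_od(out$tile))
  masks <- segment_tile(pair)
  ft <- extract_tile_features(out$tile, pair, masks)
  man <- feature_manifest(ft)
  expect_setequal(unique(man$compartment), c("image", "nuclei", "cytoplasm"))
  nuc_cols <- setdiff(names(ft$nuclei), c("case_id", "grid_row", "grid_col", "label"))
  expect_setequal(man$column[man$compartment == "nuclei"], nuc_cols)
})
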