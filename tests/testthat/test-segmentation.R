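test_that("thresholds degrade gracefully on constant input", {
  expect_identical(li_threshold(matrix(0.5, 10, 10)), Inf)
  expect_identical(otsu_threshold(matrix(3, 5, 5)), Inf)
})

test_that("Li threshold separates a clearly bimodal sample", {
  set.seed(2)
  x <- c(rnorm(4000, 0.2, 0.03), rnorm(1000, 1.0, 0.05))
  thr <- li_threshold(x)
  expect_gt(thr, 0.3)
  expect_lt(thr, 0.95)
  expect_gt(mean(x > thr), 0.15)
  expect_lt(mean(x > thr), 0.25)
})

test_that("fold detection flags the doubled-OD patch and nothing else", {
  # clean tile: moderate staining, no folds
  spec <- small_spec(tile_size = 128L, nuclei_per_tile = 10L)
  out <- render_tile(spec, "responder", seed = 8)
  pair <- deconvolve(rgb_to_od(out$tile))
  folds <- detect_folds(pair)
  expect_lt(mean(folds), 0.01)
  # uniform tile: degenerate histogram, empty mask
  upair <- structure(
    list(h = matrix(0.4, 64, 64), e = matrix(0.3, 64, 64)),
    class = "stain_pair"
  )
  expect_true(!any(detect_folds(upair)))
  # tile with a ground-truth fold: Jaccard > 0.7
  spec <- small_spec(tile_size = 128L, nuclei_per_tile = 10L, fold_probability = 1)
  out <- render_tile(spec, "responder", seed = 8)
  pair <- deconvolve(rgb_to_od(out$tile))
  folds <- detect_folds(pair)
  truth <- out$truth$fold_mask
  jac <- sum(folds & truth) / sum(folds | truth)
  expect_gt(jac, 0.7)
})

test_that("nuclei segmentation recovers well-separated nuclei and empty tiles", {
  spec <- small_spec(
    tile_size = 256L, nuclei_per_tile = 50L,
    nucleus_radius_mean = 5, texture_noise_sd = 0.01,
    background_fraction = 0.2
  )
  out <- render_tile(spec, "responder", seed = 17)
  pair <- deconvolve(rgb_to_od(out$tile))
  nuclei <- segment_nuclei(pair$h)
  expect_gte(max(nuclei), 48L)
  expect_lte(max(nuclei), 52L)
  # blank tile
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
})

test_that("watershed declumping splits two blur-merged nuclei", {
  # two disks whose halos merge into one component
  h <- matrix(0, 60, 60)
  h <- draw_disk(60, 30, 22, 8, 1, into = h)
  h <- draw_disk(60, 30, 46, 8, 1, into = h) # centers 24 px = 1.5 * diameter
  h <- as.matrix(EBImage::gblur(h, sigma = 2)) + 0.02
  nuclei <- segment_nuclei(h, min_diameter = 5)
  expect_equal(max(nuclei), 2L)
})

test_that("propagation matches brute-force shortest paths on a toy grid", {
  set.seed(31)
  guide <- matrix(runif(50 * 20, 0, 1), 20, 50)
  seeds <- matrix(0L, 20, 50)
  seeds[5, 8] <- 1L
  seeds[15, 40] <- 2L
  seeds[4, 44] <- 3L
  fg <- matrix(TRUE, 20, 50)
  fg[10, 20:25] <- FALSE # a small barrier
  got <- propagate_cells(seeds, guide, lambda_reg = 0.05, foreground = fg)
  want <- oracle_propagate(seeds, guide, fg | seeds > 0, 0.05)
  expect_identical(got, want)
})

test_that("propagation limits: Voronoi at large lambda, flood for one seed", {
  g <- matrix(1, 20, 50)
  seeds <- matrix(0L, 20, 50)
  seeds[10, 5] <- 1L
  seeds[10, 46] <- 2L
  lab <- propagate_cells(seeds, g, lambda_reg = 100, foreground = matrix(TRUE, 20, 50))
  # boundary at the mid-line +/- 1 px
  boundary_cols <- vapply(1:20, function(r) max(which(lab[r, ] == 1)), numeric(1))
  expect_true(all(abs(boundary_cols - 25) <= 1))
  # single seed floods its connected foreground component
  seeds2 <- matrix(0L, 20, 50)
  seeds2[10, 25] <- 1L
  fg <- matrix(FALSE, 20, 50)
  fg[5:15, 10:40] <- TRUE
  lab2 <- propagate_cells(seeds2, g, lambda_reg = 0.05, foreground = fg)
  expect_true(all(lab2[fg | seeds2 > 0] == 1L))
  expect_true(all(lab2[!(fg | seeds2 > 0)] == 0L))
})

test_that("negative lambda is rejected", {
  seeds <- matrix(0L, 4, 4)
  seeds[2, 2] <- 1L
  expect_error(
    propagate_cells(seeds, matrix(1, 4, 4), lambda_reg = -1),
    class = "pathomics_config_error"
  )
})

test_that("cytoplasm is the exact per-label set difference", {
  cells <- matrix(0L, 30, 30)
  cells <- draw_disk(30, 15, 15, 10, 1L, into = cells)
  nuclei <- matrix(0L, 30, 30)
  nuclei <- draw_disk(30, 15, 15, 5, 1L, into = nuclei)
  cyto <- derive_cytoplasm(cells, nuclei)
  expect_equal(sum(cyto == 1L), sum(cells == 1L) - sum(nuclei == 1L))
  expect_true(!any(cyto > 0L & nuclei > 0L))
  # cell identical to nucleus: empty cytoplasm, no error
  cyto2 <- derive_cytoplasm(nuclei, nuclei)
  expect_equal(max(cyto2), 0L)
  # mismatched label sets: integrity error
  bad <- nuclei
  bad[1, 1] <- 7L
  expect_error(derive_cytoplasm(cells, bad), class = "pathomics_integrity_error")
})

test_that("full-tile segmentation satisfies the pixel-partition invariants", {
  spec <- small_spec(tile_size = 128L, nuclei_per_tile = 10L, fold_probability = 1)
  out <- render_tile(spec, "responder", seed = 23)
  pair <- deconvolve(rgb_to_od(out$tile))
  masks <- segment_tile(pair)
  labs <- sort(unique(masks$nuclei[masks$nuclei > 0]))
  expect_gt(length(labs), 0L)
  for (k in labs) {
    nuc <- masks$nuclei == k
    expect_true(all(masks$cells[nuc] == k)) # nuclei(k) within cells(k)
    expect_equal(
      sum(masks$cells == k),
      sum(masks$nuclei == k) + sum(masks$cytoplasm == k)
    )
  }
  # fold exclusion: no segmented pixel intersects the fold mask
  expect_true(!any(masks$nuclei > 0 & masks$fold_mask))
  expect_true(!any(masks$cells > 0 & masks$fold_mask))
  # determinism: identical inputs give identical geometry
  expect_identical(masks, segment_tile(pair))
  # labels are canonical 1..n in raster order
  expect_identical(labs, seq_along(labs))
})
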