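# Independent oracle implementations and fixture builders. These deliberately
# use naive per-pixel / per-pair loops so they share no code path with the
# package's vectorized implementations.

draw_disk <- function(size, r0, c0, radius, value = 1L, into = NULL) {
  m <- into %||% matrix(0L, size, size)
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      if ((r - r0)^2 + (c - c0)^2 <= radius^2) m[r, c] <- value
    }
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_spec <- function(...) {
  args <- utils::modifyList(
    list(
      n_responders = 2L, n_nonresponders = 2L, tiles_per_case = 1L,
      tile_size = 96L, nuclei_per_tile = 10L,
      nucleus_radius_mean = 6, nucleus_eccentricity = 0.5,
      fold_probability = 0, seed = 11L
    ),
    list(...)
  )
  do.call(cohort_spec, args)
}

# ---- Haralick oracle: enumerate pixel pairs, textbook formulas -------------

oracle_haralick <- function(image, mask, levels = 8L) {
  vals <- image[mask]
  mn <- min(vals)
  mx <- max(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  q[mask] <- pmin(levels, pmax(1L, floor((image[mask] - mn) / (mx - mn) * levels) + 1L))
  offsets <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  per_dir <- list()
  for (off in offsets) {
    counts <- matrix(0, levels, levels)
    for (r in seq_len(nrow(q))) {
      for (c in seq_len(ncol(q))) {
        r2 <- r + off[1]
        c2 <- c + off[2]
        if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
        a <- q[r, c]
        b <- q[r2, c2]
        if (is.na(a) || is.na(b)) next
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
    if (sum(counts) == 0) next
    p <- counts / sum(counts)
    # marginals and auxiliary distributions
    px <- rowSums(p)
    py <- colSums(p)
    mu_x <- sum(seq_len(levels) * px)
    mu_y <- sum(seq_len(levels) * py)
    sd_x <- sqrt(sum((seq_len(levels) - mu_x)^2 * px))
    sd_y <- sqrt(sum((seq_len(levels) - mu_y)^2 * py))
    psum <- numeric(2 * levels)
    pdiff <- numeric(levels)
    sij <- 0
    for (i in seq_len(levels)) {
      for (j in seq_len(levels)) {
        psum[i + j] <- psum[i + j] + p[i, j]
        pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
        sij <- sij + i * j * p[i, j]
      }
    }
    ent <- function(v) {
      v <- v[v > 0]
      -sum(v * log(v))
    }
    asm <- sum(p^2)
    contrast <- 0
    idm <- 0
    varf <- 0
    for (i in seq_len(levels)) {
      for (j in seq_len(levels)) {
        contrast <- contrast + (i - j)^2 * p[i, j]
        idm <- idm + p[i, j] / (1 + (i - j)^2)
        varf <- varf + (i - mu_x)^2 * p[i, j]
      }
    }
    corr <- if (sd_x > 0 && sd_y > 0) (sij - mu_x * mu_y) / (sd_x * sd_y) else 0
    sa <- sum(seq(2, 2 * levels) * psum[seq(2, 2 * levels)])
    sv <- sum((seq(2, 2 * levels) - sa)^2 * psum[seq(2, 2 * levels)])
    da <- sum((0:(levels - 1)) * pdiff)
    dv <- sum(((0:(levels - 1)) - da)^2 * pdiff)
    hxy <- ent(p)
    hx <- ent(px)
    hy <- ent(py)
    hxy1 <- 0
    hxy2 <- 0
    for (i in seq_len(levels)) {
      for (j in seq_len(levels)) {
        if (px[i] * py[j] > 0) {
          if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log(px[i] * py[j])
          hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
        }
      }
    }
    per_dir[[length(per_dir) + 1]] <- c(
      asm, contrast, corr, varf, idm, sa, sv, ent(psum), hxy,
      dv, ent(pdiff),
      if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
      sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
    )
  }
  out <- colMeans(do.call(rbind, per_dir))
  names(out) <- c(
    "texture_asm", "texture_contrast", "texture_correlation",
    "texture_variance", "texture_idm", "texture_sumaverage",
    "texture_sumvariance", "texture_sumentropy", "texture_entropy",
    "texture_diffvariance", "texture_diffentropy",
    "texture_infomeas1", "texture_infomeas2"
  )
  out
}

# ---- radial-distribution oracle: per-pixel loop ----------------------------

oracle_radial <- function(mask, image, label, n_rings = 4L, n_wedges = 8L) {
  pos <- which(mask == label, arr.ind = TRUE)
  v <- image[mask == label]
  r0 <- mean(pos[, 1])
  c0 <- mean(pos[, 2])
  d <- sqrt((pos[, 1] - r0)^2 + (pos[, 2] - c0)^2)
  rel <- if (max(d) > 0) d / max(d) else rep(0, length(d))
  out <- list()
  for (k in seq_len(n_rings)) {
    sel <- logical(length(v))
    wsum <- rep(0, n_wedges)
    wn <- rep(0, n_wedges)
    for (i in seq_along(v)) {
      ring <- min(n_rings, floor(rel[i] * n_rings) + 1)
      if (ring == k) {
        sel[i] <- TRUE
        ang <- atan2(pos[i, 2] - c0, pos[i, 1] - r0) + pi
        w <- min(n_wedges, floor(ang / (2 * pi) * n_wedges) + 1)
        wsum[w] <- wsum[w] + v[i]
        wn[w] <- wn[w] + 1
      }
    }
    frac <- if (sum(v) != 0) sum(v[sel]) / sum(v) else 0
    pixfrac <- sum(sel) / length(v)
    wm <- (wsum / wn)[wn > 0]
    cv <- if (length(wm) >= 2 && abs(mean(wm)) > 1e-12) sd(wm) / abs(mean(wm)) else 0
    out[[paste0("radial_fracatd_", k)]] <- frac
    out[[paste0("radial_meanfrac_", k)]] <- if (pixfrac > 0) frac / pixfrac else 0
    out[[paste0("radial_cv_", k)]] <- cv
  }
  unlist(out)
}

# ---- neighbor oracle: O(n^2) pairwise boundary distances -------------------

oracle_neighbors <- function(mask, expand_distance = 5) {
  labs <- sort(unique(mask[mask > 0]))
  coords <- lapply(labs, function(k) which(mask == k, arr.ind = TRUE))
  names(coords) <- labs
  is_boundary <- function(k, r, c) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]
      c2 <- c + d[2]
      if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask)) {
        return(TRUE)
      }
      if (mask[r2, c2] != k) {
        return(TRUE)
      }
    }
    FALSE
  }
  res <- list()
  for (k in labs) {
    pk <- coords[[as.character(k)]]
    bk <- pk[apply(pk, 1, function(rc) is_boundary(k, rc[1], rc[2])), , drop = FALSE]
    other_pix <- do.call(rbind, coords[as.character(setdiff(labs, k))])
    if (is.null(other_pix) || nrow(other_pix) == 0) {
      res[[as.character(k)]] <- c(count = 0, pct = 0)
      next
    }
    nb <- 0
    for (j in setdiff(labs, k)) {
      pj <- coords[[as.character(j)]]
      mind <- Inf
      for (a in seq_len(nrow(bk))) {
        for (b in seq_len(nrow(pj))) {
          dd <- sqrt(sum((bk[a, ] - pj[b, ])^2))
          if (dd < mind) mind <- dd
        }
      }
      if (mind <= expand_distance) nb <- nb + 1
    }
    touching <- 0
    for (a in seq_len(nrow(bk))) {
      mind <- Inf
      for (b in seq_len(nrow(other_pix))) {
        dd <- sqrt(sum((bk[a, ] - other_pix[b, ])^2))
        if (dd < mind) mind <- dd
      }
      if (mind <= expand_distance) touching <- touching + 1
    }
    res[[as.character(k)]] <- c(count = nb, pct = touching / nrow(bk))
  }
  res
}

# ---- granularity oracle: brute-force grayscale opening ---------------------

oracle_granularity <- function(image, n_scales) {
  min_filter <- function(img, se) {
    off <- which(se > 0, arr.ind = TRUE)
    ctr <- (dim(se) + 1) / 2
    out <- img
    for (r in seq_len(nrow(img))) {
      for (c in seq_len(ncol(img))) {
        best <- Inf
        for (i in seq_len(nrow(off))) {
          r2 <- r + off[i, 1] - ctr[1]
          c2 <- c + off[i, 2] - ctr[2]
          v <- if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) Inf else img[r2, c2]
          if (v < best) best <- v
        }
        out[r, c] <- best
      }
    }
    out
  }
  max_filter <- function(img, se) {
    off <- which(se > 0, arr.ind = TRUE)
    ctr <- (dim(se) + 1) / 2
    out <- img
    for (r in seq_len(nrow(img))) {
      for (c in seq_len(ncol(img))) {
        best <- -Inf
        for (i in seq_len(nrow(off))) {
          r2 <- r + off[i, 1] - ctr[1]
          c2 <- c + off[i, 2] - ctr[2]
          v <- if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) -Inf else img[r2, c2]
          if (v > best) best <- v
        }
        out[r, c] <- best
      }
    }
    out
  }
  vol0 <- sum(image)
  if (vol0 <= 0) {
    return(rep(0, n_scales))
  }
  prev <- image
  out <- numeric(n_scales)
  for (i in seq_len(n_scales)) {
    se <- EBImage::makeBrush(2L * i + 1L, shape = "disc")
    opened <- max_filter(min_filter(image, se), se)
    out[i] <- 100 * (sum(prev) - sum(opened)) / vol0
    prev <- opened
  }
  out
}

# ---- shortest-path propagation oracle: O(V^2) Bellman-Ford -----------------

oracle_propagate <- function(seeds, guide, foreground, lambda) {
  nr <- nrow(seeds)
  nc <- ncol(seeds)
  cost <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  cost[seeds > 0] <- 0
  lab[seeds > 0] <- seeds[seeds > 0]
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        if (!foreground[r, c] || seeds[r, c] > 0) next
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          r2 <- r + d[1]
          c2 <- c + d[2]
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          if (!is.finite(cost[r2, c2])) next
          step <- sqrt((guide[r, c] - guide[r2, c2])^2 + lambda^2)
          nv <- cost[r2, c2] + step
          if (nv < cost[r, c] - 1e-12) {
            cost[r, c] <- nv
            lab[r, c] <- lab[r2, c2]
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  lab
}

# ---- discrete MI oracle on binned data -------------------------------------

oracle_discrete_mi <- function(x, y, breaks = 8L) {
  bx <- cut(x, breaks = breaks, labels = FALSE)
  tab <- table(bx, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  as.numeric(mi)
}
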