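# Shared fixture builders.

# labeled two-Gaussian dataset: two informative columns separated by `sep`
# standard deviations plus pure-noise columns
make_gaussian_data <- function(n = 80, sep = 6, p_noise = 8, seed = 99) {
  withr::with_seed(seed, {
    y <- rep(c(1L, 0L), each = n / 2)
    signal <- matrix(rnorm(n * 2), n, 2) + sep * y
    noise <- matrix(rnorm(n * p_noise), n, p_noise)
    X <- cbind(signal, noise)
    colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
    dplyr::bind_cols(
      tibble::tibble(case_id = sprintf("s%03d", 1:n), label = y),
      tibble::as_tibble(as.data.frame(X))
    )
  })
}

# minimal per-case feature tables in the extract_tile_features() shape
fake_tables <- function(nuclei_vals, image_vals = c(1, 2), cyto_vals = nuclei_vals) {
  ref <- function(n) {
    tibble::tibble(
      case_id = rep("c1", n), grid_row = rep(0L, n), grid_col = rep(0L, n)
    )
  }
  list(
    image = dplyr::bind_cols(ref(length(image_vals)), tibble::tibble(img_feat = image_vals)),
    nuclei = dplyr::bind_cols(
      ref(length(nuclei_vals)),
      tibble::tibble(label = seq_along(nuclei_vals), featA = nuclei_vals)
    ),
    cytoplasm = dplyr::bind_cols(
      ref(length(cyto_vals)),
      tibble::tibble(label = seq_along(cyto_vals), featB = cyto_vals)
    )
  )
}
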