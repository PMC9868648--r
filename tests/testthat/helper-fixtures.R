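# fixtures are generated once per test run and memoised here; everything is
# built in code from fixed seeds

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# a digital ball mask (optionally anisotropic) centered in its grid
make_ball_mask <- function(radius_mm, spacing = c(1, 1, 1), margin = 2L) {
  shape <- as.integer(ceiling(2 * radius_mm / spacing) + 2L * margin + 1L)
  half <- (shape - 1L) * spacing / 2
  xs <- (seq_len(shape[1]) - 1) * spacing[1] - half[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2] - half[2]
  zs <- (seq_len(shape[3]) - 1) * spacing[3] - half[3]
  d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  seg_mask(d2 <= radius_mm^2, spacing)
}

# constant-intensity volume matching a mask's geometry
make_const_volume <- function(mask, value = 0) {
  image_volume(array(value, dim(mask)), voxel_spacing(mask))
}

# a small scan pair (volume + mask) built directly at 1 mm for cheap tests
small_scan <- function() {
  fixture("small_scan", function() {
    generate_nodule(nodule_params(base_radius_mm = 6, lobulation_count = 1,
                                  cavity_count = 1),
                    spacing = c(1, 1, 1), seed = 42)
  })
}

# random small filtered grid for oracle comparisons: values from a coarse
# set (ties on purpose), some +Inf cells, at least one finite
random_small_grid <- function(max_side = 4) {
  shape <- sample(2:max_side, 3, replace = TRUE)
  vals <- sample(c(1, 2, 3, 5, 8, Inf), prod(shape), replace = TRUE,
                 prob = c(rep(0.17, 5), 0.15))
  if (!any(is.finite(vals))) vals[1] <- 1
  array(vals, shape)
}

random_small_cloud <- function(n_points = NULL) {
  n <- if (is.null(n_points)) sample(4:8, 1) else n_points
  matrix(runif(3 * n, 0, 2), ncol = 3)
}

expect_same_diagrams <- function(a, b, tol = 1e-10) {
  a <- dplyr::arrange(tibble::as_tibble(a)[c("dimension", "birth", "death")],
                      dimension, birth, death)
  b <- dplyr::arrange(tibble::as_tibble(b)[c("dimension", "birth", "death")],
                      dimension, birth, death)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$dimension, b$dimension)
  expect_equal(a$birth, b$birth, tolerance = tol)
  expect_equal(a$death, b$death, tolerance = tol)
}

# quick synthetic feature table (no images) for ML-layer tests
make_feature_table <- function(n = 40, n_rad = 5, n_top = 5, signal = 0,
                               seed = 1, n_patients = n) {
  withr::with_seed(seed, {
    cls <- rep(c("A", "B"), length.out = n)
    mk <- function(p, prefix) {
      m <- matrix(rnorm(n * p), n, p)
      if (signal > 0) m[, 1] <- m[, 1] + signal * (cls == "B")
      colnames(m) <- paste0(prefix, "f", seq_len(p))
      tibble::as_tibble(m)
    }
    dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%03d", rep_len(seq_len(n_patients), n)),
                     nodule_id = sprintf("N%03d", seq_len(n)),
                     class_label = cls,
                     malignancy_score = 2 + (cls == "B") * signal + rnorm(n, 0, 0.5)),
      mk(n_rad, "rad_"), mk(n_top, "top_"))
  })
}
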