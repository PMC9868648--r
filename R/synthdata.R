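#' Parameters of a synthetic nodule
#'
#' Morphology and intensity parameters for one CT-like nodule. The planted
#' morphology mirrors the semantic descriptors radiologists score on lung
#' nodules: lobulation (overlapping surface bumps), internal cavitation
#' (air-filled voids), and spiculation (thin radial protrusions).
#'
#' @param base_radius_mm positive lesion core radius in mm.
#' @param lobulation_count,cavity_count,spicule_count non-negative integers.
#' @param intensity_mu mean lesion intensity (HU-like; soft tissue ~ +20..+60).
#' @param intensity_sigma amplitude of the smooth radial intensity profile
#'   (center brighter than rim by this much).
#' @param noise_sigma Gaussian intensity noise sd (HU-like).
#' @param class_label `"A"` (benign-like) or `"B"` (malignant-like).
#' @param malignancy_score real in `[1, 5]` or `NA`.
#' @return A `nodule_params` list.
#' @export
nodule_params <- function(base_radius_mm = 8, lobulation_count = 0,
                          cavity_count = 0, spicule_count = 0,
                          intensity_mu = 40, intensity_sigma = 15,
                          noise_sigma = 15, class_label = "A",
                          malignancy_score = NA_real_) {
  stopifnot(base_radius_mm > 0, lobulation_count >= 0, cavity_count >= 0,
            spicule_count >= 0, noise_sigma >= 0,
            class_label %in% c("A", "B"))
  if (!is.na(malignancy_score) &&
      (malignancy_score < 1 || malignancy_score > 5))
    stop("malignancy_score must lie in [1, 5]")
  structure(list(base_radius_mm = base_radius_mm,
                 lobulation_count = as.integer(lobulation_count),
                 cavity_count = as.integer(cavity_count),
                 spicule_count = as.integer(spicule_count),
                 intensity_mu = intensity_mu,
                 intensity_sigma = intensity_sigma,
                 noise_sigma = noise_sigma,
                 class_label = class_label,
                 malignancy_score = malignancy_score),
            class = "nodule_params")
}

#' Generate one synthetic CT-like nodule
#'
#' Digitizes a lesion on an (by default anisotropic) voxel grid: a solid
#' ball, optionally unioned with lobulation bumps and spicules, minus
#' enclosed spherical cavities. Intensities follow a smooth radial profile
#' plus Gaussian noise inside the lesion and a dark lung-like background
#' (~ -800 HU) outside; cavity interiors are background air. The output is a
#' pure function of `(params, grid_shape, spacing, seed)`.
#'
#' Cavities are placed with a shell of at least 2.5 mm of lesion tissue
#' around them so the planted dimension-2 topology survives 1 mm resampling.
#'
#' @param params a [nodule_params()] object.
#' @param grid_shape integer length-3, or `NULL` to auto-size the grid to fit
#'   the nodule plus margin.
#' @param spacing voxel spacing in mm (default anisotropic `(0.7, 0.7, 2.5)`).
#' @param seed integer RNG seed.
#' @return list with elements `volume` ([image_volume()]) and `mask`
#'   ([seg_mask()]).
#' @export
generate_nodule <- function(params, grid_shape = NULL,
                            spacing = c(0.7, 0.7, 2.5), seed = 1) {
  stopifnot(inherits(params, "nodule_params"))
  spacing <- as.numeric(spacing)
  r <- params$base_radius_mm
  reach <- r
  if (params$lobulation_count > 0) reach <- max(reach, 1.25 * r)
  if (params$spicule_count > 0) reach <- max(reach, 1.6 * r)
  margin_mm <- pmax(3, 2 * spacing)
  need <- 2 * (reach + margin_mm)
  if (is.null(grid_shape)) {
    grid_shape <- as.integer(ceiling(need / spacing) + 1L)
  } else {
    grid_shape <- as.integer(grid_shape)
    if (any((grid_shape - 1L) * spacing < need))
      stop(sprintf(
        "nodule (reach %.1f mm + margin) does not fit grid of %s voxels at spacing (%s)",
        reach, paste(grid_shape, collapse = "x"),
        paste(spacing, collapse = ", ")))
  }
  with_seed(seed, {
    half <- (grid_shape - 1L) * spacing / 2
    xs <- (seq_len(grid_shape[1]) - 1) * spacing[1] - half[1]
    ys <- (seq_len(grid_shape[2]) - 1) * spacing[2] - half[2]
    zs <- (seq_len(grid_shape[3]) - 1) * spacing[3] - half[3]
    X <- array(xs, grid_shape)
    Y <- array(rep(ys, each = grid_shape[1]), grid_shape)
    Z <- array(rep(zs, each = grid_shape[1] * grid_shape[2]), grid_shape)
    d2 <- X^2 + Y^2 + Z^2
    mask <- d2 <= r^2
    for (i in seq_len(params$lobulation_count)) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ctr <- 0.8 * r * dir
      rb <- 0.45 * r
      mask <- mask | ((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= rb^2)
    }
    sp_rad <- max(1.5, 0.8 * max(spacing))
    for (i in seq_len(params$spicule_count)) {
      # near-axial directions keep thin spicules connected on coarse z grids
      th <- runif(1, 0, 2 * pi); zc <- runif(1, -0.4, 0.4)
      dir <- c(sqrt(1 - zc^2) * cos(th), sqrt(1 - zc^2) * sin(th), zc)
      proj <- X * dir[1] + Y * dir[2] + Z * dir[3]
      perp2 <- d2 - proj^2
      mask <- mask | (proj >= 0.5 * r & proj <= 1.6 * r & perp2 <= sp_rad^2)
    }
    if (params$cavity_count > 0) {
      rc <- max(1.6, 0.15 * r)
      budget <- r - 3 - rc
      if (budget < 0)
        stop("cavities do not fit: nodule radius too small for a 3 mm shell")
      # the tissue wall between two voids must contain voxel centers along
      # any axis, or digitization merges them: separation accounts for the
      # coarsest spacing
      sep <- 2 * rc + max(spacing) + 1
      if (params$cavity_count > 1 && 2 * budget < sep)
        stop("cavities do not fit: nodule radius too small to separate ",
             params$cavity_count, " voids on this grid")
      place_set <- function() {
        centers <- matrix(NA_real_, 0, 3)
        for (j in seq_len(params$cavity_count)) {
          placed <- FALSE
          for (t in 1:60) {
            dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
            ctr <- budget * runif(1)^(1 / 3) * dir  # uniform in the ball
            if (nrow(centers) == 0 ||
                all(sqrt(rowSums(sweep(centers, 2, ctr)^2)) >= sep)) {
              centers <- rbind(centers, ctr)
              placed <- TRUE
              break
            }
          }
          if (!placed) return(NULL)
        }
        centers
      }
      centers <- NULL
      for (a in 1:50) {
        centers <- place_set()
        if (!is.null(centers)) break
      }
      if (is.null(centers)) stop("could not place non-overlapping cavities")
      for (i in seq_len(nrow(centers))) {
        ctr <- centers[i, ]
        mask <- mask &
          !((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= rc^2)
      }
    }
    # keep the largest connected component (stray spicule crumbs are dropped)
    lab <- label_components(mask)
    if (max(lab) > 0) {
      tab <- tabulate(lab[lab > 0])
      mask <- lab == which.max(tab)
    }
    voids <- count_enclosed_voids(mask)
    if (voids != params$cavity_count)
      stop(sprintf("planted topology check failed: %d enclosed voids, expected %d",
                   voids, params$cavity_count))
    n <- prod(grid_shape)
    vol <- -800 + rnorm(n, sd = params$noise_sigma)
    prof <- params$intensity_mu +
      params$intensity_sigma * (1 - pmin(sqrt(d2) / r, 1)^2)
    inside <- which(mask)
    vol[inside] <- prof[inside] + rnorm(length(inside), sd = params$noise_sigma)
    list(volume = image_volume(array(vol, grid_shape), spacing),
         mask = seg_mask(mask, spacing))
  })
}

# ---------------------------------------------------------------------------
# naive component / void labeling: the audit oracle for planted topology

shift_array <- function(a, axis, s) {
  d <- dim(a)
  out <- array(0L, d)
  idx_to <- lapply(d, seq_len)
  idx_from <- idx_to
  if (s == 1L) {
    idx_to[[axis]] <- 2:d[axis]; idx_from[[axis]] <- 1:(d[axis] - 1L)
  } else {
    idx_to[[axis]] <- 1:(d[axis] - 1L); idx_from[[axis]] <- 2:d[axis]
  }
  out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
    a[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
  out
}

# 6-connected component labeling (breadth-first flood fill)
label_components <- function(v) {
  v <- unclass(v) != 0
  label_components_cpp(as.logical(v), dim(v))
}

count_enclosed_voids <- function(mask) {
  v <- unclass(mask) != 0
  d <- dim(v)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  bg <- label_components(!padded)
  border_labels <- unique(c(bg[c(1, d[1] + 2), , ], bg[, c(1, d[2] + 2), ],
                            bg[, , c(1, d[3] + 2)]))
  length(setdiff(unique(bg[bg > 0L]), border_labels))
}

# Euler characteristic of the V-construction cubical complex of a binary mask
euler_characteristic <- function(v) {
  v <- unclass(v) != 0
  d <- dim(v)
  ex <- v[-d[1], , , drop = FALSE] & v[-1, , , drop = FALSE]
  ey <- v[, -d[2], , drop = FALSE] & v[, -1, , drop = FALSE]
  ez <- v[, , -d[3], drop = FALSE] & v[, , -1, drop = FALSE]
  fxy <- ex[, -d[2], , drop = FALSE] & ex[, -1, , drop = FALSE]
  fxz <- ex[, , -d[3], drop = FALSE] & ex[, , -1, drop = FALSE]
  fyz <- ey[, , -d[3], drop = FALSE] & ey[, , -1, drop = FALSE]
  cub <- fxy[, , -d[3], drop = FALSE] & fxy[, , -1, drop = FALSE]
  sum(v) - (sum(ex) + sum(ey) + sum(ez)) +
    (sum(fxy) + sum(fxz) + sum(fyz)) - sum(cub)
}

#' Betti numbers of a binary mask
#'
#' Audits the planted topology of a segmentation by naive labeling, entirely
#' independently of the persistence machinery: `b0` by 6-connected foreground
#' component labeling, `b2` by labeling enclosed background pockets, and
#' `b1 = b0 + b2 - chi` with `chi` the Euler characteristic of the mask's
#' cubical complex (voxels as vertices).
#'
#' @param mask a [seg_mask()] or 3D binary array.
#' @return named integer vector `c(b0, b1, b2)`.
#' @export
betti_numbers <- function(mask) {
  v <- unclass(mask) != 0
  b0 <- max(label_components(v))
  b2 <- count_enclosed_voids(v)
  chi <- euler_characteristic(v)
  c(b0 = as.integer(b0), b1 = as.integer(b0 + b2 - chi), b2 = as.integer(b2))
}

# ---------------------------------------------------------------------------

#' Class-conditional morphology distributions for cohort generation
#'
#' Defines how nodule parameters are drawn per histology class. Counts are
#' drawn as `base + Poisson(lambda)` (cavities: `base + Bernoulli(p_extra)`);
#' radius and mean intensity as truncated Gaussians. The default planted
#' configuration separates the classes: class B nodules are larger, more
#' lobulated and spiculated, brighter, and always carry 1-2 internal
#' cavities, while class A nodules have none.
#'
#' @param A,B per-class parameter lists; see the default for the format.
#' @param noise_sigma intensity noise sd shared by both classes (HU-like).
#' @param score_noise_sd sd of the Gaussian noise added to the malignancy
#'   score on its 1-5 scale.
#' @return An `effect_config` list.
#' @export
effect_config <- function(
    A = list(radius = c(mean = 7, sd = 1.2), lobulation = c(base = 0, lambda = 0.6),
             cavities = c(base = 0, p_extra = 0), spicules = c(base = 0, lambda = 0.5),
             mu = c(mean = 30, sd = 6)),
    B = list(radius = c(mean = 8.5, sd = 1.2), lobulation = c(base = 1, lambda = 1.2),
             cavities = c(base = 1, p_extra = 0.6), spicules = c(base = 1, lambda = 1),
             mu = c(mean = 45, sd = 6)),
    noise_sigma = 15, score_noise_sd = 0.4) {
  structure(list(A = A, B = B, noise_sigma = noise_sigma,
                 score_noise_sd = score_noise_sd),
            class = "effect_config")
}

#' Null (zero class separation) cohort configuration
#'
#' Both classes draw morphology from the class-A distribution, so class
#' labels carry no signal; downstream cross-validated AUC should sit at
#' chance level.
#' @inheritParams effect_config
#' @export
null_effect_config <- function(noise_sigma = 15, score_noise_sd = 0.4) {
  cfg <- effect_config(noise_sigma = noise_sigma,
                       score_noise_sd = score_noise_sd)
  cfg$B <- cfg$A
  cfg
}

draw_params <- function(class_cfg, class_label, noise_sigma, score_noise_sd) {
  radius <- max(4, rnorm(1, class_cfg$radius["mean"], class_cfg$radius["sd"]))
  lob <- class_cfg$lobulation["base"] + rpois(1, class_cfg$lobulation["lambda"])
  cav <- class_cfg$cavities["base"] + rbinom(1, 1, class_cfg$cavities["p_extra"])
  # enforce the geometric feasibility of the requested cavities: each void
  # needs a >= 3 mm tissue shell and a voxel-resolvable wall to its neighbor
  if (cav >= 2) radius <- max(radius, 8.2)
  else if (cav == 1) radius <- max(radius, 5.5)
  spic <- class_cfg$spicules["base"] + rpois(1, class_cfg$spicules["lambda"])
  mu <- rnorm(1, class_cfg$mu["mean"], class_cfg$mu["sd"])
  lin <- -2 + 0.3 * (radius - 7) + 0.45 * lob + 1.1 * cav + 0.35 * spic
  score <- 1 + 4 * plogis(lin) + rnorm(1, 0, score_noise_sd)
  score <- min(5, max(1, score))
  nodule_params(base_radius_mm = radius, lobulation_count = lob,
                cavity_count = cav, spicule_count = spic,
                intensity_mu = mu, noise_sigma = noise_sigma,
                class_label = class_label, malignancy_score = score)
}

#' Generate a synthetic nodule cohort
#'
#' Draws a patient-level class assignment, an occasional second nodule per
#' patient (Bernoulli with probability `multi_nodule_rate`, so the expected
#' nodule count is `n_patients * (1 + multi_nodule_rate)`), class-conditional
#' morphology from `config`, and a malignancy score that is a scaled logistic
#' function of the morphology plus Gaussian noise, clipped to `[1, 5]`.
#'
#' @param n_patients number of patients (>= 4).
#' @param class_proportions named proportions for classes A and B (sum to 1).
#' @param multi_nodule_rate probability in `[0, 1]` that a patient carries a
#'   second nodule.
#' @param config an [effect_config()] (planted signal by default).
#' @param seed integer seed; the cohort is a pure function of the arguments.
#' @return A `nodule_cohort` tibble with columns `patient_id`, `nodule_id`,
#'   `class_label`, `malignancy_score` and list-columns `params`, `volume`,
#'   `mask`.
#' @export
generate_cohort <- function(n_patients, class_proportions = c(A = 0.5, B = 0.5),
                            multi_nodule_rate = 0.1,
                            config = effect_config(), seed = 1) {
  stopifnot(n_patients >= 4, multi_nodule_rate >= 0, multi_nodule_rate <= 1)
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  if (is.null(names(class_proportions))) names(class_proportions) <- c("A", "B")
  with_seed(seed, {
    n_a <- round(n_patients * class_proportions[["A"]])
    n_b <- n_patients - n_a
    if (n_a == 0 || n_b == 0)
      warning("degenerate class proportions: a class has zero patients; ",
              "stratified cross-validation downstream will fail")
    classes <- sample(rep(c("A", "B"), c(n_a, n_b)))
    rows <- purrr::map(seq_len(n_patients), function(p) {
      n_nod <- 1L + rbinom(1, 1, multi_nodule_rate)
      purrr::map(seq_len(n_nod), function(j) {
        cl <- classes[p]
        pars <- draw_params(config[[cl]], cl, config$noise_sigma,
                            config$score_noise_sd)
        list(patient_id = sprintf("P%03d", p),
             nodule_id = sprintf("P%03d_N%d", p, j),
             class_label = cl, params = pars)
      })
    }) |> purrr::flatten()
    nod_seeds <- sample.int(.Machine$integer.max - 1L, length(rows))
    recs <- purrr::imap(rows, function(rec, i) {
      scan <- generate_nodule(rec$params, seed = nod_seeds[i])
      tibble::tibble(patient_id = rec$patient_id, nodule_id = rec$nodule_id,
                     class_label = rec$params$class_label,
                     malignancy_score = rec$params$malignancy_score,
                     params = list(rec$params),
                     volume = list(scan$volume), mask = list(scan$mask))
    })
    out <- dplyr::bind_rows(recs)
    stopifnot(!anyDuplicated(out$nodule_id))
    structure(out, seed = seed, config = config,
              class = c("nodule_cohort", class(out)))
  })
}

# ---------------------------------------------------------------------------

#' Stand-in radiomic feature set
#'
#' A small, fixed set of first-order intensity statistics and basic 3D shape
#' descriptors of the segmented lesion, named with prefixes `intensity_` and
#' `shape_`. It is a declared simple stand-in playing the structural role of
#' an externally extracted radiomic feature table (e.g. an IBSI-compliant
#' extractor's CSV, which can be substituted wherever this block is used).
#'
#' @param volume an [image_volume()].
#' @param mask an aligned [seg_mask()].
#' @return named numeric vector of 21 features.
#' @export
standin_radiomic_features <- function(volume, mask) {
  check_aligned(volume, mask)
  v <- unclass(volume)
  m <- unclass(mask) != 0
  if (!any(m)) stop("empty mask")
  x <- v[m]
  sp <- voxel_spacing(volume)
  n <- length(x)
  qs <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  sdv <- if (n > 1) sd(x) else 0
  skew <- if (sdv > 0) e1071::skewness(x) else 0
  kurt <- if (sdv > 0) e1071::kurtosis(x) else 0
  # exposed voxel faces -> surface area
  area <- 0
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- shift_array(array(as.integer(m), dim(m)), axis, s)
      area <- area + sum(m & nb == 0L) * face_area[axis]
    }
  }
  vol_mm3 <- n * prod(sp)
  spher <- pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area
  idx <- which(m, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, sp, `*`)
  if (n > 1) {
    ev <- eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  bbox <- apply(idx, 2, range)
  bbox_vox <- bbox[2, ] - bbox[1, ] + 1
  bbox_diag <- sqrt(sum(((bbox_vox - 1) * sp)^2))
  c(intensity_mean = mean(x), intensity_sd = sdv, intensity_min = min(x),
    intensity_max = max(x), intensity_median = qs[3], intensity_p10 = qs[1],
    intensity_p90 = qs[5], intensity_iqr = qs[4] - qs[2],
    intensity_skewness = skew, intensity_kurtosis = kurt,
    intensity_range = max(x) - min(x),
    shape_volume_mm3 = vol_mm3, shape_surface_area_mm2 = area,
    shape_sphericity = spher, shape_extent = n / prod(bbox_vox),
    shape_major_axis_mm = axes[1], shape_minor_axis_mm = axes[2],
    shape_least_axis_mm = axes[3],
    shape_elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    shape_flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1,
    shape_bbox_diag_mm = bbox_diag)
}
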