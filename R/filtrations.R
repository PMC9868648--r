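#' Resample a volume and mask to isotropic spacing
#'
#' Standard radiomics preprocessing: the intensity volume is interpolated
#' trilinearly and the mask by nearest neighbor onto an isotropic grid
#' (default 1 x 1 x 1 mm) covering the same physical extent.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned [seg_mask()].
#' @param target_mm target isotropic spacing in mm (default 1).
#' @return list with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask, target_mm = 1) {
  check_aligned(volume, mask)
  stopifnot(target_mm > 0)
  sp <- voxel_spacing(volume)
  d <- dim(volume)
  out_shape <- pmax(2L, as.integer(floor((d - 1L) * sp / target_mm)) + 1L)
  # continuous source index (1-based) of each output voxel center, per axis
  src <- lapply(1:3, function(a) {
    pmin((seq_len(out_shape[a]) - 1) * target_mm / sp[a] + 1, d[a])
  })
  lo <- lapply(1:3, function(a) pmax(1L, pmin(as.integer(floor(src[[a]])), d[a] - 1L)))
  fr <- lapply(1:3, function(a) src[[a]] - lo[[a]])
  v <- unclass(volume)
  n1 <- out_shape[1]; n2 <- out_shape[2]; n3 <- out_shape[3]
  ix <- rep(lo[[1]], times = n2 * n3)
  iy <- rep(rep(lo[[2]], each = n1), times = n3)
  iz <- rep(lo[[3]], each = n1 * n2)
  fx <- rep(fr[[1]], times = n2 * n3)
  fy <- rep(rep(fr[[2]], each = n1), times = n3)
  fz <- rep(fr[[3]], each = n1 * n2)
  at <- function(dx, dy, dz) v[cbind(ix + dx, iy + dy, iz + dz)]
  out <- at(0L, 0L, 0L) * (1 - fx) * (1 - fy) * (1 - fz) +
         at(1L, 0L, 0L) * fx * (1 - fy) * (1 - fz) +
         at(0L, 1L, 0L) * (1 - fx) * fy * (1 - fz) +
         at(1L, 1L, 0L) * fx * fy * (1 - fz) +
         at(0L, 0L, 1L) * (1 - fx) * (1 - fy) * fz +
         at(1L, 0L, 1L) * fx * (1 - fy) * fz +
         at(0L, 1L, 1L) * (1 - fx) * fy * fz +
         at(1L, 1L, 1L) * fx * fy * fz
  m <- unclass(mask)
  nn <- lapply(1:3, function(a) pmax(1L, pmin(as.integer(round(src[[a]])), d[a])))
  mx <- rep(nn[[1]], times = n2 * n3)
  my <- rep(rep(nn[[2]], each = n1), times = n3)
  mz <- rep(nn[[3]], each = n1 * n2)
  mout <- array(m[cbind(mx, my, mz)], out_shape)
  if (sum(mout) == 0L) stop("resampling emptied the mask")
  list(volume = image_volume(array(out, out_shape), rep(target_mm, 3)),
       mask = seg_mask(mout, rep(target_mm, 3), check_margin = FALSE))
}

mask_bbox <- function(mask) {
  idx <- which(unclass(mask) != 0, arr.ind = TRUE)
  rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

new_filtered_grid <- function(values, object_id, spacing) {
  structure(values, object_id = object_id, spacing = spacing,
            class = c("filtered_grid", "array"))
}

#' @export
print.filtered_grid <- function(x, ...) {
  d <- dim(x)
  fin <- is.finite(unclass(x))
  cat(sprintf("<filtered_grid '%s'> %d x %d x %d cells, %d finite (%.0f%%)\n",
              attr(x, "object_id"), d[1], d[2], d[3], sum(fin),
              100 * mean(fin)))
  invisible(x)
}

#' Lesion-restricted filtration grid
#'
#' Intensities restricted to the segmented lesion voxels: inside the mask the
#' value is the (optionally sign-flipped) intensity; outside it is `+Inf`,
#' meaning the voxel never enters the sublevel filtration. The grid is
#' cropped to the mask bounding box plus a one-voxel `+Inf` border so that
#' boundary effects are uniform.
#'
#' @param volume,mask aligned, typically resampled, inputs.
#' @param negate flip the sign of the intensities (sublevel filtration of
#'   `-x` is the superlevel filtration of `x`).
#' @return a `filtered_grid` with object id `"lesion"` or `"lesion_neg"`.
#' @export
build_lesion_grid <- function(volume, mask, negate = FALSE) {
  check_aligned(volume, mask)
  m <- unclass(mask) != 0
  if (!any(m)) stop("empty mask")
  bb <- mask_bbox(mask)
  v <- unclass(volume)[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
                       drop = FALSE]
  mm <- m[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3], drop = FALSE]
  g <- ifelse(mm, if (negate) -v else v, Inf)
  d <- dim(g) + 2L
  padded <- array(Inf, d)
  padded[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- g
  new_filtered_grid(padded, if (negate) "lesion_neg" else "lesion",
                    voxel_spacing(volume))
}

#' Boundary-box filtration grid
#'
#' Crops the full intensity volume to the lesion's axis-aligned bounding box
#' expanded by `margin_voxels` (clipped to the volume extent), so the lesion
#' is seen together with its immediate surroundings. All entries are finite.
#'
#' @inheritParams build_lesion_grid
#' @param margin_voxels non-negative expansion of the bounding box (default 2).
#' @return a `filtered_grid` with object id `"box"` or `"box_neg"`.
#' @export
build_box_grid <- function(volume, mask, negate = FALSE, margin_voxels = 2) {
  check_aligned(volume, mask)
  stopifnot(margin_voxels >= 0)
  if (!any(unclass(mask) != 0)) stop("empty mask")
  bb <- mask_bbox(mask)
  d <- dim(volume)
  lo <- pmax(1L, bb[1, ] - as.integer(margin_voxels))
  hi <- pmin(d, bb[2, ] + as.integer(margin_voxels))
  v <- unclass(volume)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (negate) v <- -v
  new_filtered_grid(v, if (negate) "box_neg" else "box", voxel_spacing(volume))
}

#' Lesion surface point cloud
#'
#' Stacks the lesion contours of all axial (z) slices: in every slice, the
#' foreground voxels with at least one background 4-neighbor in-plane are
#' emitted, converted to mm via the voxel spacing, and deduplicated.
#'
#' @param mask a [seg_mask()].
#' @param spacing override spacing (defaults to the mask's).
#' @return a `point_cloud` tibble with columns `x_mm`, `y_mm`, `z_mm`.
#' @export
build_surface_cloud <- function(mask, spacing = voxel_spacing(mask)) {
  m <- unclass(mask) != 0
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  pad <- array(FALSE, d[1:2] + 2L)
  pts <- purrr::map(seq_len(d[3]), function(z) {
    sl <- m[, , z]
    if (!any(sl)) return(NULL)
    pad[2:(d[1] + 1), 2:(d[2] + 1)] <- sl
    interior <- pad[2:(d[1] + 1), 2:(d[2] + 1)] &
      pad[1:d[1], 2:(d[2] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1)] &
      pad[2:(d[1] + 1), 1:d[2]] & pad[2:(d[1] + 1), 3:(d[2] + 2)]
    idx <- which(sl & !interior, arr.ind = TRUE)
    cbind(idx, z)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) < 4)
    stop("degenerate surface: fewer than 4 boundary voxels")
  coords <- sweep(pts - 1, 2, spacing, `*`)
  out <- tibble::tibble(x_mm = coords[, 1], y_mm = coords[, 2],
                        z_mm = coords[, 3]) |> dplyr::distinct()
  structure(out, object_id = "surface",
            class = c("point_cloud", class(out)))
}

#' Build the five filtration objects of a scan
#'
#' Resamples the scan to isotropic spacing and constructs the lesion grid
#' (raw and negated), the boundary-box grid (raw and negated), and the
#' lesion-surface point cloud. For masks with several connected components
#' only the largest is kept, with a warning.
#'
#' @inheritParams resample_isotropic
#' @param margin_voxels boundary-box expansion, see [build_box_grid()].
#' @param resample resample to `target_mm` first (default `TRUE`).
#' @return named list `lesion`, `lesion_neg`, `box`, `box_neg`, `surface`.
#' @export
build_filtration_objects <- function(volume, mask, target_mm = 1,
                                     margin_voxels = 2, resample = TRUE) {
  if (resample) {
    res <- resample_isotropic(volume, mask, target_mm)
    volume <- res$volume; mask <- res$mask
  }
  lab <- label_components(mask)
  if (max(lab) > 1) {
    warning("mask has multiple connected components; keeping the largest")
    mask <- seg_mask(lab == which.max(tabulate(lab[lab > 0])),
                     voxel_spacing(mask), check_margin = FALSE)
  }
  list(lesion = build_lesion_grid(volume, mask, negate = FALSE),
       lesion_neg = build_lesion_grid(volume, mask, negate = TRUE),
       box = build_box_grid(volume, mask, negate = FALSE,
                            margin_voxels = margin_voxels),
       box_neg = build_box_grid(volume, mask, negate = TRUE,
                                margin_voxels = margin_voxels),
       surface = build_surface_cloud(mask))
}
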