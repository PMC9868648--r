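#' CT-like image volume
#'
#' A 3D grid of finite intensity values (Hounsfield-unit-like scale) with a
#' physical voxel spacing in mm along each axis.
#'
#' @param values 3D numeric array of finite intensities.
#' @param spacing numeric length-3, mm per voxel along each axis (positive).
#' @return An `image_volume` (a 3D array with a `spacing` attribute).
#' @export
image_volume <- function(values, spacing) {
  values <- unclass(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!all(is.finite(values))) stop("image intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive reals (mm/voxel)")
  structure(values, spacing = spacing, class = c("image_volume", "array"))
}

#' Binary segmentation mask
#'
#' A 3D binary grid aligned with an [image_volume()]. The foreground (lesion)
#' must be non-empty and lie strictly inside the grid border (at least a
#' one-voxel background margin on every face).
#'
#' @param values 3D array coercible to 0/1.
#' @param spacing as in [image_volume()].
#' @param check_margin verify the one-voxel border margin (default `TRUE`).
#' @return A `seg_mask` (integer 0/1 array with a `spacing` attribute).
#' @export
seg_mask <- function(values, spacing, check_margin = TRUE) {
  values <- unclass(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  v <- array(as.integer(values != 0), dim = dim(values))
  if (sum(v) == 0L) stop("mask has no foreground voxels")
  if (check_margin && .touches_border(v))
    stop("mask foreground touches the grid border; need >= 1 voxel margin")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive reals (mm/voxel)")
  structure(v, spacing = spacing, class = c("seg_mask", "array"))
}

.touches_border <- function(v) {
  d <- dim(v)
  any(v[c(1, d[1]), , ] != 0) || any(v[, c(1, d[2]), ] != 0) ||
    any(v[, , c(1, d[3])] != 0)
}

#' Voxel spacing of a volume or mask
#' @param x an `image_volume`, `seg_mask` or `filtered_grid`.
#' @return numeric length-3 spacing in mm.
#' @export
voxel_spacing <- function(x) attr(x, "spacing")

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing (%s) mm, range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(format(voxel_spacing(x)), collapse = ", "),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<seg_mask> %d x %d x %d voxels, spacing (%s) mm, %d foreground voxels\n",
              d[1], d[2], d[3], paste(format(voxel_spacing(x)), collapse = ", "),
              sum(unclass(x))))
  invisible(x)
}

# mm coordinates of voxel centers along each axis (origin at first voxel)
axis_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

# stopifnot-style check that a volume and mask are aligned
check_aligned <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask shapes differ")
  if (!isTRUE(all.equal(voxel_spacing(volume), voxel_spacing(mask))))
    stop("volume and mask spacings differ")
  invisible(TRUE)
}
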