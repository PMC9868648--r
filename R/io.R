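#' Write persistence diagrams to a text file
#'
#' One line per pair, `dim birth death`, with `inf` for essential classes
#' (GUDHI-compatible dialect). A `diagram_set` is written with the object id
#' as a `# object: <id>` comment line preceding each block.
#'
#' @param diagrams a `persistence_diagrams` or `diagram_set` tibble.
#' @param file output path.
#' @export
write_diagrams <- function(diagrams, file) {
  fmt <- function(df) sprintf("%d %.17g %s", df$dimension, df$birth,
                              ifelse(is.finite(df$death),
                                     sprintf("%.17g", df$death), "inf"))
  lines <- if ("object" %in% names(diagrams)) {
    unlist(lapply(unique(diagrams$object), function(ob) {
      c(paste("# object:", ob), fmt(diagrams[diagrams$object == ob, ]))
    }))
  } else fmt(diagrams)
  writeLines(lines, file)
  invisible(file)
}

#' Read persistence diagrams written by [write_diagrams()]
#' @param file input path.
#' @return a tibble with `dimension`, `birth`, `death` and, if present in
#'   the file, `object`.
#' @export
read_diagrams <- function(file) {
  lines <- readLines(file)
  ob <- NA_character_
  rows <- list()
  for (ln in lines) {
    if (startsWith(ln, "# object:")) {
      ob <- trimws(sub("# object:", "", ln, fixed = TRUE))
    } else if (nzchar(trimws(ln))) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        object = ob, dimension = as.integer(parts[1]),
        birth = as.numeric(parts[2]),
        death = if (identical(parts[3], "inf")) Inf else as.numeric(parts[3]))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$object))) out$object <- NULL
  out
}

#' Write a cohort to disk (NIfTI volumes + CSV metadata)
#'
#' Each nodule's intensity volume and mask are written as compressed NIfTI
#' with the voxel spacing in the header, and the cohort metadata
#' (`patient_id`, `nodule_id`, `class`, `score`) as `metadata.csv`.
#'
#' @param cohort a `nodule_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$nodule_id[i]
    vol <- cohort$volume[[i]]
    msk <- cohort$mask[[i]]
    img <- RNifti::asNifti(unclass(vol))
    RNifti::pixdim(img) <- voxel_spacing(vol)
    RNifti::writeNifti(img, file.path(dir, paste0(id, "_image.nii.gz")))
    mski <- RNifti::asNifti(array(as.numeric(unclass(msk)), dim(msk)))
    RNifti::pixdim(mski) <- voxel_spacing(msk)
    RNifti::writeNifti(mski, file.path(dir, paste0(id, "_mask.nii.gz")))
  }
  meta <- tibble::tibble(patient_id = cohort$patient_id,
                         nodule_id = cohort$nodule_id,
                         class = cohort$class_label,
                         score = cohort$malignancy_score)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a scan (image + mask NIfTI pair)
#'
#' @param image,mask NIfTI file paths.
#' @return list with `volume` ([image_volume()]) and `mask` ([seg_mask()]).
#' @export
read_scan <- function(image, mask) {
  img <- RNifti::readNifti(image)
  msk <- RNifti::readNifti(mask)
  sp <- RNifti::pixdim(img)[1:3]
  list(volume = image_volume(array(as.numeric(img), dim(img)[1:3]), sp),
       mask = seg_mask(array(as.numeric(msk), dim(msk)[1:3]), sp,
                       check_margin = FALSE))
}

#' Write a point cloud as CSV
#' @param cloud a `point_cloud` tibble.
#' @param file output path.
#' @export
write_point_cloud <- function(cloud, file) {
  utils::write.csv(as.data.frame(cloud), file, row.names = FALSE)
  invisible(file)
}
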