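diagram_stat_names <- function() {
  c("n_finite", "n_infinite",
    as.vector(outer(c("mean", "sd", "min", "max"),
                    c("birth", "death", "pers", "midlife"),
                    function(s, d) paste(d, s, sep = "_"))),
    "entropy")
}

#' Summary statistics of one persistence diagram
#'
#' Over the finite pairs of a single-dimension diagram, computes the mean,
#' population sd, min and max of each derived series — birth, death,
#' persistence (`death - birth`) and midlife (`(birth + death) / 2`) — plus
#' the finite-pair count, the infinite-pair count, and the persistence
#' entropy `H = -sum(p_i log p_i)` with `p_i` the normalized persistences
#' (natural log; 0 for a single pair). A diagram with no finite pairs yields
#' counts and `NA` for every other statistic.
#'
#' @param diagram tibble with columns `birth` and `death` (and optionally a
#'   constant `dimension`).
#' @return named numeric vector of length 19.
#' @export
diagram_statistics <- function(diagram) {
  if ("dimension" %in% names(diagram) &&
      length(unique(diagram$dimension)) > 1)
    stop("diagram mixes homology dimensions; subset to one dimension first")
  fin <- diagram[is.finite(diagram$death), , drop = FALSE]
  n_fin <- nrow(fin)
  n_inf <- nrow(diagram) - n_fin
  out <- setNames(rep(NA_real_, 19), diagram_stat_names())
  out["n_finite"] <- n_fin
  out["n_infinite"] <- n_inf
  if (n_fin > 0) {
    series <- list(birth = fin$birth, death = fin$death,
                   pers = fin$death - fin$birth,
                   midlife = (fin$birth + fin$death) / 2)
    for (nm in names(series)) {
      x <- series[[nm]]
      out[paste0(nm, "_mean")] <- mean(x)
      out[paste0(nm, "_sd")] <- sqrt(mean((x - mean(x))^2))
      out[paste0(nm, "_min")] <- min(x)
      out[paste0(nm, "_max")] <- max(x)
    }
    p <- series$pers / sum(series$pers)
    out["entropy"] <- -sum(p * log(p))
  }
  out
}

#' Canonical topological feature names
#'
#' The fixed, ordered set of 290 feature names: 19 summary statistics for
#' each of the 15 diagrams (5 objects x 3 dimensions), plus one
#' `essential0_birth` per object (the minimum birth among the object's
#' infinite dimension-0 pairs).
#'
#' @return character vector of length 290.
#' @export
topo_feature_names <- function() {
  objs <- filtration_object_ids()
  nm <- unlist(lapply(objs, function(ob) {
    c(unlist(lapply(0:2, function(d)
      paste(ob, paste0("dim", d), diagram_stat_names(), sep = "_"))),
      paste0(ob, "_essential0_birth"))
  }))
  unname(nm)
}

#' Vectorize a scan's diagram set into 290 topological features
#'
#' Concatenates the 19 summary statistics of each of the 15 diagrams with the
#' five per-object essential dimension-0 births, in the canonical order of
#' [topo_feature_names()]. Persistence-based statistics are invariant under
#' global intensity shifts; birth and death statistics shift along with the
#' intensities.
#'
#' @param diagrams a `diagram_set` from [compute_diagram_set()], or any
#'   tibble with columns `object`, `dimension`, `birth`, `death` covering all
#'   five canonical objects.
#' @return named numeric vector of length 290 (`NA` only for statistics of
#'   empty diagrams).
#' @export
vectorize_scan <- function(diagrams) {
  objs <- filtration_object_ids()
  missing_obj <- setdiff(objs, unique(diagrams$object))
  if (length(missing_obj))
    stop("incomplete diagram set: no diagrams for object(s) ",
         paste(missing_obj, collapse = ", "))
  vals <- unlist(lapply(objs, function(ob) {
    sub <- diagrams[diagrams$object == ob, , drop = FALSE]
    per_dim <- unlist(lapply(0:2, function(d) {
      diagram_statistics(sub[sub$dimension == d, , drop = FALSE])
    }))
    ess0 <- sub$birth[sub$dimension == 0 & is.infinite(sub$death)]
    c(per_dim, if (length(ess0)) min(ess0) else NA_real_)
  }))
  setNames(vals, topo_feature_names())
}

#' Extract the full feature table of a cohort
#'
#' Runs the per-scan pipeline over every nodule of a cohort: isotropic
#' resampling, the five filtration objects, the 15 persistence diagrams, the
#' 290 topological features (prefixed `top_`), and the stand-in radiomic
#' block (prefixed `rad_`). Feature names and order are identical across
#' scans and runs.
#'
#' @param cohort a `nodule_cohort` from [generate_cohort()], or any tibble
#'   with list-columns `volume` and `mask` plus key columns.
#' @param target_mm,margin_voxels,max_points,seed pipeline parameters, see
#'   [compute_diagram_set()].
#' @return tibble with `patient_id`, `nodule_id`, `class_label`,
#'   `malignancy_score`, then `rad_*` and `top_*` feature columns.
#' @export
extract_features <- function(cohort, target_mm = 1, margin_voxels = 2,
                             max_points = 64, seed = 1) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    vol <- cohort$volume[[i]]
    msk <- cohort$mask[[i]]
    res <- resample_isotropic(vol, msk, target_mm)
    ds <- compute_diagram_set(res$volume, res$mask, resample = FALSE,
                              margin_voxels = margin_voxels,
                              max_points = max_points, seed = seed)
    top <- vectorize_scan(ds)
    rad <- standin_radiomic_features(res$volume, res$mask)
    tibble::as_tibble(c(
      list(patient_id = cohort$patient_id[i], nodule_id = cohort$nodule_id[i],
           class_label = cohort$class_label[i],
           malignancy_score = cohort$malignancy_score[i]),
      setNames(as.list(rad), paste0("rad_", names(rad))),
      setNames(as.list(top), paste0("top_", names(top)))))
  })
  dplyr::bind_rows(rows)
}
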