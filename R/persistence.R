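new_diagrams <- function(df, object_id = NULL) {
  df <- dplyr::arrange(df, .data$dimension, .data$birth, .data$death)
  structure(df, object_id = object_id,
            class = c("persistence_diagrams", class(tibble::tibble())))
}

#' Cubical sublevel persistence of a filtered grid
#'
#' Computes persistence diagrams in dimensions 0-2 of the sublevel filtration
#' of a 3D grid under the V-construction: voxels are the vertices of the
#' complex, a higher cell enters the filtration at the maximum of its
#' vertices, and `+Inf` voxels (with all incident cells) are excluded.
#' Zero-persistence pairs are discarded. Each connected component of the
#' finite support yields one infinite dimension-0 pair born at the
#' component's minimum value; grids whose excluded region encloses voids
#' (e.g. a lesion mask around an internal cavity) can additionally carry
#' infinite pairs in dimensions 1-2.
#'
#' @param grid a `filtered_grid` or a plain 3D numeric array (use `Inf` for
#'   voxels outside the filtration).
#' @param max_dim highest homology dimension to return (at most 2).
#' @return a `persistence_diagrams` tibble with columns `dimension`, `birth`,
#'   `death` (`Inf` for essential classes).
#' @export
cubical_persistence <- function(grid, max_dim = 2) {
  v <- unclass(grid)
  if (length(dim(v)) != 3L) stop("`grid` must be a 3D array")
  if (!any(is.finite(v))) stop("grid has no finite values")
  if (any(is.na(v))) stop("grid values must not be NA")
  pairs <- cubical_pairs_cpp(as.numeric(v), dim(v))
  df <- tibble::tibble(dimension = as.integer(pairs[, 1]),
                       birth = pairs[, 2], death = pairs[, 3]) |>
    dplyr::filter(.data$dimension <= max_dim)
  new_diagrams(df, attr(grid, "object_id"))
}

# enclosing radius: min over points of the max distance to any other point;
# every homology class of the Rips filtration dies by this scale
enclosing_radius <- function(pts) {
  dm <- as.matrix(stats::dist(pts))
  min(apply(dm, 1, max))
}

#' Vietoris-Rips persistence of a point cloud
#'
#' Approximated Rips persistence in dimensions 0-2. Clouds larger than
#' `max_points` are first reduced by farthest-point subsampling (the start
#' point is drawn from the seeded RNG); simplices up to dimension 3 with
#' diameter at most `threshold` (default: the enclosing radius of the
#' subsample, beyond which no class survives) are enumerated explicitly and
#' reduced. Dimension-0 classes are all born at 0 and, when the threshold
#' reaches the subsample diameter, exactly one is essential.
#'
#' @param cloud a `point_cloud` tibble, data frame, or numeric matrix of 3D
#'   coordinates.
#' @param max_dim highest homology dimension (at most 2).
#' @param threshold maximum edge length entering the filtration (> 0).
#' @param max_points subsampling budget (default 64; kept modest because the
#'   complex holds all `choose(n, 4)` tetrahedra up to the threshold).
#' @param seed seed for the subsample start point.
#' @return a `persistence_diagrams` tibble; attributes `n_points` and
#'   `threshold` record the approximation actually used.
#' @export
rips_persistence <- function(cloud, max_dim = 2, threshold = NULL,
                             max_points = 64, seed = 1) {
  pts <- as.matrix(as.data.frame(cloud)[, 1:3])
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  if (nrow(pts) < 4) stop("need at least 4 distinct points")
  if (nrow(pts) > max_points) {
    pts <- with_seed(seed, {
      start <- sample.int(nrow(pts), 1)
      pts[fps_cpp(pts, as.integer(max_points), start), , drop = FALSE]
    })
  }
  if (is.null(threshold)) threshold <- enclosing_radius(pts)
  if (threshold <= 0) stop("`threshold` must be positive")
  pairs <- rips_pairs_cpp(pts, threshold)
  df <- tibble::tibble(dimension = as.integer(pairs[, 1]),
                       birth = pairs[, 2], death = pairs[, 3]) |>
    dplyr::filter(.data$dimension <= max_dim)
  out <- new_diagrams(df, attr(cloud, "object_id") %||% "cloud")
  attr(out, "n_points") <- nrow(pts)
  attr(out, "threshold") <- threshold
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The 15-diagram set of a scan
#'
#' Builds the five filtration objects of a scan and computes persistence in
#' dimensions 0-2 for each, yielding the keyed set of 5 x 3 = 15 diagrams
#' (cubical sublevel persistence for the four grids, Vietoris-Rips for the
#' surface cloud).
#'
#' @inheritParams build_filtration_objects
#' @param max_points,seed passed to [rips_persistence()].
#' @return a `diagram_set` tibble with columns `object`, `dimension`,
#'   `birth`, `death`; diagrams with no pairs are simply absent rows.
#' @export
compute_diagram_set <- function(volume, mask, target_mm = 1,
                                margin_voxels = 2, max_points = 64,
                                seed = 1, resample = TRUE) {
  objs <- build_filtration_objects(volume, mask, target_mm = target_mm,
                                   margin_voxels = margin_voxels,
                                   resample = resample)
  dl <- purrr::imap(objs, function(ob, id) {
    dg <- if (id == "surface") {
      rips_persistence(ob, max_points = max_points, seed = seed)
    } else {
      cubical_persistence(ob)
    }
    dplyr::mutate(tibble::as_tibble(dg), object = id, .before = 1)
  })
  out <- dplyr::bind_rows(dl)
  structure(out, objects = filtration_object_ids(),
            class = c("diagram_set", class(tibble::tibble())))
}

#' Canonical filtration object ids
#' @return character vector of the five object ids in canonical order.
#' @export
filtration_object_ids <- function() {
  c("lesion", "lesion_neg", "box", "box_neg", "surface")
}

#' @export
print.persistence_diagrams <- function(x, ...) {
  cat(sprintf("<persistence diagrams%s>\n",
              if (!is.null(attr(x, "object_id")))
                paste0(" of '", attr(x, "object_id"), "'") else ""))
  NextMethod()
}

#' Boundary-matrix reduction
#'
#' The standard left-to-right persistence pairing over the field with two
#' elements, without the clearing optimization: column `j` holds the (sorted)
#' indices of the facets of cell `j`, cells being listed in filtration order.
#' Columns are reduced by adding earlier columns with the same pivot until
#' the pivot is unique or the column vanishes. This is the reference path the
#' optimized cubical and Rips implementations are validated against.
#'
#' @param columns list of integer vectors; `columns[[j]]` are the facet
#'   indices of cell `j` and must all be `< j` (faces precede cofaces).
#' @return list with `pairs`, a tibble of `(birth, death)` cell indices, and
#'   `essential`, the indices of cells whose classes never die.
#' @export
reduce_boundary_matrix <- function(columns) {
  n <- length(columns)
  cols <- lapply(columns, function(x) sort(unique(as.integer(x))))
  for (j in seq_len(n)) {
    if (length(cols[[j]]) && max(cols[[j]]) >= j)
      stop("non-nested filtration: a cell precedes one of its faces")
  }
  owner <- integer(n)  # pivot index -> owning column (0 = none)
  births <- integer(0); deaths <- integer(0)
  positive <- logical(n)
  for (j in seq_len(n)) {
    col <- cols[[j]]
    while (length(col)) {
      piv <- col[length(col)]
      o <- owner[piv]
      if (o == 0L) break
      other <- cols[[o]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    cols[[j]] <- col
    if (length(col)) {
      piv <- col[length(col)]
      owner[piv] <- j
      births <- c(births, piv); deaths <- c(deaths, j)
    } else {
      positive[j] <- TRUE
    }
  }
  essential <- setdiff(which(positive), births)
  list(pairs = tibble::tibble(birth = births, death = deaths),
       essential = essential)
}
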