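# Naive reference implementations of cubical and Rips persistence, written
# independently of the optimized path (explicit cell enumeration in R, plain
# left-to-right reduction via reduce_boundary_matrix, no clearing). Intended
# for validation on small inputs; complexity is unoptimized on purpose.

#' Naive cubical persistence (reference path)
#'
#' Same V-construction sublevel convention as [cubical_persistence()], but
#' with all cells enumerated in R and the pairing computed by the plain
#' [reduce_boundary_matrix()] reduction. Use on small grids only.
#'
#' @inheritParams cubical_persistence
#' @return a tibble with columns `dimension`, `birth`, `death`.
#' @export
naive_cubical_persistence <- function(grid, max_dim = 2) {
  v <- unclass(grid)
  d <- dim(v)
  ex <- 2L * d - 1L
  ids <- seq_len(prod(ex)) - 1L
  cx <- ids %% ex[1]
  cy <- (ids %/% ex[1]) %% ex[2]
  cz <- ids %/% (ex[1] * ex[2])
  cdim <- (cx %% 2L) + (cy %% 2L) + (cz %% 2L)
  cval <- vapply(seq_along(ids), function(i) {
    vx <- cx[i] %/% 2L + 0:(cx[i] %% 2L)
    vy <- cy[i] %/% 2L + 0:(cy[i] %% 2L)
    vz <- cz[i] %/% 2L + 0:(cz[i] %% 2L)
    max(v[vx + 1L, vy + 1L, vz + 1L])
  }, numeric(1))
  keep <- which(is.finite(cval))
  if (!length(keep)) stop("grid has no finite values")
  ord <- keep[order(cval[keep], cdim[keep], keep)]
  pos <- integer(length(ids)); pos[ord] <- seq_along(ord)
  columns <- lapply(ord, function(i) {
    id <- ids[i]
    fac <- integer(0)
    if (cx[i] %% 2L) fac <- c(fac, id - 1L, id + 1L)
    if (cy[i] %% 2L) fac <- c(fac, id - ex[1], id + ex[1])
    if (cz[i] %% 2L) fac <- c(fac, id - ex[1] * ex[2], id + ex[1] * ex[2])
    pos[fac + 1L]
  })
  red <- reduce_boundary_matrix(columns)
  pairs_to_diagram(red, cval[ord], cdim[ord], max_dim)
}

#' Naive Vietoris-Rips persistence (reference path)
#'
#' Enumerates every simplex up to dimension 3 with `utils::combn` and reduces
#' the full boundary matrix with [reduce_boundary_matrix()]. Exponential in
#' the number of points; intended for clouds of at most ~10 points.
#'
#' @inheritParams rips_persistence
#' @export
naive_rips_persistence <- function(cloud, max_dim = 2, threshold = NULL) {
  pts <- unique(as.matrix(as.data.frame(cloud)[, 1:3]))
  n <- nrow(pts)
  if (is.null(threshold)) threshold <- enclosing_radius(pts)
  dm <- as.matrix(stats::dist(pts))
  verts_list <- list(); val <- numeric(0); sdim <- integer(0)
  for (k in 1:4) {
    if (n < k) next
    cmb <- utils::combn(n, k)
    for (j in seq_len(ncol(cmb))) {
      vv <- cmb[, j]
      dia <- if (k == 1) 0 else max(dm[vv, vv])
      if (dia <= threshold) {
        verts_list[[length(verts_list) + 1L]] <- vv
        val <- c(val, dia)
        sdim <- c(sdim, k - 1L)
      }
    }
  }
  ord <- order(val, sdim, seq_along(val))
  key <- vapply(verts_list, paste, character(1), collapse = "-")
  pos <- setNames(seq_along(ord), key[ord])
  columns <- lapply(ord, function(i) {
    vv <- verts_list[[i]]
    if (length(vv) == 1) return(integer(0))
    fac <- utils::combn(vv, length(vv) - 1L)
    unname(pos[apply(fac, 2, paste, collapse = "-")])
  })
  red <- reduce_boundary_matrix(columns)
  pairs_to_diagram(red, val[ord], sdim[ord], max_dim)
}

pairs_to_diagram <- function(red, values, dims, max_dim) {
  b <- red$pairs$birth; dth <- red$pairs$death
  keep <- values[b] != values[dth]
  df <- tibble::tibble(dimension = dims[b[keep]], birth = values[b[keep]],
                       death = values[dth[keep]])
  ess <- red$essential
  df <- dplyr::bind_rows(df, tibble::tibble(dimension = dims[ess],
                                            birth = values[ess],
                                            death = Inf))
  df |>
    dplyr::filter(.data$dimension <= max_dim) |>
    dplyr::arrange(.data$dimension, .data$birth, .data$death)
}
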