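#' Plot persistence diagrams
#'
#' Birth-death scatter per homology dimension; essential classes (infinite
#' death) are drawn as triangles on a dashed line just above the largest
#' finite death. Diagram sets are faceted by filtration object.
#'
#' @param object a `persistence_diagrams` or `diagram_set` tibble.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.persistence_diagrams <- function(object, ...) {
  df <- tibble::as_tibble(object)
  fin <- df$death[is.finite(df$death)]
  top <- if (length(fin)) max(fin) + 0.05 * diff(range(c(df$birth, fin)))
         else max(df$birth) + 1
  df <- df |>
    dplyr::mutate(essential = is.infinite(.data$death),
                  death_plot = ifelse(.data$essential, top, .data$death),
                  dimension = factor(.data$dimension,
                                     labels = paste0("H", sort(unique(.data$dimension)))))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$birth, y = .data$death_plot,
                                        color = .data$dimension,
                                        shape = .data$essential)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_hline(yintercept = top, linetype = "dashed",
                        color = "grey80") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(x = "birth", y = "death", color = "dimension") +
    ggplot2::theme_minimal()
  if ("object" %in% names(df)) p <- p + ggplot2::facet_wrap(~object)
  p
}

#' @export
autoplot.diagram_set <- autoplot.persistence_diagrams

#' Plot cross-validation scores of an experiment
#'
#' Boxplots of the per-fold scores by combination strategy, faceted by model
#' family.
#'
#' @param object a `cv_result` from [run_experiment()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  metric <- if (object$config$task == "classification") "ROC AUC"
            else "r squared"
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$strategy, y = .data$score,
                               fill = .data$strategy)) +
    ggplot2::geom_boxplot(outlier.size = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "combination strategy", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a scan with its mask contour
#'
#' @param volume an [image_volume()].
#' @param mask optional aligned [seg_mask()].
#' @param z slice index (default: middle slice, or the mask's busiest slice).
#' @return a ggplot.
#' @export
plot_nodule_slice <- function(volume, mask = NULL, z = NULL) {
  v <- unclass(volume)
  if (is.null(z)) {
    z <- if (!is.null(mask)) which.max(apply(unclass(mask), 3, sum))
         else ceiling(dim(v)[3] / 2)
  }
  sp <- voxel_spacing(volume)
  sl <- v[, , z]
  df <- expand.grid(x = (seq_len(nrow(sl)) - 1) * sp[1],
                    y = (seq_len(ncol(sl)) - 1) * sp[2])
  df$hu <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm", fill = "HU") +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    ms <- unclass(mask)[, , z]
    if (any(ms != 0)) {
      mdf <- df
      mdf$m <- as.vector(ms)
      p <- p + ggplot2::geom_contour(
        data = mdf,
        mapping = ggplot2::aes(x = .data$x, y = .data$y, z = .data$m),
        breaks = 0.5, color = "red", inherit.aes = FALSE)
    }
  }
  p
}
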