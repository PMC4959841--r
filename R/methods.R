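# broom-style accessors and ggplot2 visualisations for result objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_raster geom_rect
#'   geom_segment geom_col scale_y_reverse coord_fixed labs theme_minimal
#'   facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a reconstruction
#'
#' One row per segment with its 3D component assignment and geometry.
#' @param x An `em_reconstruction`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.em_reconstruction <- function(x, ...) {
  left_join(x$components, x$table$segments, by = "label")
}

#' One-row reconstruction summary
#' @param x An `em_reconstruction`.
#' @param ... Unused.
#' @return A tibble with component/segment counts and extents.
#' @export
glance.em_reconstruction <- function(x, ...) {
  tibble(n_components = nrow(x$summary),
         n_segments = nrow(x$components),
         n_pruned = sum(x$table$segments$pruned_flag),
         z_span = diff(range(x$table$meta$sections)) + 1L,
         largest_component_segments = if (nrow(x$summary)) max(x$summary$n_segments) else 0L)
}

#' Tidy a segment match
#' @param x An `em_match`.
#' @param ... Unused.
#' @return The per-truth-segment tibble.
#' @export
tidy.em_match <- function(x, ...) x$per_truth

#' One-row match summary (recall, precision, missed sizes)
#' @param x An `em_match`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.em_match <- function(x, ...) x$summary

#' Tidy an ROI proposal
#' @param x An `em_roi`.
#' @param ... Unused.
#' @return The boxes tibble.
#' @export
tidy.em_roi <- function(x, ...) x$boxes

#' One-row ROI summary
#' @param x An `em_roi`.
#' @param ... Unused.
#' @return A tibble with volumes and reduction factor.
#' @export
glance.em_roi <- function(x, ...) {
  tibble(total_volume_um3 = x$total_volume_um3,
         roi_volume_um3 = x$roi_volume_um3,
         reduction_factor = x$reduction_factor)
}

#' Plot the segment centroids of a reconstruction
#'
#' Centroid chains coloured by 3D component, in physical nm coordinates —
#' a quick structural view of the reconstructed processes.
#' @param object An `em_reconstruction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.em_reconstruction <- function(object, ...) {
  d <- tidy(object)
  v <- object$table$meta$voxel_nm
  d <- mutate(d, x_nm = centroid_x * v["x"], y_nm = centroid_y * v["y"])
  ggplot(d, aes(x = x_nm, y = y_nm, colour = factor(component))) +
    geom_point(size = 0.6) +
    scale_y_reverse() + coord_fixed() +
    labs(x = "x (nm)", y = "y (nm)", colour = "component",
         title = "Reconstructed processes (segment centroids)") +
    theme_minimal()
}

#' Plot match outcome by truth-segment size
#'
#' Matched and missed ground-truth segments by their bounding-box size:
#' missed segments should concentrate at small sizes.
#' @param object An `em_match`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.em_match <- function(object, ...) {
  ggplot(object$per_truth,
         aes(x = width_px, y = height_px, colour = matched)) +
    geom_point(alpha = 0.6) +
    labs(x = "truth bbox width (px)", y = "truth bbox height (px)",
         title = sprintf("2D segmentation recall %.1f%%",
                         100 * object$summary$recall)) +
    theme_minimal()
}

#' Plot one section with its segment overlay
#'
#' Grayscale section with kept-segment bounding boxes; a fast visual check
#' of the 2D stage.
#' @param img Intensity matrix on \[0, 1\].
#' @param segments Segment tibble restricted to this section.
#' @return A ggplot.
#' @export
plot_section <- function(img, segments = NULL) {
  check_image(img)
  d <- tibble(y = as.vector(row(img)) - 1, x = as.vector(col(img)) - 1,
              intensity = as.vector(img))
  p <- ggplot(d, aes(x = x, y = y, fill = intensity)) +
    geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    scale_y_reverse() + coord_fixed() + theme_minimal() +
    labs(x = "x (px)", y = "y (px)")
  if (!is.null(segments) && nrow(segments) > 0L) {
    p <- p + geom_rect(data = segments,
                       aes(xmin = bbox_x_min, xmax = bbox_x_max,
                           ymin = bbox_y_min, ymax = bbox_y_max),
                       inherit.aes = FALSE, colour = "red", fill = NA,
                       linewidth = 0.3)
  }
  p
}
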