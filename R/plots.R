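# ggplot2 views of the result objects. These are diagnostics, not the
# rendered validation images themselves (those are rasters; see
# write_validation_map()).

#' Plot a screening map
#'
#' Patch rectangles over the image extent, filled by visited state, with the
#' current position outlined.
#'
#' @param object A `screening_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screening_map
#' @export
autoplot.screening_map <- function(object, ...) {
  g <- tidy(object)
  cur <- g[g$row == object$current_index[1] & g$col == object$current_index[2], ]
  ggplot2::ggplot(g, ggplot2::aes(xmin = .data$x1, xmax = .data$x2,
                                  ymin = .data$y1, ymax = .data$y2)) +
    ggplot2::geom_rect(ggplot2::aes(fill = .data$visited), colour = "grey30", alpha = 0.6) +
    ggplot2::geom_rect(data = cur, fill = NA, colour = "purple", linewidth = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "seagreen3")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Screening %s: %.0f%% done", object$image_id,
                                  100 * progress(object)),
                  x = "x (px)", y = "y (px)")
}

#' Plot a validation map's tile layout
#'
#' Placed tile rectangles on the canvas; density maps colour by score,
#' others by source image.
#'
#' @param object A `validation_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot validation_map
#' @export
autoplot.validation_map <- function(object, ...) {
  t <- tidy(object)
  p <- ggplot2::ggplot(t, ggplot2::aes(xmin = .data$px, xmax = .data$px + .data$pw,
                                       ymin = .data$py, ymax = .data$py + .data$ph))
  p <- if (object$map_kind == "density") {
    p + ggplot2::geom_rect(ggplot2::aes(fill = .data$score), colour = "grey40")
  } else {
    p + ggplot2::geom_rect(ggplot2::aes(fill = .data$source_image_id),
                           colour = "grey40", show.legend = FALSE)
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s map: %d tiles", object$map_kind, nrow(t)),
                  x = "canvas x (px)", y = "canvas y (px)")
}

#' Plot a 2-D embedding
#'
#' @param object A `slide_embedding` from [reduce_features()].
#' @param labels Optional per-point labels (e.g. classes) to colour by.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot slide_embedding
#' @export
autoplot.slide_embedding <- function(object, labels = NULL, ...) {
  d <- tibble(u = object$u, v = object$v,
              label = labels %||% rep("point", nrow(object)))
  ggplot2::ggplot(d, ggplot2::aes(.data$u, .data$v, colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = "2-D feature embedding", x = "dim 1", y = "dim 2")
}
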