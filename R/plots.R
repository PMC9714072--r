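#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a root system model
#'
#' Draws every organ polyline colored by node apparition time, in image
#' coordinates (y axis reversed so depth grows downward).
#'
#' @param object a [root_system_model()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.root_system_model <- function(object, ...) {
  organs <- model_organs(object)
  df <- dplyr::bind_rows(lapply(seq_along(organs), function(k) {
    e <- organs[[k]]
    tibble(x = e$organ$x, y = e$organ$y, t = e$organ$t,
           order = factor(e$organ$order),
           organ = paste(e$plant, e$organ_id, sep = "."))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$organ,
                                   colour = .data$t)) +
    ggplot2::geom_path(ggplot2::aes(linewidth = .data$order)) +
    ggplot2::scale_linewidth_manual(values = c(`1` = 0.9, `2` = 0.4),
                                    guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "apparition\ntime") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot an apparition-time label image
#'
#' @param object an [apparition_image()].
#' @param max_px downsample so the longer side stays below this.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.apparition_image <- function(object, max_px = 600, ...) {
  step <- max(1, ceiling(max(dim(object)) / max_px))
  sub <- object[seq(1, nrow(object), by = step),
                seq(1, ncol(object), by = step)]
  df <- tibble(row = rep(seq_len(nrow(sub)), ncol(sub)) * step,
               col = rep(seq_len(ncol(sub)), each = nrow(sub)) * step,
               t = as.numeric(sub))
  df$t[df$t == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "apparition\ntime",
                                  na.value = "grey95") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot a depth-binned elongation heatmap
#'
#' @param object an [elongation_heatmap()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.elongation_heatmap <- function(object, ...) {
  H <- object$heatmap
  df <- tibble(bin = rep(rownames(H), ncol(H)),
               depth = rep(utils::head(object$depth_bins, -1) +
                             diff(object$depth_bins) / 2, ncol(H)),
               time = rep(object$times, each = nrow(H)),
               rate = as.numeric(H))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$depth,
                                         fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "elongation\n(mm/interval)",
                                  na.value = "grey95") +
    ggplot2::labs(x = "observation", y = "insertion depth (mm)") +
    ggplot2::theme_minimal()
  tip <- object$primary_tip
  if (nrow(tip))
    gg <- gg +
      ggplot2::geom_line(data = tip,
                         ggplot2::aes(.data$time, .data$mean_mm),
                         inherit.aes = FALSE, colour = "darkgreen") +
      ggplot2::geom_ribbon(data = tip,
                           ggplot2::aes(.data$time,
                                        ymin = .data$mean_mm - .data$sd_mm,
                                        ymax = .data$mean_mm + .data$sd_mm),
                           inherit.aes = FALSE, fill = "darkgreen",
                           alpha = 0.2)
  gg
}
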