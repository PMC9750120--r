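# ggplot2 visualisations of the result containers.

#' @export
autoplot.contact_map <- function(object, trans = "log10", floor = NULL, ...) {
  df <- tidy(object)
  if (identical(trans, "log10")) {
    if (is.null(floor)) {
      pos <- df$prob[df$prob > 0]
      floor <- if (length(pos) > 0) min(pos) / 2 else 1e-6
    }
    df$prob <- pmax(df$prob, floor)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start1_kb, y = .data$start2_kb,
                                   fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "P(contact)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position (kb)", y = "position (kb)",
                  title = sprintf("virtual Hi-C (%s, %g kb bins)",
                                  object$chrom_label, object$bin_size_kb)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.occupancy_track <- function(object, ...) {
  ggplot2::ggplot(object$track, ggplot2::aes(x = .data$start_kb, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (kb)", y = "LEF legs / bin / snapshot",
                  title = "virtual ChIP-seq occupancy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.grid_summary <- function(object, ...) {
  df <- tidy(object)
  ax <- names(object$axes)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data[[ax[1]]]),
                                   y = factor(.data[[ax[2]]]),
                                   fill = .data$chi2)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$is_best, ], shape = 8, size = 3,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "chi2") +
    ggplot2::labs(x = ax[1], y = ax[2], title = "grid-simulation scores") +
    ggplot2::theme_minimal()
}

#' Plot a contact-probability curve
#'
#' @param map A `contact_map` (or a list of named maps to overlay).
#' @return A ggplot of P(s) on log-log axes.
#' @export
plot_ps_curve <- function(map) {
  maps <- if (inherits(map, "contact_map")) list(map = map) else map
  df <- dplyr::bind_rows(lapply(maps, ps_curve), .id = "map")
  df <- df[df$distance_kb > 0 & df$prob > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_kb, y = .data$prob,
                                   colour = .data$map)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic separation s (kb)", y = "mean contact probability",
                  title = "P(s)") +
    ggplot2::theme_minimal()
}
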