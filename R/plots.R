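## Figure-style output: expression heat maps and line plots.
## Plotting is optional; ggplot2 is only required when these are called.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_fz("ggplot2 is required for plotting; install it or use the CSV/",
            "JSON exports instead", class = "fuzzynet_config_error")
  }
}

#' Expression heat map of a trajectory
#'
#' Time on x, nodes grouped by module on y, expression level mapped to a
#' fixed \eqn{[0,1]} colour scale so panels from different scenarios are
#' comparable. Environmental input nodes are excluded by default.
#'
#' @param traj A `fz_trajectory`.
#' @param include_inputs Show clamped input nodes too? Default `FALSE`.
#' @return A ggplot object.
#' @export
plot_trajectory_heatmap <- function(traj, include_inputs = FALSE) {
  need_ggplot()
  stopifnot(inherits(traj, "fz_trajectory"))
  if (nrow(traj) == 0) {
    stop_fz("empty trajectory", class = "fuzzynet_validation_error")
  }
  net <- trajectory_network(traj)
  info <- network_nodes(net)
  if (!include_inputs) info <- info[!info$is_input, ]
  long <- tidyr::pivot_longer(as.data.frame(traj)[, c("time", info$name)],
                              -"time", names_to = "node",
                              values_to = "level")
  long$node <- factor(long$node, levels = rev(info$name))
  long$module <- info$module[match(long$node, info$name)]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$node,
                                     fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), oob = scales_squish) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$module), scales = "free_y",
                        space = "free_y", switch = "y") +
    ggplot2::labs(x = "time (dimensionless units)", y = NULL,
                  fill = "level") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(strip.text.y.left = ggplot2::element_text(angle = 0),
                   panel.spacing = ggplot2::unit(2, "pt"))
}

## minimal squish so we avoid a hard scales dependency
scales_squish <- function(x, range = c(0, 1)) pmin(pmax(x, range[1]), range[2])

#' Line plot of selected nodes over time
#'
#' @param traj A `fz_trajectory`.
#' @param nodes Character vector of node names to draw.
#' @return A ggplot object.
#' @export
plot_trajectory_lines <- function(traj, nodes) {
  need_ggplot()
  stopifnot(inherits(traj, "fz_trajectory"))
  if (length(nodes) == 0) {
    stop_fz("no nodes requested", class = "fuzzynet_validation_error")
  }
  missing <- setdiff(nodes, colnames(traj))
  if (length(missing)) {
    stop_fz("unknown node(s): ", paste(missing, collapse = ", "),
            class = "fuzzynet_unresolved_symbol")
  }
  long <- tidyr::pivot_longer(as.data.frame(traj)[, c("time", nodes)],
                              -"time", names_to = "node",
                              values_to = "level")
  long$node <- factor(long$node, levels = nodes)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$level,
                                     colour = .data$node)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (dimensionless units)", y = "expression level",
                  colour = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}

#' @rdname plot_trajectory_heatmap
#' @param object A `fz_trajectory`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.fz_trajectory <- function(object, ...) {
  plot_trajectory_heatmap(object)
}
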