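#' Plot methods
#'
#' ggplot2 views of the main result types: a stacked-area clonal prevalence
#' plot (fishplot-style, own fractions), mutation frequency trajectories, a
#' zygosity evolution bar chart, and a node-link clone tree. All return a
#' ggplot object for further styling.
#'
#' @param object,x A result object from this package.
#' @param ... Ignored.
#' @name clonearch-plots
NULL

#' @rdname clonearch-plots
#' @export
autoplot.prevalence_table <- function(object, ...) {
  df <- dplyr::filter(object, .data$observed)
  ggplot2::ggplot(df, ggplot2::aes(x = as.integer(.data$timepoint), y = .data$own_fraction,
                                   fill = .data$clone)) +
    ggplot2::geom_area(position = "stack", color = "grey30", linewidth = 0.2) +
    ggplot2::scale_x_continuous(breaks = seq_along(levels(object$timepoint)),
                                labels = levels(object$timepoint)) +
    ggplot2::labs(x = "timepoint", y = "clone prevalence", fill = "clone") +
    ggplot2::theme_minimal()
}

#' @rdname clonearch-plots
#' @export
autoplot.trajectory_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$timepoint, y = .data$mutated_fraction,
                                       color = stats::reorder(.data$mutation, .data$rank),
                                       group = .data$mutation)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "timepoint", y = "mutated-cell fraction", color = "mutation") +
    ggplot2::theme_minimal()
}

#' @rdname clonearch-plots
#' @param gm A [genotype_matrix()].
#' @param mutation Mutation id.
#' @export
plot_zygosity_evolution <- function(gm, mutation) {
  df <- zygosity_evolution(gm, mutation) |> dplyr::filter(.data$state != "MISSING")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$prop_called,
                                   fill = .data$state)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(title = mutation, x = "timepoint", y = "fraction of called cells",
                  fill = "zygosity") +
    ggplot2::theme_minimal()
}

# simple layered layout: x = number of events (depth), y spreads leaves
tree_layout <- function(tree) {
  children <- split(tree$edges$child, tree$edges$parent)
  y <- list(); counter <- 0
  assign_y <- function(label) {
    kids <- children[[label]]
    if (is.null(kids)) {
      counter <<- counter + 1
      y[[label]] <<- counter
    } else {
      for (k in kids) assign_y(k)
      y[[label]] <<- mean(unlist(y[kids]))
    }
  }
  assign_y(tree$root)
  depth <- stats::setNames(tree$nodes$n_events, tree$nodes$label)
  tibble::tibble(label = names(y), x = unname(depth[names(y)]), y = unlist(y))
}

#' @rdname clonearch-plots
#' @export
autoplot.clone_tree <- function(object, ...) {
  lay <- tree_layout(object)
  seg <- object$edges |>
    dplyr::left_join(lay, by = c(parent = "label")) |>
    dplyr::left_join(lay, by = c(child = "label"), suffix = c("", "_child"))
  nodes <- dplyr::left_join(object$nodes, lay, by = "label")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg, ggplot2::aes(x = .data$x, y = .data$y,
                                                   xend = .data$x_child, yend = .data$y_child),
                          color = "grey50") +
    ggplot2::geom_text(data = seg, ggplot2::aes(x = (.data$x + .data$x_child) / 2,
                                                y = (.data$y + .data$y_child) / 2 + 0.15,
                                                label = .data$event), size = 3) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                                   shape = .data$observed), size = 3) +
    ggplot2::geom_text(data = nodes, ggplot2::aes(x = .data$x, y = .data$y - 0.2,
                                                  label = .data$label), size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "events since founder", y = NULL, shape = "observed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' @rdname clonearch-plots
#' @export
plot.clone_tree <- function(x, ...) print(autoplot.clone_tree(x, ...))
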