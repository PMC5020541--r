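#' Plot methods
#'
#' `autoplot()` methods give a quick ggplot2 view of each result type:
#' a stacked topic-proportion bar chart for `topic_model`, a force-directed
#' tree layout for `cell_tree`, and the same layout with role-scaled nodes
#' for `backbone_tree` (backbone cells drawn large, vertebrae small).
#'
#' @param object The object to plot.
#' @param groups Optional named group labels used to colour cells.
#' @param d Distance matrix (required for `backbone_tree`, to place
#'   vertebrae).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-topictree
NULL

#' @rdname autoplot-topictree
#' @export
autoplot.topic_model <- function(object, groups = NULL, ...) {
  tab <- tidy.topic_model(object)
  if (!is.null(groups)) tab$group <- unname(groups[tab$cell_id])
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$cell_id,
                                         y = .data$proportion,
                                         fill = factor(.data$topic))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "cell", y = "topic proportion", fill = "topic") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(groups))
    p <- p + ggplot2::facet_grid(~group, scales = "free_x", space = "free_x")
  p
}

tree_layout_tbl <- function(g) {
  xy <- igraph::layout_with_kk(g)
  tibble::tibble(cell_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

#' @rdname autoplot-topictree
#' @export
autoplot.cell_tree <- function(object, groups = NULL, ...) {
  g <- tree_igraph(object)
  lay <- tree_layout_tbl(g)
  seg <- object$edges |>
    dplyr::left_join(lay, by = c(from = "cell_id")) |>
    dplyr::left_join(lay, by = c(to = "cell_id"), suffix = c("", "_to"))
  lay$group <- if (!is.null(groups)) unname(groups[lay$cell_id]) else "cell"
  lay$is_root <- !is.na(object$root) & lay$cell_id == object$root
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_to, yend = .data$y_to),
                          colour = "grey60") +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group,
                                     shape = .data$is_root), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_void()
}

#' @rdname autoplot-topictree
#' @export
autoplot.backbone_tree <- function(object, d = NULL, groups = NULL, ...) {
  g <- backbone_igraph(object, d)
  lay <- tree_layout_tbl(g)
  roles <- tidy.backbone_tree(object)
  lay <- dplyr::left_join(lay, roles, by = "cell_id")
  ed <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
  seg <- ed |>
    dplyr::left_join(lay, by = c(from = "cell_id")) |>
    dplyr::left_join(lay, by = c(to = "cell_id"), suffix = c("", "_to"))
  lay$group <- if (!is.null(groups)) unname(groups[lay$cell_id]) else lay$role
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_to, yend = .data$y_to),
                          colour = "grey60") +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group,
                                     size = .data$role == "backbone")) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 1.5, `TRUE` = 4),
                               guide = "none") +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_void()
}

#' Plot the topic-count selection scan
#'
#' @param scores Tibble from [select_topic_count()]`$scores`.
#' @return A ggplot object.
#' @export
plot_topic_selection <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$K, y = .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "penalised log posterior") +
    ggplot2::theme_minimal()
}
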