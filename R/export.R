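#' Export a cell tree
#'
#' Trees are written as a 3-column TSV edge list (`child`, `parent`,
#' `weight`; parent = the endpoint nearer the root, or the `from` column
#' verbatim for unrooted trees), GraphML, or DOT.
#'
#' @param t A [cell_tree()].
#' @param path Output file.
#' @export
write_tree_tsv <- function(t, path) {
  ed <- t$edges
  if (!is.na(t$root)) {
    g <- tree_igraph(t)
    dist <- igraph::distances(g, v = t$root, weights = igraph::E(g)$weight)[1, ]
    child_first <- dist[ed$from] >= dist[ed$to]
    ed <- tibble::tibble(child = ifelse(child_first, ed$from, ed$to),
                         parent = ifelse(child_first, ed$to, ed$from),
                         weight = ed$weight)
  } else names(ed) <- c("child", "parent", "weight")
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_tsv
#' @export
write_tree_graphml <- function(t, path) {
  igraph::write_graph(tree_igraph(t), path, format = "graphml")
  invisible(path)
}

#' @rdname write_tree_tsv
#' @export
write_tree_dot <- function(t, path) {
  igraph::write_graph(tree_igraph(t), path, format = "dot")
  invisible(path)
}

#' Export an ordering as a two-column TSV (rank, cell_id)
#' @param ordering Tibble from [ordering_from_tree()] or
#'   [tsp_baseline_ordering()].
#' @param path Output file.
#' @export
write_ordering_tsv <- function(ordering, path) {
  utils::write.table(ordering[, c("rank", "cell_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

backbone_igraph <- function(t, d = NULL) {
  ed <- t$backbone_edges
  if (length(t$attachments)) {
    w <- if (!is.null(d)) {
      dd <- as_dist_matrix(d)
      dd[cbind(names(t$attachments), unname(t$attachments))]
    } else rep(NA_real_, length(t$attachments))
    ed <- dplyr::bind_rows(ed, tibble::tibble(
      from = names(t$attachments), to = unname(t$attachments), weight = w))
  }
  roles <- tidy.backbone_tree(t)
  igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = setdiff(t$cell_ids, t$outliers)) |>
      merge(roles, by.x = "name", by.y = "cell_id"))
}

#' Export a backbone tree
#'
#' TSV columns: `cell_id`, `role` (backbone/vertebra/outlier), `attachment`,
#' `distance_to_attachment`. DOT/GraphML exports carry the role as a vertex
#' attribute (outliers, having no edges, appear only in the TSV).
#'
#' @param t A [backbone_tree()].
#' @param d Cell distance matrix (for attachment distances).
#' @param path Output file.
#' @export
write_backbone_tsv <- function(t, d, path) {
  d <- as_dist_matrix(d)
  tab <- tidy.backbone_tree(t) |>
    dplyr::mutate(distance_to_attachment = ifelse(
      is.na(.data$attachment), NA_real_,
      d[cbind(.data$cell_id, .data$attachment)]))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_backbone_tsv
#' @export
write_backbone_dot <- function(t, d, path) {
  igraph::write_graph(backbone_igraph(t, d), path, format = "dot")
  invisible(path)
}

#' @rdname write_backbone_tsv
#' @export
write_backbone_graphml <- function(t, d, path) {
  igraph::write_graph(backbone_igraph(t, d), path, format = "graphml")
  invisible(path)
}

#' Export an enrichment table as TSV
#' @param tab Tibble from [enrich_topics()].
#' @param path Output file.
#' @export
write_enrichment_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
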