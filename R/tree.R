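#' Cell tree container
#'
#' A spanning tree over cells: a tibble of weighted edges plus an optional
#' root. Built by [minimum_spanning_tree()] and rooted by [root_by_diameter()].
#'
#' @param edges Tibble or data frame with columns `from`, `to`, `weight`.
#' @param cell_ids Character vector of all vertices.
#' @param root Optional root cell id.
#' @return A `cell_tree`.
#' @export
cell_tree <- function(edges, cell_ids, root = NA_character_) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (!is.na(root) && !root %in% cell_ids)
    rlang::abort("root is not a vertex of the tree",
                 class = "topictree_value_error")
  if (nrow(edges) != length(cell_ids) - 1L)
    rlang::abort("a tree on M vertices needs M - 1 edges",
                 class = "topictree_value_error")
  structure(list(edges = edges, cell_ids = cell_ids, root = root),
            class = "cell_tree")
}

#' @export
print.cell_tree <- function(x, ...) {
  cat("<cell_tree> ", length(x$cell_ids), " cells, total weight ",
      signif(sum(x$edges$weight), 6),
      if (!is.na(x$root)) paste0(", root ", x$root), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.topic_model
#' @export
tidy.cell_tree <- function(x, ...) x$edges

tree_igraph <- function(t) {
  igraph::graph_from_data_frame(
    t$edges, directed = FALSE,
    vertices = data.frame(name = t$cell_ids, stringsAsFactors = FALSE))
}

#' Minimum spanning tree over a cell distance matrix
#'
#' Kruskal's algorithm with a stable lexicographic edge sort (weight, then
#' both endpoint ids), so ties resolve identically on every platform.
#'
#' @param d Symmetric distance matrix with cell ids as dimnames.
#' @return An unrooted [cell_tree()].
#' @export
minimum_spanning_tree <- function(d) {
  d <- as_dist_matrix(d)
  ids <- rownames(d)
  M <- length(ids)
  if (M == 1L)
    return(cell_tree(tibble::tibble(from = character(), to = character(),
                                    weight = numeric()), ids))
  pair <- which(upper.tri(d), arr.ind = TRUE)
  ed <- tibble::tibble(from = ids[pair[, 1]], to = ids[pair[, 2]],
                       weight = d[pair])
  # canonical endpoint order within each edge, then lexicographic sort
  swap <- ed$from > ed$to
  tmp <- ed$from[swap]; ed$from[swap] <- ed$to[swap]; ed$to[swap] <- tmp
  ed <- ed[order(ed$weight, ed$from, ed$to), ]
  parent <- stats::setNames(seq_len(M), ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  keep <- logical(nrow(ed))
  n_used <- 0L
  idx <- stats::setNames(seq_len(M), ids)
  for (e in seq_len(nrow(ed))) {
    a <- find(idx[[ed$from[e]]]); b <- find(idx[[ed$to[e]]])
    if (a != b) { parent[a] <- b; keep[e] <- TRUE; n_used <- n_used + 1L }
    if (n_used == M - 1L) break
  }
  cell_tree(ed[keep, ], ids)
}

#' Root a tree at one end of its diameter path
#'
#' Finds the longest weighted shortest path in the tree (its diameter) and
#' roots the tree at the diameter endpoint whose mean distance (in `d`) to the
#' start-group cells is smaller; ties break lexicographically. Suited to
#' populations forming a linear continuum.
#'
#' @param t An unrooted [cell_tree()].
#' @param d The cell distance matrix.
#' @param start_group Character vector of cell ids believed to start the
#'   process (e.g. the earliest time point).
#' @return The tree with `root` set.
#' @export
root_by_diameter <- function(t, d, start_group) {
  d <- as_dist_matrix(d)
  if (!length(start_group))
    rlang::abort("empty start group", class = "topictree_value_error")
  if (!any(start_group %in% t$cell_ids))
    rlang::abort("start group disjoint from tree cells",
                 class = "topictree_key_error")
  start_group <- intersect(start_group, t$cell_ids)
  g <- tree_igraph(t)
  dm <- igraph::distances(g, weights = igraph::E(g)$weight)
  diam <- max(dm)
  cand <- which(dm == diam, arr.ind = TRUE)
  nm <- rownames(dm)
  # deterministic diameter pair: lexicographically smallest (a, b)
  ab <- cbind(nm[cand[, 1]], nm[cand[, 2]])
  ab <- t(apply(ab, 1, sort))
  ab <- ab[order(ab[, 1], ab[, 2]), , drop = FALSE]
  ends <- sort(ab[1, ])
  mean_to_group <- vapply(ends, function(v)
    mean(d[v, start_group]), numeric(1))
  root <- ends[order(mean_to_group, ends)][1]
  t$root <- root
  t
}

#' Most central cell of a group
#'
#' Returns the group member minimising the mean *squared* chi-square distance
#' to the other members; a singleton group returns its element. Suited to
#' rooting when branching is expected.
#'
#' @param d Cell distance matrix.
#' @param start_group Non-empty character vector of cell ids.
#' @return A single cell id.
#' @export
root_by_centrality <- function(d, start_group) {
  d <- as_dist_matrix(d)
  if (!length(start_group))
    rlang::abort("empty start group", class = "topictree_value_error")
  missing <- setdiff(start_group, rownames(d))
  if (length(missing))
    rlang::abort("start group names unknown cells",
                 class = "topictree_key_error")
  if (length(start_group) == 1L) return(start_group)
  msq <- vapply(start_group, function(g)
    mean(d[g, setdiff(start_group, g)]^2), numeric(1))
  start_group[order(msq, start_group)][1]
}

#' Detect the starting group of a trajectory
#'
#' Picks the group label with the lowest mean pairwise intra-group distance,
#' on the assumption that population variance grows as the underlying process
#' unfolds. Ties go to the lexicographically smallest label.
#'
#' @param d Cell distance matrix.
#' @param groups Named character vector mapping cell id to group label; every
#'   group needs at least 2 members.
#' @return The selected group label.
#' @export
detect_start_group <- function(d, groups) {
  d <- as_dist_matrix(d)
  labs <- sort(unique(unname(groups)))
  if (length(labs) < 2)
    rlang::abort("need at least 2 groups", class = "topictree_config_error")
  sizes <- table(groups)
  if (any(sizes < 2))
    rlang::abort("every group needs >= 2 members for an intra-group distance",
                 class = "topictree_config_error")
  intra <- vapply(labs, function(l) {
    cells <- names(groups)[groups == l]
    sub <- d[cells, cells]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  labs[order(intra, labs)][1]
}

#' Order cells by tree path distance from the root
#'
#' A pseudotime proxy: every cell is ranked by its weighted path distance from
#' the root along the tree, ties broken by cell id.
#'
#' @param t A rooted [cell_tree()] (or a `backbone_tree`, whose full tree --
#'   backbone edges plus vertebra attachments -- is used; outliers are placed
#'   last, ordered by their distance to the nearest backbone vertex).
#' @return A tibble with columns `rank`, `cell_id`, `distance`.
#' @export
ordering_from_tree <- function(t) {
  if (inherits(t, "backbone_tree")) return(ordering_from_backbone(t))
  if (is.na(t$root))
    rlang::abort("tree is not rooted", class = "topictree_state_error")
  g <- tree_igraph(t)
  dist <- igraph::distances(g, v = t$root, weights = igraph::E(g)$weight)[1, ]
  ids <- names(dist)[order(dist, names(dist))]
  tibble::tibble(rank = seq_along(ids), cell_id = ids,
                 distance = unname(dist[ids]))
}

#' Pairwise ordering accuracy against a reference ordering
#'
#' The percentage of unordered cell pairs whose relative order agrees between
#' a candidate ordering and the reference. Reference ties (cells sharing a
#' group label / rank) are excluded from the denominator, and the candidate is
#' reversed when that raises the score, so a perfectly reversed ordering also
#' scores 100.
#'
#' @param candidate Character vector of cell ids in candidate order, or a
#'   tibble with a `cell_id` column (e.g. from [ordering_from_tree()]).
#' @param truth Either a character vector of cell ids in true order (strict
#'   ranks), or a data frame with columns `cell_id` and `rank` where equal
#'   ranks mark ties.
#' @return Accuracy in percent (50-100 for strict references).
#' @export
pairwise_ordering_accuracy <- function(candidate, truth) {
  if (is.data.frame(candidate)) candidate <- candidate$cell_id
  if (is.data.frame(truth)) {
    tr <- stats::setNames(as.numeric(truth$rank), truth$cell_id)
  } else {
    tr <- stats::setNames(seq_along(truth), truth)
  }
  if (!setequal(candidate, names(tr)) ||
      length(candidate) != length(tr))
    rlang::abort("candidate and truth must contain the same cells",
                 class = "topictree_value_error")
  r1 <- seq_along(candidate)
  r2 <- unname(tr[candidate])
  s1 <- sign(outer(r1, r1, "-"))
  s2 <- sign(outer(r2, r2, "-"))
  ut <- upper.tri(s1)
  comparable <- s2[ut] != 0
  n_comp <- sum(comparable)
  if (n_comp == 0)
    rlang::abort("no comparable pairs in the reference",
                 class = "topictree_value_error")
  agree_fwd <- sum((s1[ut] == s2[ut])[comparable])
  100 * max(agree_fwd, n_comp - agree_fwd) / n_comp
}

#' Travelling-salesman baseline ordering
#'
#' Builds a tour by nearest-neighbour construction followed by 2-opt
#' improvement until no swap shortens it, rotates the tour so the most central
#' start-group cell leads, and orients it so start-group cells sit early. This
#' is the naive baseline the tree-based orderings are compared against.
#'
#' @param d Distance matrix (typically euclidean distances on log expression,
#'   but any cell distance matrix works).
#' @param start_group Character vector of start-group cell ids.
#' @param seed Integer seed for the nearest-neighbour starting cell.
#' @return A tibble with columns `rank`, `cell_id`.
#' @export
tsp_baseline_ordering <- function(d, start_group, seed = 1L) {
  d <- as_dist_matrix(d)
  ids <- rownames(d)
  M <- length(ids)
  if (M == 1L) return(tibble::tibble(rank = 1L, cell_id = ids))
  set.seed(seed)
  start <- sample.int(M, 1L)
  # nearest-neighbour tour
  tour <- integer(M); used <- logical(M)
  tour[1] <- start; used[start] <- TRUE
  for (i in seq(2, M)) {
    prev <- tour[i - 1]
    cand <- which(!used)
    nxt <- cand[order(d[prev, cand], ids[cand])][1]
    tour[i] <- nxt; used[nxt] <- TRUE
  }
  tour_len <- function(tr) sum(d[cbind(tr, c(tr[-1], tr[1]))])
  # 2-opt: first-improvement scans until a full pass finds nothing
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(M - 1)) {
      for (j in seq(i + 1, M)) {
        a <- tour[i]; b <- tour[if (i == 1) M else i - 1]
        c_ <- tour[j]; e <- tour[if (j == M) 1 else j + 1]
        if (i == 1 && j == M) next
        delta <- d[b, c_] + d[a, e] - d[b, a] - d[c_, e]
        if (delta < -1e-12) {
          tour[i:j] <- rev(tour[i:j])
          improved <- TRUE
        }
      }
    }
  }
  lead <- root_by_centrality(d, intersect(start_group, ids))
  pos <- which(ids[tour] == lead)
  tour <- c(tour[pos:M], tour[seq_len(pos - 1)])
  # orient so start-group cells come early
  grp_pos <- which(ids[tour] %in% start_group)
  rev_tour <- c(tour[1], rev(tour[-1]))
  grp_pos_rev <- which(ids[rev_tour] %in% start_group)
  if (mean(grp_pos_rev) < mean(grp_pos)) tour <- rev_tour
  tibble::tibble(rank = seq_len(M), cell_id = ids[tour])
}
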