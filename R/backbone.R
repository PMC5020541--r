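#' Backbone tree container
#'
#' A condensed tree over cells: a small "backbone" subtree of representative
#' cells, with every remaining cell either attached as a "vertebra" to its
#' nearest backbone vertex within distance `delta`, or declared an outlier.
#'
#' @param backbone_vertices Character vector of backbone cell ids.
#' @param backbone_edges Tibble (`from`, `to`, `weight`) forming a tree over
#'   the backbone vertices.
#' @param attachments Named character vector: vertebra cell id -> backbone
#'   cell id.
#' @param outliers Character vector of outlier cell ids.
#' @param delta Backbone width (maximum vertebra-to-backbone distance).
#' @param cell_ids All cell ids (the partition backbone/vertebrae/outliers
#'   must cover them exactly).
#' @param root Optional root, a backbone vertex.
#' @return A `backbone_tree`.
#' @export
backbone_tree <- function(backbone_vertices, backbone_edges, attachments,
                          outliers, delta, cell_ids, root = NA_character_) {
  parts <- c(backbone_vertices, names(attachments), outliers)
  if (anyDuplicated(parts) || !setequal(parts, cell_ids))
    rlang::abort("backbone, vertebrae and outliers must partition the cells",
                 class = "topictree_value_error")
  if (!is.na(root) && !root %in% backbone_vertices)
    rlang::abort("root must be a backbone vertex",
                 class = "topictree_value_error")
  structure(list(backbone_vertices = backbone_vertices,
                 backbone_edges = tibble::as_tibble(backbone_edges),
                 attachments = attachments, outliers = outliers,
                 delta = delta, cell_ids = cell_ids, root = root,
                 objective = sum(backbone_edges$weight)),
            class = "backbone_tree")
}

#' @export
print.backbone_tree <- function(x, ...) {
  cat("<backbone_tree> ", length(x$backbone_vertices), " backbone + ",
      length(x$attachments), " vertebrae + ", length(x$outliers),
      " outliers; delta = ", signif(x$delta, 4), ", objective = ",
      signif(x$objective, 6),
      if (!is.na(x$root)) paste0(", root ", x$root), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.topic_model
#' @export
tidy.backbone_tree <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(cell_id = x$backbone_vertices, role = "backbone",
                   attachment = NA_character_),
    tibble::tibble(cell_id = names(x$attachments), role = "vertebra",
                   attachment = unname(x$attachments)),
    tibble::tibble(cell_id = x$outliers, role = "outlier",
                   attachment = NA_character_)) |>
    dplyr::arrange(.data$cell_id)
}

#' @rdname tidy.topic_model
#' @export
glance.backbone_tree <- function(x, ...) {
  tibble::tibble(n_backbone = length(x$backbone_vertices),
                 n_vertebrae = length(x$attachments),
                 n_outliers = length(x$outliers),
                 delta = x$delta, objective = x$objective, root = x$root)
}

#' Estimate the backbone width delta from the distance distribution
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth) to
#' the strict upper-triangle pairwise distances on a 512-point grid over
#' `[0, max]` and returns the smallest grid point that is a strict interior
#' local maximum carrying non-negligible mass (at least 1% of the peak
#' density, which screens out numerical ripple in empty tails) -- the first
#' mode. If the density has no interior mode the
#' 25th percentile of the distances is returned instead, with attribute
#' `method = "quantile_fallback"`.
#'
#' @param d Cell distance matrix (at least 3 cells).
#' @return The estimated delta with attribute `method` (`"first_mode"` or
#'   `"quantile_fallback"`).
#' @export
estimate_delta <- function(d) {
  d <- as_dist_matrix(d)
  if (nrow(d) < 3)
    rlang::abort("need at least 3 cells", class = "topictree_value_error")
  x <- d[upper.tri(d)]
  if (all(x == 0))
    rlang::abort("all pairwise distances are zero",
                 class = "topictree_degenerate_error")
  dens <- stats::density(x, bw = "nrd0", n = 512, from = 0, to = max(x))
  y <- dens$y
  i <- which(y[-c(1, length(y))] > y[-c(length(y) - 1, length(y))] &
               y[-c(1, length(y))] > y[-c(1, 2)] &
               y[-c(1, length(y))] > 0.01 * max(y)) + 1L
  if (length(i)) {
    structure(dens$x[i[1]], method = "first_mode", bandwidth = dens$bw)
  } else {
    structure(stats::quantile(x, 0.25, names = FALSE),
              method = "quantile_fallback", bandwidth = dens$bw)
  }
}

min_dist_to <- function(d, v, set) {
  if (!length(set)) return(Inf)
  min(d[v, set])
}

nearest_in <- function(d, v, set) {
  dv <- d[v, set]
  set[order(dv, set)][1]
}

#' Validate a backbone tree against its defining conditions
#'
#' Checks the four structural conditions: (1) the backbone is a connected,
#' acyclic subtree; (2) every vertebra is within `delta` of its attachment;
#' (3) every vertebra is attached to its *closest* backbone vertex; (4) the
#' backbone, vertebrae and outliers partition the cells and the outliers stay
#' within the allowed fraction.
#'
#' @param t A [backbone_tree()].
#' @param d Cell distance matrix.
#' @param outlier_fraction Maximum tolerated fraction of outlier cells.
#' @return A tibble with columns `condition`, `ok`, `detail`; zero `!ok`
#'   rows means the tree is valid.
#' @export
check_backbone <- function(t, d, outlier_fraction = 0.05) {
  d <- as_dist_matrix(d)
  tol <- 1e-9
  out <- list()
  vb <- t$backbone_vertices
  # 1: backbone subtree connected & acyclic
  ok1 <- nrow(t$backbone_edges) == length(vb) - 1L
  if (ok1 && length(vb) > 1) {
    g <- igraph::graph_from_data_frame(t$backbone_edges, directed = FALSE,
                                       vertices = data.frame(name = vb))
    ok1 <- igraph::is_connected(g)
  }
  out$c1 <- tibble::tibble(condition = "backbone_is_tree", ok = ok1,
                           detail = if (ok1) "" else "backbone not a spanning tree of V_B")
  # 2: vertebra within delta of attachment
  bad2 <- names(t$attachments)[vapply(names(t$attachments), function(v)
    d[v, t$attachments[[v]]] > t$delta + tol, logical(1))]
  out$c2 <- tibble::tibble(condition = "vertebra_within_delta",
                           ok = !length(bad2),
                           detail = paste(bad2, collapse = ","))
  # 3: attachment is the closest backbone vertex
  bad3 <- names(t$attachments)[vapply(names(t$attachments), function(v)
    d[v, t$attachments[[v]]] > min(d[v, vb]) + tol, logical(1))]
  out$c3 <- tibble::tibble(condition = "attached_to_nearest",
                           ok = !length(bad3),
                           detail = paste(bad3, collapse = ","))
  # 4: partition + outlier budget
  parts <- c(vb, names(t$attachments), t$outliers)
  ok4a <- !anyDuplicated(parts) && setequal(parts, t$cell_ids)
  ok4b <- length(t$outliers) / length(t$cell_ids) <= outlier_fraction + tol
  out$c4 <- tibble::tibble(condition = "partition_and_outlier_budget",
                           ok = ok4a && ok4b,
                           detail = if (ok4a && ok4b) "" else
                             if (!ok4a) "not a partition" else "outlier budget exceeded")
  dplyr::bind_rows(out)
}

# Prim weight only, for the exact solver's inner loop
mst_weight <- function(d, vb) {
  n <- length(vb)
  if (n <= 1L) return(0)
  sub <- d[vb, vb, drop = FALSE]
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  mind <- sub[1, ]
  total <- 0
  for (i in seq_len(n - 1)) {
    j <- which(!in_tree)[which.min(mind[!in_tree])]
    total <- total + mind[j]
    in_tree[j] <- TRUE
    mind <- pmin(mind, sub[j, ])
  }
  total
}

mst_over <- function(d, vb) {
  if (length(vb) <= 1L)
    return(tibble::tibble(from = character(), to = character(),
                          weight = numeric()))
  minimum_spanning_tree(d[vb, vb, drop = FALSE])$edges
}

#' Build a backbone tree by MST leaf absorption
#'
#' Heuristic for the (NP-hard) optimal backbone tree: starting from the full
#' minimum spanning tree, repeatedly pick the leaf with the heaviest incident
#' edge among leaves that can be absorbed -- as a vertebra if it lies within
#' `delta` of some remaining vertex, otherwise against the outlier budget --
#' and remove it. The surviving vertices form the backbone (re-spanned by an
#' MST over them), and every absorbed cell is attached to its nearest backbone
#' vertex. Cells left stranded beyond `delta` of the final backbone are
#' charged to the outlier budget or returned to the backbone. If condensation
#' does not beat the trivial all-backbone solution, the full MST is returned.
#'
#' @param d Cell distance matrix.
#' @param delta Backbone width, or `"auto"` to use [estimate_delta()].
#' @param outlier_fraction Maximum fraction of cells allowed at distance
#'   greater than `delta` from every backbone vertex (default 0.05).
#' @param root_hint Optional cell ids used to root the result via
#'   [root_backbone()].
#' @return A valid [backbone_tree()] (see [check_backbone()]).
#' @export
build_backbone <- function(d, delta = "auto", outlier_fraction = 0.05,
                           root_hint = NULL) {
  d <- as_dist_matrix(d)
  ids <- rownames(d)
  M <- length(ids)
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    rlang::abort("outlier_fraction must be in [0, 1)",
                 class = "topictree_value_error")
  if (identical(delta, "auto")) delta <- as.numeric(estimate_delta(d))
  budget <- floor(outlier_fraction * M)

  # cells beyond delta of every other cell simply stay in the backbone (the
  # all-backbone tree is always a valid backbone tree), so construction can
  # never be infeasible; they may still be charged to the outlier budget by
  # the greedy pass below if that lowers the objective.
  outliers <- character()
  active <- ids

  full_mst <- minimum_spanning_tree(d)
  mst_active <- full_mst$edges
  adj <- stats::setNames(vector("list", length(active)), active)
  for (e in seq_len(nrow(mst_active))) {
    a <- mst_active$from[e]; b <- mst_active$to[e]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  vertebrae <- character()
  repeat {
    if (length(active) <= 1L) break
    deg <- lengths(adj[active])
    leaves <- active[deg == 1L]
    if (!length(leaves)) break
    inc_w <- vapply(leaves, function(l) d[l, adj[[l]][1]], numeric(1))
    can_absorb <- vapply(leaves, function(l)
      min_dist_to(d, l, setdiff(active, l)) <= delta, logical(1))
    eligible <- can_absorb | (budget > 0L)
    if (!any(eligible)) break
    cand <- leaves[eligible]
    pick <- cand[order(-inc_w[eligible], cand)][1]
    nb <- adj[[pick]][1]
    adj[[nb]] <- setdiff(adj[[nb]], pick)
    adj[[pick]] <- NULL
    active <- setdiff(active, pick)
    if (min_dist_to(d, pick, active) <= delta) {
      vertebrae <- c(vertebrae, pick)
    } else {
      outliers <- c(outliers, pick)
      budget <- budget - 1L
    }
  }
  vb <- active
  # attach + repair: stranded vertebrae become outliers or rejoin the backbone
  repeat {
    stranded <- vertebrae[vapply(vertebrae, function(v)
      min_dist_to(d, v, vb) > delta, logical(1))]
    if (!length(stranded)) break
    for (v in stranded) {
      vertebrae <- setdiff(vertebrae, v)
      if (budget > 0L) {
        outliers <- c(outliers, v); budget <- budget - 1L
      } else {
        vb <- sort(c(vb, v))
      }
    }
  }
  # local descent on the backbone set: demote a backbone vertex to vertebra,
  # or swap one backbone vertex for a current vertebra, whenever the move
  # keeps every non-outlier within delta of the backbone and strictly lowers
  # the backbone MST weight; first-improvement scans in id order keep the
  # search deterministic
  covered <- function(vset, bset) {
    !length(vset) || all(vapply(vset, function(u)
      min_dist_to(d, u, bset) <= delta, logical(1)))
  }
  obj <- mst_weight(d, vb)
  repeat {
    improved <- FALSE
    for (v in sort(vb)) {
      if (length(vb) == 1L) break
      vb2 <- setdiff(vb, v)
      if (covered(c(vertebrae, v), vb2)) {
        w2 <- mst_weight(d, vb2)
        if (w2 < obj - 1e-12) {
          vb <- vb2; vertebrae <- c(vertebrae, v); obj <- w2
          improved <- TRUE
          break
        }
      }
    }
    if (improved) next
    for (v in sort(vb)) {
      for (u in sort(vertebrae)) {
        vb2 <- c(setdiff(vb, v), u)
        if (!covered(c(setdiff(vertebrae, u), v), vb2)) next
        w2 <- mst_weight(d, vb2)
        if (w2 < obj - 1e-12) {
          vb <- vb2
          vertebrae <- c(setdiff(vertebrae, u), v)
          obj <- w2
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  # a single hub covering everything (minus the outlier budget) is optimal
  if (obj > 0) {
    non_out <- setdiff(ids, outliers)
    for (v in sort(non_out)) {
      beyond <- non_out[d[v, non_out] > delta]
      beyond <- setdiff(beyond, v)
      if (length(beyond) <= budget) {
        vb <- v
        outliers <- c(outliers, beyond)
        budget <- budget - length(beyond)
        vertebrae <- setdiff(non_out, c(v, beyond))
        obj <- 0
        break
      }
    }
  }
  attachments <- stats::setNames(
    vapply(vertebrae, function(v) nearest_in(d, v, vb), character(1)),
    vertebrae)
  edges <- mst_over(d, vb)
  res <- backbone_tree(sort(vb), edges, attachments, sort(outliers),
                       delta, ids)
  if (res$objective > sum(full_mst$edges$weight) + 1e-12) {
    res <- backbone_tree(ids, full_mst$edges,
                         stats::setNames(character(), character()),
                         character(), delta, ids)
  }
  if (!is.null(root_hint)) res <- root_backbone(res, d, root_hint)
  res
}

#' Exact optimal backbone tree by exhaustive enumeration
#'
#' Enumerates every outlier set within budget and every backbone subset of
#' the remaining cells, keeps the feasible combinations (every non-backbone,
#' non-outlier cell within `delta` of some backbone vertex), spans each
#' backbone by its MST and returns the solution with minimal backbone weight.
#' Ties prefer the smaller backbone, then the lexicographically smallest
#' vertex set. Intended as a test oracle; limited to 10 cells.
#'
#' @inheritParams build_backbone
#' @param delta Backbone width (a number; no automatic estimation here).
#' @return The optimal [backbone_tree()].
#' @export
brute_force_backbone <- function(d, delta, outlier_fraction = 0.05) {
  d <- as_dist_matrix(d)
  ids <- rownames(d)
  M <- length(ids)
  if (M > 10)
    rlang::abort("exact solver is limited to 10 cells",
                 class = "topictree_size_error")
  budget <- floor(outlier_fraction * M)
  subsets_upto <- function(set, kmax) {
    out <- list(character())
    for (k in seq_len(min(kmax, length(set))))
      out <- c(out, utils::combn(set, k, simplify = FALSE))
    out
  }
  best <- NULL
  for (outl in subsets_upto(ids, budget)) {
    rest <- setdiff(ids, outl)
    if (!length(rest)) next
    for (size in seq_along(rest)) {
      for (vb in utils::combn(rest, size, simplify = FALSE)) {
        vert <- setdiff(rest, vb)
        ok <- all(vapply(vert, function(v)
          min_dist_to(d, v, vb) <= delta, logical(1)))
        if (!ok) next
        obj <- mst_weight(d, vb)
        key <- list(obj = obj, nb = length(vb),
                    id = paste(vb, collapse = "|"))
        if (is.null(best) || obj < best$key$obj - 1e-12 ||
            (abs(obj - best$key$obj) <= 1e-12 &&
             (key$nb < best$key$nb ||
              (key$nb == best$key$nb && key$id < best$key$id)))) {
          best <- list(key = key, vb = vb, vert = vert, outl = outl)
        }
      }
    }
  }
  if (is.null(best))
    rlang::abort("no feasible backbone tree at this delta and outlier budget",
                 class = "topictree_infeasible_error")
  att <- stats::setNames(
    vapply(best$vert, function(v) nearest_in(d, v, best$vb), character(1)),
    best$vert)
  backbone_tree(best$vb, mst_over(d, best$vb), att, best$outl, delta, ids)
}

#' Root a backbone tree at the most central start-group backbone vertex
#'
#' If the start group contains backbone vertices, the most central of those
#' (by [root_by_centrality()]) becomes the root; otherwise the most central
#' start-group cell is located and the root is the backbone vertex it
#' attaches to (its nearest backbone vertex).
#'
#' @param t A [backbone_tree()].
#' @param d Cell distance matrix.
#' @param start_group Character vector of start-group cell ids.
#' @return The tree with `root` set (always a backbone vertex).
#' @export
root_backbone <- function(t, d, start_group) {
  d <- as_dist_matrix(d)
  in_bb <- intersect(start_group, t$backbone_vertices)
  root <- if (length(in_bb)) {
    root_by_centrality(d, in_bb)
  } else {
    central <- root_by_centrality(d, start_group)
    nearest_in(d, central, t$backbone_vertices)
  }
  t$root <- root
  t
}

ordering_from_backbone <- function(t) {
  rlang::abort(paste0("ordering a backbone_tree needs the distance matrix; ",
                      "use backbone_ordering(t, d)"),
               class = "topictree_state_error")
}

#' Order cells of a backbone tree by path distance from its root
#'
#' Vertebrae inherit their attachment edge (weight = their distance to the
#' attachment); outliers are placed last, ordered by distance to the nearest
#' backbone vertex.
#'
#' @param t A rooted [backbone_tree()].
#' @param d Cell distance matrix.
#' @return A tibble with columns `rank`, `cell_id`, `distance`.
#' @export
backbone_ordering <- function(t, d) {
  if (is.na(t$root))
    rlang::abort("backbone tree is not rooted", class = "topictree_state_error")
  d <- as_dist_matrix(d)
  ed <- t$backbone_edges
  if (length(t$attachments))
    ed <- dplyr::bind_rows(ed, tibble::tibble(
      from = names(t$attachments), to = unname(t$attachments),
      weight = d[cbind(names(t$attachments), unname(t$attachments))]))
  inner <- setdiff(t$cell_ids, t$outliers)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = inner))
  dist <- igraph::distances(g, v = t$root, weights = igraph::E(g)$weight)[1, ]
  ids <- names(dist)[order(dist, names(dist))]
  res <- tibble::tibble(rank = seq_along(ids), cell_id = ids,
                        distance = unname(dist[ids]))
  if (length(t$outliers)) {
    od <- vapply(t$outliers, function(v)
      min_dist_to(d, v, t$backbone_vertices), numeric(1))
    ord <- t$outliers[order(od, t$outliers)]
    res <- dplyr::bind_rows(res, tibble::tibble(
      rank = nrow(res) + seq_along(ord), cell_id = ord,
      distance = max(res$distance) + od[ord]))
  }
  res
}
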