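#' Read a GMT gene-set file
#'
#' Tab-separated lines: term id, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of gene id vectors; descriptions kept in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    rlang::abort("duplicate term ids in GMT", class = "topictree_format_error")
  sets <- lapply(parts, function(p) p[-c(1, 2)])
  names(sets) <- ids
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, character(1), 2L), ids)
  sets
}

#' Write gene sets to GMT
#' @param sets Named list of gene id vectors.
#' @param path Output file.
#' @param descriptions Optional named descriptions (defaults to the ids).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(id)
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Build a gene-set DAG
#'
#' Validates acyclicity of the parent graph and propagates annotations
#' upward so that every ancestor term contains all genes of its descendants
#' (the upward-closure convention of ontology annotation).
#'
#' @param term_genes Named list: term id -> character vector of gene ids.
#' @param parents Named list: term id -> character vector of parent term ids
#'   (may be empty or omit terms with no parents).
#' @param term_meta Optional tibble with columns `term_id`, `name` and
#'   optionally `namespace`.
#' @return A `gene_set_dag` with propagated annotations, per-term depth
#'   (longest path from a parentless term) and precomputed ancestor sets.
#' @export
gene_set_dag <- function(term_genes, parents = list(), term_meta = NULL) {
  ids <- names(term_genes)
  parents <- parents[intersect(names(parents), ids)]
  parents <- lapply(parents, intersect, ids)
  parents <- parents[lengths(parents) > 0]
  edges <- if (length(parents)) {
    do.call(rbind, lapply(names(parents), function(ch)
      cbind(ch, parents[[ch]])))
  } else matrix(character(), ncol = 2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = TRUE,
    vertices = data.frame(name = ids))
  if (!igraph::is_dag(g))
    rlang::abort("term parent graph contains a cycle",
                 class = "topictree_format_error")
  topo <- names(igraph::topo_sort(g, mode = "out"))  # children before parents
  genes <- term_genes
  for (t in topo) {
    for (p in parents[[t]]) genes[[p]] <- union(genes[[p]], genes[[t]])
  }
  # ancestors (transitive parents) and depth (longest path from a root)
  ancestors <- stats::setNames(vector("list", length(ids)), ids)
  depth <- stats::setNames(integer(length(ids)), ids)
  for (t in rev(topo)) {  # parents before children
    ps <- parents[[t]]
    ancestors[[t]] <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
    depth[[t]] <- if (length(ps)) 1L + max(depth[ps]) else 0L
  }
  if (is.null(term_meta))
    term_meta <- tibble::tibble(term_id = ids, name = ids,
                                namespace = NA_character_)
  term_meta <- tibble::as_tibble(term_meta)
  if (!"namespace" %in% names(term_meta)) term_meta$namespace <- NA_character_
  structure(list(terms = term_meta, term_genes = genes, parents = parents,
                 ancestors = ancestors, depth = depth),
            class = "gene_set_dag")
}

direct_children <- function(dag, term) {
  names(dag$parents)[vapply(dag$parents, function(p) term %in% p, logical(1))]
}

#' Load a gene-set DAG from GMT + edge files
#'
#' @param gmt_path GMT file with term annotations.
#' @param edges_path Optional two-column TSV (child_id, parent_id), no header.
#' @param meta_path Optional TSV (term_id, name, namespace), no header.
#' @return A [gene_set_dag()].
#' @export
read_term_dag <- function(gmt_path, edges_path = NULL, meta_path = NULL) {
  sets <- read_gmt(gmt_path)
  parents <- list()
  if (!is.null(edges_path) && file.size(edges_path) > 0) {
    ed <- utils::read.table(edges_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    parents <- split(as.character(ed[[2]]), as.character(ed[[1]]))
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    md <- utils::read.table(meta_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    meta <- tibble::tibble(term_id = as.character(md[[1]]),
                           name = as.character(md[[2]]),
                           namespace = if (ncol(md) >= 3)
                             as.character(md[[3]]) else NA_character_)
  }
  gene_set_dag(sets, parents, meta)
}

#' Rank genes of a topic by per-topic probability
#'
#' @param m A `topic_model`.
#' @param topic Topic index in `1..K`.
#' @return A tibble (`gene_id`, `probability`) sorted by decreasing
#'   probability, ties broken by gene id; probabilities sum to 1.
#' @export
rank_genes <- function(m, topic) {
  if (topic < 1 || topic > m$K)
    rlang::abort("topic out of range", class = "topictree_value_error")
  p <- m$phi[topic, ]
  ord <- order(-p, names(p))
  tibble::tibble(gene_id = names(p)[ord], probability = unname(p[ord]))
}

#' One-sided Kolmogorov-Smirnov enrichment test for a gene set
#'
#' Tests whether the per-topic probabilities of the set's member genes are
#' stochastically greater than those of non-members, i.e. whether the set
#' concentrates at the top of the topic's gene ranking.
#'
#' @param ranked Tibble from [rank_genes()] (columns `gene_id`,
#'   `probability`), or a named numeric score vector.
#' @param term_genes Character vector of member gene ids.
#' @param min_size Minimum members present in the universe (default 3);
#'   smaller sets return `NA` with attribute `reason = "too_small"`.
#' @param max_prop Sets covering more than this fraction of the universe
#'   return `NA` with `reason = "too_large"`; a set equal to the whole
#'   universe returns p = 1 (no contrast).
#' @return The p-value (or `NA` for skipped sets).
#' @export
ks_term_test <- function(ranked, term_genes, min_size = 3, max_prop = 0.5) {
  if (is.data.frame(ranked)) {
    scores <- stats::setNames(ranked$probability, ranked$gene_id)
  } else scores <- ranked
  members <- intersect(names(scores), term_genes)
  nonmembers <- setdiff(names(scores), members)
  if (!length(nonmembers)) return(1)
  if (length(members) < min_size)
    return(structure(NA_real_, reason = "too_small"))
  if (length(members) > max_prop * length(scores))
    return(structure(NA_real_, reason = "too_large"))
  suppressWarnings(
    stats::ks.test(scores[members], scores[nonmembers],
                   alternative = "less")$p.value)
}

#' Gene-set enrichment of one topic with DAG decorrelation
#'
#' Ranks the topic's genes by probability and KS-tests every sufficiently
#' large term. `method = "classic"` tests terms independently;
#' `"elim"` walks the DAG deepest-first and removes the genes of any term
#' found significant (raw p below `sig_threshold`) from all of its ancestors
#' before they are tested; `"weight"` compares each term against its direct
#' children and, where a child is the more significant (raw p-value ratio
#' below 1), discounts the child's genes from the term and its ancestors
#' before recording the term's p-value. On a DAG without edges all three
#' methods coincide. Bonferroni correction is applied per topic over the
#' terms actually tested.
#'
#' @param m A `topic_model`.
#' @param topic Topic index.
#' @param dag A [gene_set_dag()].
#' @param method `"classic"`, `"elim"` or `"weight"`.
#' @param sig_threshold Raw-p threshold driving elim's gene removal
#'   (default 0.01).
#' @param min_size,max_prop Term size filters (see [ks_term_test()]).
#' @return A tibble (`topic`, `term_id`, `name`, `p_raw`, `p_bonferroni`,
#'   `n_genes_in_term`, `method`), one row per tested term.
#' @export
enrich_topic <- function(m, topic, dag, method = c("classic", "elim", "weight"),
                         sig_threshold = 0.01, min_size = 3, max_prop = 0.5) {
  method <- match.arg(method)
  ranked <- rank_genes(m, topic)
  scores <- stats::setNames(ranked$probability, ranked$gene_id)
  universe <- names(scores)
  work <- lapply(dag$term_genes, intersect, universe)
  ord <- names(sort(dag$depth[names(work)], decreasing = TRUE))
  ks <- function(genes) ks_term_test(scores, genes, min_size, max_prop)
  p <- stats::setNames(rep(NA_real_, length(work)), names(work))
  n_tested <- stats::setNames(rep(NA_integer_, length(work)), names(work))
  if (method == "classic") {
    for (t in names(work)) { p[t] <- ks(work[[t]]); n_tested[t] <- length(work[[t]]) }
  } else if (method == "elim") {
    for (t in ord) {
      p[t] <- ks(work[[t]]); n_tested[t] <- length(work[[t]])
      if (!is.na(p[t]) && p[t] < sig_threshold) {
        for (a in dag$ancestors[[t]])
          work[[a]] <- setdiff(work[[a]], work[[t]])
      }
    }
  } else {
    for (t in ord) {
      p0 <- ks(work[[t]])
      kids <- direct_children(dag, t)
      sig_kids <- kids[!is.na(p[kids]) & !is.na(p0) & p[kids] < p0]
      if (length(sig_kids)) {
        drop <- unique(unlist(work[sig_kids], use.names = FALSE))
        for (a in c(t, dag$ancestors[[t]]))
          work[[a]] <- setdiff(work[[a]], drop)
        p0 <- ks(work[[t]])
      }
      p[t] <- p0; n_tested[t] <- length(work[[t]])
    }
  }
  tested <- names(p)[!is.na(p)]
  m_tests <- length(tested)
  meta <- stats::setNames(dag$terms$name, dag$terms$term_id)
  tibble::tibble(topic = as.integer(topic), term_id = tested,
                 name = unname(meta[tested]),
                 p_raw = unname(p[tested]),
                 p_bonferroni = pmin(1, m_tests * unname(p[tested])),
                 n_genes_in_term = unname(n_tested[tested]),
                 method = method) |>
    dplyr::arrange(.data$p_raw, .data$term_id)
}

#' Enrich every topic and flag topic-unique terms
#'
#' @inheritParams enrich_topic
#' @param alpha Significance level on the Bonferroni-corrected p-values.
#' @return The row-bound [enrich_topic()] tables with uniqueness flags (see
#'   [partition_unique_terms()]).
#' @export
enrich_topics <- function(m, dag, method = c("classic", "elim", "weight"),
                          sig_threshold = 0.01, alpha = 0.05,
                          min_size = 3, max_prop = 0.5) {
  method <- match.arg(method)
  tab <- purrr::map_dfr(seq_len(m$K), function(k)
    enrich_topic(m, k, dag, method, sig_threshold, min_size, max_prop))
  partition_unique_terms(tab, alpha)
}

#' Flag terms unique to one topic or shared by a minority
#'
#' A term significant (Bonferroni-corrected p below `alpha`) in exactly one
#' topic is `unique_to_topic` there; a term significant in at least one but
#' strictly fewer than half of the topics is `in_minority` (terms enriched in
#' half or more of the topics are excluded from that list).
#'
#' @param tables Row-bound [enrich_topic()] output covering >= 2 topics.
#' @param alpha Significance level on `p_bonferroni`.
#' @return `tables` with added columns `significant`, `n_topics_significant`,
#'   `unique_to_topic`, `in_minority`.
#' @export
partition_unique_terms <- function(tables, alpha = 0.05) {
  K <- length(unique(tables$topic))
  tables |>
    dplyr::mutate(significant = .data$p_bonferroni < alpha) |>
    dplyr::group_by(.data$term_id) |>
    dplyr::mutate(n_topics_significant = sum(.data$significant)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      unique_to_topic = .data$significant & .data$n_topics_significant == 1L,
      in_minority = .data$significant & .data$n_topics_significant >= 1L &
        .data$n_topics_significant < K / 2)
}
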