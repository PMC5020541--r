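#' Pipeline configuration
#'
#' Collects every user-settable parameter of the pipeline with its default.
#' Configurations round-trip through [save_config()] / [load_config()] and a
#' run with the same configuration and seed reproduces identical outputs.
#'
#' @param input Path to an expression matrix file, or `NULL` to simulate a
#'   trajectory with [generate_trajectory()].
#' @param format Input format (`"tsv"`, `"csv"`, `"mtx"`).
#' @param groups Path to a two-column cell-group TSV, or `NULL`.
#' @param sd_threshold,log_base Pre-treatment parameters (see [pretreat()]).
#' @param topics `"auto"` (scan `k_min..k_max`) or a fixed integer K.
#' @param k_min,k_max Scan range for automatic topic selection.
#' @param alpha,beta LDA priors (`NULL` = defaults of [fit_lda()]).
#' @param sweeps,burn_in,thin Gibbs schedule.
#' @param rooting `"diameter"` or `"centrality"`.
#' @param start_group `"auto"` (detect from group labels) or a group label.
#' @param delta `"auto"` or a numeric backbone width.
#' @param outlier_fraction Backbone outlier budget.
#' @param gene_sets Path to a GMT file, or `NULL` to skip enrichment (for
#'   simulated input the planted anchor sets are used).
#' @param dag_edges Path to a child-parent term edge TSV, or `NULL`.
#' @param enrich_method `"classic"`, `"elim"` or `"weight"`.
#' @param sig_threshold,sig_alpha Enrichment thresholds.
#' @param sim_M,sim_V,sim_K,sim_branches,sim_tokens,sim_noise Simulation
#'   parameters used when `input` is `NULL`.
#' @param seed Master seed for every stochastic stage.
#' @param output_dir Directory for the artefacts and manifest.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` (a named list).
#' @export
run_config <- function(input = NULL, format = "tsv", groups = NULL,
                       sd_threshold = 0.5, log_base = 2,
                       topics = "auto", k_min = 2, k_max = 10,
                       alpha = NULL, beta = NULL,
                       sweeps = 800, burn_in = 200, thin = 10,
                       rooting = "diameter", start_group = "auto",
                       delta = "auto", outlier_fraction = 0.05,
                       gene_sets = NULL, dag_edges = NULL,
                       enrich_method = "weight", sig_threshold = 0.01,
                       sig_alpha = 0.05,
                       sim_M = 80, sim_V = 400, sim_K = 3, sim_branches = 1,
                       sim_tokens = 1500, sim_noise = 0.2,
                       seed = 1, output_dir = tempfile("topictree_run_"),
                       log_level = "info") {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration as a flat key=value file
#'
#' The output directory is deliberately not stored: a configuration file
#' describes the run parameters, and re-loading it sets `output_dir` to the
#' directory the file sits in, so runs into different directories from the
#' same configuration are byte-identical.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @export
save_config <- function(cfg, path) {
  cfg <- cfg[setdiff(names(cfg), "output_dir")]
  enc <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.null(v)) "NULL" else paste0(class(v)[1], ":", paste(v, collapse = ","))
  }, character(1))
  writeLines(paste0(names(cfg), "=", enc), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  cfg <- lapply(kv, function(p) {
    v <- p[2]
    if (v == "NULL") return(NULL)
    cls <- sub(":.*$", "", v)
    val <- sub("^[^:]*:", "", v)
    switch(cls, numeric = as.numeric(strsplit(val, ",")[[1]]),
           integer = as.integer(strsplit(val, ",")[[1]]),
           logical = as.logical(strsplit(val, ",")[[1]]),
           val)
  })
  names(cfg) <- vapply(kv, `[`, character(1), 1)
  cfg$output_dir <- dirname(path)
  structure(cfg[names(formals(run_config))], class = "run_config")
}

log_stage <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message(format(Sys.time(), "%H:%M:%S"), " [topictree] ", ...)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Reads (or simulates) expression data, pre-treats and discretises it, fits
#' the topic model (with automatic topic-count selection unless fixed),
#' computes the chi-square distance matrix, builds and roots the minimum
#' spanning tree and the backbone tree, extracts the cell ordering, runs
#' gene-set enrichment when gene sets are available, and writes every
#' artefact plus a checksum manifest to `cfg$output_dir`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results (`model`, `dist`,
#'   `mst`, `backbone`, `ordering`, `enrichment`, `truth` if simulated) and
#'   `manifest` (tibble `file`, `md5`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  run_stage <- function(name, expr) {
    log_stage(cfg, "stage ", name)
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline failed at stage '", name, "': ",
                          conditionMessage(e)),
                   class = "topictree_pipeline_error", parent = e)
    })
  }
  save_config(cfg, file.path(cfg$output_dir, "config.txt"))

  truth <- NULL
  counts <- run_stage("input", {
    if (is.null(cfg$input)) {
      sim <- generate_trajectory(M = cfg$sim_M, V = cfg$sim_V, K = cfg$sim_K,
                                 branches = cfg$sim_branches,
                                 tokens_per_cell = cfg$sim_tokens,
                                 noise = cfg$sim_noise, seed = cfg$seed)
      truth <- sim$truth
      res$truth <- truth
      sim$counts
    } else {
      expr <- read_expression(cfg$input, cfg$format, cfg$groups)
      discretise(pretreat(expr, cfg$sd_threshold, cfg$log_base))
    }
  })
  groups <- if (!is.null(truth)) truth$groups else {
    if (!is.null(cfg$groups)) {
      gdf <- utils::read.table(cfg$groups, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
      stats::setNames(as.character(gdf[[2]]), as.character(gdf[[1]]))
    } else NULL
  }

  model <- run_stage("fit", {
    args <- list(counts = counts, seed = cfg$seed, sweeps = cfg$sweeps,
                 burn_in = cfg$burn_in, thin = cfg$thin)
    if (!is.null(cfg$alpha)) args$alpha <- cfg$alpha
    if (!is.null(cfg$beta)) args$beta <- cfg$beta
    if (identical(cfg$topics, "auto")) {
      sel <- do.call(select_topic_count,
                     c(list(counts = counts, k_min = cfg$k_min,
                            k_max = cfg$k_max, seed = cfg$seed,
                            sweeps = cfg$sweeps, burn_in = cfg$burn_in,
                            thin = cfg$thin),
                       if (!is.null(cfg$alpha)) list(alpha = cfg$alpha),
                       if (!is.null(cfg$beta)) list(beta = cfg$beta)))
      res$selection <- sel$scores
      sel$model
    } else do.call(fit_lda, c(args, list(K = as.integer(cfg$topics))))
  })
  res$model <- model
  write_model(model, file.path(cfg$output_dir, "model.json"))

  d <- run_stage("distances", distance_matrix(model))
  res$dist <- d

  start <- run_stage("start_group", {
    if (is.null(groups)) {
      rownames(d)  # no labels: every cell is a rooting candidate
    } else {
      lab <- if (identical(cfg$start_group, "auto"))
        detect_start_group(d, groups) else cfg$start_group
      res$start_label <- lab
      names(groups)[groups == lab]
    }
  })

  mst <- run_stage("tree", {
    t <- minimum_spanning_tree(d)
    if (identical(cfg$rooting, "centrality")) {
      t$root <- root_by_centrality(d, start)
      t
    } else root_by_diameter(t, d, start)
  })
  res$mst <- mst
  write_tree_tsv(mst, file.path(cfg$output_dir, "tree_edges.tsv"))
  write_tree_dot(mst, file.path(cfg$output_dir, "tree.dot"))
  write_tree_graphml(mst, file.path(cfg$output_dir, "tree.graphml"))

  ordering <- run_stage("ordering", ordering_from_tree(mst))
  res$ordering <- ordering
  write_ordering_tsv(ordering, file.path(cfg$output_dir, "ordering.tsv"))

  bb <- run_stage("backbone",
                  build_backbone(d, delta = cfg$delta,
                                 outlier_fraction = cfg$outlier_fraction,
                                 root_hint = start))
  res$backbone <- bb
  write_backbone_tsv(bb, d, file.path(cfg$output_dir, "backbone.tsv"))
  write_backbone_dot(bb, d, file.path(cfg$output_dir, "backbone.dot"))

  sets_path <- cfg$gene_sets
  if (is.null(sets_path) && !is.null(truth)) {
    sets_path <- file.path(cfg$output_dir, "planted_terms.gmt")
    write_gmt(truth$planted_terms, sets_path)
  }
  if (!is.null(sets_path)) {
    enr <- run_stage("enrich", {
      dag <- read_term_dag(sets_path, cfg$dag_edges)
      enrich_topics(model, dag, method = cfg$enrich_method,
                    sig_threshold = cfg$sig_threshold, alpha = cfg$sig_alpha)
    })
    res$enrichment <- enr
    write_enrichment_tsv(enr, file.path(cfg$output_dir, "enrichment.tsv"))
  }

  files <- sort(list.files(cfg$output_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$output_dir, files))))
  utils::write.table(manifest, file.path(cfg$output_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  log_stage(cfg, "done: ", nrow(manifest), " artefacts in ", cfg$output_dir)
  invisible(res)
}

#' Compare orderings against a reference
#'
#' Scores the tree-based ordering and the TSP baseline side by side with
#' [pairwise_ordering_accuracy()].
#'
#' @param run Result list from [run_pipeline()] (needs `ordering`, `dist`,
#'   and group labels through `truth` or `start`), or omit and pass parts.
#' @param truth A `synthetic_truth`, a data frame (`cell_id`, `rank`), or a
#'   character vector of cell ids in true order. For a `synthetic_truth` the
#'   reference is the stage labels in order (ties within stage excluded).
#' @param seed Seed for the TSP baseline.
#' @return A tibble (`method`, `accuracy`).
#' @export
evaluate_ordering <- function(run, truth, seed = 1L) {
  ref <- truth_to_reference(truth)
  start <- intersect(ref$cell_id[ref$rank == min(ref$rank)],
                     run$ordering$cell_id)
  tsp <- tsp_baseline_ordering(run$dist, start, seed = seed)
  tibble::tibble(
    method = c("topic_tree", "tsp_baseline"),
    accuracy = c(pairwise_ordering_accuracy(run$ordering, ref),
                 pairwise_ordering_accuracy(tsp, ref)))
}

truth_to_reference <- function(truth) {
  if (inherits(truth, "synthetic_truth")) {
    lev <- truth$group_order
    tibble::tibble(cell_id = names(truth$groups),
                   rank = match(unname(truth$groups), lev))
  } else if (is.data.frame(truth)) {
    tibble::as_tibble(truth[, c("cell_id", "rank")])
  } else {
    tibble::tibble(cell_id = truth, rank = seq_along(truth))
  }
}
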