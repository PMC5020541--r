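#' Simulate an expression count matrix along a known trajectory
#'
#' Generates data from the same generative assumptions the topic model makes:
#' each topic is a probability distribution over genes with a disjoint
#' high-mass "anchor" block (the planted gene sets), and each cell's topic
#' mixture moves along a piecewise-linear path between topic vertices of the
#' simplex as pseudotime advances. Dirichlet noise around the path grows with
#' pseudotime, so the earliest stage is the tightest -- the assumption used by
#' [detect_start_group()] holds by construction: progression along the path
#' is warped (`position = pseudotime^1.6`), keeping early cells tightly packed
#' near the first topic vertex, and the Dirichlet noise amplitude grows with
#' pseudotime. Tokens (discrete expression counts) are drawn per cell from
#' the mixture, `tokens_per_cell` each.
#'
#' With `branches > 1` the population follows a common trunk until pseudotime
#' 0.5 and then splits evenly into `branches` lineages heading to distinct
#' topic vertices (requires `K >= branches + 1`).
#'
#' @param M,V,K Number of cells, genes and topics.
#' @param branches Number of lineages (1 = linear trajectory).
#' @param tokens_per_cell Tokens drawn per cell (>= 100).
#' @param noise Dirichlet noise scale in `[0, 1)` mixed into the simplex path;
#'   the effective amount ramps from `0.25 * noise` at pseudotime 0 to `noise`
#'   at pseudotime 1.
#' @param seed Integer seed; the output is bit-identical across runs and
#'   platforms for a given seed.
#' @return A list with `counts` (a `count_matrix`) and `truth` (a
#'   `synthetic_truth`: `theta_true`, `phi_true`, `pseudotime_true`,
#'   `branch_true`, `groups` (stage labels `t0..t3` by pseudotime quartile),
#'   `group_order`, `planted_terms`, `topic_counts`, `seed`).
#' @export
generate_trajectory <- function(M = 80, V = 400, K = 3, branches = 1,
                                tokens_per_cell = 1500, noise = 0.2,
                                seed = 1L) {
  if (!(K >= branches && branches >= 1))
    rlang::abort("need K >= branches >= 1", class = "topictree_value_error")
  if (branches > 1 && K < branches + 1)
    rlang::abort("branching trajectories need K >= branches + 1",
                 class = "topictree_value_error")
  if (tokens_per_cell < 100)
    rlang::abort("tokens_per_cell must be >= 100",
                 class = "topictree_value_error")
  if (noise < 0 || noise >= 1)
    rlang::abort("noise must be in [0, 1)", class = "topictree_value_error")
  withr::local_seed(seed)
  gene_ids <- sprintf("gene_%04d", seq_len(V))
  cell_ids <- sprintf("cell_%04d", seq_len(M))

  # topics: Dirichlet(0.1) bulk with a disjoint high-mass anchor block each
  block <- max(1L, floor(V / (2 * K)))
  anchors <- lapply(seq_len(K), function(k) seq((k - 1) * block + 1, k * block))
  phi <- matrix(0, K, V, dimnames = list(paste0("topic_", seq_len(K)), gene_ids))
  for (k in seq_len(K)) {
    g <- stats::rgamma(V, shape = 0.1)
    g[anchors[[k]]] <- stats::rgamma(block, shape = 5)
    phi[k, ] <- g / sum(g)
  }
  planted <- stats::setNames(lapply(anchors, function(a) gene_ids[a]),
                             paste0("topic_", seq_len(K)))

  pseudotime <- if (M == 1) 0.5 else (seq_len(M) - 1) / (M - 1)
  branch <- rep(1L, M)
  if (branches > 1) {
    late <- which(pseudotime > 0.5)
    branch[late] <- rep_len(seq_len(branches), length(late))
  }
  vertex <- function(k) { e <- numeric(K); e[k] <- 1; e }
  warp <- 1.6  # slows early progression so the first stage is the tightest
  path_point <- function(t, b) {
    if (branches == 1) {
      s <- t^warp * (K - 1)
      j <- min(floor(s) + 1, K - 1)
      f <- s - (j - 1)
      (1 - f) * vertex(j) + f * vertex(j + 1)
    } else {
      trunk_end <- rowMeans(vapply(seq_len(branches) + 1, vertex,
                                   numeric(K)))
      if (t <= 0.5) {
        f <- (t / 0.5)^warp
        (1 - f) * vertex(1) + f * trunk_end
      } else {
        f <- ((t - 0.5) / 0.5)^warp
        (1 - f) * trunk_end + f * vertex(b + 1)
      }
    }
  }
  theta <- matrix(0, M, K, dimnames = list(cell_ids,
                                           paste0("topic_", seq_len(K))))
  for (d in seq_len(M)) {
    base <- path_point(pseudotime[d], branch[d])
    eps <- noise * (0.25 + 0.75 * pseudotime[d])
    if (eps > 0) {
      dir <- stats::rgamma(K, shape = 1)
      theta[d, ] <- (1 - eps) * base + eps * dir / sum(dir)
    } else theta[d, ] <- base
  }

  draw <- lda_generate_cpp(theta, phi, as.integer(tokens_per_cell),
                           as.numeric(seed), cell_ids)
  counts <- draw$counts
  dimnames(counts) <- list(gene_ids, cell_ids)
  topic_counts <- draw$topic_counts
  dimnames(topic_counts) <- list(cell_ids, paste0("topic_", seq_len(K)))

  stage <- pmin(floor(pseudotime * 4), 3)
  groups <- stats::setNames(paste0("t", stage), cell_ids)

  # structural guarantees of the fixture, asserted on every draw
  stopifnot(!anyDuplicated(unlist(anchors)),
            all(colSums(counts) == tokens_per_cell))
  if (noise > 0 && M >= 8) {
    disp <- function(g) {
      th <- theta[groups == g, , drop = FALSE]
      mean(stats::dist(th))
    }
    stopifnot(disp("t3") > disp("t0"))
  }

  truth <- structure(list(theta_true = theta, phi_true = phi,
                          pseudotime_true = stats::setNames(pseudotime, cell_ids),
                          branch_true = stats::setNames(branch, cell_ids),
                          groups = groups, group_order = paste0("t", 0:3),
                          planted_terms = planted,
                          topic_counts = topic_counts, seed = seed),
                     class = "synthetic_truth")
  list(counts = count_matrix(counts,
                             provenance = list(source = "generate_trajectory",
                                               seed = seed)),
       truth = truth)
}

#' Simulate an unstructured (null) count matrix
#'
#' All cells share one gene distribution; there is no trajectory, branching
#' or topic structure. Used for type-I-error calibration of the enrichment
#' tests and for degenerate-tree behaviour.
#'
#' @inheritParams generate_trajectory
#' @return A `count_matrix`.
#' @export
generate_null <- function(M = 40, V = 400, tokens_per_cell = 1000, seed = 1L) {
  withr::local_seed(seed)
  gene_ids <- sprintf("gene_%04d", seq_len(V))
  cell_ids <- sprintf("cell_%04d", seq_len(M))
  g <- stats::rgamma(V, shape = 0.1)
  phi <- matrix(g / sum(g), 1, V)
  theta <- matrix(1, M, 1)
  draw <- lda_generate_cpp(theta, phi, as.integer(tokens_per_cell),
                           as.numeric(seed), cell_ids)
  counts <- draw$counts
  dimnames(counts) <- list(gene_ids, cell_ids)
  count_matrix(counts, provenance = list(source = "generate_null", seed = seed))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$theta_true), " cells, ",
      ncol(x$phi_true), " genes, K = ", ncol(x$theta_true),
      ", branches = ", length(unique(x$branch_true)), "\n", sep = "")
  invisible(x)
}
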