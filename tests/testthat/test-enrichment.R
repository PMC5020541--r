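# a minimal hand-built topic model (only phi and K are needed for enrichment)
fake_model <- function(phi) {
  K <- nrow(phi)
  rownames(phi) <- paste0("topic_", seq_len(K))
  structure(list(phi = phi, K = K,
                 theta = matrix(1 / K, 2, K,
                                dimnames = list(c("cA", "cB"), rownames(phi)))),
            class = "topic_model")
}

graded_phi <- function(V, top = NULL, boost = 50) {
  p <- rev(seq_len(V)) + 0  # strictly decreasing in gene index
  names(p) <- sprintf("g%04d", seq_len(V))
  if (!is.null(top)) p[top] <- p[top] + boost * V
  matrix(p / sum(p), 1, V, dimnames = list(NULL, names(p)))
}

# exchangeable base scores with a boosted signal block: genes outside `top`
# carry no rank information, so removing the signal leaves a genuine null
flat_phi <- function(V, top, boost = 50, seed = 1) {
  set.seed(seed)
  p <- rgamma(V, shape = 5)
  names(p) <- sprintf("g%04d", seq_len(V))
  p[top] <- p[top] + boost * V
  matrix(p / sum(p), 1, V, dimnames = list(NULL, names(p)))
}

test_that("GMT files round-trip and agree with an independent reader", {
  skip_if_not_installed("fgsea")
  sets <- list(TERM1 = c("g1", "g2", "g3"), TERM2 = c("g2", "g9"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f, descriptions = c(TERM1 = "first", TERM2 = "second"))
  mine <- read_gmt(f)
  other <- fgsea::gmtPathways(f)
  expect_equal(mine[order(names(mine))], other[order(names(other))],
               ignore_attr = TRUE)
  expect_equal(attr(mine, "descriptions")[["TERM1"]], "first")
})

test_that("the DAG loader rejects cycles and propagates annotations upward", {
  expect_error(gene_set_dag(list(a = "g1", b = "g2"),
                            parents = list(a = "b", b = "a")),
               class = "topictree_format_error")
  dag <- gene_set_dag(
    list(root = "g0", mid = "g1", leaf = c("g2", "g3")),
    parents = list(leaf = "mid", mid = "root"))
  expect_setequal(dag$term_genes$root, c("g0", "g1", "g2", "g3"))
  expect_setequal(dag$term_genes$mid, c("g1", "g2", "g3"))
  expect_equal(unname(dag$depth[c("root", "mid", "leaf")]), c(0L, 1L, 2L))
  expect_setequal(dag$ancestors$leaf, c("mid", "root"))
})

test_that("gene ranking sorts by probability with lexicographic ties", {
  phi <- rbind(c(0.5, 0.2, 0.3), c(1 / 3, 1 / 3, 1 / 3))
  colnames(phi) <- c("gB", "gC", "gA")
  m <- fake_model(phi)
  r1 <- rank_genes(m, 1)
  expect_equal(r1$gene_id, c("gB", "gA", "gC"))
  expect_equal(sum(r1$probability), 1)
  r2 <- rank_genes(m, 2)
  expect_equal(r2$gene_id, c("gA", "gB", "gC"))  # uniform: ties lexicographic
  expect_error(rank_genes(m, 3), class = "topictree_value_error")
})

test_that("a term at the very top of the ranking is extremely significant", {
  m <- fake_model(graded_phi(1000, top = sprintf("g%04d", 1:10)))
  ranked <- rank_genes(m, 1)
  p <- ks_term_test(ranked, sprintf("g%04d", 1:10))
  expect_lt(p, 1e-6)
  # permutation cross-check: observed KS statistic never reached by chance
  scores <- setNames(ranked$probability, ranked$gene_id)
  obs <- ks.test(scores[sprintf("g%04d", 1:10)],
                 scores[!names(scores) %in% sprintf("g%04d", 1:10)],
                 alternative = "less")$statistic
  set.seed(7)
  exceed <- sum(replicate(2000, {
    idx <- sample(names(scores), 10)
    suppressWarnings(ks.test(scores[idx], scores[!names(scores) %in% idx],
                             alternative = "less")$statistic) >= obs
  }))
  expect_equal(exceed, 0)
})

test_that("null terms give approximately uniform p-values and size filters apply", {
  m <- fake_model(graded_phi(1000))
  ranked <- rank_genes(m, 1)
  set.seed(19)
  ps <- replicate(500, ks_term_test(ranked, sample(ranked$gene_id, 10)))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_equal(ks_term_test(ranked, ranked$gene_id), 1)  # whole universe
  small <- ks_term_test(ranked, ranked$gene_id[1:2])
  expect_true(is.na(small))
  expect_equal(attr(small, "reason"), "too_small")
  huge <- ks_term_test(ranked, ranked$gene_id[1:800])
  expect_equal(attr(huge, "reason"), "too_large")
})

test_that("on an edgeless DAG elim and weight reduce exactly to classic", {
  m <- fake_model(graded_phi(300, top = sprintf("g%04d", 1:8)))
  set.seed(4)
  sets <- c(list(SIG = sprintf("g%04d", 1:8)),
            setNames(lapply(1:10, function(i)
              sample(sprintf("g%04d", 1:300), 12)), paste0("RND", 1:10)))
  dag <- gene_set_dag(sets)
  classic <- enrich_topic(m, 1, dag, "classic")
  elim <- enrich_topic(m, 1, dag, "elim")
  weight <- enrich_topic(m, 1, dag, "weight")
  expect_equal(elim[names(elim) != "method"], classic[names(classic) != "method"])
  expect_equal(weight[names(weight) != "method"], classic[names(classic) != "method"])
})

test_that("elim weakens an ancestor whose signal lives in a significant child", {
  m <- fake_model(flat_phi(400, top = sprintf("g%04d", 1:10)))
  sets <- list(child = sprintf("g%04d", 1:10),
               parent = sprintf("g%04d", 1:40))
  dag <- gene_set_dag(sets, parents = list(child = "parent"))
  classic <- enrich_topic(m, 1, dag, "classic", sig_threshold = 0.01)
  elim <- enrich_topic(m, 1, dag, "elim", sig_threshold = 0.01)
  p_classic <- classic$p_raw[classic$term_id == "parent"]
  p_elim <- elim$p_raw[elim$term_id == "parent"]
  expect_gt(p_elim, p_classic)
  # the child itself is tested on its own genes in both runs
  expect_equal(elim$p_raw[elim$term_id == "child"],
               classic$p_raw[classic$term_id == "child"])
  # decorrelation never reports more significant terms than classic
  expect_lte(sum(elim$p_raw < 0.01), sum(classic$p_raw < 0.01))
  wt <- enrich_topic(m, 1, dag, "weight", sig_threshold = 0.01)
  expect_lte(sum(wt$p_raw < 0.01), sum(classic$p_raw < 0.01))
})

test_that("elim's removals preserve upward closure in the working copy", {
  # chain leaf -> mid -> root, all signal in the leaf
  m <- fake_model(flat_phi(400, top = sprintf("g%04d", 1:10)))
  sets <- list(leaf = sprintf("g%04d", 1:10),
               mid = sprintf("g%04d", 1:25),
               root = sprintf("g%04d", 1:60))
  dag <- gene_set_dag(sets, parents = list(leaf = "mid", mid = "root"))
  elim <- enrich_topic(m, 1, dag, "elim", sig_threshold = 0.01)
  # the leaf's genes were removed from BOTH ancestors (no intermediate state
  # where mid keeps a gene root lost): both ancestors were tested on sets
  # excluding the 10 leaf genes, and mid (left with noise genes only) is no
  # longer significant, so root keeps mid's remainder
  expect_equal(elim$n_genes_in_term[elim$term_id == "mid"], 15L)
  expect_gt(elim$p_raw[elim$term_id == "mid"], 0.01)
  expect_equal(elim$n_genes_in_term[elim$term_id == "root"], 50L)
})

test_that("Bonferroni correction is per topic and monotone", {
  m <- fake_model(graded_phi(300, top = sprintf("g%04d", 1:8)))
  set.seed(9)
  sets <- c(list(SIG = sprintf("g%04d", 1:8)),
            setNames(lapply(1:7, function(i)
              sample(sprintf("g%04d", 1:300), 10)), paste0("R", 1:7)))
  tab <- enrich_topic(m, 1, gene_set_dag(sets), "classic")
  expect_true(all(tab$p_bonferroni >= tab$p_raw))
  expect_true(all(tab$p_bonferroni <= 1))
  expect_equal(tab$p_bonferroni, pmin(1, nrow(tab) * tab$p_raw))
})

test_that("planted anchor terms are recovered as each topic's top term", {
  sim <- generate_trajectory(M = 40, V = 300, K = 3, tokens_per_cell = 800,
                             seed = 5)
  m <- fit_lda(sim$counts, K = 3, sweeps = 300, burn_in = 100, seed = 5)
  set.seed(5)
  decoys <- setNames(lapply(1:10, function(i)
    sample(colnames(m$phi), 15)), paste0("DECOY", 1:10))
  dag <- gene_set_dag(c(sim$truth$planted_terms, decoys))
  for (method in c("classic", "elim", "weight")) {
    tab <- enrich_topics(m, dag, method = method)
    top_terms <- tab |>
      dplyr::group_by(topic) |>
      dplyr::slice_min(p_raw, n = 1, with_ties = FALSE) |>
      dplyr::pull(term_id)
    expect_setequal(top_terms, names(sim$truth$planted_terms))
  }
})

test_that("under the true topic distributions each planted term is unique to its topic", {
  # on a continuum, *fitted* topics legitimately share mass with neighbouring
  # stages; the clean disjoint-signal property is asserted on the generating
  # distributions themselves
  sim <- generate_trajectory(M = 40, V = 300, K = 3, tokens_per_cell = 800,
                             seed = 5)
  m_true <- structure(list(phi = sim$truth$phi_true, K = 3,
                           theta = sim$truth$theta_true),
                      class = "topic_model")
  set.seed(6)
  decoys <- setNames(lapply(1:10, function(i)
    sample(colnames(sim$truth$phi_true), 15)), paste0("DECOY", 1:10))
  dag <- gene_set_dag(c(sim$truth$planted_terms, decoys))
  tab <- enrich_topics(m_true, dag, method = "classic")
  planted <- tab[tab$term_id %in% names(sim$truth$planted_terms), ]
  expect_true(all(planted$significant[planted$term_id ==
                                        paste0("topic_", planted$topic)]))
  expect_equal(sum(planted$unique_to_topic), 3L)
  expect_true(all(planted$unique_to_topic ==
                    (planted$term_id == paste0("topic_", planted$topic))))
})

test_that("uniqueness and minority flags follow the topic-count boundary", {
  tab <- tibble::tibble(
    topic = rep(1:4, each = 2),
    term_id = rep(c("A", "B"), 4),
    name = term_id, method = "classic", n_genes_in_term = 5L,
    p_raw = c(1e-6, 1e-6, 0.5, 1e-6, 0.5, 1e-6, 0.5, 0.5),
    p_bonferroni = pmin(1, 2 * p_raw))
  out <- partition_unique_terms(tab, alpha = 0.05)
  a <- out[out$term_id == "A", ]
  b <- out[out$term_id == "B", ]
  expect_equal(sum(a$unique_to_topic), 1L)        # A significant only in topic 1
  expect_true(all(a$in_minority[a$significant]))  # 1 < 4/2
  expect_false(any(b$unique_to_topic))            # B significant in 3 topics
  expect_false(any(b$in_minority))                # 3 >= 4/2 boundary: excluded
})
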