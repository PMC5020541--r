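two_cluster_dist <- function(gap = 5, spread = 0.05, n = 5, seed = 2) {
  set.seed(seed)
  pts <- rbind(matrix(rnorm(2 * n, 0, spread), n),
               matrix(rnorm(2 * n, gap, spread), n))
  rownames(pts) <- sprintf("c%02d", seq_len(2 * n))
  as.matrix(dist(pts))
}

test_that("delta lands on the first mode of a bimodal distance distribution", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- abs(c(rnorm(150, 1, 0.1), rnorm(150, 3, 0.1)))
    delta <- estimate_delta(dist_from_sample(x))
    expect_true(delta >= 0.8 && delta <= 1.2)
    expect_equal(attr(delta, "method"), "first_mode")
  }
})

test_that("a single mode is also the first mode", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- abs(rnorm(200, 2, 0.1))
    delta <- estimate_delta(dist_from_sample(x))
    expect_true(delta >= 1.8 && delta <= 2.2)
  }
})

test_that("monotone densities fall back to the 25th percentile, flagged", {
  # mass piled at zero with one distant point: the KDE decreases from the
  # left boundary, so no interior mode exists
  x <- c(rep(0.001, 50), 5)
  delta <- estimate_delta(dist_from_sample(x))
  expect_equal(as.numeric(delta), quantile(x, 0.25, names = FALSE),
               tolerance = 0.5)
  expect_equal(attr(delta, "method"), "quantile_fallback")
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(estimate_delta(d0), class = "topictree_degenerate_error")
})

test_that("check_backbone accepts a star and localises a wrong attachment", {
  ids <- c("hub", "v1", "v2", "v3")
  d <- matrix(c(0, 1, 1, 1,
                1, 0, 2, 2,
                1, 2, 0, 2,
                1, 2, 2, 0), 4, 4, dimnames = list(ids, ids))
  star <- backbone_tree("hub",
                        tibble::tibble(from = character(), to = character(),
                                       weight = numeric()),
                        setNames(rep("hub", 3), c("v1", "v2", "v3")),
                        character(), delta = 1.5, cell_ids = ids)
  expect_true(all(check_backbone(star, d, 0)$ok))
  # attach v1 to a non-nearest backbone vertex
  d2 <- d; d2["v1", "v2"] <- d2["v2", "v1"] <- 0.1
  wrong <- backbone_tree(c("hub", "v2"),
                         tibble::tibble(from = "hub", to = "v2", weight = 1),
                         setNames(c("hub", "hub"), c("v1", "v3")),
                         character(), delta = 1.5, cell_ids = ids)
  rep2 <- check_backbone(wrong, d2, 0)
  bad <- rep2[!rep2$ok, ]
  expect_equal(bad$condition, "attached_to_nearest")
  expect_match(bad$detail, "v1")
})

test_that("check_backbone agrees with a literal transcription of the conditions", {
  for (seed in 1:10) {
    d <- random_point_dist(8, seed + 10)$d
    delta <- as.numeric(estimate_delta(d))
    bb <- build_backbone(d, delta = delta, outlier_fraction = 0.1)
    expect_identical(all(check_backbone(bb, d, 0.1)$ok),
                     oracle_backbone_valid(bb, d, 0.1))
    expect_true(oracle_backbone_valid(bb, d, 0.1))
  }
})

test_that("two tight clusters condense to a 2-vertex backbone matching the exact optimum", {
  d <- two_cluster_dist()
  bb <- build_backbone(d, delta = 0.5, outlier_fraction = 0)
  expect_equal(length(bb$backbone_vertices), 2L)
  expect_equal(length(bb$attachments), 8L)
  bf <- brute_force_backbone(d, delta = 0.5, outlier_fraction = 0)
  expect_equal(bb$objective, bf$objective)
  # the single backbone edge is the inter-cluster link
  expect_gt(bb$objective, 4)
})

test_that("mutually close cells may shrink to a single backbone vertex with zero objective", {
  d <- two_cluster_dist(gap = 0.2, spread = 0.02)
  bb <- build_backbone(d, delta = 1, outlier_fraction = 0)
  expect_equal(length(bb$backbone_vertices), 1L)
  expect_equal(bb$objective, 0)
  bf <- brute_force_backbone(d, delta = 1, outlier_fraction = 0)
  expect_equal(bf$objective, 0)
  expect_equal(length(bf$backbone_vertices), 1L)
})

test_that("the heuristic is valid, never beats the exact solver, and stays within 1.5x", {
  ratios <- c()
  for (seed in 1:12) {
    d <- random_point_dist(8, seed)$d
    delta <- as.numeric(estimate_delta(d))
    bb <- build_backbone(d, delta = delta, outlier_fraction = 0.1)
    expect_true(all(check_backbone(bb, d, 0.1)$ok))
    bf <- brute_force_backbone(d, delta = delta, outlier_fraction = 0.1)
    expect_gte(bb$objective, bf$objective - 1e-9)
    ratio <- if (bf$objective == 0) as.numeric(bb$objective == 0) + 0 else
      bb$objective / bf$objective
    if (bf$objective > 0) ratios <- c(ratios, ratio)
  }
  expect_true(all(ratios <= 1.5))
})

test_that("the heuristic never exceeds the all-backbone MST objective", {
  for (seed in 1:8) {
    d <- random_point_dist(9, seed + 30)$d
    mstw <- sum(minimum_spanning_tree(d)$edges$weight)
    bb <- build_backbone(d, delta = "auto", outlier_fraction = 0.05)
    expect_lte(bb$objective, mstw + 1e-9)
    expect_equal(length(bb$backbone_vertices) + length(bb$attachments) +
                   length(bb$outliers), 9L)
  }
})

test_that("enlarging delta never increases the exact optimum", {
  for (seed in 1:4) {
    d <- random_point_dist(7, seed + 60)$d
    deltas <- quantile(d[upper.tri(d)], c(0.3, 0.5, 0.8))
    objs <- sapply(deltas, function(dl)
      brute_force_backbone(d, delta = dl, outlier_fraction = 0)$objective)
    expect_true(all(diff(objs) <= 1e-9))
  }
})

test_that("isolated cells stay in the backbone and oversize exact requests error", {
  ids <- c("a", "b", "far")
  d <- matrix(c(0, 0.1, 9, 0.1, 0, 9, 9, 9, 0), 3, 3,
              dimnames = list(ids, ids))
  bb <- build_backbone(d, delta = 1, outlier_fraction = 0)
  expect_true("far" %in% bb$backbone_vertices)
  expect_true(all(check_backbone(bb, d, 0)$ok))
  expect_equal(bb$objective,
               brute_force_backbone(d, delta = 1, outlier_fraction = 0)$objective)
  big <- random_point_dist(11, 1)$d
  expect_error(brute_force_backbone(big, 1, 0), class = "topictree_size_error")
})

test_that("backbone rooting always lands on a backbone vertex", {
  for (seed in 1:6) {
    d <- random_point_dist(9, seed + 200)$d
    bb <- build_backbone(d, delta = "auto", outlier_fraction = 0.1)
    grp <- sample(rownames(d), 3)
    rooted <- root_backbone(bb, d, grp)
    expect_true(rooted$root %in% rooted$backbone_vertices)
  }
  # start group entirely within one backbone vertex's vertebrae
  d <- two_cluster_dist()
  bb <- build_backbone(d, delta = 0.5, outlier_fraction = 0)
  vb_of_cluster1 <- intersect(bb$backbone_vertices, sprintf("c%02d", 1:5))
  verts <- names(bb$attachments)[bb$attachments == vb_of_cluster1]
  rooted <- root_backbone(bb, d, verts)
  expect_equal(rooted$root, vb_of_cluster1)
  # singleton start group that is itself a backbone vertex
  rooted2 <- root_backbone(bb, d, vb_of_cluster1)
  expect_equal(rooted2$root, vb_of_cluster1)
})

test_that("backbone ordering and exports are coherent", {
  d <- two_cluster_dist()
  bb <- root_backbone(build_backbone(d, delta = 0.5, outlier_fraction = 0),
                      d, "c01")
  o <- backbone_ordering(bb, d)
  expect_setequal(o$cell_id, rownames(d))
  # cluster 1 cells all precede cluster 2 cells
  r1 <- o$rank[o$cell_id %in% sprintf("c%02d", 1:5)]
  r2 <- o$rank[o$cell_id %in% sprintf("c%02d", 6:10)]
  expect_lt(max(r1), min(r2))
  dir <- withr::local_tempdir()
  write_backbone_tsv(bb, d, file.path(dir, "bb.tsv"))
  tab <- utils::read.table(file.path(dir, "bb.tsv"), header = TRUE, sep = "\t")
  expect_setequal(tab$role, c("backbone", "vertebra"))
  expect_equal(nrow(tab), 10)
  write_backbone_dot(bb, d, file.path(dir, "bb.dot"))
  expect_gt(file.size(file.path(dir, "bb.dot")), 0)
})
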