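# Independent oracles used to cross-check the package implementations.
# Everything here is deliberately written from first principles (plain loops,
# exhaustive enumeration) and shares no code with R/.

# term-by-term chi-square summation
oracle_chisq <- function(x, y) {
  total <- 0
  for (k in seq_along(x)) {
    s <- x[k] + y[k]
    if (s > 0) total <- total + (x[k] - y[k])^2 / s
  }
  sqrt(unname(total))
}

# random symmetric distance matrix from points in the plane (a true metric)
random_point_dist <- function(M, seed, sd = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(2 * M, sd = sd), ncol = 2)
  rownames(pts) <- sprintf("c%02d", seq_len(M))
  list(d = as.matrix(dist(pts)), pts = pts)
}

# exhaustive minimum spanning-tree weight via Prufer sequences (Cayley):
# every labelled tree on M vertices corresponds to one sequence in
# {1..M}^(M-2); decode each and take the minimum total weight.
oracle_mst_weight <- function(d) {
  M <- nrow(d)
  if (M == 1) return(0)
  if (M == 2) return(d[1, 2])
  decode_prufer <- function(pr) {
    M <- length(pr) + 2
    degree <- rep(1L, M)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, M - 1, 2)
    ptr <- 1L
    for (v in pr) {
      leaf <- which(degree == 1L)[1]
      edges[ptr, ] <- c(leaf, v); ptr <- ptr + 1L
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    edges[ptr, ] <- which(degree == 1L)
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(M)), M - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- decode_prufer(seqs[r, ])
    w <- sum(d[ed])
    if (w < best) best <- w
  }
  best
}

# all-pairs shortest paths on a weighted edge list by Floyd-Warshall
oracle_floyd_warshall <- function(edges, ids) {
  n <- length(ids)
  dm <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(dm) <- 0
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]; w <- edges$weight[r]
    dm[a, b] <- dm[b, a] <- min(dm[a, b], w)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (dm[i, k] + dm[k, j] < dm[i, j]) dm[i, j] <- dm[i, k] + dm[k, j]
  dm
}

# exact travelling-salesman cycle length by Held-Karp dynamic programming
oracle_held_karp <- function(d) {
  n <- nrow(d)
  full <- bitwShiftL(1L, n - 1L) - 1L  # subsets of vertices 2..n
  C <- matrix(Inf, full, n - 1)
  for (j in seq_len(n - 1)) C[bitwShiftL(1L, j - 1L), j] <- d[1, j + 1]
  for (S in seq_len(full)) {
    for (j in seq_len(n - 1)) {
      if (!bitwAnd(S, bitwShiftL(1L, j - 1L))) next
      Sprev <- bitwXor(S, bitwShiftL(1L, j - 1L))
      if (Sprev == 0L) next
      best <- Inf
      for (k in seq_len(n - 1)) {
        if (!bitwAnd(Sprev, bitwShiftL(1L, k - 1L))) next
        v <- C[Sprev, k] + d[k + 1, j + 1]
        if (v < best) best <- v
      }
      C[S, j] <- best
    }
  }
  min(C[full, ] + d[2:n, 1])
}

# literal transcription of the four backbone-tree conditions
oracle_backbone_valid <- function(t, d, outlier_fraction) {
  vb <- t$backbone_vertices
  # condition 1: backbone is a tree over V_B
  if (nrow(t$backbone_edges) != length(vb) - 1) return(FALSE)
  if (length(vb) > 1) {
    reach <- vb[1]
    repeat {
      nxt <- unique(c(reach,
                      t$backbone_edges$to[t$backbone_edges$from %in% reach],
                      t$backbone_edges$from[t$backbone_edges$to %in% reach]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    if (!setequal(reach, vb)) return(FALSE)
  }
  # conditions 2 + 3: every vertebra within delta of, and attached to, its
  # nearest backbone vertex
  for (v in names(t$attachments)) {
    a <- t$attachments[[v]]
    if (d[v, a] > t$delta + 1e-9) return(FALSE)
    if (d[v, a] > min(d[v, vb]) + 1e-9) return(FALSE)
  }
  # condition 4: partition and outlier budget
  parts <- c(vb, names(t$attachments), t$outliers)
  if (anyDuplicated(parts) || !setequal(parts, t$cell_ids)) return(FALSE)
  length(t$outliers) / length(t$cell_ids) <= outlier_fraction + 1e-9
}

# best-permutation mean L1 error between an estimated and a true mixture
# matrix, over all K! column permutations
oracle_perm_l1 <- function(theta_hat, theta_true) {
  K <- ncol(theta_true)
  perms <- combinat_perms(K)
  min(vapply(perms, function(p)
    mean(rowSums(abs(theta_hat[, p, drop = FALSE] - theta_true))),
    numeric(1)))
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1))
    for (i in 0:(n - 1))
      out[[length(out) + 1L]] <- as.integer(append(p, n, after = i))
  out
}

# reference truth (stage labels as tied ranks) for a synthetic trajectory
stage_reference <- function(truth) {
  data.frame(cell_id = names(truth$groups),
             rank = match(unname(truth$groups), truth$group_order))
}

# symmetric matrix whose strict upper triangle carries a given sample
# (estimate_delta only reads the upper triangle)
dist_from_sample <- function(x) {
  M <- which((seq_len(50) * (seq_len(50) - 1) / 2) >= length(x))[1]
  need <- M * (M - 1) / 2
  vals <- c(x, rep(stats::median(x), need - length(x)))
  d <- matrix(0, M, M, dimnames = list(sprintf("c%02d", 1:M),
                                       sprintf("c%02d", 1:M)))
  d[upper.tri(d)] <- vals
  d + t(d)
}
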