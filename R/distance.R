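#' Chi-square distance between two histograms
#'
#' Computes
#' \deqn{\chi(x, y) = \sqrt{\sum_k (x_k - y_k)^2 / (x_k + y_k)}}
#' the distance used to compare per-cell topic histograms. Components where
#' `x_k + y_k = 0` contribute nothing.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return The distance, a single non-negative number.
#' @export
chi_square_distance <- function(x, y) {
  if (length(x) != length(y))
    rlang::abort("histograms differ in length", class = "topictree_value_error")
  if (any(x < 0) || any(y < 0))
    rlang::abort("histogram entries must be non-negative",
                 class = "topictree_value_error")
  s <- x + y
  diff2 <- (x - y)^2
  sqrt(sum(ifelse(s == 0, 0, diff2 / s)))
}

#' Pairwise chi-square distance matrix between cells
#'
#' @param m A `topic_model` (rows of `theta` are compared) or a cells x K
#'   matrix of topic proportions with row names.
#' @return A symmetric `cell_dist` matrix (cells x cells) with zero diagonal.
#' @export
distance_matrix <- function(m) {
  theta <- if (inherits(m, "topic_model")) m$theta else as.matrix(m)
  M <- nrow(theta)
  d <- matrix(0, M, M, dimnames = list(rownames(theta), rownames(theta)))
  if (M > 1) {
    for (i in seq_len(M - 1)) {
      xi <- theta[i, ]
      for (j in seq(i + 1, M)) {
        s <- xi + theta[j, ]
        v <- (xi - theta[j, ])^2
        d[i, j] <- d[j, i] <- sqrt(sum(ifelse(s == 0, 0, v / s)))
      }
    }
  }
  structure(d, class = c("cell_dist", class(d)))
}

as_dist_matrix <- function(d) {
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix needs cell id dimnames")
  if (any(!is.finite(d)))
    rlang::abort("non-finite distances", class = "topictree_value_error")
  d
}
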