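#' Fit a latent Dirichlet allocation model by collapsed Gibbs sampling
#'
#' Cells play the role of documents and discretised expression levels the role
#' of word frequencies: each cell is modelled as a mixture over `K` latent
#' "topics", each topic a probability distribution over genes. Token-topic
#' assignments are sampled from the standard collapsed conditional
#' \deqn{p(z = k \mid \cdot) \propto (n_{dk} + \alpha_k)\,
#'   (n_{kw} + \beta_w) / (n_{k\cdot} + \textstyle\sum_w \beta_w)}
#' and the returned `theta` (cells x topics) and `phi` (topics x genes) are
#' posterior means over post-burn-in, thinned sweeps.
#'
#' Sampling uses one independent random stream per cell, seeded from the
#' master seed and the cell identifier, and always visits cells in
#' lexicographic id order, so results do not depend on the column order of
#' the input.
#'
#' @param counts A `count_matrix` (see [discretise()]) or a plain non-negative
#'   integer genes x cells matrix with dimnames.
#' @param K Number of topics (>= 2).
#' @param alpha Dirichlet prior on per-cell topic weights; scalar (symmetric)
#'   or length-`K` vector. Default `50 / K`.
#' @param beta Dirichlet prior on per-topic gene weights; scalar or length-`V`
#'   vector. Default 0.1.
#' @param sweeps,burn_in,thin Gibbs schedule: total sweeps, burn-in sweeps
#'   discarded, and thinning interval for the posterior mean.
#' @param seed Integer master seed; the fit is deterministic given the seed.
#' @param init_assignments Internal: warm-start token assignments (list of
#'   0-based integer vectors, one per cell in column order).
#' @return A `topic_model` with fields `theta`, `phi`, `alpha`, `beta`, `K`,
#'   `assignments`, `loglik_trace`, `seed`.
#' @export
fit_lda <- function(counts, K, alpha = 50 / K, beta = 0.1,
                    sweeps = 800L, burn_in = 200L, thin = 10L, seed = 1L,
                    init_assignments = NULL) {
  cm <- if (inherits(counts, "count_matrix")) counts$counts else counts
  stopifnot(is.matrix(cm))
  storage.mode(cm) <- "integer"
  if (K < 2)
    rlang::abort("K must be >= 2", class = "topictree_value_error")
  if (sweeps <= burn_in || burn_in < 0)
    rlang::abort("need sweeps > burn_in >= 0", class = "topictree_value_error")
  V <- nrow(cm); M <- ncol(cm)
  expressed <- sum(rowSums(cm) > 0L)
  if (K > expressed)
    rlang::abort(paste0("K = ", K, " exceeds the ", expressed,
                        " distinct expressed genes"),
                 class = "topictree_config_error")
  if (sum(cm) == 0L)
    rlang::abort("no tokens to sample", class = "topictree_value_error")
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  if (length(beta) == 1L) beta <- rep(beta, V)
  if (length(alpha) != K || length(beta) != V)
    rlang::abort("prior length mismatch", class = "topictree_value_error")
  if (any(alpha <= 0) || any(beta <= 0))
    rlang::abort("priors must be strictly positive",
                 class = "topictree_value_error")

  fit <- lda_gibbs_cpp(cm, as.integer(K), as.numeric(alpha), as.numeric(beta),
                       as.integer(sweeps), as.integer(burn_in),
                       as.integer(thin), as.numeric(seed), colnames(cm),
                       init_assignments)
  theta <- fit$theta
  dimnames(theta) <- list(colnames(cm), paste0("topic_", seq_len(K)))
  phi <- fit$phi
  dimnames(phi) <- list(paste0("topic_", seq_len(K)), rownames(cm))
  structure(list(theta = theta, phi = phi, alpha = alpha, beta = beta,
                 K = as.integer(K), assignments = fit$assignments,
                 loglik_trace = fit$loglik, seed = seed,
                 sweeps = sweeps, burn_in = burn_in, thin = thin,
                 n_samples = fit$n_samples),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat("<topic_model> K = ", x$K, ", ", nrow(x$theta), " cells x ",
      ncol(x$phi), " genes; ", length(x$loglik_trace), " sweeps (",
      x$n_samples, " posterior samples)\n", sep = "")
  invisible(x)
}

#' Choose the number of topics by a penalised-likelihood scan
#'
#' Fits models for `K = k_min .. k_max`, warm-starting each fit from the
#' previous one's token assignments (the `1/K` fraction of tokens with the
#' lowest conditional probability under the previous model seed the fresh
#' topic, so the new topic starts with roughly its share of mass) and
#' scores each model by its best post-burn-in complete-data log likelihood
#' minus a BIC-style penalty `(K * V / 2) * log(total tokens)`. The score is a
#' tractable stand-in for full marginal-likelihood model comparison.
#'
#' @inheritParams fit_lda
#' @param k_min,k_max Scan range, `2 <= k_min < k_max`.
#' @param ... Passed to [fit_lda()] (e.g. `sweeps`, `burn_in`, priors).
#' @return A list with `best_K` (the maximising K; ties go to the smallest),
#'   `scores` (a tibble with columns `K`, `loglik`, `penalty`, `score`) and
#'   `models` (the fitted `topic_model` for `best_K`).
#' @export
select_topic_count <- function(counts, k_min = 2L, k_max = 10L, seed = 1L, ...) {
  if (!(2L <= k_min && k_min < k_max))
    rlang::abort("need 2 <= k_min < k_max", class = "topictree_value_error")
  cm <- if (inherits(counts, "count_matrix")) counts$counts else counts
  n_tokens <- sum(cm)
  V <- nrow(cm)
  rows <- list()
  fits <- list()
  prev <- NULL
  post_ll <- function(f)
    max(f$loglik_trace[(f$burn_in + 1L):length(f$loglik_trace)])
  for (K in seq(k_min, k_max)) {
    # the collapsed chain is multimodal: run the warm-started fit and an
    # independent cold fit, keep whichever mixes into the better mode
    fit <- fit_lda(counts, K = K, seed = seed, ...)
    if (!is.null(prev)) {
      init <- warm_start_assignments(prev, cm, K)
      warm <- fit_lda(counts, K = K, seed = seed, init_assignments = init, ...)
      if (post_ll(warm) > post_ll(fit)) fit <- warm
    }
    ll <- post_ll(fit)
    penalty <- (K * V / 2) * log(n_tokens)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(K = K, loglik = ll, penalty = penalty,
                     score = ll - penalty)
    fits[[as.character(K)]] <- fit
    prev <- fit
  }
  scores <- dplyr::bind_rows(rows)
  best_K <- scores$K[which.max(scores$score)]
  list(best_K = best_K, scores = scores,
       model = fits[[as.character(best_K)]])
}

# Reassign the worst-fit 1/K_new of tokens (lowest posterior conditional
# probability of their current topic) to the new topic; everything else is
# retained. A smaller reseed starves the fresh topic and the chain stays in
# the previous mode.
warm_start_assignments <- function(model, cm, K_new) {
  M <- ncol(cm)
  theta <- model$theta; phi <- model$phi
  zs <- model$assignments
  ps <- vector("list", M)
  for (d in seq_len(M)) {
    genes0 <- rep.int(seq_len(nrow(cm)), cm[, d]) # token genes, 0-based below
    z <- zs[[d]] + 1L
    num <- theta[d, z] * phi[cbind(z, genes0)]
    den <- as.numeric(matrix(theta[d, ], nrow = 1) %*%
                        phi[, genes0, drop = FALSE])
    ps[[d]] <- num / pmax(den, .Machine$double.xmin)
  }
  allp <- unlist(ps, use.names = FALSE)
  if (!length(allp)) return(NULL)
  cut <- stats::quantile(allp, 1 / K_new, names = FALSE)
  lapply(seq_len(M), function(d) {
    z <- zs[[d]]
    z[ps[[d]] <= cut] <- K_new - 1L
    as.integer(z)
  })
}

#' Tidy and summarise fitted objects
#'
#' Broom-style methods: `tidy()` returns the object's main content as a long
#' tibble (topic proportions for a `topic_model`, edges for a `cell_tree`,
#' per-cell roles for a `backbone_tree`); `glance()` returns a one-row model
#' summary.
#'
#' @param x A fitted or container object from this package.
#' @param matrix For `topic_model`: `"theta"` (cells x topics, default) or
#'   `"phi"` (topics x genes).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.topic_model <- function(x, matrix = c("theta", "phi"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "theta") {
    tibble::as_tibble(as.data.frame.table(x$theta, stringsAsFactors = FALSE)) |>
      stats::setNames(c("cell_id", "topic", "proportion")) |>
      dplyr::mutate(topic = as.integer(sub("topic_", "", .data$topic)))
  } else {
    tibble::as_tibble(as.data.frame.table(x$phi, stringsAsFactors = FALSE)) |>
      stats::setNames(c("topic", "gene_id", "probability")) |>
      dplyr::mutate(topic = as.integer(sub("topic_", "", .data$topic)))
  }
}

#' @rdname tidy.topic_model
#' @export
glance.topic_model <- function(x, ...) {
  tibble::tibble(K = x$K, n_cells = nrow(x$theta), n_genes = ncol(x$phi),
                 loglik = x$loglik_trace[length(x$loglik_trace)],
                 n_samples = x$n_samples, seed = x$seed)
}

#' Persist a topic model as JSON
#'
#' @param model A `topic_model`.
#' @param path Output file.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(theta = model$theta, phi = model$phi, alpha = model$alpha,
         beta = model$beta, K = model$K, seed = model$seed,
         cell_ids = rownames(model$theta), gene_ids = colnames(model$phi),
         loglik_trace = model$loglik_trace),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a topic model written by [write_model()]
#' @param path JSON file.
#' @return A `topic_model` (without sampler assignments).
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- j$theta; phi <- j$phi
  dimnames(theta) <- list(j$cell_ids, paste0("topic_", seq_len(j$K)))
  dimnames(phi) <- list(paste0("topic_", seq_len(j$K)), j$gene_ids)
  structure(list(theta = theta, phi = phi, alpha = j$alpha, beta = j$beta,
                 K = as.integer(j$K), assignments = NULL,
                 loglik_trace = j$loglik_trace, seed = j$seed,
                 n_samples = NA_integer_),
            class = "topic_model")
}
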