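#' Construct an expression matrix object
#'
#' Container for a genes-by-cells real-valued expression matrix with optional
#' ordered per-cell group labels (e.g. sampling times).
#'
#' @param values Numeric matrix, genes in rows, cells in columns. Row names are
#'   gene identifiers, column names cell identifiers (or supply `gene_ids` /
#'   `cell_ids`).
#' @param gene_ids,cell_ids Optional character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @param groups Optional named character vector mapping every cell id to a
#'   group label.
#' @param group_order Optional character vector giving the biological order of
#'   the group labels (e.g. time points).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              groups = NULL, group_order = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids))
    rlang::abort("gene and cell identifiers are required",
                 class = "topictree_format_error")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids))
    rlang::abort("identifier lengths do not match matrix dimensions",
                 class = "topictree_format_error")
  if (anyDuplicated(gene_ids))
    rlang::abort("duplicate gene identifiers", class = "topictree_format_error")
  if (anyDuplicated(cell_ids))
    rlang::abort("duplicate cell identifiers", class = "topictree_format_error")
  if (any(!is.finite(values)))
    rlang::abort("expression values must be finite", class = "topictree_value_error")
  if (any(values < 0))
    rlang::abort("expression values must be non-negative",
                 class = "topictree_value_error")
  dimnames(values) <- list(gene_ids, cell_ids)
  if (!is.null(groups)) {
    groups <- stats::setNames(as.character(groups), names(groups))
    unknown <- setdiff(names(groups), cell_ids)
    if (length(unknown))
      rlang::abort(paste0("group labels name unknown cells: ",
                          paste(utils::head(unknown, 5), collapse = ", ")),
                   class = "topictree_key_error")
    missing <- setdiff(cell_ids, names(groups))
    if (length(missing))
      rlang::abort(paste0("cells without a group label: ",
                          paste(utils::head(missing, 5), collapse = ", ")),
                   class = "topictree_key_error")
    groups <- groups[cell_ids]
    if (is.null(group_order)) group_order <- sort(unique(unname(groups)))
  }
  structure(list(values = values, groups = groups, group_order = group_order,
                 provenance = list()),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells", if (!is.null(x$groups))
        paste0(", ", length(unique(x$groups)), " groups"), "\n", sep = "")
  if (isTRUE(x$provenance$pretreated))
    cat("  pre-treated: log base ", x$provenance$log_base, ", sd >= ",
        x$provenance$sd_threshold, "\n", sep = "")
  invisible(x)
}

gene_ids <- function(x) rownames(if (inherits(x, "count_matrix")) x$counts else x$values)
cell_ids <- function(x) colnames(if (inherits(x, "count_matrix")) x$counts else x$values)

#' Read an expression matrix from file
#'
#' Dense TSV/CSV files have gene ids in the first column and a header row of
#' cell ids. MatrixMarket files (`format = "mtx"`) need sidecar name files
#' `<stem>.genes.txt` and `<stem>.cells.txt`, one name per line.
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @param groups_path Optional two-column TSV (cell_id, label), no header.
#' @param group_order_path Optional file listing group labels one per line in
#'   biological order.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx"),
                            groups_path = NULL, group_order_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    rlang::abort(paste0("no such file: ", path), class = "topictree_io_error")
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                            row.names = NULL, stringsAsFactors = FALSE)
    gids <- as.character(df[[1]])
    if (anyDuplicated(gids))
      rlang::abort("duplicate gene identifiers in file",
                   class = "topictree_format_error")
    values <- as.matrix(df[, -1, drop = FALSE])
    rownames(values) <- gids
  } else {
    stem <- sub("\\.mtx$", "", path)
    gfile <- paste0(stem, ".genes.txt")
    cfile <- paste0(stem, ".cells.txt")
    if (!file.exists(gfile) || !file.exists(cfile))
      rlang::abort("mtx format requires <stem>.genes.txt and <stem>.cells.txt",
                   class = "topictree_io_error")
    values <- as.matrix(Matrix::readMM(path))
    rownames(values) <- readLines(gfile)
    colnames(values) <- readLines(cfile)
  }
  groups <- NULL
  group_order <- NULL
  if (!is.null(groups_path)) {
    gdf <- utils::read.table(groups_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    groups <- stats::setNames(as.character(gdf[[2]]), as.character(gdf[[1]]))
  }
  if (!is.null(group_order_path)) group_order <- readLines(group_order_path)
  expression_matrix(values, groups = groups, group_order = group_order)
}

#' Log-transform and variance-filter an expression matrix
#'
#' Replaces values by `log(1 + x) / log(log_base)` and removes genes whose
#' post-transform standard deviation across cells (denominator n - 1) falls
#' below `sd_threshold`. This is the default pre-treatment applied before
#' discretisation and topic-model fitting.
#'
#' @param m An [expression_matrix()].
#' @param sd_threshold Minimum per-gene standard deviation to keep (default
#'   0.5, on the log scale).
#' @param log_base Base of the log transform (default 2).
#' @return A filtered, log-scale `expression_matrix`; `provenance` records the
#'   parameters. Calling `pretreat()` twice on the same object is an error.
#' @export
pretreat <- function(m, sd_threshold = 0.5, log_base = 2) {
  stopifnot(inherits(m, "expression_matrix"))
  if (isTRUE(m$provenance$pretreated))
    rlang::abort("matrix is already pre-treated; refusing to log-transform twice",
                 class = "topictree_state_error")
  if (sd_threshold < 0)
    rlang::abort("sd_threshold must be >= 0", class = "topictree_value_error")
  if (log_base <= 1)
    rlang::abort("log_base must be > 1", class = "topictree_value_error")
  v <- log1p(m$values) / log(log_base)
  sds <- apply(v, 1L, stats::sd)
  keep <- sds >= sd_threshold
  if (!any(keep))
    rlang::abort(paste0("all genes removed at sd_threshold = ", sd_threshold),
                 class = "topictree_empty_model_error")
  out <- m
  out$values <- v[keep, , drop = FALSE]
  out$provenance <- c(m$provenance,
                      list(pretreated = TRUE, sd_threshold = sd_threshold,
                           log_base = log_base, genes_removed = sum(!keep)))
  out
}

#' Discretise a pre-treated expression matrix into integer counts
#'
#' Rounds each (log-scale) value to the nearest integer (half-up), optionally
#' after multiplying by `scale`. The resulting counts play the role of word
#' frequencies in the topic model.
#'
#' @param m A pre-treated [expression_matrix()].
#' @param scale Multiplier applied before rounding (default 1).
#' @return A `count_matrix` object (fields `counts`, `provenance`).
#' @export
discretise <- function(m, scale = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  counts <- floor(m$values * scale + 0.5)
  storage.mode(counts) <- "integer"
  zero <- colSums(counts) == 0L
  if (any(zero))
    rlang::abort(paste0("discretisation left cells with zero total count: ",
                        paste(utils::head(colnames(counts)[zero], 5),
                              collapse = ", ")),
                 class = "topictree_degenerate_cell_error")
  structure(list(counts = counts,
                 provenance = c(m$provenance,
                                list(discretised = "round-half-up",
                                     scale = scale))),
            class = "count_matrix")
}

#' Wrap an integer matrix as a count matrix
#'
#' @param counts Non-negative integer matrix (genes x cells) with dimnames.
#' @param provenance Optional provenance list.
#' @return A `count_matrix`.
#' @export
count_matrix <- function(counts, provenance = list()) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    rlang::abort("counts must be non-negative integers",
                 class = "topictree_value_error")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    rlang::abort("counts need gene and cell dimnames",
                 class = "topictree_format_error")
  if (any(colSums(counts) == 0L))
    rlang::abort("count matrix contains an all-zero cell column",
                 class = "topictree_degenerate_cell_error")
  structure(list(counts = counts, provenance = provenance),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells, ", sum(x$counts), " tokens\n", sep = "")
  invisible(x)
}

#' @rdname tidy.topic_model
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$values, stringsAsFactors = FALSE),
                    .name_repair = "minimal") |>
    stats::setNames(c("gene_id", "cell_id", "value"))
}

#' @rdname tidy.topic_model
#' @export
tidy.count_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE),
                    .name_repair = "minimal") |>
    stats::setNames(c("gene_id", "cell_id", "count"))
}
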