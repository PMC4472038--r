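#' Gene-by-sample expression matrix
#'
#' Light container for a gene-by-sample matrix of non-negative expression
#' values plus a platform tag. `platform` records what the values are:
#' `"counts"` (raw integer read counts), `"cpm"` (counts per million, possibly
#' after TMM scaling), or `"intensity"` (microarray fluorescence, arbitrary
#' positive scale). Gene and sample identifiers live in the dimnames and must
#' be unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param platform One of `"counts"`, `"cpm"`, `"intensity"`.
#' @param meta Named list of free-form provenance strings.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `platform`, `meta`.
#' @export
#' @examples
#' m <- matrix(0:5, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expression_matrix(m, "counts")
expression_matrix <- function(values, platform = c("counts", "cpm", "intensity"),
                              meta = list()) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have rownames (gene IDs) and colnames (sample IDs).")
  }
  if (anyDuplicated(rownames(values))) {
    abort(paste0("Duplicate gene IDs: ",
                 paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    abort(paste0("Duplicate sample IDs: ",
                 paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", ")))
  }
  if (anyNA(values)) abort("Expression values must not contain NA.")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Negative expression value at gene '%s', sample '%s'.",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (platform == "counts" && any(values != round(values))) {
    bad <- which(values != round(values), arr.ind = TRUE)[1, ]
    abort(sprintf("platform = 'counts' requires integer values; gene '%s', sample '%s' is %s.",
                  rownames(values)[bad[1]], colnames(values)[bad[2]],
                  format(values[bad[1], bad[2]])))
  }
  structure(list(values = values, platform = platform, meta = meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, platform = %s\n",
              nrow(x$values), ncol(x$values), x$platform))
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of IDs.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`.
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Subset an expression matrix by genes and/or samples
#'
#' @param x An `expr_matrix`.
#' @param genes,samples Character IDs or indices to keep (order respected);
#'   `NULL` keeps all.
#' @return The subsetted `expr_matrix` (platform and meta preserved).
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, x$platform, x$meta)
}

#' Restrict two expression matrices to their shared genes
#'
#' Both matrices are cut down to the intersection of their gene IDs (matched
#' by exact string equality) so that downstream steps — housekeeper selection,
#' classifier fitting — operate on a single namespace. The shared genes keep
#' the order they have in `a`.
#'
#' @param a,b `expr_matrix` objects.
#' @return A list with elements `a` and `b`, both restricted to the common
#'   genes in identical order.
#' @export
align_genes <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  common <- intersect(gene_ids(a), gene_ids(b))
  if (length(common) == 0) {
    abort("No genes shared between the two matrices: gene ID namespaces do not match.")
  }
  inform(sprintf("align_genes: %d shared genes (of %d and %d).",
                 length(common), nrow(a$values), nrow(b$values)))
  list(a = subset_expr(a, genes = common), b = subset_expr(b, genes = common))
}
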