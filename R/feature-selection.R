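#' Most variably expressed genes
#'
#' Ranks genes by expression variability across all samples and returns the
#' top `n` (the classical "top 500" candidate pool for classifier-gene
#' selection). The default measure is the variance of `log2(CPM + 1)`, which
#' stabilizes the heavy right tail of CPM; plain CPM variance is available
#' for a strictly literal ranking. Counts are converted to TMM-CPM
#' internally. Ties are broken by gene ID (C-locale lexicographic) so the
#' result is deterministic.
#'
#' @param m An `expr_matrix` (`counts` or `cpm`).
#' @param n Number of genes to return (clamped to the genes available, with a
#'   warning).
#' @param measure `"variance_logcpm"` (default) or `"variance_cpm"`.
#' @return A `variable_genes` tibble with columns `gene_id`, `score`
#'   (non-increasing), and attributes `n_requested`, `measure`.
#' @export
top_variable_genes <- function(m, n = 500,
                               measure = c("variance_logcpm", "variance_cpm")) {
  stopifnot(inherits(m, "expr_matrix"))
  measure <- match.arg(measure)
  if (length(n) != 1 || is.na(n) || n < 1) abort("`n` must be >= 1.")
  cpm <- as_cpm(m)
  v <- cpm$values
  if (measure == "variance_logcpm") v <- log2(v + 1)
  score <- apply(v, 1, var)
  ord <- order(-score, rownames(v), method = "radix")
  if (n > length(score)) {
    warn(sprintf("Requested %d genes but only %d available; returning all.",
                 n, length(score)))
    n <- length(score)
  }
  ord <- ord[seq_len(n)]
  out <- tibble(gene_id = rownames(v)[ord], score = unname(score[ord]))
  attr(out, "n_requested") <- n
  attr(out, "measure") <- measure
  class(out) <- c("variable_genes", class(out))
  out
}
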