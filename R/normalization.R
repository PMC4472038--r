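#' Detection filter for count matrices
#'
#' Keeps genes reaching the detection limit — at least `cutoff` reads in at
#' least one sample. The default of 4 reads is the conventional detection
#' limit for bulk RNA-seq count data.
#'
#' @param m An `expr_matrix` with `platform = "counts"`.
#' @param cutoff Non-negative integer detection limit (default 4).
#' @return The filtered `expr_matrix`.
#' @export
filter_detected <- function(m, cutoff = 4) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$platform != "counts") abort("filter_detected() needs platform = 'counts'.")
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff < 0) abort("`cutoff` must be >= 0.")
  keep <- apply(m$values, 1, max) >= cutoff
  inform(sprintf("filter_detected: removed %d of %d genes below %s reads in every sample.",
                 sum(!keep), length(keep), format(cutoff)))
  subset_expr(m, genes = which(keep))
}

#' Weighted trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample scaling factors by the weighted trimmed mean of
#' M-values method: a reference sample is chosen as the one whose upper
#' quartile of library-size-scaled counts is closest to the mean upper
#' quartile; each sample's factor is `2^` the weighted trimmed mean of
#' per-gene log2 expression ratios (M-values) against the reference, trimming
#' the most extreme `trim_m` of M-values and `trim_a` of average log
#' expression (A-values) and weighting by inverse delta-method binomial
#' variances. Genes with zero counts in either member of a pair are excluded.
#' Factors are rescaled to geometric mean 1 so their product is 1.
#'
#' The computation is delegated to `edgeR::calcNormFactors()`, the canonical
#' implementation of the method.
#'
#' @param m An `expr_matrix` with `platform = "counts"` and >= 2 samples.
#' @param trim_m Fraction of M-values trimmed from each tail (default 0.30).
#' @param trim_a Fraction of A-values trimmed from each tail (default 0.05).
#' @return A `tmm_factors` tibble with columns `sample_id`, `library_size`,
#'   `tmm_factor`; the chosen reference sample is stored in the
#'   `reference_sample` attribute.
#' @export
compute_tmm_factors <- function(m, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$platform != "counts") abort("compute_tmm_factors() needs platform = 'counts'.")
  if (ncol(m$values) < 2) abort("TMM needs at least 2 samples.")
  lib <- colSums(m$values)
  if (any(lib == 0)) {
    abort(paste0("All-zero sample(s): ",
                 paste(colnames(m$values)[lib == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(m$values, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a,
                              doWeighting = TRUE)
  # reference sample: 75th percentile of scaled counts closest to the mean
  f75 <- apply(sweep(m$values, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- colnames(m$values)[which.min(abs(f75 - mean(f75)))]
  out <- tibble(sample_id = colnames(m$values),
                library_size = unname(lib),
                tmm_factor = unname(f))
  attr(out, "reference_sample") <- ref
  class(out) <- c("tmm_factors", class(out))
  out
}

unit_factors <- function(m) {
  out <- tibble(sample_id = colnames(m$values),
                library_size = unname(colSums(m$values)),
                tmm_factor = 1)
  attr(out, "reference_sample") <- NA_character_
  class(out) <- c("tmm_factors", class(out))
  out
}

#' Counts per million
#'
#' `CPM = count / (library_size x tmm_factor) x 1e6`. With `log2_out`,
#' returns `log2(CPM + prior)`.
#'
#' @param m An `expr_matrix` with `platform = "counts"`.
#' @param factors A `tmm_factors` tibble covering all samples of `m`, or
#'   `NULL` for plain library-size CPM (all factors 1).
#' @param log2_out Return `log2(CPM + prior)` instead of CPM.
#' @param prior Pseudo-value added before the log (default 1).
#' @return An `expr_matrix` with `platform = "cpm"`.
#' @export
cpm_normalize <- function(m, factors = NULL, log2_out = FALSE, prior = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$platform != "counts") abort("cpm_normalize() needs platform = 'counts'.")
  if (is.null(factors)) factors <- unit_factors(m)
  missing <- setdiff(colnames(m$values), factors$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples missing from normalization factors: ",
                 paste(missing, collapse = ", ")))
  }
  idx <- match(colnames(m$values), factors$sample_id)
  eff <- factors$library_size[idx] * factors$tmm_factor[idx]
  v <- sweep(m$values, 2, eff, "/") * 1e6
  if (log2_out) v <- log2(v + prior)
  expression_matrix(v, "cpm",
                    meta = c(m$meta, list(normalization = if (all(factors$tmm_factor == 1)) "cpm" else "tmm-cpm",
                                          log2 = as.character(log2_out))))
}

# internal: counts -> TMM-CPM (unit factors when a single sample)
as_cpm <- function(m) {
  if (m$platform == "cpm") return(m)
  if (m$platform != "counts") abort("Cannot convert intensities to CPM; scale them first.")
  f <- if (ncol(m$values) >= 2) compute_tmm_factors(m) else unit_factors(m)
  cpm_normalize(m, f)
}
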