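#' Barcode expression bins
#'
#' Summarises mean CPM per (gene, class) — or (gene, class, stage) — into the
#' barcode display bins `<50`, `50-100`, `100-1000`, `>1000` CPM. Boundary
#' values 50 and 100 fall in `50-100`, 1000 falls in `100-1000` (bins are
#' `[0,50)`, `[50,100]`, `(100,1000]`, `(1000,Inf)`). If a classifier-gene
#' table is supplied, each row is flagged when the gene classifies that class.
#'
#' @param cpm An `expr_matrix` with `platform = "cpm"`.
#' @param labels A `label_table` for the samples.
#' @param genes Character vector of genes to summarise (e.g. the barcode).
#' @param grouping `"class_stage"` (default: split by stage when present) or
#'   `"class"`.
#' @param classifier Optional `classifier_genes` tibble for the
#'   `in_classifying_tissue` flag.
#' @return A tibble: `gene_id`, `class`, `stage` (if grouped by stage),
#'   `mean_cpm`, `bin`, `in_classifying_tissue`.
#' @export
barcode_bins <- function(cpm, labels, genes,
                         grouping = c("class_stage", "class"),
                         classifier = NULL) {
  stopifnot(inherits(cpm, "expr_matrix"))
  if (cpm$platform != "cpm") abort("barcode_bins() needs platform = 'cpm'.")
  grouping <- match.arg(grouping)
  labels <- label_table(labels)
  missing <- setdiff(genes, gene_ids(cpm))
  if (length(missing) > 0) {
    abort(paste0("Genes absent from matrix: ", paste(head(missing, 5), collapse = ", ")))
  }
  lab <- labels[match(sample_ids(cpm), labels$sample_id), ]
  grp <- if (grouping == "class_stage" && any(!is.na(lab$stage))) {
    paste(lab$class_label, ifelse(is.na(lab$stage), "", lab$stage), sep = "|")
  } else {
    lab$class_label
  }
  v <- cpm$values[genes, , drop = FALSE]
  means <- t(apply(v, 1, function(row) tapply(row, grp, mean)))
  out <- tibble(
    gene_id = rep(rownames(means), times = ncol(means)),
    group = rep(colnames(means), each = nrow(means)),
    mean_cpm = as.vector(means)
  )
  if (grouping == "class_stage" && any(!is.na(lab$stage))) {
    parts <- strsplit(out$group, "|", fixed = TRUE)
    out$class <- vapply(parts, `[`, character(1), 1)
    out$stage <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1))
    out$stage[out$stage == ""] <- NA_character_
  } else {
    out$class <- out$group
  }
  out$group <- NULL
  out$bin <- cpm_bin(out$mean_cpm)
  out$in_classifying_tissue <- FALSE
  if (!is.null(classifier)) {
    key <- paste(classifier$class, classifier$gene_id)
    out$in_classifying_tissue <- paste(out$class, out$gene_id) %in% key
  }
  out
}

#' Bin CPM values on the barcode scale
#' @param x Numeric vector of CPM values.
#' @return Ordered factor with levels `<50`, `50-100`, `100-1000`, `>1000`.
#' @export
cpm_bin <- function(x) {
  stopifnot(all(x >= 0))
  lev <- c("<50", "50-100", "100-1000", ">1000")
  out <- ifelse(x < 50, lev[1],
         ifelse(x <= 100, lev[2],
         ifelse(x <= 1000, lev[3], lev[4])))
  factor(out, levels = lev, ordered = TRUE)
}

#' Hierarchical clustering of samples by expression correlation
#'
#' Distance between samples is `1 - Pearson r` of their CPM vectors over the
#' given genes; agglomeration is complete linkage. Ties are resolved by
#' sample order (the order of columns in `cpm`), so the result is
#' deterministic.
#'
#' @param cpm An `expr_matrix` with `platform = "cpm"`.
#' @param genes Character vector of genes to correlate over.
#' @return An [stats::hclust] object.
#' @export
cluster_samples <- function(cpm, genes) {
  stopifnot(inherits(cpm, "expr_matrix"))
  if (cpm$platform != "cpm") abort("cluster_samples() needs platform = 'cpm'.")
  if (ncol(cpm$values) < 2) abort("Need at least 2 samples to cluster.")
  missing <- setdiff(genes, gene_ids(cpm))
  if (length(missing) > 0) {
    abort(paste0("Genes absent from matrix: ", paste(head(missing, 5), collapse = ", ")))
  }
  v <- cpm$values[genes, , drop = FALSE]
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance sample(s) over the gene list (correlation undefined): ",
                 paste(colnames(v)[sds == 0], collapse = ", ")))
  }
  d <- as.dist(1 - cor(v))
  hclust(d, method = "complete")
}

#' Mean within-group expression correlation
#'
#' For every group (class, or class x stage) with at least two samples,
#' computes the mean and SD of Pearson correlations over all unordered
#' within-group sample pairs, using the CPM values of the given genes.
#' Groups with a single sample are skipped with a warning. The mean of the
#' group means is stored in the `overall_mean` attribute.
#'
#' @param cpm An `expr_matrix` with `platform = "cpm"`.
#' @param labels A `label_table`.
#' @param genes Genes to correlate over.
#' @param grouping `"by_class"` or `"by_class_and_stage"`.
#' @return A tibble: `group`, `n_samples`, `n_pairs`, `mean_r`, `sd_r`.
#' @export
mean_group_correlation <- function(cpm, labels, genes,
                                   grouping = c("by_class", "by_class_and_stage")) {
  stopifnot(inherits(cpm, "expr_matrix"))
  if (cpm$platform != "cpm") abort("mean_group_correlation() needs platform = 'cpm'.")
  grouping <- match.arg(grouping)
  labels <- label_table(labels)
  lab <- labels[match(sample_ids(cpm), labels$sample_id), ]
  grp <- if (grouping == "by_class_and_stage") {
    ifelse(is.na(lab$stage) | lab$stage == "", lab$class_label,
           paste(lab$class_label, lab$stage, sep = "_"))
  } else {
    lab$class_label
  }
  v <- cpm$values[genes, , drop = FALSE]
  singles <- names(which(table(grp) < 2))
  if (length(singles) > 0) {
    warn(paste0("Skipping group(s) with a single sample: ",
                paste(singles, collapse = ", ")))
  }
  out <- purrr::map_dfr(setdiff(sort(unique(grp)), singles), function(g) {
    cols <- which(grp == g)
    cm <- cor(v[, cols, drop = FALSE])
    rs <- cm[upper.tri(cm)]
    tibble(group = g, n_samples = length(cols), n_pairs = length(rs),
           mean_r = mean(rs), sd_r = stats::sd(rs))
  })
  attr(out, "overall_mean") <- mean(out$mean_r)
  out
}

#' Stage-specific high-expression gene partition
#'
#' For each stage dataset (e.g. first trimester, second trimester, adult),
#' the organ's "high" gene set contains the genes whose mean expression in
#' that organ's samples exceeds `times` (default 10) the baseline. With
#' `baseline = "per_gene"` the baseline is that gene's mean across all
#' samples of the stage dataset (an organ-enrichment ratio); with
#' `"whole_matrix"` it is the grand mean of the stage dataset. Genes are then
#' partitioned by the combination of stages in which they are high — the
#' disjoint regions of a Venn diagram.
#'
#' @param stage_sets Named list of stage datasets, each a
#'   `list(expr = expr_matrix, labels = label_table)`.
#' @param organ Class label of the organ to compare across stages.
#' @param times Enrichment multiple (default 10).
#' @param baseline `"per_gene"` (default) or `"whole_matrix"`.
#' @return A tibble `gene_id`, `stages` (`+`-joined stage names), `n_stages`;
#'   the per-stage high sets are in the `high_sets` attribute.
#' @export
stage_specific_genes <- function(stage_sets, organ, times = 10,
                                 baseline = c("per_gene", "whole_matrix")) {
  baseline <- match.arg(baseline)
  if (is.null(names(stage_sets)) || any(names(stage_sets) == "")) {
    abort("`stage_sets` must be a named list (stage name -> dataset).")
  }
  high <- list()
  for (st in names(stage_sets)) {
    ds <- stage_sets[[st]]
    labels <- label_table(ds$labels)
    lab <- labels[match(sample_ids(ds$expr), labels$sample_id), ]
    cols <- which(lab$class_label == organ)
    if (length(cols) == 0) {
      warn(sprintf("Organ '%s' absent from stage dataset '%s'; dropping it.", organ, st))
      next
    }
    v <- as_cpm(ds$expr)$values
    organ_mean <- rowMeans(v[, cols, drop = FALSE])
    base <- if (baseline == "per_gene") rowMeans(v) else mean(v)
    high[[st]] <- rownames(v)[organ_mean > times * base]
  }
  if (length(high) < 2) abort("Need the organ in at least 2 stage datasets.")
  all_genes <- sort(unique(unlist(high)))
  membership <- vapply(all_genes, function(g) {
    paste(names(high)[vapply(high, function(s) g %in% s, logical(1))], collapse = "+")
  }, character(1))
  out <- tibble(gene_id = all_genes, stages = unname(membership),
                n_stages = lengths(strsplit(unname(membership), "+", fixed = TRUE)))
  attr(out, "high_sets") <- high
  out
}
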