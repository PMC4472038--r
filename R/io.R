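#' Read a delimited gene-by-sample expression table
#'
#' Expects a header row of sample IDs and a first column of gene IDs; the body
#' must be numeric. The delimiter is auto-detected from the header (tab
#' preferred over comma) unless given. Duplicate gene rows are collapsed —
#' summed for counts (reads for the same gene add up), averaged for
#' intensities/CPM (many-to-one probe mappings) — with a warning.
#'
#' @param path Path to a TSV/CSV file.
#' @param platform `"counts"`, `"cpm"`, or `"intensity"`.
#' @param delimiter Optional single-character field separator.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, platform = c("counts", "cpm", "intensity"),
                                  delimiter = NULL) {
  platform <- match.arg(platform)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1L)
  if (is.null(delimiter)) delimiter <- if (grepl("\t", header)) "\t" else ","
  sample_names <- strsplit(header, delimiter, fixed = TRUE)[[1]][-1]
  sample_names <- trimws(sample_names)
  if (anyDuplicated(sample_names)) {
    abort(paste0("Duplicate sample IDs in header: ",
                 paste(unique(sample_names[duplicated(sample_names)]), collapse = ", ")))
  }
  raw <- suppressWarnings(readr::read_delim(
    path, delim = delimiter, skip = 1L,
    col_names = c(".gene", sample_names),
    col_types = do.call(readr::cols, c(
      list(.gene = readr::col_character()),
      stats::setNames(rep(list(readr::col_double()), length(sample_names)), sample_names)
    )),
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf(
      "Malformed numeric value in %s at file row %d, column %d (expected %s, got '%s').",
      path, p$row, p$col, p$expected, p$actual))
  }
  genes <- raw$.gene
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warn(sprintf("Collapsing %d duplicated gene ID(s) (%s) by %s.",
                 length(dups), paste(head(dups, 5), collapse = ", "),
                 if (platform == "counts") "summation" else "mean"))
    fun <- if (platform == "counts") colSums else colMeans
    groups <- split(seq_along(genes), factor(genes, levels = unique(genes)))
    collapsed <- do.call(rbind, lapply(groups, function(i) fun(m[i, , drop = FALSE])))
    dimnames(collapsed) <- list(unique(genes), colnames(m))
    m <- collapsed
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("Missing/non-numeric value at gene '%s', sample '%s'.",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (platform == "counts" && all(m == round(m)) && max(m) < .Machine$integer.max) {
    storage.mode(m) <- "integer"
  }
  expression_matrix(m, platform, meta = list(source = path))
}

#' Write an expression matrix as TSV
#'
#' Gene IDs in the first column (`gene_id`), one column per sample. Values are
#' written with full round-trip precision.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- as.data.frame(x$values)
  df <- cbind(gene_id = rownames(x$values), df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read a sample label table
#'
#' A TSV with a header and two or three columns: sample ID, class label and an
#' optional stage (e.g. trimester `1T`/`2T`). Labels are trimmed of
#' surrounding whitespace; case is preserved.
#'
#' @param path Path to a TSV file.
#' @return A `label_table` tibble with columns `sample_id`, `class_label`,
#'   `stage` (NA when absent).
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2 || ncol(df) > 3) {
    abort(sprintf("Label table must have 2 or 3 columns, found %d.", ncol(df)))
  }
  names(df)[1:2] <- c("sample_id", "class_label")
  if (ncol(df) == 2) df$stage <- NA_character_ else names(df)[3] <- "stage"
  label_table(df)
}

#' Construct and validate a label table
#'
#' @param x A data frame with columns `sample_id`, `class_label` and
#'   optionally `stage`.
#' @return A validated `label_table` tibble.
#' @export
label_table <- function(x) {
  df <- as_tibble(x)
  if (!all(c("sample_id", "class_label") %in% names(df))) {
    abort("Label table needs columns `sample_id` and `class_label`.")
  }
  if (!"stage" %in% names(df)) df$stage <- NA_character_
  df <- df[, c("sample_id", "class_label", "stage")]
  df$sample_id <- trimws(df$sample_id)
  df$class_label <- trimws(df$class_label)
  df$stage <- trimws(df$stage)
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("Duplicate sample IDs in label table: ",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  }
  if (any(is.na(df$class_label) | df$class_label == "")) {
    abort("Empty class label(s) in label table.")
  }
  sizes <- table(df$class_label)
  if (any(sizes < 2)) {
    warn(paste0("Classes with a single sample (cross-validation degenerates for them): ",
                paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  class(df) <- c("label_table", class(df))
  df
}

#' Read a one-ID-per-line gene panel
#'
#' @param path Path to a text file, one gene ID per line.
#' @param name Panel name stored with the list.
#' @return A `gene_panel` object: list with `gene_ids` and `name`.
#' @export
read_gene_panel <- function(path, name = basename(path)) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ids <- trimws(readLines(path))
  ids <- ids[ids != ""]
  gene_panel(ids, name)
}

#' @rdname read_gene_panel
#' @param gene_ids Character vector of gene IDs.
#' @export
gene_panel <- function(gene_ids, name = "panel") {
  if (length(gene_ids) == 0) abort("Gene panel is empty.")
  if (anyDuplicated(gene_ids)) {
    warn("Dropping duplicated IDs in gene panel.")
    gene_ids <- unique(gene_ids)
  }
  structure(list(gene_ids = gene_ids, name = name), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> '%s', %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}
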