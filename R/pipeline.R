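#' Run a pipeline command
#'
#' Single programmatic entry point mirroring the command-line tool. Three
#' commands correspond to the classical three analysis scripts — `top500`
#' (rank the most variable genes), `predict` (sequencing query against a
#' sequencing atlas) and `predict-array` (microarray query; identical to
#' `predict` plus the housekeeping scaling hook, implemented as the same
#' code path so the two cannot drift) — plus `simulate` (atlas-like fixture
#' generation) and `report` (validate and summarise a score matrix).
#'
#' Every run writes a `manifest.json` next to its outputs recording the
#' command, the resolved parameters, MD5 digests of the input files, the
#' seed, and the package version. All randomness is seeded: an omitted seed
#' defaults to 1, never the clock, so reruns with the same manifest inputs
#' reproduce outputs byte-identically.
#'
#' @param command One of `"simulate"`, `"top500"`, `"predict"`,
#'   `"predict-array"`, `"report"`.
#' @param params Named list of parameters (see Details).
#' @param config Optional path to a YAML file of defaults; explicit `params`
#'   override it.
#'
#' @details Parameters by command:
#' \describe{
#'   \item{simulate}{`out` (directory), `seed`, `samples_per_tissue`,
#'     `array` (also write a distorted microarray rendering),
#'     `probe_fraction`, `noise_sd`, `gain`, `offset`.}
#'   \item{top500}{`expr` (counts TSV), `n`, `measure`, `out` (gene list
#'     file).}
#'   \item{predict}{`train`, `train_labels`, `test` (TSV paths), `top_n` or
#'     `gene_list`, `cutoff` (detection, default 4), `nfolds`, `rule`,
#'     `seed`, `out_prefix`.}
#'   \item{predict-array}{as `predict`, plus `housekeepers` (panel file),
#'     `scaling` (`affine`/`offset`/`quantile`), `detection_cpm`.}
#'   \item{report}{`scores` (TSV), `out` (directory).}
#' }
#'
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(command = c("simulate", "top500", "predict",
                                     "predict-array", "report"),
                         params = list(), config = NULL) {
  command <- match.arg(command)
  if (!is.null(config)) {
    defaults <- yaml::read_yaml(config)
    params <- utils::modifyList(defaults, params)
  }
  params$seed <- as.integer(params$seed %||% 1L)
  out <- switch(command,
    "simulate" = cmd_simulate(params),
    "top500" = cmd_top500(params),
    "predict" = cmd_predict(params, scaling = FALSE),
    "predict-array" = cmd_predict(params, scaling = TRUE),
    "report" = cmd_report(params)
  )
  manifest <- list(
    command = command,
    parameters = params[order(names(params))],
    inputs = manifest_digests(attr(out, "inputs")),
    seed = params$seed,
    tool_version = as.character(utils::packageVersion("tissueid")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(attr(out, "out_dir"), "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out <- c(out, list(manifest = manifest_path))
  invisible(out)
}

manifest_digests <- function(paths) {
  if (is.null(paths) || length(paths) == 0) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

req_param <- function(params, name) {
  if (is.null(params[[name]])) {
    abort(sprintf("Missing required parameter `%s`.", name), class = "tissueid_usage")
  }
  params[[name]]
}

cmd_simulate <- function(params) {
  out_dir <- req_param(params, "out")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulation_truth()
  spt <- params$samples_per_tissue %||% 5
  sim <- simulate_tissue_counts(truth, spt, seed = params$seed)
  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    labels = file.path(out_dir, "labels.tsv"),
    truth = file.path(out_dir, "truth.json"),
    housekeepers = file.path(out_dir, "housekeepers.txt")
  )
  holdout <- params$holdout %||% 0
  if (holdout > 0) {
    # hold out the last `holdout` samples of each tissue as a test set
    idx <- as.integer(sub(".*_", "", sim$labels$sample_id))
    test_ids <- sim$labels$sample_id[idx > spt - holdout]
    train_ids <- setdiff(sim$labels$sample_id, test_ids)
    paths$test_counts <- file.path(out_dir, "test_counts.tsv")
    paths$test_labels <- file.path(out_dir, "test_labels.tsv")
    write_expression_table(subset_expr(sim$expr, samples = test_ids),
                           paths$test_counts)
    readr::write_tsv(tibble::as_tibble(sim$labels[idx > spt - holdout, ]),
                     paths$test_labels, progress = FALSE)
    sim$expr <- subset_expr(sim$expr, samples = train_ids)
    sim$labels <- sim$labels[idx <= spt - holdout, ]
  }
  write_expression_table(sim$expr, paths$counts)
  readr::write_tsv(tibble::as_tibble(sim$labels), paths$labels, progress = FALSE)
  write_simulation_truth(truth, paths$truth)
  writeLines(truth$housekeepers, paths$housekeepers)
  if (isTRUE(params$array)) {
    arr <- simulate_microarray(sim$expr, truth,
                               probe_fraction = params$probe_fraction %||% 0.7,
                               noise_sd = params$noise_sd %||% 0.2,
                               gain = params$gain %||% 1.3,
                               offset = params$offset %||% 2,
                               seed = params$seed)
    paths$array <- file.path(out_dir, "array.tsv")
    write_expression_table(arr, paths$array)
  }
  structure(paths, out_dir = out_dir, inputs = list())
}

cmd_top500 <- function(params) {
  expr_path <- req_param(params, "expr")
  out_path <- req_param(params, "out")
  m <- read_expression_table(expr_path, platform = params$platform %||% "counts")
  if (m$platform == "counts") m <- filter_detected(m, params$cutoff %||% 4)
  top <- top_variable_genes(m, n = params$n %||% 500,
                            measure = params$measure %||% "variance_logcpm")
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  writeLines(top$gene_id, out_path)
  structure(list(gene_list = out_path),
            out_dir = dirname(out_path), inputs = list(expr = expr_path))
}

cmd_predict <- function(params, scaling = FALSE) {
  train_path <- req_param(params, "train")
  labels_path <- req_param(params, "train_labels")
  test_path <- req_param(params, "test")
  out_prefix <- req_param(params, "out_prefix")
  out_dir <- dirname(out_prefix)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  train <- read_expression_table(train_path, platform = "counts")
  labels <- read_label_table(labels_path)
  train <- filter_detected(train, params$cutoff %||% 4)
  inputs <- list(train = train_path, train_labels = labels_path, test = test_path)

  candidates <- if (!is.null(params$gene_list)) {
    inputs$gene_list <- params$gene_list
    read_gene_panel(params$gene_list)$gene_ids
  } else {
    top_variable_genes(train, n = params$top_n %||% 500)$gene_id
  }

  if (scaling) {
    test_raw <- read_expression_table(test_path, platform = "intensity")
    hk_path <- req_param(params, "housekeepers")
    inputs$housekeepers <- hk_path
    panel <- read_gene_panel(hk_path)
    hk <- select_housekeepers(panel, train, test_raw,
                              detection_cpm = params$detection_cpm %||% 1)
    test <- scale_to_training(test_raw, train, hk,
                              mode = params$scaling %||% "affine")
  } else {
    test <- read_expression_table(test_path, platform = "counts")
  }

  model <- fit_identity_classifier(train, labels, candidates,
                                   test_genes = gene_ids(test),
                                   nfolds = params$nfolds %||% 10,
                                   rule = params$rule %||% "min",
                                   seed = params$seed)
  pred <- predict_identity(model, test)

  paths <- list(scores = paste0(out_prefix, ".scores.tsv"),
                calls = paste0(out_prefix, ".calls.tsv"),
                classifier_genes = paste0(out_prefix, ".classifier_genes.tsv"))
  scores_df <- tibble::as_tibble(cbind(
    data.frame(class = rownames(pred$scores)),
    as.data.frame(pred$scores)))
  readr::write_tsv(scores_df, paths$scores, progress = FALSE)
  readr::write_tsv(pred$calls, paths$calls, progress = FALSE)
  cg <- classifier_genes(model)
  readr::write_tsv(tibble::as_tibble(cg), paths$classifier_genes, progress = FALSE)
  structure(paths, out_dir = out_dir, inputs = inputs)
}

cmd_report <- function(params) {
  scores_path <- req_param(params, "scores")
  out_dir <- req_param(params, "out")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- readr::read_tsv(scores_path, col_types = readr::cols(
    class = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$class
  sums <- colSums(m)
  bad <- which(abs(sums - 1) > 1e-8 | apply(m, 2, min) < 0 | apply(m, 2, max) > 1)
  if (length(bad) > 0) {
    abort(sprintf("Invalid identity scores for sample '%s': column sum %.6f (must be 1, entries in [0,1]).",
                  colnames(m)[bad[1]], sums[bad[1]]))
  }
  calls <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    ord <- order(-m[, j], rownames(m), method = "radix")
    tibble(sample_id = colnames(m)[j],
           best_class = rownames(m)[ord[1]], best_score = m[ord[1], j],
           second_class = rownames(m)[ord[2]], second_score = m[ord[2], j])
  })
  paths <- list(calls = file.path(out_dir, "calls.tsv"),
                summary = file.path(out_dir, "summary.tsv"))
  readr::write_tsv(calls, paths$calls, progress = FALSE)
  readr::write_tsv(tibble(
    n_samples = ncol(m), n_classes = nrow(m),
    mean_best_score = mean(calls$best_score),
    min_best_score = min(calls$best_score)), paths$summary, progress = FALSE)
  structure(paths, out_dir = out_dir, inputs = list(scores = scores_path))
}
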