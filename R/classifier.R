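#' Compose a training set from atlas pieces
#'
#' Builds the training matrix + labels actually handed to the classifier:
#' optionally restricted to a subset of classes (e.g. dropping extraembryonic
#' tissues), optionally splitting classes by developmental stage
#' (`"pancreas"` with stages `1T`/`2T` becomes `pancreas_1T`, `pancreas_2T`),
#' and optionally augmented with further labelled datasets (e.g. adult islet
#' samples), restricted to the shared gene namespace.
#'
#' @param m An `expr_matrix` of training expression.
#' @param labels A `label_table` covering the samples of `m`.
#' @param include Optional character vector of class labels to keep.
#' @param split_by_stage If `TRUE`, class labels become `class_stage` for
#'   samples with a non-missing stage.
#' @param augment Optional list of `list(expr = , labels = )` datasets to
#'   merge; genes are intersected across all matrices.
#' @return A list with elements `expr` and `labels`.
#' @export
compose_training_set <- function(m, labels, include = NULL,
                                 split_by_stage = FALSE, augment = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  labels <- label_table(labels)
  parts <- c(list(list(expr = m, labels = labels)),
             lapply(augment, function(p) list(expr = p$expr, labels = label_table(p$labels))))
  genes <- Reduce(intersect, lapply(parts, function(p) gene_ids(p$expr)))
  if (length(genes) == 0) abort("Augmenting datasets share no genes with the training set.")
  platforms <- unique(vapply(parts, function(p) p$expr$platform, character(1)))
  if (length(platforms) > 1) {
    abort("All training datasets must share one platform (counts or cpm).")
  }
  vals <- do.call(cbind, lapply(parts, function(p) p$expr$values[genes, , drop = FALSE]))
  lab <- dplyr::bind_rows(lapply(parts, function(p) tibble::as_tibble(p$labels)))
  lab <- lab[match(colnames(vals), lab$sample_id), ]
  if (anyNA(lab$sample_id)) abort("Label table does not cover every training sample.")
  if (!is.null(include)) {
    keep <- lab$class_label %in% include
    if (!any(keep)) abort("Class filter removed every training sample.")
    vals <- vals[, keep, drop = FALSE]
    lab <- lab[keep, ]
  }
  if (isTRUE(split_by_stage)) {
    has_stage <- !is.na(lab$stage) & lab$stage != ""
    lab$class_label[has_stage] <- paste(lab$class_label[has_stage],
                                        lab$stage[has_stage], sep = "_")
  }
  list(expr = expression_matrix(vals, platforms, m$meta),
       labels = label_table(lab))
}

# seeded stratified fold assignment; classes smaller than nfolds are spread
# round-robin from a random offset so their samples land in distinct folds
make_folds <- function(y, nfolds, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- if (length(idx) > 1) sample(idx) else idx
      off <- sample.int(nfolds, 1)
      fold[idx] <- ((seq_along(idx) + off - 2L) %% nfolds) + 1L
    }
  })
  # folds that received no sample (possible when classes are much smaller
  # than nfolds) are dropped by renumbering to consecutive ids
  match(fold, sort(unique(fold)))
}

#' Fit the identity classifier (cross-validated multinomial LASSO)
#'
#' Restricts the feature space to `candidate_genes` that are present in both
#' the training matrix and the query (`test_genes`) — the feature space is
#' therefore recomputed per query, which is why classifier-gene sets differ
#' between runs against different platforms. Training values are transformed
#' to `log2(CPM + 1)` and standardized per gene (mean 0, sd 1, training-derived
#' and stored for reuse on the query). A multinomial logistic model with an
#' L1 penalty is fit over a decreasing penalty path (100 values, log-spaced
#' down to `1e-4` of the smallest all-null penalty) via `glmnet`, and the
#' penalty is selected by seeded, class-stratified 10-fold cross-validation
#' on multinomial deviance.
#'
#' @param train An `expr_matrix` (`counts` or `cpm`) of reference samples.
#' @param labels A `label_table` covering the training samples.
#' @param candidate_genes A `variable_genes` tibble (see
#'   [top_variable_genes()]) or character vector of candidate gene IDs.
#' @param test_genes Character vector of gene IDs measured in the query;
#'   `NULL` keeps all candidates present in training.
#' @param nfolds Number of cross-validation folds (default 10; reduced with a
#'   warning when it exceeds the sample count).
#' @param rule Penalty selection rule: `"min"` (deviance-minimizing, default)
#'   or `"one_se"` (largest penalty within one standard error of the
#'   minimum).
#' @param seed Integer seed controlling fold assignment; recorded in the
#'   fitted object.
#' @param nlambda,lambda_min_ratio Penalty path length and span.
#' @param thresh Convergence threshold passed to the coordinate-descent
#'   solver (default `1e-12`; tighten for numerical comparisons).
#' @return An `identity_classifier` object.
#' @export
fit_identity_classifier <- function(train, labels, candidate_genes,
                                    test_genes = NULL, nfolds = 10,
                                    rule = c("min", "one_se"), seed = 1,
                                    nlambda = 100, lambda_min_ratio = 1e-4,
                                    thresh = 1e-12) {
  stopifnot(inherits(train, "expr_matrix"))
  rule <- match.arg(rule)
  labels <- label_table(labels)
  if (is.data.frame(candidate_genes)) candidate_genes <- candidate_genes$gene_id
  lab <- labels[match(sample_ids(train), labels$sample_id), ]
  if (anyNA(lab$sample_id)) abort("Label table does not cover every training sample.")
  y <- factor(lab$class_label)
  if (nlevels(y) < 2) abort("Training needs at least 2 classes.")

  feats <- intersect(candidate_genes, gene_ids(train))
  if (!is.null(test_genes)) feats <- intersect(feats, test_genes)
  if (length(feats) == 0) {
    abort("Empty feature space: no candidate gene is present in both training and query.")
  }

  cpm <- as_cpm(train)
  z <- log2(cpm$values[feats, , drop = FALSE] + 1)
  mu <- rowMeans(z)
  sd_ <- apply(z, 1, stats::sd)
  degenerate <- sd_ == 0
  if (any(degenerate)) {
    warn(sprintf("Dropping %d feature gene(s) with zero variance in training.",
                 sum(degenerate)))
    feats <- feats[!degenerate]
    z <- z[!degenerate, , drop = FALSE]
    mu <- mu[!degenerate]; sd_ <- sd_[!degenerate]
    if (length(feats) == 0) abort("All candidate features have zero training variance.")
  }
  x <- t((z - mu) / sd_)

  n <- ncol(train$values)
  if (nfolds > n) {
    warn(sprintf("nfolds = %d exceeds the %d training samples; using %d folds.",
                 nfolds, n, n))
    nfolds <- n
  }
  if (nfolds < 3) abort("Cross-validation needs at least 3 folds.")
  foldid <- make_folds(as.character(y), nfolds, seed)

  cvfit <- withCallingHandlers(
    glmnet::cv.glmnet(x, y, family = "multinomial", foldid = foldid,
                      nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
                      standardize = FALSE, type.measure = "deviance",
                      thresh = thresh, maxit = 1e7),
    warning = function(w) {
      # glmnet emits these on every fold fit when classes have few
      # replicates; the atlas legitimately has small n per tissue
      if (grepl(paste0("fewer than 8\\s+observations|not a multiple of vector length|",
                       "grouped=FALSE enforced"),
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  selected <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  fit <- cvfit$glmnet.fit
  s_idx <- which.min(abs(fit$lambda - selected))
  beta <- t(vapply(fit$beta, function(b) as.numeric(b[, s_idx]),
                   numeric(length(feats))))
  colnames(beta) <- feats
  rownames(beta) <- names(fit$beta)
  beta <- beta[levels(y), , drop = FALSE]

  structure(list(
    classes = levels(y),
    feature_genes = feats,
    coefficients = beta,
    intercepts = stats::setNames(fit$a0[levels(y), s_idx], levels(y)),
    penalty_path = fit$lambda,
    cv_deviance = tibble(penalty = cvfit$lambda, mean = cvfit$cvm,
                         se = cvfit$cvsd, nonzero = cvfit$nzero),
    selected_penalty = selected,
    selection_rule = rule,
    transform = list(kind = "standardized log2(CPM+1)", mean = mu, sd = sd_),
    class_counts = table(y),
    fold_seed = seed,
    nfolds = nfolds,
    glmnet_fit = fit
  ), class = "identity_classifier")
}

#' @export
print.identity_classifier <- function(x, ...) {
  cat(sprintf("<identity_classifier> %d classes, %d feature genes\n",
              length(x$classes), length(x$feature_genes)))
  cat(sprintf("selected penalty %.5g (rule = %s, %d-fold CV, seed %d); %d classifier genes\n",
              x$selected_penalty, x$selection_rule, x$nfolds, x$fold_seed,
              sum(colSums(x$coefficients != 0) > 0)))
  invisible(x)
}

# query expression -> standardized matrix in the model's feature space
transform_query <- function(model, test) {
  missing <- setdiff(model$feature_genes, gene_ids(test))
  if (length(missing) > 0) {
    abort(paste0("Query is missing feature gene(s): ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  cpm <- as_cpm(test)
  z <- log2(cpm$values[model$feature_genes, , drop = FALSE] + 1)
  t((z - model$transform$mean) / model$transform$sd)
}

#' Predict identity scores for query samples
#'
#' Applies the stored training transform (training-derived standardization of
#' `log2(CPM + 1)`) to the query and returns multinomial class probabilities
#' — the identity scores. Each query column of the score matrix lies in
#' `[0, 1]` and sums to 1; the best and second-best class calls are tabulated.
#'
#' @param model An `identity_classifier`.
#' @param test An `expr_matrix` (`counts` or `cpm`) containing every feature
#'   gene of the model.
#' @param penalty Penalty at which to predict; defaults to the CV-selected
#'   one.
#' @return An `identity_scores` object: list with `scores` (class-by-sample
#'   matrix) and `calls` (tibble: `sample_id`, `best_class`, `best_score`,
#'   `second_class`, `second_score`).
#' @export
predict_identity <- function(model, test, penalty = NULL) {
  stopifnot(inherits(model, "identity_classifier"), inherits(test, "expr_matrix"))
  penalty <- penalty %||% model$selected_penalty
  newx <- transform_query(model, test)
  p <- predict(model$glmnet_fit, newx = newx, s = penalty, type = "response")[, , 1]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(rownames(newx), names(p)))
  scores <- t(p)[model$classes, , drop = FALSE]
  colnames(scores) <- rownames(newx)
  stopifnot(all(scores >= 0), all(scores <= 1),
            all(abs(colSums(scores) - 1) < 1e-8))
  calls <- purrr::map_dfr(seq_len(ncol(scores)), function(j) {
    ord <- order(-scores[, j], model$classes, method = "radix")
    tibble(sample_id = colnames(scores)[j],
           best_class = model$classes[ord[1]],
           best_score = scores[ord[1], j],
           second_class = model$classes[ord[2]],
           second_score = scores[ord[2], j])
  })
  structure(list(scores = scores, calls = calls, penalty = penalty),
            class = "identity_scores")
}

#' @export
print.identity_scores <- function(x, ...) {
  cat(sprintf("<identity_scores> %d classes x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  print(x$calls, n = 10)
  invisible(x)
}

#' Extract classifier genes (the transcriptional barcode)
#'
#' Genes with a nonzero coefficient for a class at the selected penalty,
#' sorted within class by coefficient magnitude. A gene may classify several
#' classes. The deduplicated union, with per-gene class membership, is in the
#' `union` attribute.
#'
#' @param model An `identity_classifier`.
#' @return A `classifier_genes` tibble: `class`, `gene_id`, `coefficient`.
#' @export
classifier_genes <- function(model) {
  stopifnot(inherits(model, "identity_classifier"))
  beta <- model$coefficients
  out <- purrr::map_dfr(rownames(beta), function(cl) {
    nz <- which(beta[cl, ] != 0)
    if (length(nz) == 0) return(tibble(class = character(), gene_id = character(),
                                       coefficient = numeric()))
    ord <- nz[order(-abs(beta[cl, nz]), colnames(beta)[nz], method = "radix")]
    tibble(class = cl, gene_id = colnames(beta)[ord],
           coefficient = unname(beta[cl, ord]))
  })
  un <- out |>
    group_by(.data$gene_id) |>
    summarise(n_classes = dplyr::n(),
              classes = paste(sort(.data$class), collapse = "+"),
              .groups = "drop") |>
    arrange(.data$gene_id)
  attr(out, "union") <- un
  class(out) <- c("classifier_genes", class(out))
  out
}

#' Tidy an identity classifier: nonzero coefficients at the selected penalty
#' @param x An `identity_classifier`.
#' @param ... Unused.
#' @return A tibble with `class`, `gene_id`, `coefficient`.
#' @export
tidy.identity_classifier <- function(x, ...) {
  out <- classifier_genes(x)
  attr(out, "union") <- NULL
  class(out) <- class(tibble())
  out
}

#' One-row summary of an identity classifier fit
#' @param x An `identity_classifier`.
#' @param ... Unused.
#' @export
glance.identity_classifier <- function(x, ...) {
  i <- which.min(abs(x$cv_deviance$penalty - x$selected_penalty))
  tibble(n_classes = length(x$classes),
         n_features = length(x$feature_genes),
         n_classifier_genes = nrow(attr(classifier_genes(x), "union")),
         selected_penalty = x$selected_penalty,
         selection_rule = x$selection_rule,
         cv_deviance = x$cv_deviance$mean[i],
         nfolds = x$nfolds,
         fold_seed = x$fold_seed)
}

#' Tidy identity scores into a long tibble
#' @param x An `identity_scores` object.
#' @param ... Unused.
#' @return A tibble with `class`, `sample_id`, `score`.
#' @export
tidy.identity_scores <- function(x, ...) {
  tibble(class = rep(rownames(x$scores), times = ncol(x$scores)),
         sample_id = rep(colnames(x$scores), each = nrow(x$scores)),
         score = as.vector(x$scores))
}

#' Intersect classifier-gene sets across runs
#'
#' The genes used across several prediction runs (e.g. against different
#' query platforms) can be intersected to find the common core of the
#' barcode.
#'
#' @param ... `classifier_genes` tibbles (or character vectors of gene IDs).
#' @return Character vector of gene IDs present in every set.
#' @export
intersect_classifier_genes <- function(...) {
  sets <- lapply(list(...), function(s) {
    if (is.data.frame(s)) unique(s$gene_id) else unique(as.character(s))
  })
  sort(Reduce(intersect, sets))
}
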