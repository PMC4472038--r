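# small well-separated fixture so classifier tests stay fast
small_truth <- function(...) {
  simulation_truth(tissues = c("brain", "heart", "liver", "kidney"),
                   n_genes = 600, n_markers = 10, n_housekeepers = 50, ...)
}

test_that("compose_training_set filters classes, splits stages, and augments", {
  tr <- small_truth()
  sim <- simulate_tissue_counts(tr, 2, seed = 4)
  comp <- compose_training_set(sim$expr, sim$labels,
                               include = c("brain", "heart"))
  expect_setequal(unique(comp$labels$class_label), c("brain", "heart"))
  expect_equal(ncol(comp$expr$values), 4L)
  expect_error(compose_training_set(sim$expr, sim$labels, include = "bone"),
               "removed every")

  # 2 classes x 2 stages -> 4 single-sample classes (flagged)
  expect_warning(
    two <- compose_training_set(sim$expr, sim$labels,
                                include = c("brain", "heart"),
                                split_by_stage = TRUE),
    "single sample")
  expect_setequal(unique(two$labels$class_label),
                  c("brain_1T", "brain_2T", "heart_1T", "heart_2T"))

  # augmentation intersects gene namespaces
  sim2 <- simulate_tissue_counts(small_truth(), 2, seed = 5)
  aug <- sim2$expr
  rownames(aug$values) <- paste0("alt_", rownames(aug$values))
  aug$labels <- sim2$labels
  expect_error(
    compose_training_set(sim$expr, sim$labels,
                         augment = list(list(expr = aug, labels = sim2$labels))),
    "no genes")

  aug2 <- subset_expr(sim2$expr, genes = 1:400)
  lab2 <- sim2$labels
  lab2$sample_id <- paste0("x_", lab2$sample_id)
  colnames(aug2$values) <- lab2$sample_id
  merged <- compose_training_set(sim$expr, sim$labels,
                                 augment = list(list(expr = aug2, labels = lab2)))
  expect_equal(nrow(merged$expr$values), 400L)
  expect_equal(ncol(merged$expr$values), 16L)
})

fit_small <- function(seed = 3, sim_seed = 21, spt = 4, ...) {
  tr <- small_truth()
  sim <- simulate_tissue_counts(tr, spt, seed = sim_seed)
  model <- fit_identity_classifier(sim$expr, sim$labels,
                                   top_variable_genes(sim$expr, 200),
                                   seed = seed, ...)
  list(truth = tr, sim = sim, model = model)
}

test_that("fold seed changes the penalty but not well-separated calls", {
  tr <- small_truth()
  sim <- simulate_tissue_counts(tr, 5, seed = 31)
  held <- sim$labels$sample_id[grepl("_5$", sim$labels$sample_id)]
  train <- subset_expr(sim$expr, samples = setdiff(sim$labels$sample_id, held))
  test <- subset_expr(sim$expr, samples = held)
  lab <- sim$labels[sim$labels$sample_id %in% sample_ids(train), ]
  top <- top_variable_genes(train, 200)
  m1 <- fit_identity_classifier(train, lab, top, test_genes = gene_ids(test), seed = 1)
  m2 <- fit_identity_classifier(train, lab, top, test_genes = gene_ids(test), seed = 2)
  expect_identical(predict_identity(m1, test)$calls$best_class,
                   predict_identity(m2, test)$calls$best_class)
})

test_that("the maximal penalty gives an intercept-only model scoring class priors", {
  fs <- fit_small()
  model <- fs$model
  lambda_max <- max(model$penalty_path)
  beta_max <- sapply(model$glmnet_fit$beta, function(b) as.numeric(b[, 1]))
  expect_true(all(beta_max == 0))

  pred <- predict_identity(model, fs$sim$expr, penalty = lambda_max)
  priors <- as.numeric(table(fs$sim$labels$class_label)[model$classes]) /
    nrow(fs$sim$labels)
  for (j in seq_len(ncol(pred$scores))) {
    expect_equal(unname(pred$scores[, j]), priors, tolerance = 1e-6)
  }
})

test_that("a perfectly separating gene dominates and matches the convex oracle", {
  withr::with_seed(6, {
    v <- matrix(rpois(20 * 12, 100), 20, 12)
    v[1, 1:6] <- v[1, 1:6] + 900L  # separates the two classes
  })
  dimnames(v) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12))
  m <- expression_matrix(v, "counts")
  lab <- label_table(tibble::tibble(sample_id = colnames(v),
                                    class_label = rep(c("a", "b"), each = 6)))
  model <- fit_identity_classifier(m, lab, gene_ids(m), nfolds = 6, seed = 2)
  mags <- apply(abs(model$coefficients), 2, max)
  expect_equal(names(which.max(mags)), "g01")

  # coefficients at the selected penalty agree with the independent solver
  cpmv <- cpm_normalize(m, compute_tmm_factors(m))$values
  z <- log2(cpmv[model$feature_genes, , drop = FALSE] + 1)
  x <- t((z - rowMeans(z)) / apply(z, 1, sd))
  y <- factor(rep(c("a", "b"), each = 6))
  ref <- fista_multinom(x, y, model$selected_penalty)
  expect_lt(max(abs(t(model$coefficients) - ref$B)), 1e-6)
})

test_that("prediction scores are valid probabilities with ordered hits", {
  fs <- fit_small()
  pred <- predict_identity(fs$model, fs$sim$expr)
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
  expect_equal(unname(colSums(pred$scores)), rep(1, ncol(pred$scores)),
               tolerance = 1e-8)
  expect_true(all(pred$calls$best_score >= pred$calls$second_score))
  expect_error(predict_identity(fs$model, subset_expr(fs$sim$expr, genes = 1:10)),
               "missing feature gene")
})

test_that("identical inputs and seed reproduce the fit exactly", {
  a <- fit_small(seed = 9)
  b <- fit_small(seed = 9)
  expect_identical(a$model$coefficients, b$model$coefficients)
  expect_identical(a$model$selected_penalty, b$model$selected_penalty)
  expect_identical(classifier_genes(a$model), classifier_genes(b$model))
})

test_that("support grows as the penalty relaxes along the path", {
  # the active set can transiently shed a gene between knots, so the check
  # is on the trend, not every step: empty at the top of the path, strongly
  # increasing towards its bottom
  fs <- fit_small()
  nz <- colSums(Reduce(`+`, lapply(fs$model$glmnet_fit$beta,
                                   function(b) as.matrix(b != 0))) > 0)
  expect_equal(unname(nz[1]), 0)
  expect_gt(cor(seq_along(nz), nz, method = "spearman"), 0.9)
  expect_gte(unname(nz[length(nz)]), max(nz) - 2)
})

test_that("classifier gene extraction respects the selected penalty", {
  fs <- fit_small()
  cg <- classifier_genes(fs$model)
  expect_true(all(cg$coefficient != 0))
  beta <- fs$model$coefficients
  expect_equal(nrow(cg), sum(beta != 0))
  # sorted by magnitude within class
  by_class <- split(abs(cg$coefficient), cg$class)
  expect_true(all(vapply(by_class, function(v) all(diff(v) <= 0), logical(1))))
  un <- attr(cg, "union")
  expect_true(all(un$n_classes >= 1))

  # intercept-only model yields empty sets
  m0 <- fs$model
  m0$coefficients[] <- 0
  expect_equal(nrow(classifier_genes(m0)), 0L)
})

test_that("tidy and glance summarise the fit", {
  fs <- fit_small()
  td <- tidy(fs$model)
  expect_named(td, c("class", "gene_id", "coefficient"))
  gl <- glance(fs$model)
  expect_equal(gl$n_classes, 4L)
  expect_equal(gl$fold_seed, 3)
  expect_true(gl$selected_penalty %in% fs$model$penalty_path)

  pred <- predict_identity(fs$model, fs$sim$expr)
  long <- tidy(pred)
  expect_equal(nrow(long), length(fs$model$classes) * ncol(fs$sim$expr$values))
  expect_s3_class(autoplot(pred), "ggplot")
  expect_s3_class(autoplot(fs$model), "ggplot")
})

test_that("classifier-gene sets intersect across runs", {
  expect_equal(intersect_classifier_genes(c("a", "b", "c"), c("b", "c", "d"),
                                          c("c", "b")),
               c("b", "c"))
})
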