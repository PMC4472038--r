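labelled_cpm <- function(v, classes, stages = NULL) {
  m <- expression_matrix(v, "cpm")
  lt <- suppressWarnings(label_table(tibble::tibble(
    sample_id = colnames(v), class_label = classes,
    stage = stages %||% NA_character_)))
  list(expr = m, labels = lt)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("barcode bins follow the legend edges, boundaries to the lower bin", {
  expect_equal(as.character(cpm_bin(c(0, 75, 1500, 49.99, 50, 100, 100.01, 1000, 1000.01))),
               c("<50", "50-100", ">1000", "<50", "50-100", "50-100",
                 "100-1000", "100-1000", ">1000"))
})

test_that("barcode table averages per class/stage and flags classifier genes", {
  v <- matrix(c(60, 2000, 90, 1200, 10, 30, 20, 40), 2, 4,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  fx <- labelled_cpm(v, c("brain", "brain", "liver", "liver"),
                     c("1T", "1T", "1T", "1T"))
  bins <- barcode_bins(fx$expr, fx$labels, c("gA", "gB"))
  brain_a <- bins[bins$gene_id == "gA" & bins$class == "brain", ]
  expect_equal(brain_a$mean_cpm, 75)
  expect_equal(as.character(brain_a$bin), "50-100")
  brain_b <- bins[bins$gene_id == "gB" & bins$class == "brain", ]
  expect_equal(as.character(brain_b$bin), ">1000")
  liver_b <- bins[bins$gene_id == "gB" & bins$class == "liver", ]
  expect_equal(as.character(liver_b$bin), "<50")

  clf <- tibble::tibble(class = "brain", gene_id = "gB", coefficient = 1.2)
  bins2 <- barcode_bins(fx$expr, fx$labels, c("gA", "gB"), classifier = clf)
  expect_true(bins2$in_classifying_tissue[bins2$gene_id == "gB" &
                                            bins2$class == "brain"])
  expect_false(any(bins2$in_classifying_tissue[bins2$gene_id == "gA"]))
  expect_s3_class(plot_barcode(bins2), "ggplot")
})

test_that("correlation clustering matches Pearson geometry", {
  withr::with_seed(21, base <- rexp(30, 1 / 100))
  v <- cbind(s1 = base, s2 = base, s3 = 2 * base, s4 = rev(base))
  rownames(v) <- sprintf("g%02d", 1:30)
  m <- expression_matrix(v, "cpm")
  hc <- cluster_samples(m, rownames(v))
  # identical samples merge at height 0; a scaled copy is also at distance 0
  d <- as.matrix(1 - cor(v))
  expect_equal(min(hc$height), 0, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0, tolerance = 1e-12)

  vz <- v; vz[, 2] <- 5
  expect_error(cluster_samples(expression_matrix(vz, "cpm"), rownames(v)),
               "s2")
})

test_that("complete-linkage heights equal the naive O(n^3) oracle", {
  for (seed in c(1, 2, 3)) {
    withr::with_seed(seed, {
      v <- matrix(rexp(40 * 6, 1 / 80), 40, 6,
                  dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
    })
    m <- expression_matrix(v, "cpm")
    hc <- cluster_samples(m, rownames(v))
    expect_true(all(diff(hc$height) >= 0))
    expect_true(all(hc$height >= 0 & hc$height <= 2))
    expect_equal(sort(hc$height),
                 oracle_complete_linkage_heights(as.matrix(1 - cor(v))),
                 tolerance = 1e-12)
  }
})

test_that("within-group correlations are averaged over all unordered pairs", {
  withr::with_seed(5, base <- rexp(20, 1 / 50))
  v <- cbind(a1 = base, a2 = base, b1 = base + runif(20, 0, 30),
             b2 = rev(base))
  rownames(v) <- sprintf("g%02d", 1:20)
  fx <- labelled_cpm(v, c("A", "A", "B", "B"))
  out <- mean_group_correlation(fx$expr, fx$labels, rownames(v))
  a <- out[out$group == "A", ]
  expect_equal(a$mean_r, 1)
  expect_equal(a$sd_r, NA_real_)  # single pair has no spread
  b <- out[out$group == "B", ]
  expect_equal(b$mean_r, cor(v[, "b1"], v[, "b2"]))
  expect_equal(attr(out, "overall_mean"), mean(c(a$mean_r, b$mean_r)))

  fx2 <- labelled_cpm(v, c("A", "A", "B", "C"))
  w <- testthat::capture_warnings(
    out2 <- mean_group_correlation(fx2$expr, fx2$labels, rownames(v)))
  expect_match(w, "single sample", all = FALSE)
  expect_equal(out2$group, "A")
})

test_that("marker genes raise within-class correlation above random genes", {
  truth <- simulation_truth(tissues = c("brain", "heart", "liver"),
                            n_genes = 600, n_markers = 15, n_housekeepers = 50)
  sim <- simulate_tissue_counts(truth, 4, seed = 77)
  cpm <- cpm_normalize(sim$expr, compute_tmm_factors(sim$expr))
  markers <- unlist(truth$markers)
  withr::with_seed(78, {
    rand <- sample(setdiff(gene_ids(cpm), c(markers, truth$housekeepers)),
                   length(markers))
  })
  r_mark <- attr(mean_group_correlation(cpm, sim$labels, markers), "overall_mean")
  r_rand <- attr(mean_group_correlation(cpm, sim$labels, rand), "overall_mean")
  expect_gt(r_mark, r_rand)
})

test_that("stage-specific partition isolates stage-restricted organ genes", {
  # the 10x-enrichment rule needs the organ to be a small fraction of the
  # dataset: 2 organ samples among 24, as in a many-organ atlas
  genes <- c("gU1T", "gBOTH", "gFLAT", paste0("f", 1:7))
  classes <- c("brain", "brain", rep(paste0("organ", 1:11), each = 2))
  mk <- function(u, b) {
    v <- matrix(100, 10, 24, dimnames = list(genes, paste0("s", 1:24)))
    v["gU1T", 1:2] <- 100 * u    # expressed only in the organ of interest
    v["gBOTH", 1:2] <- 100 * b
    v["gU1T", 3:24] <- 0
    v["gBOTH", 3:24] <- 0
    v
  }
  s1 <- labelled_cpm(mk(50, 60), classes)
  s2 <- labelled_cpm(mk(0, 60), classes)
  part <- stage_specific_genes(list(`1T` = s1, `2T` = s2), "brain")
  expect_equal(part$stages[part$gene_id == "gU1T"], "1T")
  expect_equal(part$stages[part$gene_id == "gBOTH"], "1T+2T")
  expect_false("gFLAT" %in% part$gene_id)  # uniform gene is in no high set
})

test_that("stage partition equals the brute-force set-algebra oracle", {
  withr::with_seed(31, {
    sets <- lapply(1:3, function(i) {
      v <- matrix(rexp(200 * 6, 1 / 60), 200, 6,
                  dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
      labelled_cpm(v, rep(c("organ", "other"), each = 3))
    })
  })
  names(sets) <- c("1T", "2T", "adult")
  part <- stage_specific_genes(sets, "organ", times = 2)
  # oracle: direct set algebra over independently computed high sets
  high <- lapply(sets, function(s) {
    v <- s$expr$values
    rownames(v)[rowMeans(v[, 1:3]) > 2 * rowMeans(v)]
  })
  for (g in part$gene_id) {
    want <- paste(names(high)[vapply(high, function(s) g %in% s, logical(1))],
                  collapse = "+")
    expect_equal(part$stages[part$gene_id == g], want)
  }
  expect_setequal(part$gene_id, unique(unlist(high)))
  # disjoint partition of the union
  expect_equal(anyDuplicated(part$gene_id), 0L)
})
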