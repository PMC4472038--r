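#' Select usable housekeeping genes
#'
#' From a broad housekeeping panel, keeps the genes that are present in both
#' the training and the query matrices and expressed in at least one training
#' sample (training CPM >= `detection_cpm`). These anchor the scaling of
#' microarray intensities onto the sequencing CPM scale.
#'
#' @param panel A `gene_panel` (or character vector of gene IDs).
#' @param train Training `expr_matrix` (`counts` or `cpm`).
#' @param test Query `expr_matrix` (any platform).
#' @param detection_cpm Expression threshold in CPM (default 1).
#' @return An `hk_selection` object: list with `housekeepers_used`,
#'   `panel_name`, `detection_cpm`, `n_panel`, `n_shared`.
#' @export
select_housekeepers <- function(panel, train, test, detection_cpm = 1) {
  if (is.character(panel)) panel <- gene_panel(panel)
  stopifnot(inherits(panel, "gene_panel"),
            inherits(train, "expr_matrix"), inherits(test, "expr_matrix"))
  shared <- intersect(intersect(panel$gene_ids, gene_ids(train)), gene_ids(test))
  cpm <- as_cpm(train)
  expressed <- shared[apply(cpm$values[shared, , drop = FALSE], 1, max) >= detection_cpm]
  if (length(expressed) == 0) {
    abort(paste0("No usable housekeeping genes: none of the panel is present in both ",
                 "matrices and expressed in training. Check that gene ID namespaces match."))
  }
  inform(sprintf("select_housekeepers: %d of %d panel genes usable (%d shared).",
                 length(expressed), length(panel$gene_ids), length(shared)))
  structure(list(housekeepers_used = expressed,
                 panel_name = panel$name,
                 detection_cpm = detection_cpm,
                 n_panel = length(panel$gene_ids),
                 n_shared = length(shared)),
            class = "hk_selection")
}

#' @export
print.hk_selection <- function(x, ...) {
  cat(sprintf("<hk_selection> %d usable housekeepers from panel '%s' (detection >= %g CPM)\n",
              length(x$housekeepers_used), x$panel_name, x$detection_cpm))
  invisible(x)
}

# exact 2-parameter least-absolute-deviations fit of y ~ offset + gain * x.
# The intercept is profiled out (optimal offset at fixed gain is the median
# residual), leaving a convex piecewise-linear profile in the gain that a
# bracketed ternary search pins down to ~1e-12.
lad_fit <- function(x, y) {
  prof <- function(b) {
    r <- y - b * x
    sum(abs(r - median(r)))
  }
  b0 <- if (var(x) > 0) cov(x, y) / var(x) else 1
  w <- max(1, abs(b0))
  lo <- b0 - 5 * w
  hi <- b0 + 5 * w
  for (k in 1:8) {  # widen bracket if the minimum sits at an edge
    third <- (hi - lo) / 3
    if (prof(lo) <= prof(lo + third)) lo <- lo - (hi - lo)
    else if (prof(hi) <= prof(hi - third)) hi <- hi + (hi - lo)
    else break
  }
  for (k in 1:200) {
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    if (prof(m1) <= prof(m2)) hi <- m2 else lo <- m1
  }
  gain <- (lo + hi) / 2
  offset <- median(y - gain * x)
  list(offset = offset, gain = gain,
       median_abs_residual = median(abs(y - offset - gain * x)))
}

#' Scale microarray intensities onto the training CPM scale
#'
#' For every query sample, fits a map in log space from that sample's
#' housekeeping-gene values to the training-mean housekeeping log-CPM
#' profile, then applies the map to all genes of the sample. The exact form
#' of such cross-platform scaling is not uniquely defined; three candidate
#' reconstructions are provided:
#' \describe{
#'   \item{`affine`}{(default) robust affine map `a + b * x` fit by least
#'     absolute deviations — handles both multiplicative (gain) and
#'     background (offset) differences between platforms;}
#'   \item{`offset`}{gain fixed to 1; the offset is the median log-ratio;}
#'   \item{`quantile`}{monotone quantile map anchored on the housekeepers.}
#' }
#'
#' @param test Query `expr_matrix` with `platform = "intensity"`.
#' @param train Training `expr_matrix` (`counts` or `cpm`).
#' @param hk An `hk_selection` from [select_housekeepers()].
#' @param mode `"affine"`, `"offset"`, or `"quantile"`.
#' @return An `expr_matrix` on the CPM scale (`platform = "cpm"`), with a
#'   per-sample fit summary tibble in the `scaling_fits` attribute.
#' @export
scale_to_training <- function(test, train, hk,
                              mode = c("affine", "offset", "quantile")) {
  mode <- match.arg(mode)
  stopifnot(inherits(test, "expr_matrix"), inherits(hk, "hk_selection"))
  if (test$platform != "intensity") {
    abort("scale_to_training() expects a query with platform = 'intensity'.")
  }
  genes <- hk$housekeepers_used
  if (length(genes) < 10) {
    abort(sprintf("Only %d usable housekeeping genes; need >= 10 for a stable fit.",
                  length(genes)))
  }
  train_cpm <- as_cpm(train)
  y <- rowMeans(log2(train_cpm$values[genes, , drop = FALSE] + 1))
  lt <- log2(test$values + 1)
  out <- matrix(NA_real_, nrow(lt), ncol(lt), dimnames = dimnames(lt))
  fits <- vector("list", ncol(lt))
  for (j in seq_len(ncol(lt))) {
    x <- lt[genes, j]
    if (mode == "affine") {
      f <- lad_fit(x, y)
      z <- f$offset + f$gain * lt[, j]
    } else if (mode == "offset") {
      f <- list(offset = median(y - x), gain = 1)
      f$median_abs_residual <- median(abs(y - f$offset - x))
      z <- f$offset + lt[, j]
    } else {
      ox <- sort(x); oy <- sort(y)
      map <- stats::approxfun(ox, oy, rule = 2, ties = mean)
      z <- map(lt[, j])
      f <- list(offset = NA_real_, gain = NA_real_,
                median_abs_residual = median(abs(y - map(x))))
    }
    out[, j] <- pmax(2^z - 1, 0)
    fits[[j]] <- tibble(sample_id = colnames(lt)[j], offset = f$offset,
                        gain = f$gain, median_abs_residual = f$median_abs_residual)
  }
  fits <- dplyr::bind_rows(fits)
  inform(sprintf("scale_to_training (%s): median |residual| range %.3g-%.3g over %d samples.",
                 mode, min(fits$median_abs_residual), max(fits$median_abs_residual),
                 nrow(fits)))
  res <- expression_matrix(out, "cpm",
                           meta = c(test$meta,
                                    list(scaling = mode, housekeepers = length(genes))))
  attr(res, "scaling_fits") <- fits
  res
}
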