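#' Ground truth for an atlas-like count simulation
#'
#' Describes a negative-binomial bulk expression simulation with planted,
#' tissue-specific marker genes: each tissue gets a block of marker genes
#' elevated `marker_fold`-fold in that tissue's samples. This is the minimal
#' model reproducing the barcode phenomenology — genes high in one tissue
#' (or, with `overlap_markers > 0`, shared between neighbouring tissues) and
#' near baseline elsewhere. A block of stable, well-expressed housekeeping
#' genes is reserved and never used as a marker. An optional stage effect
#' multiplies the marker fold in second-stage samples, emulating markers that
#' strengthen over developmental time.
#'
#' @param tissues Character vector of tissue names (>= 2).
#' @param n_genes Total genes simulated.
#' @param n_markers Markers planted per tissue.
#' @param marker_fold Fold elevation of a marker in its tissue (> 0).
#' @param dispersion Negative-binomial dispersion (> 0); `size = 1/dispersion`.
#' @param n_housekeepers Stable housekeeping genes reserved at the top of the
#'   matrix.
#' @param hk_mean Median count scale of housekeeping genes. Individual
#'   housekeeper means spread log-normally (sdlog `hk_sdlog`) around it:
#'   a broad housekeeping panel spans orders of magnitude of expression,
#'   and that dynamic range is what makes cross-platform scaling
#'   identifiable.
#' @param hk_sdlog Log-scale spread of housekeeper means (default 1.5).
#' @param baseline_meanlog,baseline_sdlog Log-normal law of per-gene baseline
#'   means.
#' @param libsize_range Range of per-sample library-size factors.
#' @param stages Stage labels cycled over samples within tissue, or `NULL`.
#' @param stage_fold Extra multiplier on marker means in the last stage
#'   (default 1 = no stage effect).
#' @param overlap_markers Number of markers each tissue shares with the next
#'   tissue (default 0 = disjoint marker sets).
#' @return A `simulation_truth` object (a list of the above plus `markers`, a
#'   tissue-named list of marker gene IDs, and `housekeepers`).
#' @export
simulation_truth <- function(tissues = c("brain", "heart", "liver", "kidney",
                                         "lung", "pancreas", "intestine", "skin"),
                             n_genes = 2000, n_markers = 20, marker_fold = 32,
                             dispersion = 0.1, n_housekeepers = 150,
                             hk_mean = 500, hk_sdlog = 1.5,
                             baseline_meanlog = log(50), baseline_sdlog = 1.2,
                             libsize_range = c(0.7, 1.3),
                             stages = c("1T", "2T"), stage_fold = 1,
                             overlap_markers = 0) {
  if (length(tissues) < 2) abort("Need at least 2 tissues.")
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  if (marker_fold <= 0) abort("`marker_fold` must be > 0.")
  if (n_housekeepers + length(tissues) * n_markers > n_genes) {
    abort("n_genes too small for the requested housekeepers and markers.")
  }
  gene_names <- c(
    sprintf("HK%04d", seq_len(n_housekeepers)),
    sprintf("G%05d", seq_len(n_genes - n_housekeepers))
  )
  markers <- list()
  pos <- n_housekeepers
  for (i in seq_along(tissues)) {
    own <- gene_names[pos + seq_len(n_markers)]
    pos <- pos + n_markers
    markers[[tissues[i]]] <- own
  }
  if (overlap_markers > 0) {
    # share the first `overlap_markers` markers of each tissue with the next
    for (i in seq_along(tissues)) {
      nxt <- tissues[if (i == length(tissues)) 1 else i + 1]
      markers[[nxt]] <- unique(c(markers[[nxt]],
                                 markers[[tissues[i]]][seq_len(overlap_markers)]))
    }
  }
  structure(list(tissues = tissues, n_genes = n_genes, n_markers = n_markers,
                 marker_fold = marker_fold, dispersion = dispersion,
                 n_housekeepers = n_housekeepers, hk_mean = hk_mean,
                 hk_sdlog = hk_sdlog,
                 baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
                 libsize_range = libsize_range, stages = stages,
                 stage_fold = stage_fold, overlap_markers = overlap_markers,
                 gene_names = gene_names, markers = markers,
                 housekeepers = gene_names[seq_len(n_housekeepers)]),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d tissues, %d genes (%d housekeepers), %d markers/tissue, fold %g, dispersion %g\n",
              length(x$tissues), x$n_genes, x$n_housekeepers, x$n_markers,
              x$marker_fold, x$dispersion))
  invisible(x)
}

#' Simulate an atlas-like count matrix with planted markers
#'
#' Counts are negative binomial with per-sample library-size factors drawn
#' uniformly from `truth$libsize_range`; a marker gene's mean is multiplied
#' by `truth$marker_fold` in the samples of its tissue (and additionally by
#' `truth$stage_fold` in last-stage samples). Housekeeping genes get no
#' tissue effect: their means, spread log-normally around `truth$hk_mean`,
#' are identical in every tissue. Stages cycle over the samples within each
#' tissue.
#'
#' @param truth A [simulation_truth()].
#' @param samples_per_tissue Samples drawn per tissue (>= 1).
#' @param seed Integer seed; the same `(truth, seed)` pair replays
#'   identically.
#' @return A list: `expr` (counts `expr_matrix`), `labels` (`label_table`).
#' @export
simulate_tissue_counts <- function(truth, samples_per_tissue = 5, seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (samples_per_tissue < 1) abort("`samples_per_tissue` must be >= 1.")
  n_t <- length(truth$tissues)
  n_s <- n_t * samples_per_tissue
  tissue_of <- rep(truth$tissues, each = samples_per_tissue)
  stage_of <- if (is.null(truth$stages)) rep(NA_character_, n_s) else {
    rep(rep_len(truth$stages, samples_per_tissue), times = n_t)
  }
  sample_names <- paste0(tissue_of, "_", rep(seq_len(samples_per_tissue), times = n_t))
  withr::with_seed(seed, {
    base <- stats::rlnorm(truth$n_genes, truth$baseline_meanlog, truth$baseline_sdlog)
    names(base) <- truth$gene_names
    base[truth$housekeepers] <- stats::rlnorm(truth$n_housekeepers,
                                              log(truth$hk_mean), truth$hk_sdlog)
    libf <- runif(n_s, truth$libsize_range[1], truth$libsize_range[2])
    mu <- matrix(base, truth$n_genes, n_s) * rep(libf, each = truth$n_genes)
    rownames(mu) <- truth$gene_names
    last_stage <- if (is.null(truth$stages)) NULL else truth$stages[length(truth$stages)]
    for (tis in truth$tissues) {
      cols <- which(tissue_of == tis)
      mk <- truth$markers[[tis]]
      mu[mk, cols] <- mu[mk, cols] * truth$marker_fold
      if (!is.null(last_stage) && truth$stage_fold != 1) {
        cols2 <- cols[stage_of[cols] == last_stage]
        mu[mk, cols2] <- mu[mk, cols2] * truth$stage_fold
      }
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / truth$dispersion),
                     nrow(mu), ncol(mu))
  })
  dimnames(counts) <- list(truth$gene_names, sample_names)
  list(
    expr = expression_matrix(counts, "counts",
                             meta = list(source = "simulate_tissue_counts",
                                         seed = as.character(seed))),
    labels = suppressWarnings(label_table(tibble(
      sample_id = sample_names, class_label = tissue_of, stage = stage_of)))
  )
}

#' Simulate a microarray rendering of a count dataset
#'
#' Intensities are an affine transform of each sample's log2 CPM —
#' `2^(gain * log2(CPM) + offset + noise)` with Gaussian `noise` of standard
#' deviation `noise_sd` — so `gain = 1, offset = 0, noise_sd = 0` reproduces
#' CPM exactly. Genes are subsampled to `probe_fraction` of the total
#' (emulating probes missing from an array design); housekeeping genes named
#' in `truth` are always retained so the scaling step stays anchored.
#'
#' @param counts A counts `expr_matrix` (e.g. from
#'   [simulate_tissue_counts()]).
#' @param truth The [simulation_truth()] that produced it (for the
#'   housekeeper list); may be `NULL` to protect no genes.
#' @param probe_fraction Fraction of genes retained, in (0, 1].
#' @param noise_sd Log2-scale Gaussian noise SD (>= 0).
#' @param gain,offset Affine distortion in log2 space.
#' @param seed Integer seed.
#' @return An `expr_matrix` with `platform = "intensity"`.
#' @export
simulate_microarray <- function(counts, truth = NULL, probe_fraction = 1,
                                noise_sd = 0, gain = 1, offset = 0, seed = 1) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (probe_fraction <= 0 || probe_fraction > 1) abort("`probe_fraction` must be in (0, 1].")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  cpm <- cpm_normalize(counts)$values
  withr::with_seed(seed, {
    noise <- matrix(rnorm(length(cpm), 0, noise_sd), nrow(cpm), ncol(cpm))
    inten <- ifelse(cpm > 0, 2^(gain * log2(cpm) + offset + noise), 0)
    dimnames(inten) <- dimnames(cpm)
    n_keep <- ceiling(probe_fraction * nrow(cpm))
    hk <- if (is.null(truth)) character(0) else intersect(truth$housekeepers, rownames(cpm))
    if (n_keep < length(hk)) {
      keep <- sort(sample(match(hk, rownames(cpm)), n_keep))
    } else {
      others <- setdiff(seq_len(nrow(cpm)), match(hk, rownames(cpm)))
      keep <- sort(c(match(hk, rownames(cpm)),
                     sample(others, n_keep - length(hk))))
    }
  })
  expression_matrix(inten[keep, , drop = FALSE], "intensity",
                    meta = list(source = "simulate_microarray",
                                probe_fraction = as.character(probe_fraction),
                                noise_sd = as.character(noise_sd),
                                seed = as.character(seed)))
}

#' Serialize simulation ground truth as JSON
#' @param truth A `simulation_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
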