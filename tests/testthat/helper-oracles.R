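# Independent brute-force oracles. These deliberately re-derive each
# quantity from its published definition, sharing no code with the package.

# Literal weighted trimmed mean of M-values: reference = sample whose 75th
# percentile of library-scaled counts is closest to the mean; pairwise
# M/A-values with double trimming; inverse delta-method binomial variance
# weights; factors rescaled to geometric mean 1.
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]; refc <- counts[, ref]
    nO <- lib[i]; nR <- lib[ref]
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Generic convex solver for the L1-penalized multinomial logistic objective
# min -loglik/n + lambda * sum(|B|), intercepts unpenalized: FISTA proximal
# gradient to locate the support, then a high-precision smooth (BFGS) solve
# restricted to the support with fixed signs.
fista_multinom <- function(x, y, lambda, iters = 40000) {
  n <- nrow(x); K <- nlevels(y); p <- ncol(x)
  Y <- stats::model.matrix(~ y - 1)
  B <- matrix(0, p, K); b0 <- rep(0, K)
  Xa <- cbind(1, x)
  L <- 0.5 * max(eigen(crossprod(Xa) / n, symmetric = TRUE,
                       only.values = TRUE)$values)
  Bz <- B; b0z <- b0; t_old <- 1
  for (it in seq_len(iters)) {
    eta <- sweep(x %*% Bz, 2, b0z, "+"); m <- apply(eta, 1, max)
    P <- exp(eta - m); P <- P / rowSums(P)
    G <- crossprod(Xa, P - Y) / n
    b0n <- b0z - G[1, ] / L
    Bn <- Bz - G[-1, , drop = FALSE] / L
    Bn <- sign(Bn) * pmax(abs(Bn) - lambda / L, 0)
    t_new <- (1 + sqrt(1 + 4 * t_old^2)) / 2
    Bz <- Bn + (t_old - 1) / t_new * (Bn - B)
    b0z <- b0n + (t_old - 1) / t_new * (b0n - b0)
    B <- Bn; b0 <- b0n; t_old <- t_new
  }
  supp <- which(B != 0)
  sgn <- sign(B)[supp]
  fn <- function(par) {
    b0p <- par[1:K]; Bp <- matrix(0, p, K); Bp[supp] <- par[-(1:K)]
    eta <- sweep(x %*% Bp, 2, b0p, "+"); m <- apply(eta, 1, max)
    ll <- sum(eta * Y) - sum(m + log(rowSums(exp(eta - m))))
    -ll / n + lambda * sum(sgn * par[-(1:K)])
  }
  gr <- function(par) {
    b0p <- par[1:K]; Bp <- matrix(0, p, K); Bp[supp] <- par[-(1:K)]
    eta <- sweep(x %*% Bp, 2, b0p, "+"); m <- apply(eta, 1, max)
    P <- exp(eta - m); P <- P / rowSums(P)
    G <- crossprod(Xa, P - Y) / n
    c(G[1, ], G[-1, , drop = FALSE][supp] + lambda * sgn)
  }
  o <- stats::optim(c(b0, B[supp]), fn, gr, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-16))
  Bp <- matrix(0, p, K); Bp[supp] <- o$par[-(1:K)]
  list(B = Bp, b0 = o$par[1:K])
}

# Naive O(n^3) complete-linkage agglomeration; returns sorted merge heights.
oracle_complete_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# small labelled toy expression fixture used across files
toy_counts <- function(genes = 6, samples = 4, seed = 42, max_count = 200) {
  withr::with_seed(seed, {
    m <- matrix(rpois(genes * samples, max_count / 2), genes, samples)
  })
  dimnames(m) <- list(sprintf("g%02d", seq_len(genes)),
                      sprintf("s%d", seq_len(samples)))
  expression_matrix(m, "counts")
}

# the standard study fixture: default truth, 5 samples/tissue, last sample
# per tissue held out
default_fixture <- function(sim_seed = 101) {
  truth <- simulation_truth()
  sim <- simulate_tissue_counts(truth, samples_per_tissue = 5, seed = sim_seed)
  held <- sim$labels$sample_id[grepl("_5$", sim$labels$sample_id)]
  train_ids <- setdiff(sim$labels$sample_id, held)
  list(
    truth = truth,
    train = subset_expr(sim$expr, samples = train_ids),
    test = subset_expr(sim$expr, samples = held),
    train_labels = sim$labels[sim$labels$sample_id %in% train_ids, ],
    test_classes = sub("_5$", "", held)
  )
}

fit_default_fixture <- function(fx, fold_seed = 11, ...) {
  train <- suppressMessages(filter_detected(fx$train, 4))
  top <- suppressMessages(top_variable_genes(train, 500))
  fit_identity_classifier(train, fx$train_labels, top,
                          test_genes = gene_ids(fx$test),
                          seed = fold_seed, ...)
}
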