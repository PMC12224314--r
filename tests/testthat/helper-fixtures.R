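# Fixture builders and independent oracles shared across the suite.

# -- fixture builders -------------------------------------------------------

# 3-substrate proteomic design, `reps` readings per substrate
tiny_protein_design <- function(reps = 3L, substrates = c("dentine", "enamel", "titanium")) {
  experiment_design(
    experiment_id = paste0(rep(substrates, each = reps), "_r",
                           rep(seq_len(reps), times = length(substrates))),
    substrate = rep(substrates, each = reps),
    replicate = rep(seq_len(reps), times = length(substrates)))
}

tiny_asv_design <- function(reps = 3L, timepoint = "2h",
                            substrates = c("dentine", "enamel", "titanium")) {
  experiment_design(
    experiment_id = paste0("m", timepoint, "_", rep(substrates, each = reps), "_r",
                           rep(seq_len(reps), times = length(substrates))),
    substrate = rep(substrates, each = reps),
    timepoint = timepoint,
    replicate = rep(seq_len(reps), times = length(substrates)))
}

# random censored lognormal protein fixture (right-skewed, left-censored):
# the world the imputation step assumes
censored_fixture <- function(n_proteins = 20L, reps = 3L, censor_q = 0.15, seed = 1L) {
  set.seed(seed)
  design <- tiny_protein_design(reps)
  vals <- matrix(10^rnorm(n_proteins * nrow(design), mean = 6, sd = 0.8),
                 n_proteins, nrow(design),
                 dimnames = list(sprintf("P%03d", seq_len(n_proteins)),
                                 design$experiment_id))
  L <- quantile(vals, censor_q)
  vals[vals < L] <- NA
  keep <- rowSums(!is.na(vals)) > 0L
  protein_table(vals[keep, , drop = FALSE], design)
}

# -- oracles ----------------------------------------------------------------

# exhaustive grid oracle for the imputation constant (step over (0, min])
grid_imputation_oracle <- function(present, n_missing, step = 1e-6) {
  hi <- min(present)
  grid <- seq(step, hi, by = step * hi)
  sk2 <- vapply(grid, function(cc) {
    v <- c(present, rep(cc, n_missing))
    abs(3 * (mean(v) - median(v)) / sd(v))
  }, 0)
  list(c = grid[which.min(sk2)], sk2 = min(sk2))
}

# brute-force Venn region counts over all 2^S membership patterns
brute_venn_regions <- function(det) {
  subs <- colnames(det)
  pattern <- apply(det, 1L, function(r) paste(subs[r], collapse = "+"))
  subsets <- unlist(lapply(seq_along(subs), function(k)
    combn(subs, k, simplify = FALSE)), recursive = FALSE)
  keys <- vapply(subsets, paste, "", collapse = "+")
  vapply(keys, function(k) sum(pattern == k), integer(1L))
}

# O(n^3) complete-linkage agglomeration: returns sorted merge heights
brute_complete_linkage_heights <- function(points) {
  D <- as.matrix(dist(points))
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# dense generalized-eigenproblem oracle for canonical LDA on full-rank input:
# eigen of solve(Wc) %*% B with coefficients normalized to a' Wc a = 1 and
# the package's sign convention applied
lda_eigen_oracle <- function(X, groups) {
  glev <- unique(groups)
  N <- nrow(X); p <- ncol(X); g <- length(glev)
  grand <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in glev) {
    idx <- groups == lev
    m_g <- colMeans(X[idx, , drop = FALSE])
    W <- W + crossprod(sweep(X[idx, , drop = FALSE], 2L, m_g))
    B <- B + sum(idx) * tcrossprod(m_g - grand)
  }
  Wc <- W / (N - g)
  e <- eigen(solve(Wc) %*% B)
  k <- min(p, g - 1L)
  ord <- order(Re(e$values), decreasing = TRUE)[seq_len(k)]
  vals <- Re(e$values[ord])
  vecs <- Re(e$vectors[, ord, drop = FALSE])
  within_sd <- sqrt(diag(Wc))
  for (j in seq_len(k)) {
    a <- vecs[, j]
    a <- a / sqrt(drop(t(a) %*% Wc %*% a))
    std <- a * within_sd
    if (std[which.max(abs(std))] < 0) a <- -a
    vecs[, j] <- a
  }
  list(eigenvalues = vals, coef = vecs)
}

# dense CCA oracle: eigen of Sxx^-1 Sxy Syy^-1 Syx gives rho^2 and x-weights
cca_eigen_oracle <- function(X, Y) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1); Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  rho <- sqrt(pmax(Re(e$values[ord]), 0))
  vecs <- Re(e$vectors[, ord, drop = FALSE])
  for (j in seq_len(ncol(vecs))) {
    a <- vecs[, j]
    vecs[, j] <- a / sqrt(drop(t(a) %*% Sxx %*% a))
  }
  list(rho = rho, xcoef = vecs)
}

# brute-force substrate-filtered double loop for pair construction
brute_pairs <- function(x_design, y_design) {
  out <- NULL
  for (i in seq_len(nrow(x_design))) for (j in seq_len(nrow(y_design)))
    if (x_design$substrate[i] == y_design$substrate[j])
      out <- rbind(out, data.frame(substrate = x_design$substrate[i], i = i, j = j))
  out
}
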