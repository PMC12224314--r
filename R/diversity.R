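# Descriptive microbiome statistics: Shannon diversity, Bray-Curtis
# dissimilarity, principal coordinates analysis, and the per-taxon log2
# median proportion ratio used by differential heat trees.

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive counts; natural log
#' by default (the dominant ecology convention), switchable via `base`.
#'
#' @param counts nonnegative vector with positive total.
#' @param base logarithm base.
#' @return nonnegative diversity value; `log(k)` for a uniform community of
#'   k taxa, 0 for a single taxon.
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stopf("negative count")
  tot <- sum(counts)
  if (tot <= 0) stopf("all-zero community")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|u - v|) / sum(u + v)`: 0 for identical communities, 1 for
#' disjoint supports; invariant to common rescaling of both vectors.
#'
#' @param u,v nonnegative vectors of equal length, not both all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stopf("length mismatch")
  if (any(u < 0) || any(v < 0)) stopf("negative abundance")
  denom <- sum(u + v)
  if (denom <= 0) stopf("both communities are all-zero")
  sum(abs(u - v)) / denom
}

#' Bray-Curtis distance matrix between experiments
#'
#' @param table an [asv_table()] or matrix (features x experiments).
#' @return symmetric matrix of pairwise dissimilarities between columns.
#' @export
bray_curtis_matrix <- function(table) {
  vals <- table_values(table)
  n <- ncol(vals)
  D <- matrix(0, n, n, dimnames = list(colnames(vals), colnames(vals)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- bray_curtis(vals[, i], vals[, j])
  D
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of `-D^2 / 2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues. Negative eigenvalues (non-Euclidean input) are reported as
#' a diagnostic, not corrected.
#'
#' @param D square symmetric dissimilarity matrix with zero diagonal.
#' @param k number of axes to return (capped at the positive-eigenvalue
#'   count).
#' @return an `ordination_result`: `coordinates` (cases x axes),
#'   `eigenvalues` (all, sorted descending), `proportion` (share of the
#'   positive-eigenvalue total per returned axis), `negative_mass` (sum of
#'   |negative eigenvalues|).
#' @export
pcoa <- function(D, k = 2L) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stopf("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stopf("asymmetric distance matrix")
  if (max(abs(diag(D))) > 1e-12) stopf("distance matrix must have zero diagonal")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1L], 0) * 1e-12 & e$values > 0)
  k_use <- min(k, length(pos))
  coords <- if (k_use > 0L)
    e$vectors[, pos[seq_len(k_use)], drop = FALSE] %*%
      diag(sqrt(e$values[pos[seq_len(k_use)]]), k_use)
  else matrix(0, n, 0L)
  if (k_use > 0L)
    dimnames(coords) <- list(rownames(D), paste0("PCo", seq_len(k_use)))
  pos_total <- sum(e$values[e$values > 0])
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion = if (pos_total > 0 && k_use > 0L)
                   e$values[pos[seq_len(k_use)]] / pos_total else numeric(),
                 negative_mass = sum(abs(e$values[e$values < 0]))),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination> %d cases, %d axes; variance explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$proportion), collapse = ", ")))
  if (x$negative_mass > 0)
    cat(sprintf("negative eigenvalue mass: %.4g\n", x$negative_mass))
  invisible(x)
}

#' Per-taxon log2 median proportion ratio between two groups
#'
#' For each taxon, `log2((median_A + delta) / (median_B + delta))` with
#' `delta` a pseudo-proportion (one tenth of the smallest nonzero
#' proportion in the table) guarding against zero medians; output capped at
#' +/- 20. Positive values mark taxa dominant in group A; swapping the
#' groups flips the sign exactly.
#'
#' @param table proportion-scaled [asv_table()] (see [total_sum_scale()]).
#' @param group_a,group_b substrate (or other design group) labels, matched
#'   against the design substrate.
#' @param groups optional explicit group label per experiment, overriding
#'   the design substrate.
#' @return named numeric vector, one value per taxon.
#' @export
log2_median_proportion <- function(table, group_a, group_b, groups = NULL) {
  vals <- table_values(table)
  if (is.null(groups)) groups <- table_design(table)$substrate
  a_cols <- groups == group_a
  b_cols <- groups == group_b
  if (!any(a_cols) || !any(b_cols)) stopf("both groups must be nonempty")
  pos <- vals[vals > 0]
  delta <- if (length(pos) > 0L) min(pos) * 0.1 else 1e-6
  med_a <- apply(vals[, a_cols, drop = FALSE], 1L, stats::median)
  med_b <- apply(vals[, b_cols, drop = FALSE], 1L, stats::median)
  out <- log2((med_a + delta) / (med_b + delta))
  pmin(pmax(out, -20), 20)
}
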