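# Per-feature Kruskal-Wallis screening and canonical (Fisher) linear
# discriminant analysis with a shrinkage-regularized within-group scatter,
# plus biplot coordinate export and complete-linkage heatmap ordering.

#' Kruskal-Wallis rank-sum test
#'
#' Midranks for ties; the H statistic carries the standard tie-correction
#' divisor `1 - sum(t^3 - t) / (N^3 - N)`; the p-value is the chi-square
#' upper tail on `#groups - 1` degrees of freedom. All-identical values are
#' not an error: they yield `H = 0, p = 1`, so constant features are
#' silently non-significant.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 nonempty groups, N >= 3).
#' @param vocabulary optional allowed group labels; labels outside it error.
#' @return a `kw_result` list: `H`, `p`, `df`, `group_sizes`.
#' @export
kruskal_wallis <- function(values, groups, vocabulary = NULL) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(groups), vocabulary)
    if (length(bad) > 0L)
      stopf("group label(s) absent from vocabulary: %s", paste(bad, collapse = ", "))
  }
  sizes <- table(groups)
  g <- length(sizes)
  N <- length(values)
  if (g < 2L) stopf("need >= 2 groups")
  if (N < 3L) stopf("need N >= 3")

  r <- rank(values)  # midranks
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab)
  denom <- 1 - tie_term / (N^3 - N)
  if (denom <= 0) {  # all values identical
    H <- 0; p <- 1
  } else {
    rs <- tapply(r, groups, sum)
    H <- (12 / (N * (N + 1)) * sum(rs^2 / as.numeric(sizes[names(rs)])) -
            3 * (N + 1)) / denom
    H <- max(H, 0)
    p <- stats::pchisq(H, df = g - 1, lower.tail = FALSE)
  }
  structure(list(H = H, p = p, df = g - 1L,
                 group_sizes = as.integer(sizes)),
            class = "kw_result")
}

#' Screen features by per-feature Kruskal-Wallis p-value
#'
#' Retains features with `p < threshold` (strict). Defaults mirror the
#' screening thresholds used downstream: 0.05 for proteins, 0.01 for
#' microbes. Raw p-values by default; Benjamini-Hochberg behind a flag.
#'
#' @param table feature table, [feature_matrix()] or numeric matrix
#'   (features x experiments).
#' @param groups group label per experiment (default: the design substrate).
#' @param threshold strict retention threshold.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list with `results` (data.frame: feature, H, p, retained) and
#'   `retained` (character vector of feature ids).
#' @export
screen_features <- function(table, groups = NULL, threshold = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  vals <- table_values(table)
  if (is.null(groups)) groups <- table_design(table)$substrate
  stats_list <- apply(vals, 1L, function(v) {
    k <- kruskal_wallis(v, groups)
    c(k$H, k$p)
  })
  res <- data.frame(feature = rownames(vals),
                    H = stats_list[1L, ], p = stats_list[2L, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  p_use <- if (adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
  res$retained <- p_use < threshold
  list(results = res, retained = res$feature[res$retained])
}

# smallest lambda from the ladder making the shrunken pooled covariance
# invertible (condition number < 1e12)
choose_shrinkage <- function(Wc) {
  p <- nrow(Wc)
  target <- diag(mean(diag(Wc)), p)
  for (lambda in c(0, 1e-8, 1e-6, 1e-4, 1e-2)) {
    Wl <- (1 - lambda) * Wc + lambda * target
    ev <- eigen(Wl, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < 1e12) return(lambda)
  }
  stopf("within-group scatter is too ill-conditioned even at lambda = 1e-2")
}

#' Fit a canonical linear discriminant model
#'
#' Solves the generalized eigenproblem of between-group scatter against the
#' (shrinkage-regularized) pooled within-group covariance
#' `Wc_lambda = (1 - lambda) * Wc + lambda * (tr(Wc)/p) * I`. Axes are
#' scaled so case scores have identity pooled within-group covariance
#' (canonical scaling); standardized coefficients are the raw coefficients
#' times each feature's pooled within-group sd; each axis's sign is fixed
#' so its largest-|standardized coefficient| is positive. Shrinkage is
#' required for wide problems (e.g. 110 features on 9 cases).
#'
#' @param table feature table, [feature_matrix()] or matrix (features x
#'   experiments).
#' @param groups group label per experiment (default: design substrate).
#' @param lambda shrinkage in `[0, 1]`; `NULL` (default) picks the smallest
#'   of `{0, 1e-8, 1e-6, 1e-4, 1e-2}` giving condition number < 1e12.
#' @return a `discriminant_model`: `features`, `groups`, `coef` (raw),
#'   `std_coef`, `scores`, `centroids`, `eigenvalues`, `proportion`,
#'   `lambda`, `within_sd`, `grand_mean`.
#' @export
fit_lda <- function(table, groups = NULL, lambda = NULL) {
  vals <- table_values(table)
  if (is.null(groups)) groups <- table_design(table)$substrate
  groups <- as.character(groups)
  if (nrow(vals) == 0L) stopf("no features to fit")
  glev <- unique(groups)
  g <- length(glev)
  if (g < 2L) stopf("need >= 2 groups")
  X <- t(vals)                      # cases x features
  N <- nrow(X); p <- ncol(X)
  if (N <= g) stopf("need more cases than groups for a within-group covariance")

  grand <- colMeans(X)
  Xc <- sweep(X, 2L, grand)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (lev in glev) {
    idx <- groups == lev
    n_g <- sum(idx)
    m_g <- colMeans(X[idx, , drop = FALSE])
    D <- sweep(X[idx, , drop = FALSE], 2L, m_g)
    W <- W + crossprod(D)
    B <- B + n_g * tcrossprod(m_g - grand)
  }
  Wc <- W / (N - g)
  if (is.null(lambda)) lambda <- choose_shrinkage(Wc)
  Wl <- (1 - lambda) * Wc + lambda * diag(mean(diag(Wc)), p)

  eW <- eigen(Wl, symmetric = TRUE)
  if (min(eW$values) <= 0) stopf("regularized within-group covariance not positive definite")
  Wihalf <- eW$vectors %*% (t(eW$vectors) / sqrt(eW$values))
  M <- Wihalf %*% B %*% Wihalf
  M <- (M + t(M)) / 2
  eM <- eigen(M, symmetric = TRUE)
  k <- min(p, g - 1L)
  d <- pmax(eM$values[seq_len(k)], 0)
  A <- Wihalf %*% eM$vectors[, seq_len(k), drop = FALSE]  # raw coefficients

  within_sd <- sqrt(diag(Wc))
  std <- A * within_sd
  # axis sign: largest-|standardized coefficient| positive
  for (j in seq_len(k)) {
    i_star <- which.max(abs(std[, j]))
    if (std[i_star, j] < 0) { A[, j] <- -A[, j]; std[, j] <- -std[, j] }
  }
  scores <- Xc %*% A
  axis_names <- paste0("LD", seq_len(k))
  dimnames(A) <- dimnames(std) <- list(colnames(X), axis_names)
  dimnames(scores) <- list(rownames(X), axis_names)
  centroids <- do.call(rbind, lapply(glev, function(lev)
    colMeans(scores[groups == lev, , drop = FALSE])))
  rownames(centroids) <- glev

  structure(list(features = colnames(X), groups = groups, levels = glev,
                 coef = A, std_coef = std, scores = scores,
                 centroids = centroids, eigenvalues = d,
                 proportion = if (sum(d) > 0) d / sum(d) else rep(0, k),
                 lambda = lambda, within_sd = within_sd, grand_mean = grand),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant model> %d features, %d cases, %d groups, %d axes (lambda = %g)\n",
              length(x$features), nrow(x$scores), length(x$levels),
              ncol(x$scores), x$lambda))
  cat("proportion of discrimination:",
      paste(sprintf("%.3f", x$proportion), collapse = ", "), "\n")
  invisible(x)
}

#' Biplot coordinates on the first two discriminant axes
#'
#' Exports case scores, within-group centroids and feature vectors (the
#' standardized coefficients) on (LD1, LD2); a missing second axis is
#' zero-filled so two-group models still produce planar coordinates.
#'
#' @param model a `discriminant_model`.
#' @return list of data.frames: `cases` (case, group, LD1, LD2),
#'   `centroids` (group, LD1, LD2), `features` (feature, LD1, LD2, length).
#' @export
biplot_coordinates <- function(model) {
  take2 <- function(m) {
    out <- cbind(LD1 = m[, 1L],
                 LD2 = if (ncol(m) >= 2L) m[, 2L] else rep(0, nrow(m)))
    out
  }
  sc <- take2(model$scores)
  ce <- take2(model$centroids)
  fv <- take2(model$std_coef)
  list(cases = data.frame(case = rownames(model$scores), group = model$groups,
                          sc, row.names = NULL, stringsAsFactors = FALSE),
       centroids = data.frame(group = rownames(model$centroids), ce,
                              row.names = NULL, stringsAsFactors = FALSE),
       features = data.frame(feature = rownames(model$std_coef), fv,
                             length = sqrt(fv[, 1L]^2 + fv[, 2L]^2),
                             row.names = NULL, stringsAsFactors = FALSE))
}

#' Complete-linkage heatmap ordering
#'
#' Agglomerative complete linkage on Euclidean distances between rows (and
#' between columns), as used to arrange clustered heatmaps. Returns the
#' dendrogram leaf orders plus merge heights.
#'
#' @param matrix numeric matrix (>= 2 rows).
#' @return list: `row_order`, `col_order` (integer leaf orders),
#'   `row_heights`, `col_heights` (sorted merge heights).
#' @export
hclust_complete_order <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L) stopf("need >= 2 rows")
  hr <- stats::hclust(stats::dist(matrix), method = "complete")
  out <- list(row_order = hr$order, row_heights = hr$height)
  if (ncol(matrix) >= 2L) {
    hc <- stats::hclust(stats::dist(t(matrix)), method = "complete")
    out$col_order <- hc$order
    out$col_heights <- hc$height
  } else {
    out$col_order <- seq_len(ncol(matrix))
    out$col_heights <- numeric()
  }
  out
}
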