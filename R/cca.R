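# Regularized canonical correlation analysis via whitened cross-covariance
# SVD, with interset/intraset structure correlations for biplots.

#' Fit a (ridge-regularized) canonical correlation model
#'
#' Centers both blocks, whitens each with its ridge-regularized covariance
#' `Sxx + lambda_x * mean(diag(Sxx)) * I`, and takes the SVD of the whitened
#' cross-covariance. Canonical correlations are sorted descending and
#' clamped to `[0, 1]`; each dimension's sign is fixed so the
#' largest-|weight| x-feature has positive weight. With `lambda = 0` on
#' full-rank blocks, within-block canonical variates are exactly
#' uncorrelated and the one-variable-per-side case reduces to `|r|`.
#'
#' @param X,Y numeric matrices, cases x features, sharing the same case
#'   axis (typically the substrate-matched pair cases).
#' @param lambda_x,lambda_y ridge penalties; `NULL` (default) uses 0 when
#'   both blocks are full rank and 1e-3 when either is rank-deficient.
#' @return a `cca_model`: `cor` (canonical correlations), `xcoef`, `ycoef`
#'   (weights), `xscores`, `yscores` (variates), `lambda_x`, `lambda_y`,
#'   `x_center`, `y_center`.
#' @export
fit_cca <- function(X, Y, lambda_x = NULL, lambda_y = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("mismatched case axes: %d vs %d rows", nrow(X), nrow(Y))
  n <- nrow(X)
  if (n < 2L) stopf("need >= 2 cases")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))

  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2L, xc); Yc <- sweep(Y, 2L, yc)
  Sxx <- crossprod(Xc) / (n - 1); Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)

  deficient <- function(S, block) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    min(ev) <= 0 || max(ev) / min(ev) >= 1e12
  }
  auto <- if (deficient(Sxx) || deficient(Syy) ||
              ncol(X) >= n || ncol(Y) >= n) 1e-3 else 0
  if (is.null(lambda_x)) lambda_x <- auto
  if (is.null(lambda_y)) lambda_y <- auto

  inv_sqrt <- function(S, lambda) {
    Sr <- S + diag(lambda * mean(diag(S)), nrow(S))
    e <- eigen(Sr, symmetric = TRUE)
    if (min(e$values) <= 0) stopf("block covariance not positive definite; increase lambda")
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  Wx <- inv_sqrt(Sxx, lambda_x)
  Wy <- inv_sqrt(Syy, lambda_y)
  K <- Wx %*% Sxy %*% Wy
  sv <- svd(K)
  k <- min(ncol(X), ncol(Y), n - 1L)
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  A <- Wx %*% sv$u[, seq_len(k), drop = FALSE]
  B <- Wy %*% sv$v[, seq_len(k), drop = FALSE]

  for (j in seq_len(k)) {
    i_star <- which.max(abs(A[, j]))
    if (A[i_star, j] < 0) { A[, j] <- -A[, j]; B[, j] <- -B[, j] }
  }
  dn <- paste0("CC", seq_len(k))
  dimnames(A) <- list(colnames(X), dn); dimnames(B) <- list(colnames(Y), dn)
  U <- Xc %*% A; V <- Yc %*% B
  dimnames(U) <- list(rownames(X), dn); dimnames(V) <- list(rownames(Y), dn)

  structure(list(cor = stats::setNames(rho, dn), xcoef = A, ycoef = B,
                 xscores = U, yscores = V,
                 lambda_x = lambda_x, lambda_y = lambda_y,
                 x_center = xc, y_center = yc),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca model> %d x-features, %d y-features, %d dimensions (lambda = %g / %g)\n",
              nrow(x$xcoef), nrow(x$ycoef), length(x$cor), x$lambda_x, x$lambda_y))
  cat("canonical correlations:", paste(sprintf("%.4f", x$cor), collapse = ", "), "\n")
  invisible(x)
}

#' Interset and intraset structure correlations
#'
#' The intraset correlation of a feature on dimension k is its correlation
#' with its own block's canonical variate; the interset correlation is its
#' correlation with the other block's variate and equals the canonical
#' correlation times the intraset value, which is how it is computed here
#' (the identity holds by construction).
#'
#' @param model a `cca_model`.
#' @param X,Y the case-by-feature blocks the model was fit on.
#' @return list with matrices `x_intraset`, `x_interset`, `y_intraset`,
#'   `y_interset` (features x dimensions) and `biplot`, a data.frame of
#'   dimension-1/2 coordinates (interset for x = predictors, intraset for
#'   y = responses, following the biplot convention).
#' @export
structure_correlations <- function(model, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- rownames(model$xcoef)
  if (is.null(colnames(Y))) colnames(Y) <- rownames(model$ycoef)
  corr_block <- function(block, scores) {
    suppressWarnings(out <- stats::cor(block, scores))
    out[is.na(out)] <- 0
    out
  }
  x_intra <- corr_block(X, model$xscores)
  y_intra <- corr_block(Y, model$yscores)
  x_inter <- sweep(x_intra, 2L, model$cor, "*")
  y_inter <- sweep(y_intra, 2L, model$cor, "*")
  take2 <- function(m) cbind(dim1 = m[, 1L],
                             dim2 = if (ncol(m) >= 2L) m[, 2L] else rep(0, nrow(m)))
  biplot <- rbind(
    data.frame(feature = rownames(x_inter), set = "x", role = "interset",
               take2(x_inter), row.names = NULL, stringsAsFactors = FALSE),
    data.frame(feature = rownames(y_intra), set = "y", role = "intraset",
               take2(y_intra), row.names = NULL, stringsAsFactors = FALSE))
  list(x_intraset = x_intra, x_interset = x_inter,
       y_intraset = y_intra, y_interset = y_inter, biplot = biplot)
}
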