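# Cross-omic association over substrate-matched Cartesian pairs.
#
# Protein and microbe experiments are unpaired (different experiments on
# the same substrates), so pseudo-paired cases are built as the full
# Cartesian product of experiment indices within each shared substrate
# ("bootstrap pairing"). All collinearity between the two blocks is then
# attributable to substrate. Pairs are equally weighted downstream; no
# effective-sample-size correction is applied for the induced dependence.

#' Substrate-matched Cartesian pair index
#'
#' For each substrate shared by the two designs, all (x-experiment,
#' y-experiment) index pairs, concatenated in deterministic
#' (substrate, i, j) order.
#'
#' @param x_design,y_design experiment design data.frames.
#' @return data.frame: `substrate`, `i`, `j` (column indexes into the x and
#'   y tables), `x_exp`, `y_exp` (experiment ids).
#' @export
pair_index <- function(x_design, y_design) {
  common <- sort(intersect(unique(x_design$substrate), unique(y_design$substrate)))
  if (length(common) == 0L) stopf("no common substrate between the two designs")
  blocks <- lapply(common, function(s) {
    i <- which(x_design$substrate == s)
    j <- which(y_design$substrate == s)
    grid <- expand.grid(j = j, i = i)  # i-major, j-minor after reorder
    data.frame(substrate = s, i = grid$i, j = grid$j,
               x_exp = x_design$experiment_id[grid$i],
               y_exp = y_design$experiment_id[grid$j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out[order(out$substrate, out$i, out$j), , drop = FALSE]
}

#' Build the pair set for one (protein, microbe) pair
#'
#' @param x,y feature containers (tables or [feature_matrix()]) holding the
#'   protein levels and microbe abundances.
#' @param x_feature,y_feature feature ids to pair.
#' @return a `pair_set`: data.frame of (`l`, `a`, `substrate`) rows plus the
#'   feature ids; `|pairs|` equals the sum over substrates of
#'   `n_x(s) * n_y(s)`.
#' @export
build_pair_set <- function(x, y, x_feature, y_feature) {
  xv <- table_values(x); yv <- table_values(y)
  if (!x_feature %in% rownames(xv)) stopf("unknown x feature: %s", x_feature)
  if (!y_feature %in% rownames(yv)) stopf("unknown y feature: %s", y_feature)
  idx <- pair_index(table_design(x), table_design(y))
  structure(list(x_feature = x_feature, y_feature = y_feature,
                 pairs = data.frame(l = xv[x_feature, idx$i],
                                    a = yv[y_feature, idx$j],
                                    substrate = idx$substrate,
                                    row.names = NULL)),
            class = "pair_set")
}

pair_values <- function(pairs) {
  if (inherits(pairs, "pair_set")) pairs$pairs else as.data.frame(pairs)
}

#' Pearson correlation over a pair set
#'
#' Equal weight per pair. Returns `NA` (flagged undefined) when either
#' coordinate is constant.
#'
#' @param pairs a `pair_set` or data.frame with columns `l`, `a`.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(pairs) {
  d <- pair_values(pairs)
  if (nrow(d) < 3L) stopf("need >= 3 pairs")
  if (stats::sd(d$l) == 0 || stats::sd(d$a) == 0) return(NA_real_)
  stats::cor(d$l, d$a)
}

#' Plug-in mutual information on quantile bins
#'
#' Both margins are discretized into `b = clamp(floor(sqrt(n/5)), 2, 10)`
#' equal-frequency bins (ties broken by rank order), and the plug-in MI of
#' the contingency table is returned in nats. Symmetric by construction.
#'
#' @param pairs a `pair_set` or data.frame with columns `l`, `a` (>= 10
#'   pairs).
#' @param bins number of bins per margin; default as above.
#' @return mutual information in nats (>= 0).
#' @export
mutual_information <- function(pairs, bins = NULL) {
  d <- pair_values(pairs)
  n <- nrow(d)
  if (n < 10L) stopf("need >= 10 pairs for the MI estimate")
  if (is.null(bins)) bins <- max(2L, min(10L, floor(sqrt(n / 5))))
  if (n < bins^2 / 5)
    warning(sprintf("only %d pairs for %d^2 MI cells; estimate may be biased", n, bins))
  bx <- quantile_bins(d$l, bins)
  by <- quantile_bins(d$a, bins)
  tab <- table(bx, by) / n
  px <- rowSums(tab); py <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
}

quantile_bins <- function(x, b) {
  r <- rank(x, ties.method = "first")
  ceiling(r * b / length(x))
}

#' Pairwise association of every feature in one block with every feature in
#' another
#'
#' Vectorized over features: the pair index is shared, so Pearson
#' correlations come from one matrix product; MI is computed per pair when
#' requested.
#'
#' @param x,y feature containers (x = proteins / predictors, y = microbes /
#'   responses).
#' @param x_features,y_features optional feature subsets.
#' @param mi compute mutual information per pair (slower).
#' @param tau threshold for the `high` flag (strict `|r| > tau`).
#' @return data.frame: `x_feature`, `y_feature`, `n_pairs`, `r`, `mi`
#'   (if requested), `high`, `sign`.
#' @export
associate_features <- function(x, y, x_features = NULL, y_features = NULL,
                               mi = FALSE, tau = 0.7) {
  xv <- table_values(x); yv <- table_values(y)
  if (!is.null(x_features)) xv <- xv[x_features, , drop = FALSE]
  if (!is.null(y_features)) yv <- yv[y_features, , drop = FALSE]
  idx <- pair_index(table_design(x), table_design(y))
  Lx <- t(xv[, idx$i, drop = FALSE])  # pairs x x-features
  Ly <- t(yv[, idx$j, drop = FALSE])
  suppressWarnings(R <- stats::cor(Lx, Ly))  # NA where a margin is constant
  out <- data.frame(x_feature = rep(rownames(xv), times = nrow(yv)),
                    y_feature = rep(rownames(yv), each = nrow(xv)),
                    n_pairs = rep(nrow(idx), nrow(xv) * nrow(yv)),
                    r = as.vector(R),
                    stringsAsFactors = FALSE)
  if (mi) {
    out$mi <- mapply(function(i, j)
      mutual_information(data.frame(l = Lx[, i], a = Ly[, j])),
      match(out$x_feature, rownames(xv)), match(out$y_feature, rownames(yv)))
  }
  out$high <- !is.na(out$r) & abs(out$r) > tau
  out$sign <- sign(out$r)
  out
}

#' Threshold an association list into an edge list
#'
#' Keeps pairs with `|r| > tau` (strict), labels the sign and whether the
#' edge clears the "strong" tier, and groups edges per y-feature (microbe)
#' for chord-diagram export.
#'
#' @param results data.frame from [associate_features()].
#' @param tau edge threshold (default 0.7).
#' @param strong strong-correlation tier (default 0.8).
#' @return data.frame of edges: `x_feature`, `y_feature`, `r`, `sign`,
#'   `strong`, ordered by y-feature then |r| descending.
#' @export
threshold_associations <- function(results, tau = 0.7, strong = 0.8) {
  keep <- !is.na(results$r) & abs(results$r) > tau
  edges <- results[keep, c("x_feature", "y_feature", "r"), drop = FALSE]
  edges$sign <- sign(edges$r)
  edges$strong <- abs(edges$r) > strong
  edges <- edges[order(edges$y_feature, -abs(edges$r), edges$x_feature), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Top-k strongest negative and positive correlations
#'
#' @param results data.frame from [associate_features()].
#' @param k how many per sign (fewer are returned, with a warning, if not
#'   enough results carry that sign).
#' @return list of data.frames `negative` (most negative first) and
#'   `positive` (most positive first); ties broken by
#'   (x_feature, y_feature) lexicographic order.
#' @export
top_k_signed <- function(results, k = 3L) {
  res <- results[!is.na(results$r), , drop = FALSE]
  neg <- res[res$r < 0, , drop = FALSE]
  pos <- res[res$r > 0, , drop = FALSE]
  neg <- neg[order(neg$r, neg$x_feature, neg$y_feature), , drop = FALSE]
  pos <- pos[order(-pos$r, pos$x_feature, pos$y_feature), , drop = FALSE]
  if (nrow(neg) < k) warning(sprintf("only %d negative correlations available", nrow(neg)))
  if (nrow(pos) < k) warning(sprintf("only %d positive correlations available", nrow(pos)))
  lapply(list(negative = neg, positive = pos), function(d) {
    d <- utils::head(d, k)
    rownames(d) <- NULL
    d
  })
}

#' Microbe-microbe association between timepoints
#'
#' Applies the same substrate-matched pairing with the 2h experiments as
#' the X side and the 24h experiments as the Y side, then Pearson r per
#' (microbe at 2h, microbe at 24h) pair with a strict threshold.
#'
#' @param x_2h,y_24h ASV containers (typically offset-log transformed) at
#'   the two timepoints.
#' @param tau strict threshold on `|r|` (default 0.5).
#' @param mi also compute mutual information.
#' @return list: `results` (all pairs) and `edges` (`|r| > tau`).
#' @export
cross_timepoint_association <- function(x_2h, y_24h, tau = 0.5, mi = FALSE) {
  results <- associate_features(x_2h, y_24h, mi = mi, tau = tau)
  list(results = results, edges = threshold_associations(results, tau = tau))
}
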