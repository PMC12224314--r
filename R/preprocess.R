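# Preprocessing: detection-limit imputation by Pearson-skewness
# minimization, the offset-log transform with its closed-form alpha,
# proportion scaling, annotation aggregation, replicate averaging.

#' Lightweight feature matrix with design metadata
#'
#' Container for transformed values (which may be negative, unlike the typed
#' input tables): a numeric matrix plus the experiment design.
#'
#' @param values numeric matrix, features x experiments.
#' @param design experiment design data.frame.
#' @param taxonomy optional per-feature labels.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, design, taxonomy = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(design))
    stopf("column count (%d) != number of design rows (%d)", ncol(values), nrow(design))
  structure(list(values = values, design = design, taxonomy = taxonomy),
            class = "feature_matrix")
}

# extract (matrix, design) from any of the containers
table_values <- function(x) {
  if (inherits(x, c("feature_table", "feature_matrix"))) x$values
  else as.matrix(x)
}
table_design <- function(x) {
  if (inherits(x, c("feature_table", "feature_matrix"))) x$design
  else stopf("no design metadata attached")
}

#' Pearson's second skewness coefficient
#'
#' `3 * (mean - median) / sd`, with the sample (n-1) standard deviation.
#' Zero when mean equals median; location-invariant.
#'
#' @param values numeric vector, length >= 2, non-degenerate.
#' @return dimensionless skewness value.
#' @export
pearson_second_skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stopf("need >= 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stopf("degenerate distribution: sd = 0")
  3 * (mean(values) - stats::median(values)) / s
}

#' Fit the detection-limit imputation constant
#'
#' Finds the constant c, one value for the whole table (pooled across
#' substrates and readings), that minimizes the absolute Pearson second
#' skewness of the pooled intensity distribution once every missing cell is
#' set to c. The search runs over `(1e-9 * min_present, min_present]`: the
#' imputed value never exceeds the smallest observed intensity (the
#' detection-limit proxy). When `g(c) = mean - median` changes sign on the
#' interval, the root is found by bisection (there mean equals median, hence
#' zero skewness); otherwise the boundary argmin of |skewness| is returned
#' from bounded scalar minimization.
#'
#' @param table a [protein_table()] with at least one missing cell.
#' @param scale `"raw"` (default) minimizes skewness on the intensity scale;
#'   `"log10"` on log10 intensities (sensitivity analysis).
#' @return an `imputation_result`: `c`, `sk2_before` (present values only),
#'   `sk2_after`, `n_imputed`, `search_interval`, `method`
#'   (`"bisection"`/`"boundary"`), `applicable`.
#' @export
fit_imputation_constant <- function(table, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  vals <- table_values(table)
  present <- vals[!is.na(vals)]
  n_missing <- sum(is.na(vals))
  if (n_missing == 0L)
    return(structure(list(c = NA_real_, sk2_before = NA_real_,
                          sk2_after = NA_real_, n_imputed = 0L,
                          search_interval = c(NA_real_, NA_real_),
                          method = "none", applicable = FALSE, scale = scale),
                     class = "imputation_result"))
  if (length(present) < 2L) stopf("need >= 2 present values to fit imputation")
  if (stats::sd(present) == 0) stopf("degenerate distribution: present values constant")

  xform <- if (scale == "log10") log10 else identity
  pres_t <- xform(present)
  sk2_at <- function(cc) pearson_second_skewness(c(pres_t, rep(xform(cc), n_missing)))
  g_at <- function(cc) {
    v <- c(pres_t, rep(xform(cc), n_missing))
    mean(v) - stats::median(v)
  }

  high <- min(present)
  low <- 1e-9 * high
  sk2_before <- pearson_second_skewness(pres_t)

  g_low <- g_at(low); g_high <- g_at(high)
  if (sign(g_low) * sign(g_high) <= 0) {
    # bisection on g: mean is affine increasing in c, median piecewise
    # nondecreasing, so g is continuous; stop when |g| <= 1e-9 * mean or the
    # interval shrinks below 1e-9 of its initial width
    a <- low; b <- high; ga <- g_low
    width0 <- b - a
    for (it in seq_len(200L)) {
      mid <- (a + b) / 2
      gm <- g_at(mid)
      vbar <- mean(c(pres_t, rep(xform(mid), n_missing)))
      if (abs(gm) <= 1e-9 * abs(vbar) || (b - a) <= 1e-9 * width0) break
      if (sign(gm) == sign(ga)) { a <- mid; ga <- gm } else b <- mid
    }
    cc <- (a + b) / 2
    method <- "bisection"
  } else {
    opt <- stats::optimize(function(cc) abs(sk2_at(cc)), c(low, high),
                           tol = 1e-9 * (high - low))
    cands <- c(opt$minimum, low, high)
    cc <- cands[which.min(vapply(cands, function(cc) abs(sk2_at(cc)), 0))]
    method <- "boundary"
  }
  structure(list(c = cc, sk2_before = sk2_before, sk2_after = sk2_at(cc),
                 n_imputed = n_missing, search_interval = c(low, high),
                 method = method, applicable = TRUE, scale = scale),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  if (!x$applicable) cat("<imputation> nothing to impute\n")
  else cat(sprintf("<imputation> c = %.6g (%s, %s scale), %d cells; |Sk2| %.4g -> %.4g\n",
                   x$c, x$method, x$scale, x$n_imputed,
                   abs(x$sk2_before), abs(x$sk2_after)))
  invisible(x)
}

#' Apply an imputation constant to a protein table
#'
#' Replaces every missing cell with `c`; present values are untouched.
#' Idempotent: a complete table passes through unchanged.
#'
#' @param table a [protein_table()].
#' @param c imputation constant, `0 < c <= min present value` (from
#'   [fit_imputation_constant()] or user-supplied).
#' @return a complete [protein_table()].
#' @export
apply_imputation <- function(table, c) {
  vals <- table_values(table)
  if (!anyNA(vals)) return(table)
  if (!is_pos(c) || c > min(vals, na.rm = TRUE))
    stopf("imputation constant must satisfy 0 < c <= min present value (%.6g)",
          min(vals, na.rm = TRUE))
  vals[is.na(vals)] <- c
  protein_table(vals, table$design)
}

#' Offset-log alpha from the table's minimum nonzero abundance
#'
#' `alpha = 10^(floor(log10(m)) - 1)` with m the smallest strictly positive
#' abundance in the table: one decade below the minimum's decade. The
#' bracket convention is configurable (`"round"` = round-half-even).
#'
#' @param table an [asv_table()] (or any matrix-like) with at least one
#'   positive value.
#' @param bracket `"floor"` (default) or `"round"`.
#' @return an `offset_spec` with `alpha`, `min_nonzero`, `base = 10`.
#' @export
offset_alpha <- function(table, bracket = c("floor", "round")) {
  bracket <- match.arg(bracket)
  vals <- table_values(table)
  pos <- vals[!is.na(vals) & vals > 0]
  if (length(pos) == 0L) stopf("no nonzero minimum exists: all abundances are zero")
  m <- min(pos)
  br <- if (bracket == "floor") floor(log10(m)) else round(log10(m))
  structure(list(alpha = 10^(br - 1), min_nonzero = m, base = 10,
                 bracket = bracket),
            class = "offset_spec")
}

#' Offset-log transform
#'
#' Rescales zero-inflated right-skewed abundances by
#' `x -> log10(alpha + x)`; strictly monotone, zeros map to `log10(alpha)`.
#'
#' @param table an [asv_table()] or [feature_matrix()].
#' @param spec an `offset_spec` (default: fitted from `table`).
#' @return a [feature_matrix()] of transformed values.
#' @export
offset_log <- function(table, spec = offset_alpha(table)) {
  if (!is_pos(spec$alpha)) stopf("alpha must be > 0")
  vals <- table_values(table)
  feature_matrix(log10(spec$alpha + vals), table_design(table),
                 taxonomy = if (inherits(table, "feature_table")) table$taxonomy)
}

#' Scale each experiment to proportions (total-sum scaling)
#'
#' @param table an [asv_table()].
#' @return an [asv_table()] whose columns each sum to 1.
#' @export
total_sum_scale <- function(table) {
  vals <- table_values(table)
  sums <- colSums(vals)
  if (any(sums <= 0))
    stopf("zero-sum experiment column(s): %s",
          paste(colnames(vals)[sums <= 0], collapse = ", "))
  out <- sweep(vals, 2L, sums, "/")
  asv_table(out, table_design(table),
            taxonomy = if (inherits(table, "feature_table")) table$taxonomy)
}

#' Aggregate protein intensities by annotation label
#'
#' For each label in the chosen category, the cumulative intensity per
#' experiment is the sum of the intensities of its member proteins; a
#' protein carrying k labels contributes to all k sums. Labels with no
#' member present in the table are omitted.
#'
#' @param table a complete (imputed) [protein_table()].
#' @param map an [annotation_map()].
#' @param category `"molecular_function"` or `"biological_process"`.
#' @return a [feature_matrix()] keyed by label.
#' @export
aggregate_by_annotation <- function(table, map,
                                    category = c("molecular_function",
                                                 "biological_process")) {
  category <- match.arg(category)
  vals <- table_values(table)
  if (anyNA(vals)) stopf("aggregate_by_annotation requires a complete (imputed) table")
  m <- map[[category]]
  m <- m[names(m) %in% rownames(vals)]
  if (length(m) == 0L)
    return(feature_matrix(matrix(0, 0L, ncol(vals),
                                 dimnames = list(NULL, colnames(vals))),
                          table_design(table)))
  labels <- sort(unique(unlist(m, use.names = FALSE)))
  out <- matrix(0, length(labels), ncol(vals),
                dimnames = list(labels, colnames(vals)))
  for (p in names(m))
    for (lab in m[[p]])
      out[lab, ] <- out[lab, ] + vals[p, ]
  feature_matrix(out, table_design(table))
}

#' Average replicates within substrate (and timepoint) groups
#'
#' @param table any feature table or [feature_matrix()].
#' @return matrix of per-group arithmetic means, features x groups; group
#'   columns are named `substrate` or `substrate.timepoint`.
#' @export
average_replicates <- function(table) {
  vals <- table_values(table)
  design <- table_design(table)
  key <- if (all(is.na(design$timepoint))) design$substrate
         else paste(design$substrate, design$timepoint, sep = ".")
  groups <- unique(key)
  out <- vapply(groups, function(g)
    rowMeans(vals[, key == g, drop = FALSE]), numeric(nrow(vals)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(vals), groups))
  out
}
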