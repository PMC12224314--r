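# Typed feature-by-experiment tables and their TSV representation.
#
# A feature table couples a numeric matrix (features in rows, experiments in
# columns) with an experiment design data.frame. Two kinds exist:
#   * protein tables: LFQ-like intensities, strictly positive where present,
#     NA marks a below-detection (missing) cell; design has no timepoint.
#   * asv tables: nonnegative abundances, zeros allowed, never NA; design
#     carries a timepoint ("2h"/"24h") for every experiment.

#' Construct an experiment design table
#'
#' @param experiment_id unique experiment identifiers.
#' @param substrate substrate label per experiment; canonicalized to
#'   lowercase and validated against `vocabulary`.
#' @param timepoint optional timepoint label per experiment (`"2h"`/`"24h"`);
#'   required for microbial designs, must be absent (all `NA`) for proteomic
#'   ones.
#' @param replicate replicate/reading id per experiment (small integer).
#' @param vocabulary allowed substrate labels.
#' @return a `data.frame` with columns `experiment_id`, `substrate`,
#'   `timepoint`, `replicate`.
#' @export
experiment_design <- function(experiment_id, substrate, timepoint = NA,
                              replicate = seq_along(experiment_id),
                              vocabulary = default_substrates()) {
  experiment_id <- as.character(experiment_id)
  if (anyDuplicated(experiment_id))
    stopf("duplicate experiment_id: %s",
          paste(unique(experiment_id[duplicated(experiment_id)]), collapse = ", "))
  substrate <- check_substrates(substrate, vocabulary, what = "experiment design")
  if (length(substrate) != length(experiment_id))
    stopf("substrate must have one entry per experiment")
  timepoint <- rep_len(as.character(timepoint), length(experiment_id))
  ok <- is.na(timepoint) | canonical_label(timepoint) %in% default_timepoints()
  if (!all(ok))
    stopf("unknown timepoint label(s): %s",
          paste(unique(timepoint[!ok]), collapse = ", "))
  timepoint <- ifelse(is.na(timepoint), NA_character_, canonical_label(timepoint))
  data.frame(experiment_id = experiment_id, substrate = substrate,
             timepoint = timepoint,
             replicate = as.integer(rep_len(replicate, length(experiment_id))),
             stringsAsFactors = FALSE)
}

new_feature_table <- function(values, design, kind, taxonomy = NULL) {
  structure(list(values = values, design = design, taxonomy = taxonomy),
            class = c(paste0(kind, "_table"), "feature_table"))
}

#' Construct a protein intensity table
#'
#' @param values numeric matrix, proteins in rows (rownames = UniProt-style
#'   accessions), experiments in columns; `NA` marks a missing
#'   (below-detection) cell; present values must be strictly positive.
#' @param design experiment design (see [experiment_design()]); timepoints
#'   must be absent.
#' @return an object of class `c("protein_table", "feature_table")`.
#' @export
protein_table <- function(values, design) {
  values <- as.matrix(values)
  check_feature_matrix(values, design, "protein")
  if (any(values[!is.na(values)] <= 0))
    stopf("protein intensities must be strictly positive where present")
  if (any(rowSums(!is.na(values)) == 0L))
    stopf("protein(s) with no present value: %s",
          paste(rownames(values)[rowSums(!is.na(values)) == 0L], collapse = ", "))
  if (!all(is.na(design$timepoint)))
    stopf("proteomic designs carry no timepoint")
  new_feature_table(values, design, "protein")
}

#' Construct an ASV abundance table
#'
#' @param values numeric matrix, ASVs in rows, experiments in columns;
#'   nonnegative, zeros allowed, no `NA`.
#' @param design experiment design; every experiment needs a timepoint.
#' @param taxonomy optional character vector of taxonomy labels (species +
#'   HMT id), one per ASV.
#' @return an object of class `c("asv_table", "feature_table")`.
#' @export
asv_table <- function(values, design, taxonomy = NULL) {
  values <- as.matrix(values)
  check_feature_matrix(values, design, "asv")
  if (anyNA(values)) stopf("ASV abundances may not be missing (use 0)")
  if (any(values < 0)) stopf("negative abundance value")
  if (any(is.na(design$timepoint)))
    stopf("microbial designs require a timepoint for every experiment")
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != nrow(values))
      stopf("taxonomy must have one label per ASV")
    names(taxonomy) <- rownames(values)
  }
  new_feature_table(values, design, "asv", taxonomy)
}

check_feature_matrix <- function(values, design, kind) {
  if (is.null(rownames(values))) stopf("feature matrix needs rownames (feature ids)")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate feature id: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (ncol(values) != nrow(design))
    stopf("column count (%d) != number of design rows (%d)", ncol(values), nrow(design))
  if (is.null(colnames(values))) colnames(values) <- design$experiment_id
  if (!identical(colnames(values), design$experiment_id))
    stopf("column names must match design experiment_ids (same order)")
  if (!is.numeric(values)) stopf("non-numeric cell in %s table", kind)
  invisible(TRUE)
}

#' @export
print.feature_table <- function(x, ...) {
  kind <- if (inherits(x, "protein_table")) "protein intensity" else "ASV abundance"
  cat(sprintf("<%s table> %d features x %d experiments\n", kind,
              nrow(x$values), ncol(x$values)))
  cat("substrates:", paste(sprintf("%s (%d)", names(table(x$design$substrate)),
                                   table(x$design$substrate)), collapse = ", "), "\n")
  if (!all(is.na(x$design$timepoint)))
    cat("timepoints:", paste(unique(x$design$timepoint), collapse = ", "), "\n")
  n_missing <- sum(is.na(x$values))
  if (n_missing > 0) cat("missing cells:", n_missing, "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature ids of a table
#' @param table a feature table.
#' @return character vector of feature ids.
#' @export
feature_ids <- function(table) rownames(table$values)

# ---------------------------------------------------------------------------
# TSV i/o. Dialect: tab-separated, UTF-8, "." decimal separator; first column
# holds the feature id; an optional "taxonomy" column is allowed for ASV
# tables; all remaining columns are experiments. Missing protein cells are
# empty or "NA". The design travels in a sidecar TSV with columns
# experiment_id, substrate, timepoint, replicate.

#' Read a feature table from TSV
#'
#' @param path TSV file; first column = feature id, remaining columns =
#'   experiments (an optional `taxonomy` column is honoured for ASVs).
#'   Empty cells or the token `NA` mark missing protein intensities.
#' @param design the experiment design: a data.frame or the path of a
#'   sidecar TSV with columns `experiment_id`, `substrate`, `timepoint`,
#'   `replicate`.
#' @param schema `"protein"` or `"asv"`.
#' @param vocabulary allowed substrate labels.
#' @return a [protein_table()] or [asv_table()].
#' @export
read_feature_table <- function(path, design, schema = c("protein", "asv"),
                               vocabulary = default_substrates()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stopf("feature TSV needs a feature-id column plus experiments")
  ids <- as.character(raw[[1L]])
  taxonomy <- NULL
  data_cols <- raw[-1L]
  if ("taxonomy" %in% names(data_cols)) {
    taxonomy <- as.character(data_cols[["taxonomy"]])
    data_cols[["taxonomy"]] <- NULL
  }
  for (cn in names(data_cols)) {
    col <- data_cols[[cn]]
    if (!is.numeric(col)) {
      bad <- suppressWarnings(is.na(as.numeric(col)) & !is.na(col))
      if (any(bad))
        stopf("non-numeric cell(s) in experiment column %s: %s", sQuote(cn),
              paste(utils::head(unique(col[bad]), 3L), collapse = ", "))
      data_cols[[cn]] <- as.numeric(col)
    }
  }
  values <- as.matrix(as.data.frame(data_cols, check.names = FALSE))
  rownames(values) <- ids
  if (any(values[!is.na(values)] < 0)) stopf("negative value in %s", path)

  if (is.character(design) && length(design) == 1L) design <- read_design(design, vocabulary)
  if (!is.data.frame(design)) stopf("design must be a data.frame or a TSV path")
  design <- experiment_design(design$experiment_id, design$substrate,
                              if ("timepoint" %in% names(design)) design$timepoint else NA,
                              if ("replicate" %in% names(design)) design$replicate else seq_len(nrow(design)),
                              vocabulary = vocabulary)
  missing_exp <- setdiff(colnames(values), design$experiment_id)
  if (length(missing_exp) > 0L)
    stopf("experiment column(s) absent from design: %s", paste(missing_exp, collapse = ", "))
  design <- design[match(colnames(values), design$experiment_id), , drop = FALSE]
  rownames(design) <- NULL

  if (schema == "protein") protein_table(values, design)
  else {
    values[is.na(values)] <- 0  # defensive; asv TSVs should not have blanks
    asv_table(values, design, taxonomy)
  }
}

read_design <- function(path, vocabulary = default_substrates()) {
  if (!file.exists(path)) stopf("design file not found: %s", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("", "NA"),
                         fileEncoding = "UTF-8")
  need <- c("experiment_id", "substrate")
  if (!all(need %in% names(d)))
    stopf("design TSV must have columns: %s", paste(need, collapse = ", "))
  d
}

#' Write a feature table (and its design) to TSV
#'
#' Round-trips through [read_feature_table()]: values, feature ids and
#' design metadata are preserved exactly.
#'
#' @param table a feature table.
#' @param path output TSV for the value matrix.
#' @param design_path optional output TSV for the design sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, design_path = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(feature_id = rownames(table$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  if (!is.null(design_path))
    utils::write.table(table$design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Detection summaries (Venn-region counts across substrates).

#' Summarize per-substrate detection and overlap
#'
#' A feature counts as detected on a substrate iff it has at least one
#' present value there: non-missing for protein tables, strictly positive
#' for ASV tables.
#'
#' @param table a feature table covering at least two substrates.
#' @return a `detection_summary`: per-substrate counts, pairwise and
#'   all-way shared counts, per-substrate exclusive id lists, and counts for
#'   every Venn region (keyed by `+`-joined substrate subsets).
#' @export
summarize_detection <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  subs <- sort(unique(table$design$substrate))
  if (length(subs) < 2L) stopf("need >=2 substrates to summarize detection")
  present <- if (inherits(table, "protein_table")) !is.na(table$values)
             else table$values > 0
  # feature x substrate detection matrix
  det <- vapply(subs, function(s) {
    cols <- table$design$substrate == s
    rowSums(present[, cols, drop = FALSE]) > 0L
  }, logical(nrow(table$values)))
  if (is.null(dim(det))) det <- matrix(det, nrow = 1L, dimnames = list(feature_ids(table), subs))

  detected <- lapply(subs, function(s) rownames(det)[det[, s]])
  names(detected) <- subs
  counts <- vapply(detected, length, integer(1L))

  # every nonempty subset of substrates: shared counts and exact regions
  subsets <- unlist(lapply(seq_along(subs), function(k)
    utils::combn(subs, k, simplify = FALSE)), recursive = FALSE)
  shared <- vapply(subsets, function(ss)
    sum(rowSums(det[, ss, drop = FALSE]) == length(ss)), integer(1L))
  names(shared) <- vapply(subsets, paste, "", collapse = "+")
  pattern <- apply(det, 1L, function(r) paste(subs[r], collapse = "+"))
  regions <- vapply(names(shared), function(k) sum(pattern == k), integer(1L))
  exclusive <- lapply(subs, function(s) rownames(det)[pattern == s])
  names(exclusive) <- subs

  structure(list(substrates = subs, detected = detected, counts = counts,
                 shared = shared, regions = regions, exclusive = exclusive,
                 union_count = sum(rowSums(det) > 0L)),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("<detection summary>\n")
  for (s in x$substrates)
    cat(sprintf("  %s: %d detected (%d exclusive)\n", s, x$counts[[s]],
                length(x$exclusive[[s]])))
  cat(sprintf("  shared by all: %d; union: %d\n",
              x$shared[[paste(x$substrates, collapse = "+")]], x$union_count))
  invisible(x)
}

#' Write a detection summary as JSON and TSV
#' @param summary a `detection_summary`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @return invisibly, the summary.
#' @export
write_detection_summary <- function(summary, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    df <- data.frame(region = names(summary$regions),
                     exact_count = as.integer(summary$regions),
                     shared_count = as.integer(summary$shared))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(summary)
}
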