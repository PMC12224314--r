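# Protein annotation maps: UniProt-style molecular function / biological
# process labels, read from a long-format TSV.

annotation_categories <- function() c("molecular_function", "biological_process")

#' Construct an annotation map
#'
#' @param protein_id,category,label parallel vectors: one row per
#'   (protein, category, label) assignment; `category` must be
#'   `"molecular_function"` or `"biological_process"`.
#' @return an `annotation_map`: per category, a named list mapping each
#'   protein id to its de-duplicated label set.
#' @export
annotation_map <- function(protein_id = character(), category = character(),
                           label = character()) {
  protein_id <- as.character(protein_id); category <- as.character(category)
  label <- as.character(label)
  stopifnot(length(protein_id) == length(category),
            length(category) == length(label))
  bad <- setdiff(unique(category), annotation_categories())
  if (length(bad) > 0L)
    stopf("unknown annotation category token(s): %s (expected %s)",
          paste(bad, collapse = ", "),
          paste(annotation_categories(), collapse = ", "))
  if (any(!nzchar(trimws(label))))
    stopf("annotation labels must be nonempty strings")
  out <- lapply(annotation_categories(), function(cat) {
    keep <- category == cat
    if (!any(keep)) return(structure(list(), names = character()))
    lapply(split(label[keep], protein_id[keep]), function(l) sort(unique(l)))
  })
  names(out) <- annotation_categories()
  structure(out, class = "annotation_map")
}

#' Read an annotation map from TSV
#'
#' Expects columns `protein_id`, `category`, `label` (long format, one
#' assignment per row). Duplicate (protein, category, label) rows collapse
#' to one entry. An empty file yields a valid empty map. Proteins absent
#' from any intensity table are retained; consumers subset as needed.
#'
#' @param path TSV path.
#' @return an [annotation_map()].
#' @export
read_annotation_map <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) data.frame(protein_id = character(),
                                   category = character(), label = character()))
  if (nrow(d) == 0L) return(annotation_map())
  need <- c("protein_id", "category", "label")
  if (!all(need %in% names(d)))
    stopf("annotation TSV must have columns: %s", paste(need, collapse = ", "))
  annotation_map(d$protein_id, d$category, d$label)
}

#' Write an annotation map to TSV (long format)
#' @param map an `annotation_map`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_map <- function(map, path) {
  rows <- do.call(rbind, lapply(annotation_categories(), function(cat) {
    m <- map[[cat]]
    if (length(m) == 0L) return(NULL)
    data.frame(protein_id = rep(names(m), lengths(m)), category = cat,
               label = unlist(m, use.names = FALSE), stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(protein_id = character(), category = character(),
                       label = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation map> %d proteins with molecular functions, %d with biological processes\n",
              length(x$molecular_function), length(x$biological_process)))
  invisible(x)
}
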