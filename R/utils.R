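# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Canonical substrate vocabulary. Extensible: functions accepting substrates
# take a `vocabulary` argument defaulting to this.
default_substrates <- function() c("dentine", "enamel", "titanium")

default_timepoints <- function() c("2h", "24h")

#' Canonicalize substrate (or timepoint) labels
#'
#' Lowercases, trims surrounding whitespace, and collapses internal runs of
#' whitespace, so e.g. `"Enamel "` becomes `"enamel"`.
#'
#' @param x character vector of labels.
#' @return canonicalized character vector.
#' @keywords internal
canonical_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Validate substrate labels against a vocabulary; `what` names the offending
# source (e.g. a column) in the error message.
check_substrates <- function(x, vocabulary = default_substrates(), what = "design") {
  x <- canonical_label(x)
  bad <- setdiff(unique(x), vocabulary)
  if (length(bad) > 0L) {
    stop(sprintf("unknown substrate label(s) %s in %s (expected one of: %s)",
                 paste(sQuote(bad), collapse = ", "), what,
                 paste(vocabulary, collapse = ", ")), call. = FALSE)
  }
  x
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# scalar checks
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}
is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
is_pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
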