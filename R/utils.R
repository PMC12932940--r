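#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort hash
#' @importFrom stats runif
#' @importFrom utils read.csv write.csv
NULL

# Sentinel value for an explicit "no value present" response. Kept as a
# string so records serialize cleanly to JSONL.
ABSTAIN <- "ABSTAIN"

#' Abstention sentinel
#'
#' The canonical value an extraction backend emits when it judges that no
#' allowed value for the field is present in the text. Abstention is a value,
#' not an error: it is scored (as a true negative or false negative) by the
#' evaluation engine.
#'
#' @return The string `"ABSTAIN"`.
#' @export
abstain_value <- function() ABSTAIN

#' Normalize a value string for matching and exact-match scoring
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, casefolds to lower case, and unifies dash variants (em-dash,
#' en-dash, hyphen) to a plain hyphen. All option matching and all
#' "exact match" comparisons in the evaluator go through this normalization,
#' so surface differences in spacing, case, and dash typography never decide
#' an outcome.
#'
#' @param x character vector.
#' @return character vector of the same length, normalized.
#' @examples
#' normalize_value("  Atypical  Ductal\nHyperplasia ")
#' normalize_value("Exact distance: — mm")
#' @export
normalize_value <- function(x) {
  x <- as.character(x)
  x <- gsub("[—–]", "-", x)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  tolower(x)
}

# Matching form of a canonical option: normalized, and for numeric-template
# options the placeholder dash is dropped (reports print "Exact distance: mm",
# the template prints "Exact distance: — mm").
match_form <- function(x) {
  x <- normalize_value(x)
  x <- gsub("\\s*-\\s*", " ", x)
  gsub("\\s+", " ", trimws(x))
}

# fixed = TRUE substring containment on matching forms
contains_match <- function(haystack_norm, needle) {
  grepl(match_form(needle), gsub("\\s*-\\s*", " ", haystack_norm), fixed = TRUE)
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Render a proportion as a percentage string
#'
#' @param p proportion in \[0, 1\] (or `NA`).
#' @param digits decimal places (half-up rounding, matching how clinical
#'   tables are typically printed).
#' @return numeric percentage rounded half-up, `NA` for `NA` input.
#' @export
as_percent <- function(p, digits = 1) {
  ifelse(is.na(p), NA_real_, round_half_up(100 * p, digits))
}

#' Read and write JSON Lines files
#'
#' One JSON object per line; used for reports, extraction records, synthetic
#' cases, and ground-truth manifests.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_jsonl()` returns a data frame; `write_jsonl()` returns
#'   `path` invisibly.
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname read_jsonl
#' @export
write_jsonl <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    as.character(jsonlite::toJSON(as.list(x[i, , drop = FALSE]),
                                  auto_unbox = TRUE, na = "null",
                                  digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
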