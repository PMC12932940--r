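#' Derive a segmentation pattern table from the schema
#'
#' Synoptic reports label their items as `"Label: value"`. Segmentation is
#' schema-driven: each pattern is the field's (or subsection's) label,
#' anchored at the start of a line and followed by a colon, matched
#' case-insensitively. An override table can replace the derived pattern for
#' irregular headings without touching the schema.
#'
#' @param schema an `ontology_schema`.
#' @param level `"field"` (default) derives one pattern per field from its
#'   label; `"subsection"` derives one pattern per subsection name, tied to
#'   the subsection's first field. The bundled schema gives every field a
#'   distinct label, so field-level patterns are unambiguous and keep
#'   segments non-overlapping.
#' @param overrides optional data frame with columns `field_id`, `regex`
#'   replacing the derived regex for those fields.
#' @return data frame with columns `pattern_id`, `field_id`, `regex`.
#' @export
derive_patterns <- function(schema, level = c("field", "subsection"),
                            overrides = NULL) {
  stopifnot(inherits(schema, "ontology_schema"))
  level <- match.arg(level)
  f <- schema$fields
  if (level == "field") {
    pat <- data.frame(pattern_id = paste0("pat_", f$field_id),
                      field_id = f$field_id,
                      regex = paste0("(?mi)^[ \\t]*",
                                     escape_regex(f$label), ":"),
                      stringsAsFactors = FALSE)
  } else {
    key <- !duplicated(paste(f$section, f$subsection, sep = "\r"))
    s <- f[key, ]
    pat <- data.frame(pattern_id = paste0("pat_sub_", seq_len(nrow(s))),
                      field_id = s$field_id,
                      regex = paste0("(?mi)^[ \\t]*",
                                     escape_regex(s$subsection), ":"),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(overrides)) {
    stopifnot(all(c("field_id", "regex") %in% names(overrides)))
    i <- match(overrides$field_id, pat$field_id)
    if (anyNA(i)) abort("override references field(s) absent from pattern table")
    pat$regex[i] <- overrides$regex
  }
  pat
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Segment a report into labeled free-text blocks
#'
#' Scans the report for every pattern occurrence; each match opens a segment
#' that runs to the next match of any pattern (or end of text). Spans are
#' 0-based half-open character offsets into the source text; `text` is the
#' span substring with leading/trailing whitespace trimmed, so the segment
#' remains anchored losslessly to the report. Repeated labels each yield a
#' segment. Noise tokens such as `"nan"` are retained: filtering is the
#' extractor's job.
#'
#' @param report_text single non-empty string.
#' @param schema an `ontology_schema`.
#' @param patterns pattern table from [derive_patterns()]; derived at field
#'   level when omitted.
#' @return data frame of segments ordered by `start`: columns `field_id`,
#'   `text`, `start`, `end`, `pattern_id`. Zero rows when no label matches.
#' @examples
#' sch <- load_schema(default_schema_path())
#' segment_report("Additional Findings: Atypical ductal hyperplasia", sch)
#' @export
segment_report <- function(report_text, schema, patterns = NULL) {
  stopifnot(inherits(schema, "ontology_schema"))
  if (length(report_text) != 1L || is.na(report_text) ||
      !nzchar(trimws(report_text))) {
    abort("empty document")
  }
  if (is.null(patterns)) patterns <- derive_patterns(schema)
  unknown <- setdiff(patterns$field_id, schema$fields$field_id)
  if (length(unknown)) {
    abort(paste0("pattern references unknown field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  hits <- lapply(seq_len(nrow(patterns)), function(i) {
    m <- gregexpr(patterns$regex[i], report_text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(start = as.integer(m) - 1L,  # 0-based
               pattern_id = patterns$pattern_id[i],
               field_id = patterns$field_id[i],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(field_id = character(0), text = character(0),
                      start = integer(0), end = integer(0),
                      pattern_id = character(0), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$start, hits$pattern_id), , drop = FALSE]
  ends <- c(hits$start[-1L], nchar(report_text))
  seg_text <- substring(report_text, hits$start + 1L, ends)
  data.frame(field_id = hits$field_id,
             text = trimws(seg_text),
             start = hits$start,
             end = as.integer(ends),
             pattern_id = hits$pattern_id,
             row.names = NULL, stringsAsFactors = FALSE)
}
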