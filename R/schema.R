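#' Path to the bundled breast synoptic-report schema
#'
#' The package ships a normalized, CAP-derived reporting ontology for the five
#' major breast cancer report types (DCIS, invasive biopsy/resection,
#' Phyllodes biopsy/resection): 8 sections, 86 subsections, 229 discrete
#' fields. Field names are representative of CAP breast protocols; the
#' hierarchy and cardinality are the package's reference conditions.
#'
#' @return path to the bundled schema CSV.
#' @export
default_schema_path <- function() {
  system.file("extdata", "schema", "breast_synoptic_schema.csv",
              package = "synoptex", mustWork = TRUE)
}

SECTION_NAMES <- c("specimen", "tumor", "margins", "regional lymph nodes",
                   "distant metastasis", "pTNM classification",
                   "additional findings", "comments")

REPORT_TYPES <- c("dcis", "invasive_biopsy", "invasive_resection",
                  "phyllodes_biopsy", "phyllodes_resection")

VALUE_KINDS <- c("categorical", "numeric_template", "free_text")

SCHEMA_COLUMNS <- c("section", "subsection", "field_id", "label", "value_kind",
                    "options", "numeric_template", "synonyms", "report_types")

split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
}

# "surface=>Canonical option" pairs, pipe-delimited in the CSV cell
parse_synonyms <- function(x) {
  entries <- split_pipe(x)
  if (!length(entries)) return(data.frame(surface = character(0),
                                          canonical = character(0)))
  parts <- strsplit(entries, "=>", fixed = TRUE)
  data.frame(surface = trimws(vapply(parts, `[`, "", 1L)),
             canonical = trimws(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Load and validate an ontology schema from CSV
#'
#' Reads one or more UTF-8, comma-delimited schema files (columns: `section`,
#' `subsection`, `field_id`, `label`, `value_kind`, `options`,
#' `numeric_template`, `synonyms`, `report_types`; `options` and `synonyms`
#' pipe-delimited within the cell) and returns a validated `ontology_schema`
#' object. Loading is order-stable: the same files always produce an
#' identical schema, and the schema `version` is a content hash over the
#' normalized field table, recorded in downstream records for traceability.
#'
#' Validation enforces the structural invariants: unique `field_id`s,
#' sections drawn from the fixed 8-name set, categorical fields with at least
#' two allowed options, free-text fields with none, numeric-template fields
#' with exactly one placeholder dash in their template, and no allowed option
#' repeated within a field.
#'
#' @param schema_paths character vector of CSV paths; rows are concatenated
#'   in the order given.
#' @return An `ontology_schema`: list with `sections` (ordered names),
#'   `subsections` (named list, section -> ordered subsection names),
#'   `fields` (data frame, one row per field in schema order), `version`
#'   (content hash).
#' @examples
#' sch <- load_schema(default_schema_path())
#' schema_counts(sch)
#' @export
load_schema <- function(schema_paths) {
  for (p in schema_paths) {
    if (!file.exists(p)) abort(paste0("schema file not found: ", p))
  }
  tabs <- lapply(schema_paths, function(p) {
    tab <- tryCatch(
      read.csv(p, stringsAsFactors = FALSE, colClasses = "character",
               encoding = "UTF-8"),
      error = function(e) abort(paste0("malformed schema CSV '", p, "': ",
                                       conditionMessage(e))))
    missing <- setdiff(SCHEMA_COLUMNS, names(tab))
    if (length(missing)) {
      abort(paste0("schema CSV '", p, "' lacks required column(s): ",
                   paste(missing, collapse = ", ")))
    }
    tab[, SCHEMA_COLUMNS]
  })
  fields <- do.call(rbind, tabs)
  if (!nrow(fields)) abort("schema contains no fields")
  # ASCII placeholder accepted on read; canonical form is the em-dash
  fields$numeric_template <- vapply(fields$numeric_template, function(t) {
    if (!nzchar(t)) return(t)
    if (!grepl("—", t, fixed = TRUE)) t <- sub("(?<=\\s)-(?=\\s|$)",
                                                    "—", t, perl = TRUE)
    t
  }, character(1), USE.NAMES = FALSE)
  fields$options <- ifelse(fields$value_kind == "numeric_template" &
                             nzchar(fields$numeric_template),
                           fields$numeric_template, fields$options)
  validate_schema_fields(fields)
  sections <- unique(fields$section)
  subsections <- lapply(stats::setNames(sections, sections), function(s)
    unique(fields$subsection[fields$section == s]))
  rownames(fields) <- NULL
  structure(list(sections = sections,
                 subsections = subsections,
                 fields = fields,
                 version = rlang::hash(fields)),
            class = "ontology_schema")
}

validate_schema_fields <- function(fields) {
  probs <- character(0)
  dup <- unique(fields$field_id[duplicated(fields$field_id)])
  if (length(dup)) {
    probs <- c(probs, paste0("duplicate field_id(s): ",
                             paste(dup, collapse = ", ")))
  }
  bad_sec <- setdiff(unique(fields$section), SECTION_NAMES)
  if (length(bad_sec)) {
    probs <- c(probs, paste0("unknown section name(s): ",
                             paste(bad_sec, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(fields$value_kind), VALUE_KINDS)
  if (length(bad_kind)) {
    probs <- c(probs, paste0("unknown value_kind(s): ",
                             paste(bad_kind, collapse = ", ")))
  }
  for (i in seq_len(nrow(fields))) {
    f <- fields[i, ]
    opts <- split_pipe(f$options)
    row_err <- function(msg) paste0("row ", i, " (", f$field_id, "): ", msg)
    if (identical(f$value_kind, "categorical") && length(opts) < 2) {
      probs <- c(probs, row_err("categorical field needs >= 2 allowed options"))
    }
    if (identical(f$value_kind, "free_text") && length(opts) > 0) {
      probs <- c(probs, row_err("free_text field must have no allowed options"))
    }
    if (identical(f$value_kind, "numeric_template")) {
      n_dash <- lengths(regmatches(f$numeric_template,
                                   gregexpr("—", f$numeric_template)))
      if (n_dash != 1L) {
        probs <- c(probs, row_err("numeric_template needs exactly one placeholder dash"))
      }
    }
    if (anyDuplicated(opts)) {
      probs <- c(probs, row_err("allowed options repeat within the field"))
    }
  }
  if (length(probs)) {
    abort(c("schema validation failed", stats::setNames(probs, rep("x", length(probs)))))
  }
  invisible(TRUE)
}

#' Write a schema back to CSV
#'
#' Inverse of [load_schema()]: writes the field table in the documented CSV
#' dialect so that re-loading reproduces the schema field-for-field.
#'
#' @param schema an `ontology_schema`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "ontology_schema"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(schema$fields, con, row.names = FALSE)
  invisible(path)
}

#' Look up one field's specification
#'
#' @param schema an `ontology_schema`.
#' @param field_id field identifier token.
#' @return A `field_spec`: list with `field_id`, `label`, `section`,
#'   `subsection`, `value_kind`, `allowed_options` (character vector, empty
#'   for free-text fields), `numeric_template` (`NA` unless the field is a
#'   numeric template), `synonyms` (data frame surface -> canonical),
#'   `report_types`.
#' @export
get_field <- function(schema, field_id) {
  stopifnot(inherits(schema, "ontology_schema"))
  i <- match(field_id, schema$fields$field_id)
  if (is.na(i)) abort(paste0("unknown field_id: ", field_id))
  f <- schema$fields[i, ]
  types <- split_pipe(f$report_types)
  if (identical(types, "all")) types <- REPORT_TYPES
  structure(list(field_id = f$field_id,
                 label = f$label,
                 section = f$section,
                 subsection = f$subsection,
                 value_kind = f$value_kind,
                 allowed_options = split_pipe(f$options),
                 numeric_template = if (nzchar(f$numeric_template))
                   f$numeric_template else NA_character_,
                 synonyms = parse_synonyms(f$synonyms),
                 report_types = types),
            class = "field_spec")
}

#' Allowed options for a field
#'
#' Returns the field's canonical option list verbatim and order-stable; the
#' empty character vector for free-text fields.
#'
#' @inheritParams get_field
#' @return character vector of canonical value strings.
#' @examples
#' sch <- load_schema(default_schema_path())
#' get_options(sch, "procedure")
#' @export
get_options <- function(schema, field_id) {
  get_field(schema, field_id)$allowed_options
}

#' Cardinality of the three hierarchy levels
#'
#' @param schema an `ontology_schema`.
#' @return named integer vector `c(n_sections, n_subsections, n_fields)`;
#'   the bundled default gives `c(8, 86, 229)`.
#' @export
schema_counts <- function(schema) {
  stopifnot(inherits(schema, "ontology_schema"))
  c(n_sections = length(schema$sections),
    n_subsections = length(unlist(schema$subsections, use.names = FALSE)),
    n_fields = nrow(schema$fields))
}

#' Fields applicable to a report type
#'
#' @param schema an `ontology_schema`.
#' @param report_type one of `"dcis"`, `"invasive_biopsy"`,
#'   `"invasive_resection"`, `"phyllodes_biopsy"`, `"phyllodes_resection"`,
#'   or `"all"` for every field.
#' @return character vector of field ids in schema order.
#' @export
fields_for_report_type <- function(schema, report_type = "all") {
  stopifnot(inherits(schema, "ontology_schema"))
  if (identical(report_type, "all")) return(schema$fields$field_id)
  if (!report_type %in% REPORT_TYPES) {
    abort(paste0("unknown report type: ", report_type))
  }
  keep <- vapply(schema$fields$report_types, function(t) {
    identical(t, "all") || report_type %in% split_pipe(t)
  }, logical(1), USE.NAMES = FALSE)
  schema$fields$field_id[keep]
}

#' @export
print.ontology_schema <- function(x, ...) {
  n <- schema_counts(x)
  cat("<ontology_schema> version", substr(x$version, 1, 8), "\n")
  cat("  ", n[1], "sections /", n[2], "subsections /", n[3], "fields\n")
  invisible(x)
}

#' @export
print.field_spec <- function(x, ...) {
  cat("<field_spec>", x$field_id, "(", x$value_kind, ")\n")
  cat("  label:", x$label, "\n")
  cat("  hierarchy:", x$section, ">", x$subsection, "\n")
  if (length(x$allowed_options)) {
    cat("  options:", paste(x$allowed_options, collapse = " | "), "\n")
  }
  invisible(x)
}
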