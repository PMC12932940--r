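# Shared fixtures, built in code.

# The bundled production schema, loaded once per test session.
SCH <- load_schema(default_schema_path())

# A hand-sized toy schema: 2 sections, 3 subsections, 4 fields.
toy_schema_csv <- function(path = tempfile(fileext = ".csv"),
                           rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      section = c("specimen", "specimen", "tumor", "tumor"),
      subsection = c("Procedure", "Procedure", "Grade", "Notes"),
      field_id = c("proc", "proc_other", "grade", "notes"),
      label = c("Procedure", "Procedure Other", "Grade", "Notes"),
      value_kind = c("categorical", "free_text", "categorical", "free_text"),
      options = c("Biopsy|Excision|Mastectomy", "", "Low|Intermediate|High", ""),
      numeric_template = c("", "", "", ""),
      synonyms = c("lumpectomy=>Excision", "", "", ""),
      report_types = "all",
      stringsAsFactors = FALSE)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

toy_schema <- function(...) load_schema(toy_schema_csv(...))

# independent normalizer for oracle-style scans in tests (kept separate from
# the package's normalize_value on purpose)
scan_norm <- function(x) {
  x <- gsub("[—–-]", " ", tolower(x))
  gsub("\\s+", " ", trimws(x))
}

# independent brute-force scan: does any allowed value (or synonym surface)
# of the field occur in the text?
scan_option_in_text <- function(schema, field_id, text) {
  spec <- get_field(schema, field_id)
  surfaces <- c(spec$allowed_options, spec$synonyms$surface)
  any(vapply(surfaces, function(s) {
    grepl(scan_norm(s), scan_norm(text), fixed = TRUE)
  }, logical(1)))
}
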