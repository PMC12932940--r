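# Prompt construction: templates are versioned text assets shipped under
# inst/templates and addressed by template_id, so the exact instruction text
# is data, not code, and a rendered prompt is reproducible byte-for-byte.

PROMPT_CEILING <- 20000L  # characters; rendering errors above this

template_path <- function(template_id) {
  p <- system.file("templates", paste0(template_id, ".txt"),
                   package = "synoptex")
  if (!nzchar(p)) abort(paste0("unknown prompt template: ", template_id))
  p
}

#' Load a versioned prompt template
#'
#' @param template_id template token, e.g. `"default-v1"` (option-matching
#'   fields) or `"freetext-v1"` (free-text fields).
#' @return single string, the raw template with `{{placeholder}}` slots.
#' @export
load_template <- function(template_id) {
  paste(readLines(template_path(template_id), warn = FALSE, encoding = "UTF-8"),
        collapse = "\n")
}

default_template_for <- function(spec) {
  if (identical(spec$value_kind, "free_text")) "freetext-v1" else "default-v1"
}

#' Build the instruction prompt for one segment and one field
#'
#' Renders the template with the segment text (embedded verbatim, exactly
#' once), the field's canonical options enumerated exactly once each, and the
#' machine-readable output contract (a single JSON object with keys `field`,
#' `value`, and optional integer `extra`). Rendering is a pure function of
#' its inputs: no timestamps, no randomness.
#'
#' @param segment one segment: a list or 1-row data frame with at least
#'   `field_id` and `text`.
#' @param spec the matching [get_field()] `field_spec`.
#' @param template_id template token; chosen from the field's value kind when
#'   `NULL`.
#' @return A `prompt_bundle`: list with `field_id`, `rendered_text`,
#'   `options_offered`, `output_contract` (list of contract keys), and
#'   `template_id`.
#' @export
build_prompt <- function(segment, spec, template_id = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  seg_field <- if (is.data.frame(segment)) segment$field_id[1] else segment$field_id
  seg_text <- if (is.data.frame(segment)) segment$text[1] else segment$text
  if (!identical(seg_field, spec$field_id)) {
    abort(paste0("segment field '", seg_field, "' does not match spec field '",
                 spec$field_id, "'"))
  }
  if (is.null(template_id)) template_id <- default_template_for(spec)
  needs_options <- !identical(template_id, "freetext-v1")
  if (identical(spec$value_kind, "free_text") && needs_options) {
    abort(paste0("template '", template_id,
                 "' requires options but field '", spec$field_id,
                 "' is free_text"))
  }
  template <- load_template(template_id)
  options_block <- paste0("- ", spec$allowed_options, collapse = "\n")
  rendered <- glue::glue(template,
                         field_id = spec$field_id,
                         field_label = spec$label,
                         segment_text = seg_text,
                         options_block = options_block,
                         .open = "{{", .close = "}}", .trim = FALSE)
  rendered <- as.character(rendered)
  if (nchar(rendered) > PROMPT_CEILING) {
    abort(paste0("rendered prompt exceeds the ", PROMPT_CEILING,
                 "-character ceiling (", nchar(rendered), ")"))
  }
  structure(list(field_id = spec$field_id,
                 rendered_text = rendered,
                 options_offered = spec$allowed_options,
                 output_contract = list(field = "string", value = "string|null",
                                        extra = "integer (optional)"),
                 template_id = template_id,
                 segment_text = seg_text),
            class = "prompt_bundle")
}

#' @export
print.prompt_bundle <- function(x, ...) {
  cat("<prompt_bundle>", x$field_id, "via", x$template_id,
      sprintf("(%d chars, %d options)\n", nchar(x$rendered_text),
              length(x$options_offered)))
  invisible(x)
}
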