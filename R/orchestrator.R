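# Workflow orchestration: schema load and segmentation are independent
# initialization stages; each attempted field then flows through prompt
# construction, backend completion, and response parsing. Stages share no
# hidden state, so composing the stage calls by hand reproduces a full run
# exactly, and a seeded run is byte-reproducible at the JSONL level.

#' Execute one pipeline stage in isolation
#'
#' Dispatches a named stage with the same semantics it has inside
#' [run_report()], which makes stage-level testing and ad-hoc composition
#' possible. Registered tasks: `"segment"`, `"build_prompt"`, `"complete"`,
#' `"parse"`.
#'
#' @param task_name stage token.
#' @param payload named list of stage arguments: `segment` takes
#'   `report_text`, `schema`, optional `patterns`; `build_prompt` takes
#'   `segment`, `spec`, optional `template_id`; `complete` takes `backend`,
#'   `bundle`; `parse` takes `raw`, `spec`.
#' @return the stage result.
#' @export
call_agent <- function(task_name, payload = list()) {
  switch(task_name,
    segment = segment_report(payload$report_text, payload$schema,
                             payload$patterns),
    build_prompt = build_prompt(payload$segment, payload$spec,
                                payload$template_id),
    complete = payload$backend$complete(payload$bundle),
    parse = parse_response(payload$raw, payload$spec),
    abort(paste0("unknown task '", task_name,
                 "'; registered: segment, build_prompt, complete, parse")))
}

# one field against one segment, with per-field isolation: a backend or
# parse failure becomes an invalid record, never an exception
attempt_field <- function(spec, segment, backend) {
  raw <- tryCatch({
    bundle <- build_prompt(segment, spec)
    backend$complete(bundle)
  }, error = function(e) structure(conditionMessage(e), failed = TRUE))
  if (!is.null(attr(raw, "failed"))) {
    rec <- new_record(field_id = spec$field_id, value = ABSTAIN,
                      status = "invalid",
                      raw_response = paste0("backend error: ", as.character(raw)))
  } else {
    rec <- parse_response(raw, spec)
  }
  rec
}

#' Run the full extraction workflow over one report
#'
#' Segments the report, then emits exactly one extraction record per
#' attempted field, in schema field order. A field is attempted against
#' every segment carrying its own pattern; when several segments exist, the
#' first non-abstaining result (document order) wins. Fields with no segment
#' yield an abstaining record flagged `no_segment`. A backend failure on one
#' field yields an `invalid` record for that field and the run continues.
#'
#' @param report list or one-row data frame with `report_id` and `text`;
#'   a bare string is accepted (report id `"report_1"`).
#' @param schema an `ontology_schema`.
#' @param backend handle from [select_backend()].
#' @param report_type restrict attempted fields to one report type
#'   (`"all"` attempts every schema field).
#' @param fields optional explicit character vector of field ids to attempt,
#'   overriding `report_type`.
#' @param patterns optional pattern table (see [derive_patterns()]).
#' @return extraction-record data frame, one row per attempted field.
#' @export
run_report <- function(report, schema, backend, report_type = "all",
                       fields = NULL, patterns = NULL) {
  stopifnot(inherits(schema, "ontology_schema"))
  if (is.character(report)) report <- list(report_id = "report_1", text = report)
  report_id <- if (is.data.frame(report)) report$report_id[1] else report$report_id
  text <- if (is.data.frame(report)) report$text[1] else report$text
  segs <- call_agent("segment", list(report_text = text, schema = schema,
                                     patterns = patterns))
  if (is.null(fields)) fields <- fields_for_report_type(schema, report_type)
  out <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    spec <- get_field(schema, fields[k])
    mine <- segs[segs$field_id == spec$field_id, , drop = FALSE]
    if (!nrow(mine)) {
      rec <- new_record(field_id = spec$field_id, value = ABSTAIN,
                        status = "ok", no_segment = TRUE)
    } else {
      rec <- NULL
      for (j in seq_len(nrow(mine))) {
        cand <- attempt_field(spec, mine[j, ], backend)
        if (is.null(rec)) rec <- cand
        if (!identical(cand$value, ABSTAIN) &&
            identical(cand$status, "ok")) { rec <- cand; break }
      }
    }
    rec$report_id <- report_id
    rec$backend_id <- backend$backend_id
    out[[k]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the extraction pipeline over a synthetic validation suite
#'
#' Each synthetic case is a single already-isolated snippet for one field,
#' so the case text is taken as the field's segment directly (whole-report
#' segmentation is [run_report()]'s job). One record per case, in case
#' order.
#'
#' @param cases synthetic-case data frame from [generate_suite()] (only
#'   `case_id`, `field_id`, `input_text` are consulted — ground truth never
#'   leaks into extraction).
#' @param schema an `ontology_schema`.
#' @param backend handle from [select_backend()].
#' @return extraction-record data frame, one row per case (`report_id` is
#'   the case id).
#' @export
run_suite <- function(cases, schema, backend) {
  stopifnot(inherits(schema, "ontology_schema"),
            all(c("case_id", "field_id", "input_text") %in% names(cases)))
  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    spec <- get_field(schema, cases$field_id[i])
    segment <- list(field_id = spec$field_id, text = cases$input_text[i])
    rec <- attempt_field(spec, segment, backend)
    rec$report_id <- cases$case_id[i]
    rec$backend_id <- backend$backend_id
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the manifest describing a finished run
#'
#' The manifest pins everything needed to re-run the configuration: schema
#' content hash, backend, template, seed, and per-report record counts.
#' Timing never enters the manifest, so two identical runs compare equal.
#'
#' @param records extraction-record data frame.
#' @param schema an `ontology_schema`.
#' @param backend backend handle.
#' @param seed integer seed used for the run.
#' @param run_id token naming the run.
#' @param template_id prompt template token.
#' @return `run_manifest` list.
#' @export
run_manifest <- function(records, schema, backend, seed,
                         run_id = "run_1", template_id = "default-v1") {
  counts <- table(records$report_id)
  structure(list(run_id = run_id,
                 schema_version = schema$version,
                 backend_id = backend$backend_id,
                 template_id = template_id,
                 seed = as.integer(seed),
                 n_records = nrow(records),
                 records_per_report = as.list(stats::setNames(
                   as.integer(counts), names(counts)))),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$run_id, "backend:", x$backend_id,
      "seed:", x$seed, "records:", x$n_records, "\n")
  invisible(x)
}
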