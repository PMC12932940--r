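# Pluggable extraction backends. A backend handle maps a prompt bundle to a
# raw response string; parsing and schema validation happen in
# parse_response() so every provider is held to the same output contract.
# The built-in "oracle" is a deterministic rule-based matcher that stands in
# for a live model during testing; "oracle-noisy" corrupts its output at
# seeded rates so imperfect models can be emulated with known expected
# metrics. Live-provider adapters are optional and never required for
# installation or testing.

.backend_registry <- new.env(parent = emptyenv())

#' Register an extraction backend factory
#'
#' @param name backend token.
#' @param factory `function(config)` returning a backend handle: a list with
#'   `backend_id` and `complete(bundle)` returning a raw response string.
#' @return `name`, invisibly.
#' @export
register_backend <- function(name, factory) {
  stopifnot(is.character(name), length(name) == 1L, is.function(factory))
  assign(name, factory, envir = .backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @export
list_backends <- function() sort(ls(.backend_registry))

#' Obtain a backend handle by name
#'
#' @param name registered backend token (see [list_backends()]); built-ins
#'   are `"oracle"` and `"oracle-noisy"`.
#' @param config named list of backend parameters. `"oracle-noisy"` takes
#'   `rates` (length-3 numeric: swap, drop, spurious) and `seed`.
#' @return backend handle (class `extraction_backend`).
#' @export
select_backend <- function(name, config = list()) {
  if (!exists(name, envir = .backend_registry, inherits = FALSE)) {
    abort(paste0("unknown backend '", name, "'; available: ",
                 paste(list_backends(), collapse = ", ")))
  }
  factory <- get(name, envir = .backend_registry, inherits = FALSE)
  handle <- factory(config)
  class(handle) <- "extraction_backend"
  handle
}

#' @export
print.extraction_backend <- function(x, ...) {
  cat("<extraction_backend>", x$backend_id, "\n")
  invisible(x)
}

# ---- oracle matcher ---------------------------------------------------------

# Candidate surfaces for a bundle: canonical options first (schema order),
# then registered synonyms mapping back to their canonical option.
candidate_table <- function(options, synonyms = NULL) {
  tab <- data.frame(surface = options, canonical = options,
                    stringsAsFactors = FALSE)
  if (!is.null(synonyms) && nrow(synonyms)) {
    syn <- synonyms[synonyms$canonical %in% options, , drop = FALSE]
    tab <- rbind(tab, syn)
  }
  tab
}

#' Deterministic rule-based completion (the oracle backend)
#'
#' Selects the longest allowed option (or registered synonym, mapped back to
#' its canonical option) whose normalized matching form occurs in the
#' normalized segment text; equal-length candidates resolve to the first in
#' schema order. Numeric-template options match with the placeholder dash
#' removed, mirroring how reports print them (`"Exact distance: mm"`). A
#' trailing `"Found number N"` phrase is captured as the integer `extra`.
#' When no candidate matches, the oracle abstains — abstention is a value,
#' not an error.
#'
#' @param prompt a `prompt_bundle` from [build_prompt()].
#' @param segment_text segment text to match against; defaults to the text
#'   embedded in the bundle.
#' @param synonyms optional synonym table (`surface`, `canonical`).
#' @return raw JSON response string honouring the output contract.
#' @export
oracle_complete <- function(prompt, segment_text = NULL, synonyms = NULL) {
  stopifnot(inherits(prompt, "prompt_bundle"))
  if (is.null(segment_text)) segment_text <- prompt$segment_text
  hay <- match_form(segment_text)
  cand <- candidate_table(prompt$options_offered, synonyms)
  value <- NULL
  if (nrow(cand)) {
    forms <- vapply(cand$surface, match_form, character(1), USE.NAMES = FALSE)
    hit <- vapply(forms, function(f) nzchar(f) &&
                    grepl(f, hay, fixed = TRUE), logical(1))
    if (any(hit)) {
      lens <- nchar(forms)
      lens[!hit] <- -1L
      value <- cand$canonical[which.max(lens)]  # ties: first in schema order
    }
  }
  extra <- NULL
  m <- regmatches(hay, regexpr("found number ([0-9]+)", hay))
  if (length(m)) extra <- as.integer(sub("found number ", "", m, fixed = TRUE))
  out <- list(field = prompt$field_id,
              value = if (is.null(value)) NA else value)
  if (!is.null(extra) && !is.null(value)) out$extra <- extra
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, na = "null"))
}

# ---- response parsing -------------------------------------------------------

new_record <- function(report_id = NA_character_, field_id, value, extra = NA_integer_,
                       status = "ok", no_segment = FALSE,
                       backend_id = NA_character_, raw_response = "") {
  data.frame(report_id = report_id, field_id = field_id, value = value,
             extra = as.integer(extra), status = status,
             no_segment = no_segment, backend_id = backend_id,
             raw_response = raw_response, stringsAsFactors = FALSE)
}

try_json <- function(txt) {
  tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
           error = function(e) NULL)
}

# One bounded repair pass: strip code fences and surrounding prose, then
# take the first brace-delimited object.
repair_json <- function(raw) {
  txt <- gsub("```[a-zA-Z]*", "", raw)
  m <- regmatches(txt, regexpr("\\{[^{}]*\\}", txt))
  if (!length(m)) return(NULL)
  try_json(m[[1]])
}

#' Parse and schema-validate a raw backend response
#'
#' Attempts a strict JSON parse first; on failure, exactly one repair pass
#' (fences and prose stripped, first JSON object extracted) marks the record
#' `repaired`. Categorical and numeric-template values are normalized and
#' validated against the field's allowed options (synonym surfaces map back
#' to their canonical option); a response that cannot be validated yields
#' `status = "invalid"` with the raw text retained — parsing never throws,
#' and the evaluator scores invalid records as non-extractions.
#'
#' @param raw raw response string (arbitrary content is tolerated).
#' @param spec the field's `field_spec`.
#' @return one-row extraction-record data frame with columns `report_id`,
#'   `field_id`, `value`, `extra`, `status`, `no_segment`, `backend_id`,
#'   `raw_response`.
#' @export
parse_response <- function(raw, spec) {
  stopifnot(inherits(spec, "field_spec"))
  raw <- if (is.null(raw) || length(raw) != 1L || is.na(raw)) "" else as.character(raw)
  obj <- try_json(raw)
  status <- "ok"
  if (is.null(obj) || !is.list(obj)) {
    obj <- repair_json(raw)
    status <- "repaired"
  }
  if (is.null(obj) || !is.list(obj)) {
    return(new_record(field_id = spec$field_id, value = ABSTAIN,
                      status = "invalid", raw_response = raw))
  }
  value <- obj$value
  extra <- NA_integer_
  if (!is.null(obj$extra) && !is.na(suppressWarnings(as.integer(obj$extra)[1]))) {
    extra <- as.integer(obj$extra)[1]
  }
  if (is.null(value) || length(value) != 1L || is.na(value) ||
      identical(toupper(as.character(value)), ABSTAIN) ||
      !nzchar(trimws(as.character(value)))) {
    return(new_record(field_id = spec$field_id, value = ABSTAIN,
                      status = status, raw_response = raw))
  }
  value <- as.character(value)
  if (spec$value_kind %in% c("categorical", "numeric_template")) {
    cand <- candidate_table(spec$allowed_options, spec$synonyms)
    forms <- vapply(cand$surface, match_form, character(1), USE.NAMES = FALSE)
    i <- match(match_form(value), forms)
    if (is.na(i)) {
      return(new_record(field_id = spec$field_id, value = ABSTAIN,
                        status = "invalid", raw_response = raw))
    }
    value <- cand$canonical[i]
    if (!identical(spec$value_kind, "numeric_template") &&
        !prompt_requests_extra(spec)) {
      extra <- NA_integer_
    }
  }
  new_record(field_id = spec$field_id, value = value, extra = extra,
             status = status, raw_response = raw)
}

# the default option template carries an optional integer extra channel
prompt_requests_extra <- function(spec) !identical(spec$value_kind, "free_text")

#' Serialize an extraction record to the response contract
#'
#' Inverse of [parse_response()] on well-formed records: parsing the
#' serialized form reproduces the record's value and extra.
#'
#' @param record one-row record data frame.
#' @return raw JSON string.
#' @export
serialize_record <- function(record) {
  out <- list(field = record$field_id[1],
              value = if (identical(record$value[1], ABSTAIN)) NA
                      else record$value[1])
  if (!is.na(record$extra[1])) out$extra <- record$extra[1]
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, na = "null"))
}

# ---- error injection --------------------------------------------------------

#' Inject seeded extraction errors into records
#'
#' Emulates an imperfect model with known expected metrics. Row-wise, with
#' one seeded RNG stream over the whole record set: a non-abstaining record
#' is replaced by a uniformly drawn wrong option with probability
#' `rates[1]` (swap) or forced to abstain with probability `rates[2]`
#' (drop); an abstaining record emits a uniformly drawn option with
#' probability `rates[3]` (spurious). A swap on a field with no alternative
#' option (numeric templates have a single canonical value) degrades to a
#' drop. Reproducible: same records, rates, and seed give identical output.
#'
#' @param records extraction-record data frame (a single record is a one-row
#'   data frame).
#' @param rates numeric length 3: `c(swap, drop, spurious)`, each in
#'   \[0, 1\], with `swap + drop <= 1`.
#' @param seed integer RNG seed.
#' @param schema the `ontology_schema` supplying each field's options.
#' @return the records with corrupted values; other columns unchanged.
#' @export
inject_errors <- function(records, rates, seed, schema) {
  if (length(rates) != 3L || any(is.na(rates)) || any(rates < 0) ||
      any(rates > 1) || rates[1] + rates[2] > 1) {
    abort("rates must be c(swap, drop, spurious) in [0,1] with swap + drop <= 1")
  }
  stopifnot(inherits(schema, "ontology_schema"))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(records))) {
      opts <- get_options(schema, records$field_id[i])
      u <- runif(1)
      if (!identical(records$value[i], ABSTAIN)) {
        if (u < rates[1]) {
          wrong <- setdiff(opts, records$value[i])
          if (length(wrong)) {
            records$value[i] <- wrong[sample.int(length(wrong), 1L)]
          } else {
            records$value[i] <- ABSTAIN
            records$extra[i] <- NA_integer_
          }
        } else if (u < rates[1] + rates[2]) {
          records$value[i] <- ABSTAIN
          records$extra[i] <- NA_integer_
        }
      } else if (u < rates[3] && length(opts)) {
        records$value[i] <- opts[sample.int(length(opts), 1L)]
      }
    }
  })
  records
}

# ---- built-in backends ------------------------------------------------------

oracle_factory <- function(config) {
  synonyms <- config$synonyms
  list(backend_id = "oracle",
       complete = function(bundle) oracle_complete(bundle, synonyms = synonyms))
}

oracle_noisy_factory <- function(config) {
  rates <- config$rates %||% c(0, 0, 0)
  seed <- config$seed %||% 1L
  if (length(rates) != 3L || any(rates < 0) || any(rates > 1) ||
      rates[1] + rates[2] > 1) {
    abort("oracle-noisy rates must be c(swap, drop, spurious) in [0,1] with swap + drop <= 1")
  }
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  synonyms <- config$synonyms
  list(backend_id = "oracle-noisy",
       complete = function(bundle) {
         counter$n <- counter$n + 1L
         raw <- oracle_complete(bundle, synonyms = synonyms)
         obj <- jsonlite::fromJSON(raw, simplifyVector = TRUE)
         opts <- bundle$options_offered
         withr::with_seed(seed + counter$n, {
           u <- runif(1)
           if (!is.null(obj$value) && !is.na(obj$value)) {
             if (u < rates[1]) {
               wrong <- setdiff(opts, obj$value)
               obj$value <- if (length(wrong))
                 wrong[sample.int(length(wrong), 1L)] else NA
               if (is.na(obj$value)) obj$extra <- NULL
             } else if (u < rates[1] + rates[2]) {
               obj$value <- NA
               obj$extra <- NULL
             }
           } else if (u < rates[3] && length(opts)) {
             obj$value <- opts[sample.int(length(opts), 1L)]
           }
         })
         as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null"))
       })
}

# Optional live-provider adapter stubs. They satisfy the registry contract
# but refuse to run unless the caller supplies a `transport` function, so no
# network access is ever required.
live_stub_factory <- function(provider) {
  function(config) {
    transport <- config$transport
    list(backend_id = provider,
         complete = function(bundle) {
           if (is.null(transport)) {
             abort(paste0("backend '", provider, "' is an optional live ",
                          "adapter; supply config$transport(prompt_text) ",
                          "to use it"))
           }
           as.character(transport(bundle$rendered_text))
         })
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.onLoad <- function(libname, pkgname) {
  register_backend("oracle", oracle_factory)
  register_backend("oracle-noisy", oracle_noisy_factory)
  register_backend("ollama", live_stub_factory("ollama"))
  register_backend("gemini", live_stub_factory("gemini"))
}
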