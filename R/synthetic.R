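# Synthetic validation corpus: controlled test cases with known ground
# truth, standing in for real reports (which carry PHI and cannot ship).
# Positive cases embed one correct ontology value in the snippet; negative
# cases contain no allowed value for their field. Default composition is
# 445 positive + 419 negative = 864 cases. A configurable fraction of
# positives is rendered adversarially (vague or ambiguous wording), flagged
# as such, and excluded from the oracle-identity property.

NOISE_TOKEN <- "nan"
DISTRACTOR  <- "Some other free text."

strip_placeholder <- function(template) {
  gsub("\\s+", " ", trimws(gsub("—", "", template)))
}

render_positive <- function(spec, style_id, rng_draw) {
  if (identical(spec$value_kind, "numeric_template")) {
    n <- rng_draw$int
    template <- spec$numeric_template
    if (identical(style_id, "adversarial_ambiguous")) {
      return(list(text = paste0(spec$label, ": At least:. ", NOISE_TOKEN,
                                ". Found number ", n),
                  truth_value = template, truth_extra = n,
                  style_id = style_id, adversarial = TRUE))
    }
    return(list(text = paste0(spec$label, ": ", strip_placeholder(template),
                              ". Found number ", n),
                truth_value = template, truth_extra = n,
                style_id = "numeric", adversarial = FALSE))
  }
  option <- spec$allowed_options[rng_draw$opt]
  if (identical(style_id, "adversarial_vague")) {
    return(list(text = paste0(spec$label, ": Tumor is malignant. ", NOISE_TOKEN),
                truth_value = option, truth_extra = NA_integer_,
                style_id = style_id, adversarial = TRUE))
  }
  text <- switch(style_id,
    plain = paste0(spec$label, ": ", option),
    noise = paste0(spec$label, ": ", option, ". ", NOISE_TOKEN),
    distractor = paste0(spec$label, ": ", option, ". ", DISTRACTOR),
    abort(paste0("unknown synthetic style: ", style_id)))
  list(text = text, truth_value = option, truth_extra = NA_integer_,
       style_id = style_id, adversarial = FALSE)
}

# precomputed normalized matching forms of a field's options + synonym
# surfaces, with the canonical option each maps to
candidate_forms <- function(spec) {
  cand <- candidate_table(spec$allowed_options, spec$synonyms)
  forms <- vapply(cand$surface, match_form, character(1), USE.NAMES = FALSE)
  keep <- nzchar(forms)
  list(forms = forms[keep], canonical = cand$canonical[keep])
}

forms_in_text <- function(forms, text) {
  hay <- match_form(text)
  vapply(forms$forms, grepl, logical(1), x = hay, fixed = TRUE,
         USE.NAMES = FALSE)
}

# the oracle's selection rule: longest matching form, ties to schema order
forms_select <- function(forms, text) {
  hit <- forms_in_text(forms, text)
  if (!any(hit)) return(NA_character_)
  lens <- nchar(forms$forms)
  lens[!hit] <- -1L
  forms$canonical[which.max(lens)]
}

# A negative snippet is headed by a *foreign* field's label (as in real
# reports, where the block scanned for a field often carries another item's
# heading) and must contain none of this field's allowed values.
render_negative <- function(spec, style_id, label_pool, distractor_pool,
                            forms = candidate_forms(spec)) {
  if (!length(label_pool)) label_pool <- "Unrelated Item"
  if (identical(style_id, "negative_distractor")) {
    for (lab in label_pool) {
      for (cand in distractor_pool) {
        text <- paste0(lab, ": ", cand, ". ", DISTRACTOR)
        if (!any(forms_in_text(forms, text))) {
          return(list(text = text, style_id = style_id))
        }
      }
    }
    style_id <- "negative_nan"
  }
  for (lab in label_pool) {
    text <- paste0(lab, ": Comment(s):. ", NOISE_TOKEN, ". ", DISTRACTOR)
    if (!any(forms_in_text(forms, text))) {
      return(list(text = text, style_id = style_id))
    }
  }
  abort(paste0("could not render a certified negative for '",
               spec$field_id, "'"))
}

#' Does any allowed value (or synonym) of a field occur in a text?
#'
#' Brute-force containment scan over the field's canonical options and
#' registered synonym surfaces, on normalized matching forms. This is the
#' test used to certify negative cases at generation time.
#'
#' @param spec a `field_spec`.
#' @param text snippet to scan.
#' @return logical.
#' @export
field_value_present <- function(spec, text) {
  forms <- candidate_forms(spec)
  if (!length(forms$forms)) return(FALSE)
  any(forms_in_text(forms, text))
}

# run the oracle's selection rule directly to certify that a non-adversarial
# positive is recoverable from its snippet
oracle_recovers <- function(spec, text, truth_value,
                            forms = candidate_forms(spec)) {
  identical(forms_select(forms, text), truth_value)
}

#' Render a single synthetic case
#'
#' Styles: `"plain"` (`Label: value`), `"noise"` (trailing `nan` token),
#' `"distractor"` (trailing generic free text), `"numeric"`
#' (numeric-template value with a trailing `Found number N` and integer
#' ground-truth extra), `"negative_nan"` / `"negative_distractor"`
#' (no allowed value present), and flagged adversarial styles
#' `"adversarial_vague"` / `"adversarial_ambiguous"` (edge cases with
#' deliberately ambiguous wording).
#'
#' @param spec a `field_spec` (categorical or numeric-template).
#' @param polarity `"positive"` or `"negative"`.
#' @param style_id style token as above.
#' @param rng_draw list with `opt` (option index) and `int` (numeric extra)
#'   pre-drawn by the caller; defaults pick the first option and 4.
#' @param label_pool character vector of foreign field labels heading
#'   negative snippets (negatives mimic blocks whose heading belongs to a
#'   different report item).
#' @param distractor_pool character vector of foreign option values for
#'   `"negative_distractor"`.
#' @return list with `input_text`, `truth_value`, `truth_extra`, `style_id`,
#'   `adversarial`.
#' @export
render_case <- function(spec, polarity, style_id,
                        rng_draw = list(opt = 1L, int = 4L),
                        label_pool = "Unrelated Item",
                        distractor_pool = character(0)) {
  stopifnot(inherits(spec, "field_spec"))
  if (identical(polarity, "positive")) {
    r <- render_positive(spec, style_id, rng_draw)
    list(input_text = r$text, truth_value = r$truth_value,
         truth_extra = r$truth_extra, style_id = r$style_id,
         adversarial = r$adversarial)
  } else {
    r <- render_negative(spec, style_id, label_pool, distractor_pool)
    list(input_text = r$text, truth_value = NA_character_,
         truth_extra = NA_integer_, style_id = r$style_id,
         adversarial = FALSE)
  }
}

#' Generate the synthetic validation suite
#'
#' Produces exactly the requested number of positive and negative cases
#' (default composition 445 + 419 = 864), spread round-robin over the
#' schema's categorical and numeric-template fields after a seeded shuffle.
#' Fully reproducible: the same schema, composition, and seed give a
#' byte-identical corpus. Every emitted case is certified at generation
#' time: non-adversarial positives are recoverable by the oracle's matching
#' rule, and negatives contain no allowed value of their field.
#'
#' @param schema an `ontology_schema`.
#' @param n_positive,n_negative case counts per polarity.
#' @param adversarial_frac fraction of positive cases rendered with flagged
#'   adversarial styles (vague or ambiguous wording).
#' @param seed integer seed.
#' @return data frame with columns `case_id`, `field_id`, `input_text`,
#'   `polarity`, `truth_value`, `truth_extra`, `style_id`, `adversarial`,
#'   `seed`.
#' @examples
#' sch <- load_schema(default_schema_path())
#' suite <- generate_suite(sch, n_positive = 5, n_negative = 5, seed = 1)
#' @export
generate_suite <- function(schema, n_positive = 445L, n_negative = 419L,
                           adversarial_frac = 0.05, seed = 20260101L) {
  stopifnot(inherits(schema, "ontology_schema"))
  if (n_positive < 0 || n_negative < 0) abort("composition counts must be >= 0")
  eligible <- schema$fields$field_id[
    schema$fields$value_kind %in% c("categorical", "numeric_template")]
  if (!length(eligible) && n_positive + n_negative > 0) {
    abort("schema has no categorical or numeric_template fields to simulate")
  }
  specs <- lapply(stats::setNames(eligible, eligible),
                  function(id) get_field(schema, id))
  all_values <- unlist(lapply(specs, function(s) s$allowed_options),
                       use.names = FALSE)
  # foreign labels usable to head a negative snippet for each field: a label
  # must not itself contain one of the field's allowed values (companion
  # labels such as "..., Other (specify)" can collide with an
  # "Other (specify)" option)
  forms_list <- lapply(specs, candidate_forms)
  all_labels <- schema$fields$label
  label_forms <- vapply(all_labels, match_form, character(1), USE.NAMES = FALSE)
  safe_labels <- lapply(specs, function(sp) {
    forms <- forms_list[[sp$field_id]]$forms
    hit <- Reduce(`|`, lapply(forms, grepl, x = label_forms, fixed = TRUE),
                  accumulate = FALSE)
    all_labels[!hit & all_labels != sp$label]
  })
  cat_styles <- c("plain", "noise", "distractor")
  withr::with_seed(seed, {
    pos_fields <- sample(eligible)
    neg_fields <- sample(eligible)
    n_adv <- floor(adversarial_frac * n_positive)
    adv_idx <- if (n_adv > 0) sample.int(n_positive, n_adv) else integer(0)
    rows <- vector("list", n_positive + n_negative)
    for (i in seq_len(n_positive)) {
      spec <- specs[[pos_fields[(i - 1L) %% length(pos_fields) + 1L]]]
      draw <- list(opt = if (length(spec$allowed_options))
                     sample.int(length(spec$allowed_options), 1L) else 1L,
                   int = sample.int(30L, 1L))
      style <- if (i %in% adv_idx) {
        if (identical(spec$value_kind, "numeric_template"))
          "adversarial_ambiguous" else "adversarial_vague"
      } else if (identical(spec$value_kind, "numeric_template")) {
        "numeric"
      } else {
        cat_styles[(i - 1L) %% 3L + 1L]
      }
      r <- render_case(spec, "positive", style, draw)
      if (!r$adversarial &&
          !oracle_recovers(spec, r$input_text, r$truth_value,
                           forms = forms_list[[spec$field_id]])) {
        abort(paste0("generated positive case for '", spec$field_id,
                     "' is not recoverable by the oracle matcher"))
      }
      rows[[i]] <- data.frame(field_id = spec$field_id,
                              input_text = r$input_text,
                              polarity = "positive",
                              truth_value = r$truth_value,
                              truth_extra = r$truth_extra,
                              style_id = r$style_id,
                              adversarial = r$adversarial,
                              stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_negative)) {
      spec <- specs[[neg_fields[(i - 1L) %% length(neg_fields) + 1L]]]
      style <- if (i %% 2L == 0L) "negative_distractor" else "negative_nan"
      pool <- sample(setdiff(all_values, spec$allowed_options), 8L)
      labs <- sample(safe_labels[[spec$field_id]], 4L)
      r <- render_negative(spec, style, labs, pool,
                           forms = forms_list[[spec$field_id]])
      r <- list(input_text = r$text, truth_value = NA_character_,
                truth_extra = NA_integer_, style_id = r$style_id,
                adversarial = FALSE)
      if (any(forms_in_text(forms_list[[spec$field_id]], r$input_text))) {
        abort(paste0("generated negative case for '", spec$field_id,
                     "' contains an allowed value"))
      }
      rows[[n_positive + i]] <- data.frame(field_id = spec$field_id,
                                           input_text = r$input_text,
                                           polarity = "negative",
                                           truth_value = NA_character_,
                                           truth_extra = NA_integer_,
                                           style_id = r$style_id,
                                           adversarial = FALSE,
                                           stringsAsFactors = FALSE)
    }
    suite <- do.call(rbind, rows)
    suite <- suite[sample.int(nrow(suite)), , drop = FALSE]
  })
  suite <- cbind(case_id = sprintf("case_%04d", seq_len(nrow(suite))), suite,
                 stringsAsFactors = FALSE)
  suite$seed <- as.integer(seed)
  rownames(suite) <- NULL
  suite
}

#' Ground-truth manifest for a synthetic suite
#'
#' Ground truth is kept in a manifest separate from the input texts so an
#' extraction run can never leak labels. Under the `"complete"` regime every
#' case is annotated (negatives encode explicit absence); under
#' `"positive_only"` — the shape of real-world annotation sets — only
#' positive cases are kept and absence is never asserted.
#'
#' @param suite data frame from [generate_suite()].
#' @param regime `"complete"` or `"positive_only"`.
#' @return ground-truth data frame with columns `report_id`, `field_id`,
#'   `truth_value`, `truth_extra`, `adversarial`, `regime`.
#' @export
suite_truth <- function(suite, regime = c("complete", "positive_only")) {
  regime <- match.arg(regime)
  truth <- data.frame(report_id = suite$case_id,
                      field_id = suite$field_id,
                      truth_value = suite$truth_value,
                      truth_extra = suite$truth_extra,
                      adversarial = suite$adversarial,
                      regime = regime, stringsAsFactors = FALSE)
  if (identical(regime, "positive_only")) {
    truth <- truth[!is.na(truth$truth_value), , drop = FALSE]
    rownames(truth) <- NULL
  }
  truth
}
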