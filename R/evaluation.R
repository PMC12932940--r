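# Dual-regime evaluation. Under the "complete" regime every field-sample
# pair has definitive ground truth (explicit absence included), so the full
# metric suite is computable. Under the "positive_only" regime — the shape
# of real-world annotation sets, which assert presence but never absence —
# only recall TP/(TP+FN) is defensible: false positives and true negatives
# are unknowable, and the evaluator refuses to fabricate them.

OUTCOMES <- c("TP", "FP", "TN", "FN", "skip")

# exact match on normalized forms; when ground truth carries a numeric
# extra, the extra must agree too (configurable off via require_extra)
values_match <- function(value, truth_value, extra, truth_extra,
                         require_extra = TRUE) {
  if (!identical(normalize_value(value), normalize_value(truth_value))) {
    return(FALSE)
  }
  if (require_extra && !is.na(truth_extra)) {
    return(!is.na(extra) && extra == truth_extra)
  }
  TRUE
}

#' Classify one prediction against one ground-truth record
#'
#' Complete regime: `TP` when the (normalized) extracted value exactly
#' matches the truth (and the numeric extra agrees when the truth has one);
#' `FN` when truth is present but the prediction abstains, is invalid, or
#' differs; `TN` when truth is absent and the prediction abstains; `FP` when
#' truth is absent and any value is predicted. Positive-only regime: `TP`
#' and `FN` as above; a prediction for an unannotated pair is `skip`, never
#' a false positive.
#'
#' @param prediction one-row extraction-record data frame (or list with
#'   `report_id`, `field_id`, `value`, `extra`, `status`).
#' @param truth one-row ground-truth data frame (or list with `report_id`,
#'   `field_id`, `truth_value`, `truth_extra`, `regime`); `NULL` stands for
#'   an unannotated pair.
#' @param regime evaluation regime; taken from `truth` when present there.
#' @param require_extra must the numeric extra agree when ground truth
#'   carries one?
#' @return one of `"TP"`, `"FP"`, `"TN"`, `"FN"`, `"skip"`.
#' @export
classify <- function(prediction, truth, regime = NULL, require_extra = TRUE) {
  p <- as.list(prediction)
  if (is.null(truth)) {
    t <- list(report_id = p$report_id, field_id = p$field_id,
              truth_value = NA_character_, truth_extra = NA_integer_)
    annotated <- FALSE
  } else {
    t <- as.list(truth)
    annotated <- TRUE
  }
  if (is.null(regime)) regime <- t$regime %||% "complete"
  if (!identical(p$report_id[1], t$report_id[1]) ||
      !identical(p$field_id[1], t$field_id[1])) {
    abort("prediction and ground truth disagree on (report_id, field_id)")
  }
  truth_present <- annotated && !is.na(t$truth_value)
  extracted <- !identical(p$value[1], ABSTAIN) &&
    !identical(p$status[1], "invalid")
  if (identical(regime, "positive_only") && !truth_present) return("skip")
  if (truth_present) {
    if (extracted && values_match(p$value[1], t$truth_value[1],
                                  p$extra[1] %||% NA_integer_,
                                  t$truth_extra[1] %||% NA_integer_,
                                  require_extra)) "TP" else "FN"
  } else {
    if (extracted) "FP" else "TN"
  }
}

#' Classify a whole prediction set against a ground-truth set
#'
#' Joins on `(report_id, field_id)` and applies [classify()] per pair.
#' Predictions with no matching annotation are scored against explicit
#' absence under the complete regime and skipped under positive-only.
#'
#' @param predictions extraction-record data frame.
#' @param truth ground-truth data frame (with a `regime` column or uniform
#'   `regime` argument).
#' @param regime evaluation regime; defaults to the truth set's.
#' @inheritParams classify
#' @return the predictions with an added `outcome` column.
#' @export
classify_records <- function(predictions, truth, regime = NULL,
                             require_extra = TRUE) {
  if (is.null(regime)) regime <- unique(truth$regime)
  if (length(regime) != 1L) abort("mixed regimes in ground truth")
  key_p <- paste(predictions$report_id, predictions$field_id, sep = "\r")
  key_t <- paste(truth$report_id, truth$field_id, sep = "\r")
  idx <- match(key_p, key_t)
  outcome <- character(nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    tr <- if (is.na(idx[i])) NULL else truth[idx[i], , drop = FALSE]
    outcome[i] <- classify(predictions[i, , drop = FALSE], tr,
                           regime = regime, require_extra = require_extra)
  }
  predictions$outcome <- outcome
  predictions
}

#' Tally classification outcomes into a confusion summary
#'
#' `skip` outcomes are excluded from every count. Under the positive-only
#' regime `fp` and `tn` are marked unavailable (`NA`), not zero: they are
#' unknowable, and downstream metrics must refuse rather than divide.
#'
#' @param outcomes character vector of outcomes from [classify()], or a
#'   data frame with an `outcome` column.
#' @param regime `"complete"` or `"positive_only"`.
#' @return `confusion_summary`: list with integer `tp`, `fp`, `tn`, `fn`
#'   and `regime`.
#' @export
summarize_outcomes <- function(outcomes, regime = c("complete", "positive_only")) {
  regime <- match.arg(regime)
  if (is.data.frame(outcomes)) outcomes <- outcomes$outcome
  bad <- setdiff(unique(outcomes), OUTCOMES)
  if (length(bad)) abort(paste0("unknown outcome(s): ", paste(bad, collapse = ", ")))
  if (identical(regime, "positive_only") &&
      any(outcomes %in% c("FP", "TN"))) {
    abort("positive_only outcomes cannot contain FP or TN")
  }
  n <- function(o) sum(outcomes == o)
  structure(list(tp = n("TP"),
                 fp = if (identical(regime, "positive_only")) NA_integer_ else n("FP"),
                 tn = if (identical(regime, "positive_only")) NA_integer_ else n("TN"),
                 fn = n("FN"),
                 regime = regime),
            class = "confusion_summary")
}

#' Construct a confusion summary from raw counts
#'
#' @param tp,fp,tn,fn non-negative integer counts; `fp` and `tn` must be
#'   `NA` under the positive-only regime.
#' @param regime annotation regime.
#' @return `confusion_summary`.
#' @export
confusion_summary <- function(tp, fn, fp = NA_integer_, tn = NA_integer_,
                              regime = c("complete", "positive_only")) {
  regime <- match.arg(regime)
  if (identical(regime, "complete") && (is.na(fp) || is.na(tn))) {
    abort("complete regime requires fp and tn counts")
  }
  counts <- c(tp, fp, tn, fn)
  if (any(!is.na(counts) & counts < 0)) abort("counts must be non-negative")
  structure(list(tp = as.double(tp), fp = as.double(fp), tn = as.double(tn),
                 fn = as.double(fn), regime = regime),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> regime:", x$regime, "\n")
  cat(sprintf("  TP %s  FP %s  TN %s  FN %s\n", x$tp,
              ifelse(is.na(x$fp), "n/a", x$fp),
              ifelse(is.na(x$tn), "n/a", x$tn), x$fn))
  invisible(x)
}

#' Recall (the positive-only regime's sole defensible metric)
#'
#' `TP / (TP + FN)`: the fraction of annotated ground-truth fields correctly
#' extracted. The only metric computable when annotations assert presence
#' but never absence.
#'
#' @param summary a `confusion_summary`.
#' @return list with `proportion` and `percent` (half-up, 1 decimal).
#' @examples
#' recall(confusion_summary(tp = 5831, fn = 820, regime = "positive_only"))
#' @export
recall <- function(summary) {
  stopifnot(inherits(summary, "confusion_summary"))
  denom <- summary$tp + summary$fn
  if (denom <= 0) abort("recall undefined: tp + fn = 0")
  p <- summary$tp / denom
  list(proportion = p, percent = as_percent(p))
}

metric_or_na <- function(num, denom) if (denom > 0) num / denom else NA_real_

#' Full metric suite under complete ground truth
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision
#' `tp/(tp+fp)`, F1 (harmonic mean of precision and sensitivity), Matthews
#' correlation coefficient, and accuracy `(tp+tn)/(tp+tn+fp+fn)`. A metric
#' whose denominator is zero is marked unavailable (`NA`). Positive-only
#' summaries are refused: precision, specificity, F1, and MCC require true
#' negatives, which positive-only annotation cannot supply.
#'
#' @param summary a `confusion_summary` under the complete regime.
#' @return `metric_report`: list of `proportions` (raw values; MCC in
#'   \[-1, 1\]), `percent` (half-up 1-decimal rendering; MCC rendered to 3
#'   decimals, not a percentage), the `counts`, and the `regime`.
#' @export
full_metrics <- function(summary) {
  stopifnot(inherits(summary, "confusion_summary"))
  if (identical(summary$regime, "positive_only")) {
    abort(paste0("positive-only ground truth supports recall only: ",
                 "precision, specificity, F1, and MCC require true negatives"))
  }
  tp <- as.double(summary$tp); fp <- as.double(summary$fp)
  tn <- as.double(summary$tn); fn <- as.double(summary$fn)
  sens <- metric_or_na(tp, tp + fn)
  spec <- metric_or_na(tn, tn + fp)
  prec <- metric_or_na(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  mcc_denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_denom > 0) (tp * tn - fp * fn) / mcc_denom else NA_real_
  acc <- metric_or_na(tp + tn, tp + tn + fp + fn)
  props <- list(sensitivity = sens, specificity = spec, precision = prec,
                f1 = f1, mcc = mcc, accuracy = acc)
  structure(list(proportions = props,
                 percent = list(sensitivity = as_percent(sens),
                                specificity = as_percent(spec),
                                precision = as_percent(prec),
                                f1 = as_percent(f1),
                                mcc = if (is.na(mcc)) NA_real_ else
                                  round_half_up(mcc, 3),
                                accuracy = as_percent(acc)),
                 counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
                 regime = summary$regime),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  p <- x$percent
  cat("<metric_report> (complete ground truth)\n")
  cat(sprintf("  Sens. %.1f%%  Spec. %.1f%%  Prec. %.1f%%  F1 %.1f%%  MCC %.3f  Acc. %.1f%%\n",
              p$sensitivity, p$specificity, p$precision, p$f1, p$mcc,
              p$accuracy))
  invisible(x)
}

#' Reality gap between synthetic and real-world performance
#'
#' The drop, in percentage points, from accuracy measured on controlled
#' synthetic cases (complete ground truth) to recall measured on authentic
#' annotated reports (positive-only ground truth).
#'
#' @param synthetic_accuracy percentage in \[0, 100\].
#' @param real_recall percentage in \[0, 100\].
#' @return gap in percentage points, half-up 1 decimal.
#' @examples
#' reality_gap(99.0, 87.7)
#' @export
reality_gap <- function(synthetic_accuracy, real_recall) {
  if (any(c(synthetic_accuracy, real_recall) < 0) ||
      any(c(synthetic_accuracy, real_recall) > 100)) {
    abort("reality_gap expects percentages in [0, 100]")
  }
  round_half_up(synthetic_accuracy - real_recall, 1)
}

#' Evaluate an extraction run end-to-end
#'
#' Convenience wrapper: classify, tally, and compute the regime-appropriate
#' metrics in one call.
#'
#' @inheritParams classify_records
#' @return list with `records` (classified), `summary`
#'   (`confusion_summary`), and `metrics` (a `metric_report` under the
#'   complete regime, the [recall()] list under positive-only).
#' @export
evaluate_run <- function(predictions, truth, regime = NULL,
                         require_extra = TRUE) {
  classified <- classify_records(predictions, truth, regime, require_extra)
  regime <- regime %||% unique(truth$regime)
  cs <- summarize_outcomes(classified, regime)
  metrics <- if (identical(regime, "complete")) full_metrics(cs) else recall(cs)
  list(records = classified, summary = cs, metrics = metrics)
}
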