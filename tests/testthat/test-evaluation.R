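pred_row <- function(report_id = "r1", field_id = "adh", value = "x",
                     extra = NA_integer_, status = "ok") {
  data.frame(report_id = report_id, field_id = field_id, value = value,
             extra = as.integer(extra), status = status, no_segment = FALSE,
             backend_id = "oracle", raw_response = "", stringsAsFactors = FALSE)
}
truth_row <- function(report_id = "r1", field_id = "adh",
                      truth_value = NA_character_, truth_extra = NA_integer_,
                      regime = "complete") {
  data.frame(report_id = report_id, field_id = field_id,
             truth_value = truth_value, truth_extra = as.integer(truth_extra),
             regime = regime, stringsAsFactors = FALSE)
}

test_that("classification covers all four quadrants plus skip", {
  tp <- classify(pred_row(value = "Atypical ductal hyperplasia"),
                 truth_row(truth_value = "Atypical ductal hyperplasia"))
  expect_identical(tp, "TP")
  # wrong value on an annotated field is a false negative, as is abstention
  expect_identical(classify(pred_row(value = "8 o'clock",
                                     field_id = "tumor_position_int"),
                            truth_row(field_id = "tumor_position_int",
                                      truth_value = "Distance from nipple: — cm",
                                      truth_extra = 8L)),
                   "FN")
  expect_identical(classify(pred_row(value = abstain_value()),
                            truth_row(truth_value = "Usual ductal hyperplasia")),
                   "FN")
  expect_identical(classify(pred_row(value = "x", status = "invalid"),
                            truth_row(truth_value = "x")), "FN")
  expect_identical(classify(pred_row(value = abstain_value()), truth_row()),
                   "TN")
  expect_identical(classify(pred_row(value = "anything"), truth_row()), "FP")
  # positive-only: unannotated pairs are skipped, never counted
  expect_identical(classify(pred_row(value = "anything"), NULL,
                            regime = "positive_only"), "skip")
  expect_error(classify(pred_row(report_id = "r1"),
                        truth_row(report_id = "r2")), "disagree")
})

test_that("exact match is normalized and respects the numeric extra", {
  t <- truth_row(truth_value = "Exact distance: — mm", truth_extra = 4L,
                 field_id = "dcis_margin_exact")
  expect_identical(classify(pred_row(field_id = "dcis_margin_exact",
                                     value = "exact distance: - MM",
                                     extra = 4L), t), "TP")
  expect_identical(classify(pred_row(field_id = "dcis_margin_exact",
                                     value = "Exact distance: — mm",
                                     extra = 5L), t), "FN")
  expect_identical(classify(pred_row(field_id = "dcis_margin_exact",
                                     value = "Exact distance: — mm",
                                     extra = 5L), t, require_extra = FALSE),
                   "TP")
})

test_that("summaries count outcomes exactly and ignore skips", {
  expect_identical(summarize_outcomes(rep("TP", 7))$tp, 7L)
  withr::with_seed(14, {
    for (rep in 1:20) {
      oc <- sample(c("TP", "FP", "TN", "FN", "skip"), 60, replace = TRUE)
      s <- summarize_outcomes(oc)
      # brute-force counting oracle
      expect_identical(s$tp, sum(oc == "TP"))
      expect_identical(s$fp, sum(oc == "FP"))
      expect_identical(s$tn, sum(oc == "TN"))
      expect_identical(s$fn, sum(oc == "FN"))
      expect_identical(s$tp + s$fp + s$tn + s$fn, sum(oc != "skip"))
      # order invariance
      expect_identical(summarize_outcomes(sample(oc)), s)
    }
  })
  expect_error(summarize_outcomes(c("TP", "FP"), regime = "positive_only"),
               "cannot contain FP")
  expect_error(summarize_outcomes(c("TP", "meh")), "unknown outcome")
})

test_that("recall reproduces published-style worked values", {
  expect_identical(recall(confusion_summary(tp = 5831, fn = 820,
                                            regime = "positive_only"))$percent,
                   87.7)
  expect_identical(recall(confusion_summary(tp = 4111, fn = 2540,
                                            regime = "positive_only"))$percent,
                   61.8)
  expect_identical(recall(confusion_summary(tp = 0, fn = 5,
                                            regime = "positive_only"))$percent,
                   0)
  expect_error(recall(confusion_summary(tp = 0, fn = 0,
                                        regime = "positive_only")),
               "undefined")
})

test_that("full metrics agree with a brute-force formula oracle", {
  withr::with_seed(99, {
    for (rep in 1:500) {
      cts <- sample(0:200, 4, replace = TRUE)
      tp <- cts[1]; fp <- cts[2]; tn <- cts[3]; fn <- cts[4]
      m <- full_metrics(confusion_summary(tp = tp, fn = fn, fp = fp, tn = tn))
      p <- m$proportions
      check <- function(got, num, den) {
        if (den == 0) expect_true(is.na(got))
        else expect_equal(got, num / den, tolerance = 1e-12)
      }
      check(p$sensitivity, tp, tp + fn)
      check(p$specificity, tn, tn + fp)
      check(p$precision, tp, tp + fp)
      check(p$accuracy, tp + tn, tp + tn + fp + fn)
      if (!is.na(p$precision) && !is.na(p$sensitivity) &&
          p$precision + p$sensitivity > 0) {
        expect_equal(p$f1, 2 * p$precision * p$sensitivity /
                       (p$precision + p$sensitivity), tolerance = 1e-12)
      }
      denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
      if (denom > 0) {
        expect_equal(p$mcc, (tp * tn - fp * fn) / denom, tolerance = 1e-12)
        expect_gte(p$mcc, -1); expect_lte(p$mcc, 1)
      } else {
        expect_true(is.na(p$mcc))
      }
    }
  })
})

test_that("a perfect classifier on the default composition scores 100%", {
  m <- full_metrics(confusion_summary(tp = 445, fn = 0, fp = 0, tn = 419))
  expect_identical(m$percent$accuracy, 100)
  expect_identical(m$percent$sensitivity, 100)
  expect_identical(m$percent$mcc, 1)
})

test_that("positive-only regime refuses the full metric suite", {
  s <- confusion_summary(tp = 10, fn = 2, regime = "positive_only")
  expect_error(full_metrics(s), "recall only")
  expect_true(is.na(s$fp))
  expect_true(is.na(s$tn))
})

test_that("reality gap is plain percentage-point arithmetic", {
  expect_identical(reality_gap(99.0, 87.7), 11.3)
  expect_identical(reality_gap(93.8, 61.8), 32)
  expect_identical(reality_gap(75.5, 75.5), 0)
  expect_error(reality_gap(120, 50), "\\[0, 100\\]")
})

test_that("classify_records joins, and evaluate_run dispatches by regime", {
  suite <- generate_suite(SCH, n_positive = 25, n_negative = 25, seed = 6,
                          adversarial_frac = 0)
  recs <- run_suite(suite, SCH, select_backend("oracle"))
  complete <- evaluate_run(recs, suite_truth(suite, "complete"))
  expect_identical(complete$summary$tp, 25L)
  expect_identical(complete$summary$tn, 25L)
  pos_only <- evaluate_run(recs, suite_truth(suite, "positive_only"))
  expect_identical(pos_only$metrics$percent, 100)
  skips <- sum(pos_only$records$outcome == "skip")
  expect_identical(skips, 25L)
})
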