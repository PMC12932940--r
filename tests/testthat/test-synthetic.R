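test_that("default composition is exactly 445 positive + 419 negative = 864", {
  suite <- generate_suite(SCH, seed = 500)
  expect_identical(nrow(suite), 864L)
  expect_identical(sum(suite$polarity == "positive"), 445L)
  expect_identical(sum(suite$polarity == "negative"), 419L)
  expect_identical(anyDuplicated(suite$case_id), 0L)
})

test_that("composition exactness holds for arbitrary configurations", {
  for (cfg in list(c(1, 0), c(0, 1), c(13, 29), c(50, 50))) {
    suite <- generate_suite(SCH, n_positive = cfg[1], n_negative = cfg[2],
                            seed = 7)
    expect_identical(sum(suite$polarity == "positive"), as.integer(cfg[1]))
    expect_identical(sum(suite$polarity == "negative"), as.integer(cfg[2]))
    # polarity <=> truth presence
    expect_identical(is.na(suite$truth_value), suite$polarity == "negative")
  }
})

test_that("label soundness: exhaustive scan confirms every polarity", {
  suite <- generate_suite(SCH, seed = 123)
  violations <- 0L
  for (i in seq_len(nrow(suite))) {
    present <- scan_option_in_text(SCH, suite$field_id[i], suite$input_text[i])
    expected <- switch(suite$polarity[i], positive = TRUE, negative = FALSE)
    if (suite$adversarial[i]) next  # flagged edge cases are exempt by design
    if (!identical(present, expected)) violations <- violations + 1L
  }
  expect_identical(violations, 0L)
})

test_that("same seed gives a byte-identical corpus; different seeds differ", {
  a <- generate_suite(SCH, n_positive = 60, n_negative = 40, seed = 31)
  b <- generate_suite(SCH, n_positive = 60, n_negative = 40, seed = 31)
  expect_identical(a, b)
  c <- generate_suite(SCH, n_positive = 60, n_negative = 40, seed = 32)
  expect_false(identical(a$input_text, c$input_text))
})

test_that("numeric style embeds the drawn integer as ground-truth extra", {
  suite <- generate_suite(SCH, n_positive = 300, n_negative = 0, seed = 44,
                          adversarial_frac = 0)
  nums <- suite[suite$style_id == "numeric", ]
  expect_gt(nrow(nums), 50)
  # regex re-extraction oracle
  printed <- as.integer(sub(".*Found number ([0-9]+).*", "\\1",
                            nums$input_text))
  expect_identical(printed, nums$truth_extra)
})

test_that("rendered styles carry their signature features", {
  adh <- get_field(SCH, "adh")
  plain <- render_case(adh, "positive", "plain", list(opt = 1L, int = 1L))
  expect_match(plain$input_text, "^Additional Findings: Atypical ductal hyperplasia$")
  neg <- render_case(adh, "negative", "negative_nan",
                     label_pool = "Distant Site(s) Involved")
  expect_match(neg$input_text, "nan", fixed = TRUE)
  expect_match(neg$input_text, "Some other free text.", fixed = TRUE)
  expect_true(is.na(neg$truth_value))
  adv <- render_case(get_field(SCH, "glandular_differentiation"),
                     "positive", "adversarial_vague", list(opt = 3L, int = 1L))
  expect_true(adv$adversarial)
  expect_match(adv$input_text, "Tumor is malignant", fixed = TRUE)
  expect_identical(adv$truth_value, "Score 3")
  expect_error(render_case(adh, "positive", "interpretive_dance"),
               "unknown synthetic style")
})

test_that("ground truth lives in a separate manifest per regime", {
  suite <- generate_suite(SCH, n_positive = 10, n_negative = 10, seed = 2)
  complete <- suite_truth(suite, "complete")
  expect_identical(nrow(complete), 20L)
  expect_identical(sum(is.na(complete$truth_value)), 10L)
  pos_only <- suite_truth(suite, "positive_only")
  expect_identical(nrow(pos_only), 10L)
  expect_true(all(!is.na(pos_only$truth_value)))
  expect_true(all(pos_only$regime == "positive_only"))
})

test_that("a schema without matchable fields refuses positive generation", {
  rows <- data.frame(
    section = "comments", subsection = "Report Comment",
    field_id = "c1", label = "Comment(s)", value_kind = "free_text",
    options = "", numeric_template = "", synonyms = "",
    report_types = "all", stringsAsFactors = FALSE)
  sch <- load_schema(toy_schema_csv(rows = rows))
  expect_error(generate_suite(sch, n_positive = 1, n_negative = 0, seed = 1),
               "no categorical")
  expect_error(generate_suite(SCH, n_positive = -1, n_negative = 0, seed = 1),
               ">= 0")
})
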