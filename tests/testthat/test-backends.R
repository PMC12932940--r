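oracle_raw <- function(field_id, text, schema = SCH) {
  spec <- get_field(schema, field_id)
  bundle <- build_prompt(list(field_id = field_id, text = text), spec)
  oracle_complete(bundle, synonyms = spec$synonyms)
}

test_that("backend registry resolves built-ins and rejects unknown names", {
  expect_true(all(c("oracle", "oracle-noisy") %in% list_backends()))
  be <- select_backend("oracle")
  expect_s3_class(be, "extraction_backend")
  spec <- get_field(SCH, "adh")
  bundle <- build_prompt(list(field_id = "adh",
                              text = "Additional Findings: Atypical ductal hyperplasia"),
                         spec)
  expect_identical(be$complete(bundle), be$complete(bundle))
  expect_error(select_backend("gpt-99"), "oracle")
})

test_that("oracle-noisy is run-to-run identical for a fixed seed", {
  suite <- generate_suite(SCH, n_positive = 30, n_negative = 10, seed = 3)
  run_once <- function() {
    be <- select_backend("oracle-noisy",
                         list(rates = c(0.2, 0.2, 0.3), seed = 99L))
    run_suite(suite, SCH, be)$value
  }
  expect_identical(run_once(), run_once())
})

test_that("oracle matches Table-style worked inputs", {
  spec <- get_field(SCH, "dcis_margin_exact")
  raw <- oracle_raw("dcis_margin_exact",
                    "Distance from DCIS to Anterior Margin: Exact distance: mm. Found number 4")
  rec <- parse_response(raw, spec)
  expect_identical(rec$value, "Exact distance: — mm")
  expect_identical(rec$extra, 4L)

  rec2 <- parse_response(oracle_raw("nonregional_nodes",
    "Distant Site(s) Involved: Comment(s):. nan. Some other free text."),
    get_field(SCH, "nonregional_nodes"))
  expect_identical(rec2$value, abstain_value())
})

test_that("longest option wins, verified against exhaustive enumeration", {
  rows <- data.frame(
    section = "tumor", subsection = "Grade",
    field_id = "g", label = "Grade", value_kind = "categorical",
    options = "High|High grade with necrosis|Low", numeric_template = "",
    synonyms = "", report_types = "all", stringsAsFactors = FALSE)
  sch <- load_schema(toy_schema_csv(rows = rows))
  spec <- get_field(sch, "g")
  withr::with_seed(8, {
    for (rep in 1:20) {
      opts <- sample(spec$allowed_options, sample(1:3, 1))
      txt <- paste0("Grade: ", paste(opts, collapse = " and "))
      rec <- parse_response(oracle_raw("g", txt, sch), spec)
      # brute force: enumerate all options occurring as substrings, keep longest
      present <- spec$allowed_options[vapply(spec$allowed_options, function(o)
        grepl(tolower(o), tolower(txt), fixed = TRUE), logical(1))]
      best <- present[which.max(nchar(present))]
      expect_identical(rec$value, best)
    }
  })
})

test_that("synonyms map to canonical options", {
  rec <- parse_response(oracle_raw("procedure", "Procedure: lumpectomy, left"),
                        get_field(SCH, "procedure"))
  expect_identical(rec$value, "Partial mastectomy")
})

test_that("parse_response handles strict, repairable, and hopeless payloads", {
  spec <- get_field(SCH, "adh")
  ok <- parse_response('{"field":"adh","value":"Atypical ductal hyperplasia"}',
                       spec)
  expect_identical(ok$status, "ok")
  expect_identical(ok$value, "Atypical ductal hyperplasia")

  rep <- parse_response(
    'Sure! Here is the JSON: {"field":"adh","value":"Atypical ductal hyperplasia"}',
    spec)
  expect_identical(rep$status, "repaired")
  expect_identical(rep$value, "Atypical ductal hyperplasia")

  bad <- parse_response('{"value": 42', spec)
  expect_identical(bad$status, "invalid")
  expect_identical(bad$value, abstain_value())
  expect_identical(bad$raw_response, '{"value": 42')

  offlist <- parse_response('{"field":"adh","value":"Carcinoma"}', spec)
  expect_identical(offlist$status, "invalid")

  # normalization: case, whitespace, dash variants never decide a mismatch
  norm <- parse_response('{"field":"adh","value":"  ATYPICAL   ductal hyperplasia "}',
                         spec)
  expect_identical(norm$value, "Atypical ductal hyperplasia")
  expect_identical(norm$status, "ok")
})

test_that("parse_response after serialize_record is the identity", {
  spec <- get_field(SCH, "dcis_margin_exact")
  rec <- parse_response(oracle_raw("dcis_margin_exact",
    "Distance from DCIS to Anterior Margin: Exact distance: mm. Found number 7"),
    spec)
  back <- parse_response(serialize_record(rec), spec)
  expect_identical(back$value, rec$value)
  expect_identical(back$extra, rec$extra)
  expect_identical(back$status, "ok")
})

test_that("inject_errors is an identity at zero rates and forced at rate one", {
  suite <- generate_suite(SCH, n_positive = 20, n_negative = 10, seed = 4,
                          adversarial_frac = 0)
  recs <- run_suite(suite, SCH, select_backend("oracle"))
  expect_identical(inject_errors(recs, c(0, 0, 0), seed = 1, schema = SCH),
                   recs)
  dropped <- inject_errors(recs, c(0, 1, 0), seed = 1, schema = SCH)
  expect_true(all(dropped$value == abstain_value()))
  expect_error(inject_errors(recs, c(0.8, 0.9, 0), seed = 1, schema = SCH),
               "rates")
})

test_that("drop-rate injection recovers the binomial expectation", {
  suite <- generate_suite(SCH, seed = 21, adversarial_frac = 0)
  recs <- run_suite(suite, SCH, select_backend("oracle"))
  truth <- suite_truth(suite)
  delta <- 0.1
  n_pos <- sum(suite$polarity == "positive")
  se <- sqrt(delta * (1 - delta) / n_pos)
  for (seed in c(101, 202)) {
    noisy <- inject_errors(recs, c(0, delta, 0), seed = seed, schema = SCH)
    sens <- evaluate_run(noisy, truth)$metrics$proportions$sensitivity
    expect_lt(abs(sens - (1 - delta)), 3 * se)
  }
})
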