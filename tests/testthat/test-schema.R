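test_that("bundled schema has the reference cardinality and hierarchy", {
  counts <- schema_counts(SCH)
  expect_identical(unname(counts), c(8L, 86L, 229L))
  expect_identical(SCH$sections,
                   c("specimen", "tumor", "margins", "regional lymph nodes",
                     "distant metastasis", "pTNM classification",
                     "additional findings", "comments"))
  # independent tally straight over the CSV rows
  raw <- utils::read.csv(default_schema_path(), stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  expect_identical(length(unique(raw$section)), 8L)
  expect_identical(nrow(unique(raw[, c("section", "subsection")])), 86L)
  expect_identical(length(unique(raw$field_id)), 229L)
  # every (section, subsection) pair of every field exists in the hierarchy
  for (i in seq_len(nrow(SCH$fields))) {
    expect_true(SCH$fields$subsection[i] %in%
                  SCH$subsections[[SCH$fields$section[i]]])
  }
})

test_that("schema_counts equals an independent distinct-count for any input", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(3:12, 1)
      secs <- sample(c("specimen", "tumor", "margins"), n, replace = TRUE)
      rows <- data.frame(
        section = secs,
        subsection = paste0("Sub", sample(1:4, n, replace = TRUE)),
        field_id = sprintf("f%02d", seq_len(n)),
        label = sprintf("Label %02d", seq_len(n)),
        value_kind = "categorical",
        options = "A|B",
        numeric_template = "", synonyms = "", report_types = "all",
        stringsAsFactors = FALSE)
      sch <- load_schema(toy_schema_csv(rows = rows))
      counts <- schema_counts(sch)
      expect_identical(unname(counts[1]), length(unique(rows$section)))
      expect_identical(unname(counts[2]),
                       nrow(unique(rows[, c("section", "subsection")])))
      expect_identical(unname(counts[3]), n)
    }
  })
})

test_that("schema round-trips through write_schema/load_schema", {
  p <- tempfile(fileext = ".csv")
  write_schema(SCH, p)
  again <- load_schema(p)
  expect_identical(again$fields, SCH$fields)
  expect_identical(again$version, SCH$version)
  expect_identical(again$subsections, SCH$subsections)
})

test_that("loading is order-stable and version is a content hash", {
  a <- load_schema(default_schema_path())
  expect_identical(a$version, SCH$version)
  sch1 <- toy_schema()
  sch2 <- toy_schema()
  expect_identical(sch1$version, sch2$version)
  expect_false(identical(sch1$version, SCH$version))
})

test_that("get_options returns canonical lists verbatim", {
  opts <- get_options(SCH, "procedure")
  expect_gt(length(opts), 1)
  expect_true("Partial mastectomy" %in% opts)
  expect_identical(opts, get_field(SCH, "procedure")$allowed_options)
  # options unique within every field
  for (id in SCH$fields$field_id) {
    expect_false(anyDuplicated(get_options(SCH, id)) > 0)
  }
  expect_identical(get_options(SCH, "comments"), character(0))
  expect_error(get_options(SCH, "no_such_field"), "no_such_field")
})

test_that("schema validation rejects malformed inputs", {
  hdr_only <- toy_schema_csv(rows = data.frame(
    section = character(0), subsection = character(0),
    field_id = character(0), label = character(0),
    value_kind = character(0), options = character(0),
    numeric_template = character(0), synonyms = character(0),
    report_types = character(0), stringsAsFactors = FALSE))
  expect_error(load_schema(hdr_only), "no fields")

  dup <- data.frame(
    section = "additional findings", subsection = "Epithelial Findings",
    field_id = "adh", label = c("A", "B"), value_kind = "categorical",
    options = "X|Y", numeric_template = "", synonyms = "",
    report_types = "all", stringsAsFactors = FALSE)
  expect_error(load_schema(toy_schema_csv(rows = dup)), "duplicate")

  bad_sec <- dup[1, ]; bad_sec$section <- "biomarkers"
  expect_error(load_schema(toy_schema_csv(rows = bad_sec)), "section")

  one_opt <- dup[1, ]; one_opt$options <- "X"
  expect_error(load_schema(toy_schema_csv(rows = one_opt)), ">= 2")

  expect_error(load_schema("/nonexistent/schema.csv"), "not found")
})

test_that("numeric templates carry one placeholder, ASCII dash accepted on read", {
  spec <- get_field(SCH, "dcis_margin_exact")
  expect_identical(spec$numeric_template, "Exact distance: — mm")
  row <- data.frame(
    section = "margins", subsection = "Anterior Margin",
    field_id = "d1", label = "Distance", value_kind = "numeric_template",
    options = "Exact distance: - mm", numeric_template = "Exact distance: - mm",
    synonyms = "", report_types = "all", stringsAsFactors = FALSE)
  sch <- load_schema(toy_schema_csv(rows = row))
  expect_identical(get_field(sch, "d1")$numeric_template,
                   "Exact distance: — mm")
})

test_that("report-type filtering returns schema-ordered subsets", {
  all_ids <- fields_for_report_type(SCH, "all")
  expect_identical(all_ids, SCH$fields$field_id)
  dcis <- fields_for_report_type(SCH, "dcis")
  expect_true(all(dcis %in% all_ids))
  expect_lt(length(dcis), length(all_ids))
  expect_false("glandular_differentiation" %in% dcis)
  expect_error(fields_for_report_type(SCH, "lung"), "unknown report type")
})
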