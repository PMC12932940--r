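---
title: "Ontology-constrained extraction from breast synoptic reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-constrained extraction from breast synoptic reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synoptex)
```

## The problem

Breast cancer synoptic pathology reports follow standardized checklist
templates, yet much of their clinically decisive content — margin distances,
receptor status, node counts, incidental findings — sits in free-text fields
rather than discrete data elements. Population-scale analytics need those
values as normalized, computable records. `synoptex` implements a modular,
agent-style pipeline for that conversion: isolate the text block relevant to
a reporting field, render a deterministic instruction prompt that enumerates
the field's allowed values, send it to a pluggable extraction backend, and
parse the response into a schema-validated record. Because real reports
carry protected health information and cannot ship with software, the
package also implements the other half of the methodology: a synthetic
validation corpus with known ground truth, and an evaluation engine that
keeps the synthetic (complete-truth) and real-world (positive-only)
annotation regimes strictly apart.

## The reporting ontology

The bundled schema normalizes CAP-style breast reporting checklists for the
five major report types (DCIS, invasive biopsy and resection, Phyllodes
biopsy and resection) into a three-level hierarchy:

```{r}
sch <- load_schema(default_schema_path())
schema_counts(sch)
sch$sections
```

Eight sections, 86 subsections, and 229 discrete fields. CAP checklist text
is copyrighted, so field labels and option lists are representative of
breast protocols rather than verbatim; the hierarchy and cardinality are the
package's fixed reference conditions. Each field is `categorical` (two or
more canonical options, e.g. `procedure`), a `numeric_template` (a display
template with one placeholder dash, e.g. `"Exact distance: — mm"`, plus an
integer channel), or `free_text`. Optional synonym surfaces
(`"lumpectomy" => "Partial mastectomy"`) normalize common clinical
shorthand onto canonical options. The schema is plain CSV; its loaded form
carries a content hash (`sch$version`) recorded in run manifests so every
record is traceable to the exact ontology that produced it.

## Segmentation

Synoptic text labels its items (`"Label: value"`), so segmentation is
schema-driven: every field label becomes a line-anchored, case-insensitive
pattern `^Label:`, and each match opens a segment that runs to the next
match of any pattern or end of text. Spans are 0-based half-open offsets;
segment text is the trimmed span substring, so segments stay losslessly
anchored to the source. Design choices worth stating:

* **Pattern granularity.** Patterns are derived per *field* by default. The
  bundled schema gives every field a distinct label, which makes field-level
  patterns unambiguous and keeps segments non-overlapping; one pattern per
  subsection heading is available via `derive_patterns(level =
  "subsection")` for reports that label at coarser granularity, and an
  override table handles irregular headings.
* **Repeated labels** each yield a segment; downstream, the first
  non-abstaining extraction in document order wins. Real reports repeat
  blocks (e.g. re-excision specimens), and dropping repeats silently would
  hide information.
* **Noise tokens** such as `nan` are retained. Filtering is the extractor's
  job; the segmenter never editorializes.

## Prompt construction

Prompts are rendered from versioned text templates shipped as package
assets (`default-v1` for option-bearing fields, `freetext-v1` for free-text
fields), not assembled in code: reproducing an extraction run requires the
instruction text to be data. A rendered prompt embeds the segment verbatim
exactly once, enumerates each allowed option exactly once in an options
block (the boilerplate contains no option strings), instructs the responder
to abstain when no value is present, and pins the output contract — one JSON
object with keys `field`, `value`, and an optional integer `extra` for
numeric templates. Rendering is pure: no timestamps, no randomness, and a
20,000-character ceiling errors rather than truncating.

## Backends, the oracle, and error injection

Backends are pluggable: anything exposing `complete(bundle) -> string` can
sit behind `select_backend()`. The built-in **oracle** is a deterministic
rule-based matcher: it normalizes text (trim, collapse whitespace,
casefold, unify dash variants), then selects the *longest* allowed option or
synonym surface whose matching form occurs in the segment, breaking
equal-length ties by schema order — deterministic and auditable against the
schema. Numeric-template options match with the placeholder removed, since
reports print `"Exact distance: mm"` for the template
`"Exact distance: — mm"`, and a trailing `"Found number N"` is captured as
the integer extra. The oracle is the pipeline's testing instrument, not a
clinical claim: on text where the value is stated verbatim it is perfect by
construction, which is exactly what makes it useful as a reference point.

`parse_response()` holds every backend to the same contract: strict JSON
parse, then at most one repair pass (strip fences and prose, take the first
JSON object) marking the record `repaired`; values are normalized and
validated against the ontology; anything unvalidatable becomes
`status = "invalid"` with the raw response retained. Repair is deliberately
bounded — repeated repair loops trade transparency for scores.

**Error injection** (`inject_errors`, or the `oracle-noisy` backend) turns
the perfect oracle into a model with known flaws: seeded, per-record
corruption that swaps a correct value for a uniformly drawn wrong option,
drops it to an abstention, or emits a spurious value where abstention was
correct. With drop rate $\delta$ the expected sensitivity is $1-\delta$,
which gives the evaluation engine a closed-form target to recover — the
package's main statistical self-check.

## The synthetic validation corpus

`generate_suite()` produces the controlled corpus that stands in for real
reports: by default **864 cases — 445 positive** (a correct ontology value
present in the snippet) **and 419 negative** (no allowed value of the
field present), spread round-robin over the categorical and
numeric-template fields after a seeded shuffle. Positive styles mirror the
input shapes seen in synoptic text: plain `Label: value`, value plus a
`nan` noise token, value plus distractor free text, and numeric-template
snippets with a trailing `Found number N` whose `N` is the ground-truth
extra. Negative snippets are headed by a *foreign* field's label (as in
real reports, where the block scanned for a field often carries another
item's heading) with either a `Comment(s):. nan.` filler or a foreign
field's value as distractor.

Choices the corpus design had to make:

* **Adversarial fraction.** A 5% slice of positive cases (22 of 445) is
  rendered with deliberately ambiguous wording — vague assertions like
  `"Tumor is malignant"` where a grade score is the truth, or an
  `At least:` numeric fragment inviting a clock-position confusion. These
  are flagged `adversarial = TRUE` and excluded from the perfect-oracle
  identity property; they exist so that imperfect backends have genuinely
  hard cases. Five percent keeps the corpus dominated by well-posed cases
  while making the adversarial stratum large enough to matter.
* **Certification at generation time.** Every non-adversarial positive is
  verified recoverable under the oracle's own matching rule, and every
  negative is verified free of the field's values by substring scan, before
  the case is emitted; generation aborts on violation rather than shipping
  an unsound label.
* **Label separation.** Ground truth lives in a manifest
  (`suite_truth()`) separate from the inputs, so an extraction run cannot
  leak labels; the positive-only manifest simply drops negative rows, which
  is precisely the information loss real-world annotation sets exhibit.

What the generator does **not** emulate: abbreviation soup, dictation and
OCR artifacts, negation and uncertainty phrasing, cross-field context, and
institutional style drift. A pipeline scoring perfectly here has passed a
necessary check, not a clinical validation — the gap between synthetic
accuracy and real-world recall is the methodology's central caution, and
the package ships `reality_gap()` to make that comparison routine.

## Evaluation: two regimes, one rule

Classification against ground truth uses exact match on normalized values
("exact" is otherwise undefined: trim, casefold, collapse whitespace,
unify dashes), and when the truth carries a numeric extra, the extra must
agree as well (configurable off). Under the **complete** regime every pair
has definitive truth, so TP/FP/TN/FN and the full metric suite —
sensitivity, specificity, precision, F1, MCC, accuracy — are computable.
Under the **positive-only** regime, annotations assert presence but never
absence: predictions for unannotated pairs are *skipped*, never counted as
false positives, `fp` and `tn` are marked unavailable rather than zero, and
`full_metrics()` refuses outright — recall `TP/(TP+FN)` is the only
defensible number. The refusal is a feature: computing specificity from
positive-only truth would be fabrication.

Numerical conventions: metrics with zero denominators are unavailable
(`NA`), not zero; counts are tallied in double precision (MCC's product of
four sums overflows 32-bit integers at realistic scale); printed
percentages round half-up to one decimal, mirroring clinical tables, while
raw proportions are always retained in machine output.

## Orchestration and reproducibility

`run_report()` executes the full workflow per report — segmentation and
schema load are independent initialization stages (treated as a dependency
statement, not a concurrency mandate: determinism beats speed at desk
scale) — and emits exactly one record per attempted field, with abstaining
`no_segment` records for fields whose label never appears, and per-field
isolation so one backend failure cannot contaminate other fields.
`call_agent()` exposes each stage as a self-contained task; composing the
stages by hand reproduces `run_report()` exactly, which the test suite
asserts. `run_suite()` treats each synthetic case's snippet as the
already-isolated segment for its field: suite cases are segments by
construction, and a case's snippet may legitimately carry a different
field's heading (the true-negative shape). Seeded runs serialize
byte-identically to JSON Lines, and the run manifest (schema hash, backend,
template, seed, counts — never timing) pins everything needed to re-run.

## Problem sizes and test design

The test suite generates corpora in code at the default 864-case scale for
the identity, soundness, and injection-recovery properties (seconds each),
hand-sized toy schemas for structural edge cases, and 500 random confusion
tables for metric-formula equivalence against direct evaluation at
`1e-12` tolerance. Injection recovery is asserted within three binomial
standard errors of the expected sensitivity at drop rates 0.05, 0.1, and
0.3 — a statistical tolerance chosen from the estimator's own sampling
distribution, not tuned to observations.

## Known limitations

The oracle cannot misread; it validates plumbing and arithmetic, not
language understanding. The schema is representative, not CAP-verbatim, so
field-level results do not transfer to any institution's exact checklist
without remapping. Free-text fields pass through unvalidated by
construction. The synthetic corpus bounds what passing means: systems
intended for clinical use require evaluation against expert-annotated real
reports, under the positive-only regime this package implements, before any
deployment claim.
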