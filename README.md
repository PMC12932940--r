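# synoptex

Ontology-constrained structured data extraction from breast cancer
synoptic pathology reports — with the validation machinery that such
systems actually need.

## What problem this solves

Synoptic pathology reports are structured on paper but free-text in
practice: margin distances, receptor status, node counts, and incidental
findings are typed into labeled blocks, not discrete fields. Teams building
population-scale registries, trial-screening pipelines, or QA dashboards
need those values as normalized records. `synoptex` implements the full
agent-style pipeline:

1. a normalized CAP-derived reporting **ontology** — 8 sections, 86
   subsections, 229 discrete fields across the five major breast report
   types — shipped as plain CSV with a content-hash version;
2. schema-driven **segmentation** of report text into labeled blocks;
3. deterministic **prompt construction** from versioned templates,
   enumerating each field's allowed values and a strict JSON output
   contract;
4. pluggable extraction **backends**: a deterministic rule-based oracle
   matcher (longest normalized option wins; numeric templates capture a
   `Found number N` integer channel), a seeded noisy variant for
   emulating imperfect models, and optional adapters for live providers;
5. a **synthetic validation corpus** generator — by default 864 cases,
   445 positive (a correct ontology value present in the snippet) and 419
   negative (none present), certified sound at generation time;
6. a dual-regime **evaluation engine**. Complete ground truth yields the
   full suite: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
   precision `TP/(TP+FP)`, F1, MCC, accuracy `(TP+TN)/(TP+TN+FP+FN)`.
   Positive-only ground truth — the shape of real-world expert annotation,
   which asserts presence but never absence — supports recall
   `TP/(TP+FN)` alone, and the engine refuses to fabricate the rest.
   `reality_gap()` reports the drop, in percentage points, from synthetic
   accuracy to real-world recall.

## Worked example

```r
library(synoptex)

sch <- load_schema(default_schema_path())
schema_counts(sch)
#> n_sections n_subsections      n_fields
#>          8            86           229

suite <- generate_suite(sch, seed = 7)   # 445 positive + 419 negative
recs  <- run_suite(suite, sch, select_backend("oracle"))
truth <- suite_truth(suite, "complete")

keep <- suite$case_id[!suite$adversarial]
ev <- evaluate_run(recs[recs$report_id %in% keep, ],
                   truth[truth$report_id %in% keep, ])
ev$metrics
#> <metric_report> (complete ground truth)
#>   Sens. 100.0%  Spec. 100.0%  Prec. 100.0%  F1 100.0%  MCC 1.000  Acc. 100.0%
```

The oracle is perfect on the non-adversarial corpus by construction — that
is the pipeline's identity check, not a performance claim. Emulating an
imperfect model recovers its known error rate:

```r
noisy <- inject_errors(recs, c(0, 0.1, 0), seed = 7, schema = sch)
ev2 <- evaluate_run(noisy[noisy$report_id %in% keep, ],
                    truth[truth$report_id %in% keep, ])
round(ev2$metrics$proportions$sensitivity, 3)
#> [1] 0.913        # expected 0.9, within binomial sampling error

reality_gap(99.0, 87.7)
#> [1] 11.3         # percentage-point drop, synthetic accuracy -> real recall
```

A single report runs through the full orchestrated workflow:

```r
recs <- run_report("Additional Findings: Atypical ductal hyperplasia",
                   sch, select_backend("oracle"), fields = "adh")
recs$value
#> [1] "Atypical ductal hyperplasia"
```

A thin command-line front end over the same functions ships at
`inst/cli/synoptex.R` (`schema`, `simulate`, `extract`, `evaluate`, `gap`
subcommands).

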