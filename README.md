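# lumencheck

Screening central-venous catheter lumens for physico-chemical drug
incompatibilities.

## The problem

Critically ill patients routinely receive a dozen or more intravenous
drugs through multi-lumen central-venous catheters. Two drugs running
*simultaneously through the same lumen* mix in the line, and some
combinations react — precipitation, degradation, inactivation. Whether a
given pair is safe is scattered across compatibility databases, drug
labels, and handbooks, and those sources often disagree.

`lumencheck` is for hospital pharmacists and medication-safety
researchers who want that screening to be reproducible. It provides:

* an **open knowledge-base format** (CSV/JSON) holding one assertion per
  unordered drug pair per evidence source (`KIK`, `STABILIS`, `SMPC`,
  `TRISSEL`, plus custom sources), with drug-name normalization through
  a synonym lexicon;
* a **resolution policy** mapping multi-source evidence to one verdict
  per pair — `COMPATIBLE`, `INCOMPATIBLE`, or `NOT_EVALUABLE` (conflict
  or no data) — with a full audit trail. The default `STRICT_CONSENSUS`
  mode requires data-bearing sources to agree and fails toward
  "incompatible"; `PRECEDENCE_FIRST` lets the highest-ranked source
  decide;
* **per-lumen co-administration analysis** of patient charts: half-open
  integer-minute intervals, a sweep line producing the maximal
  constant-activity windows of each lumen, the ≥ 3-simultaneous-drugs
  inclusion criterion, and cohort aggregates (frequency table,
  cross-table, patient-level medians);
* a **four-step avoidance recommender** — administer sequentially, use
  another lumen (constrained graph coloring over the catheter's lumens),
  pause a continuous infusion, or escalate to a catheter with more
  lumens — that always picks the lowest feasible step and guarantees the
  amended schedule has zero incompatible same-lumen overlaps;
* **survey scoring** for staff-knowledge questionnaires (right/wrong/
  blank against a keyed answer set, Likert summaries with explicit
  quantile conventions);
* **seeded synthetic generators** for cohorts (with planted, exactly
  recoverable incompatibilities) and survey responses, so the whole
  pipeline is testable without proprietary databases or real charts.

## Worked example

```r
library(lumencheck)

kb <- fixture_kb()   # bundled multi-source knowledge base
resolve_pair(kb, "piperacillin/tazobactam", "pantoprazole")
#> <pantoprazole + piperacillin/tazobactam> INCOMPATIBLE (SINGLE_SOURCE)
#>   KIK       NO_DATA                     [consulted, unused]
#>   STABILIS  INCOMPATIBLE
#>   SMPC      NO_DATA                     [consulted, unused]
#>   TRISSEL   NO_DATA                     [consulted, unused]
```

One source reports the pair incompatible and nothing contradicts it, so
the pair is classified `INCOMPATIBLE` with reason `SINGLE_SOURCE`; the
trail shows exactly which sources were consulted and which decided.

Screen one patient's day — a 3-lumen catheter with dedicated
catecholamine and analgesia lumens, and three drugs meeting on lumen 3:

```r
ch <- patient_chart("icu-07",
  catheter_config(3, c("1" = "catecholamine", "2" = "analgesic")),
  data.frame(
    drug = c("noradrenaline", "sufentanil", "piperacillin/tazobactam",
             "pantoprazole", "sodium chloride"),
    route = "CENTRAL_VENOUS", lumen = c(1, 2, 3, 3, 3),
    start_min = c(0, 0, 480, 500, 480),
    end_min   = c(1440, 1440, 540, 530, 600),
    mode = c("CONTINUOUS", "CONTINUOUS", "INTERMITTENT", "INTERMITTENT",
             "INTERMITTENT")))

res <- analyze_cohort(list("icu-07" = ch), kb)
res$findings[, c("lumen", "drug_a", "drug_b", "classification")]
#>   lumen                  drug_a                  drug_b classification
#> 1     3            pantoprazole piperacillin/tazobactam   INCOMPATIBLE
#> 2     3            pantoprazole         sodium chloride  NOT_EVALUABLE
#> 3     3 piperacillin/tazobactam         sodium chloride  NOT_EVALUABLE
```

The patient meets the inclusion criterion (three drugs simultaneously on
lumen 3). One pair is definitely incompatible; the two saline pairs have
no stored evidence, so they are reported `NOT_EVALUABLE` rather than
silently passed. The recommender resolves the incompatible pair at the
lowest feasible step:

```r
recs <- recommend(ch, res$findings, kb)
recs[[1]]
#> <recommendation patient icu-07> Step 1: Administer sequentially
#>   pantoprazole + piperacillin/tazobactam
#>   both pantoprazole and piperacillin/tazobactam are short
#>   administrations; give pantoprazole after piperacillin/tazobactam
#>   with a 5-min flush
count_incompatible_overlaps(attr(recs, "transformed_chart"), kb)
#> [1] 0
```

Both drugs are short infusions, so Step 1 applies: pantoprazole is
shifted to start after the piperacillin/tazobactam infusion ends plus a
5-minute flush, and re-analysis of the amended schedule finds no
incompatible overlap.

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/lumencheck`:

```sh
Rscript inst/scripts/lumencheck simulate --seed 11 --n-patients 6 --out-dir sim
Rscript inst/scripts/lumencheck analyze --charts sim/charts.csv \
    --catheters sim/catheters.yaml --kb sim/kb.json --out-dir out
Rscript inst/scripts/lumencheck recommend --charts sim/charts.csv \
    --catheters sim/catheters.yaml --kb sim/kb.json --out-dir rec
```

Outputs are plain CSV/JSON with a `run_metadata.json` sibling (package
version, subcommand, arguments, seed) sufficient to re-run any command
bit-identically.

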