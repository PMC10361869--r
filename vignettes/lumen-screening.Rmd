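---
title: "Screening catheter lumens for drug incompatibilities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening catheter lumens for drug incompatibilities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumencheck)
```

## The problem

Critically ill patients receive many intravenous drugs through multi-lumen
central-venous catheters. When two drugs run *simultaneously through the
same lumen*, they mix in the line, and some combinations react
physico-chemically — precipitation, degradation, inactivation. This is a
property of the shared fluid channel, not of the patients' pharmacology:
two drugs on different lumens of the same catheter never meet, so the unit
of analysis is the (patient, lumen, drug pair) occurrence.

Evidence on which pairs react is scattered across commercial compatibility
databases, drug labels, and handbooks, and the sources frequently
disagree. `lumencheck` implements the full screening workflow around that
reality: an open knowledge-base format with provenance, an explicit
conflict-resolution policy, per-lumen co-administration detection, a
four-step avoidance recommender, questionnaire scoring for staff-knowledge
surveys, and seeded synthetic generators so every stage is testable
without proprietary data.

## The knowledge base

A `knowledge_base` stores at most one `CompatibilityAssertion` per
(unordered drug pair, source). Four sources are built in, in default
precedence order: `KIK` and `STABILIS` (two compatibility databases),
`SMPC` (the drug label), and `TRISSEL` (a standard handbook of injectable
drugs). Each assertion carries one of four verdicts: `COMPATIBLE`,
`INCOMPATIBLE`, `CONFLICTING_WITHIN_SOURCE` (the source contradicts
itself), or — implicitly, for any absent assertion — `NO_DATA`. This
four-value vocabulary is the smallest one that can express both missing
evidence and internal contradiction, which are different things: absence
is ignorance, contradiction is a warning sign.

Drug names are normalized through a lexicon of canonical concepts with
synonym sets (e.g., *dipyrone* and *metamizole* are one concept).
Matching is exact after case-folding and whitespace collapse — there is
deliberately no fuzzy matching, because in a medication-safety context a
silently wrong match is worse than a hard error. Combination products
such as piperacillin/tazobactam are single concepts, never decomposed:
compatibility evidence is reported for the marketed mixture, not its
components. Carrier solutions, parenteral nutrition, and vitamin
supplements are ordinary lexicon entries with class tags, because they
take part in incompatibility reactions like any drug.

## Resolving conflicting evidence

`resolve_pair()` maps the per-source verdicts of one pair to a final
classification — `COMPATIBLE`, `INCOMPATIBLE`, or `NOT_EVALUABLE` (with
reason `CONFLICT` or `NO_DATA`) — plus a trail recording every source
consulted. The exact branch structure such a consultation procedure
should take is genuinely open: published descriptions of multi-source
screening list the sources but not the stopping rule. We therefore
expose the two defensible readings as explicit policy modes rather than
asserting either as *the* procedure:

* **`STRICT_CONSENSUS`** (default): consult everything; data-bearing
  sources must agree. Cross-source disagreement between `COMPATIBLE` and
  `INCOMPATIBLE` is never glossed over — the pair becomes
  `NOT_EVALUABLE`/`CONFLICT` and is reported as such. A
  `CONFLICTING_WITHIN_SOURCE` entry also taints the pair, *unless*
  `incompatible_dominates` is on (default) and every data-bearing source
  says `INCOMPATIBLE`: a safety tool should fail toward "incompatible",
  not toward silence.
* **`PRECEDENCE_FIRST`**: the first data-bearing source in
  `source_order` decides. This models a pharmacist working down a ranked
  list and stopping at the first answer.

Two properties are worth stating because the tests rely on them: under
strict consensus, adding a `NO_DATA` source never changes a verdict, and
upgrading any source from `NO_DATA` to `INCOMPATIBLE` can never turn an
`INCOMPATIBLE` verdict into `COMPATIBLE`. `classify_policy_table()`
enumerates all `4^4 = 256` verdict tuples so the whole decision surface
of a policy fits on one page; the test suite compares that table against
an independently written case-by-case reference for both modes.

## Time, lumens, and co-administration

Events are half-open integer-minute intervals `[start, end)` on a named
lumen; one chart covers one treatment day (a 1600-minute horizon check
guards against multi-day records slipping in). "Simultaneous" means a
nonempty intersection of positive duration: `[0, 60)` and `[60, 120)` do
*not* meet. This is the strictest defensible reading — it never invents a
contact that the chart does not document. Real lines hold residual drug
for a while after an infusion stops, so `simultaneous_sets()` and
`analyze_cohort()` accept a `slack` padding (minutes, default 0) that
widens every interval symmetrically before testing overlap; raising it
makes the screen more conservative.

`simultaneous_sets()` is a sweep line over event endpoints: it returns
the maximal windows on one lumen within which the active drug set is
constant, and those windows partition the union of the event intervals
exactly. Pairs, inclusion (≥ 3 drugs at once through one lumen), and all
cohort aggregates derive from these windows. The suite checks the sweep
line against a brute-force minute-grid oracle on hundreds of random
lumens — the two implementations share the half-open convention and
nothing else.

Only `CENTRAL_VENOUS` events enter the analysis; peripheral events are
parsed and retained but ignored, since the incompatibility question posed
here is specific to shared catheter lumens. Lumen labels are opaque
integers — proximal/medial/distal semantics are not modeled because
prescriptions do not reliably carry them.

## Cohort aggregation choices

A pair occurring in *k* patients counts *k* times; within one patient it
counts once per (lumen, pair). Occurrence counting matches how screening
workloads are reported ("this combination occurred five times");
`distinct_pairs = TRUE` gives the alternative per-patient reading.
`NOT_EVALUABLE` findings are never dropped: they go to their own report,
because "we could not decide" is itself an actionable result.

Percentages print with *half-up* rounding (`round_half_up()`,
`percent1()`), matching the commercial convention of spreadsheet and
clinical-statistics software rather than R's round-half-even — e.g.
`percent1(64, 104)` is `61.5` and `percent1(18, 130)` is `13.8`.
Quantiles default to type 6 (the weighted average at `(n+1)p`), the
default definition of the statistics environment such survey tables are
usually produced with; the convention is a parameter everywhere it
matters, because published quartiles cannot be validated without raw
data and the choice must at least be explicit.

## The four-step avoidance engine

For every incompatible (lumen, pair) occurrence, `recommend()` escalates
through four strategies and picks the lowest feasible one. The
feasibility predicates are this package's operationalization of the
strategy ladder; the thresholds all live in `recommender_config()`:

1. **Administer sequentially** — both members are bounded administrations
   (neither `CONTINUOUS`). The later-starting member is shifted right by
   the *minimal* delay that clears the partner plus a `flush_gap`
   (default 5 min, the line flush between incompatible drugs), subject
   to: no new incompatible overlap on that lumen, and no event past the
   horizon. The candidate-shift search enumerates every placement that
   starts just after some event's end, so infeasibility is decided
   exactly, not heuristically.
2. **Use another lumen** — a reassignment of the patient's drugs to the
   existing lumens such that no incompatible, time-overlapping pair
   shares a lumen. This is constrained graph coloring
   (`lumen_assignment()`): lumens are colors; reserved lumens (default:
   the catecholamine and analgesia lumens) accept only drugs carrying
   their purpose tag, and such drugs are pinned. Solved greedily
   largest-degree-first with an exact backtracking fallback up to 12
   nodes (patients rarely have more than a dozen concurrently scheduled
   central-venous drugs; beyond that the greedy answer stands). The
   coloring respects *potential* conflicts — incompatible pairs
   overlapping in time on any lumen — because moving two incompatible
   drugs onto a shared lumen would create a new problem. One feasible
   reassignment resolves every pending pair at once and is emitted as a
   single grouped recommendation.
3. **Take a break** — exactly the asymmetric case the step exists for: a
   *pausable* continuous infusion meets a short one. The plan interrupts
   the infusion, flushes, runs the short drug, flushes, resumes; the
   carved windows are the short drug's administrations padded by
   `flush_gap`. Catecholamines are non-pausable by default (interruption
   or the resume bolus has immediate hemodynamic consequences).
4. **Use catheters with more lumens** — the engine searches the smallest
   lumen count admitting a conflict-free assignment and reports it. If
   two conflicting drugs are pinned to the same reserved lumen no lumen
   count can separate them, so as a last resort the pinning is relaxed
   and the recommendation says so.

Fluid-restricted patients (a per-patient flag in the catheter sidecar)
get no flush-adding plans: Steps 1 and 3 become infeasible and the
engine escalates.

Plans are applied *cumulatively* while escalating, so the feasibility of
each step is judged against the schedule as already amended — this is
what makes the engine's guarantee checkable: applying every returned
plan delta leaves the chart with zero incompatible same-lumen
simultaneous pairs, and the suite verifies that on every generated
cohort. Determinism comes from sorted iteration everywhere
(lexicographic by drug name, then lumen index).

## Survey scoring

Knowledge items are scored right/wrong/blank against the keyed verdicts,
with whole-percent half-up rounding. Likert assumption items (0 = never
… 5 = always, with "no answer possible") are summarized as median,
quartiles, min, max; no-answers are excluded from the statistics rather
than scored, and a question nobody answered reports missing values, not
zeros. `reconstruct_counts()` inverts published whole percents back to
counts at a known *n* — with 14 respondents the reconstruction is exact
enough that the per-item counts recover the published grand totals, which
the package uses as a self-test.

## What the generators emulate — and what they do not

`generate_cohort()` emulates one day of an interdisciplinary
critical-care cohort: 3-lumen catheters with a 25% share of 5-lumen
(post-surgery) configurations; a dedicated catecholamine lumen
(continuous noradrenaline) and analgesia lumen (continuous sufentanil);
free lumens carrying successive non-overlapping administration sessions;
about 47% of admitted patients reaching the inclusion criterion;
drugs-per-patient drawn from a discretized log-normal with median 19 and
quartiles ≈ 15.75/23 (sdlog 0.2834) — a fitted summary, not a claim
about the true distribution; and on average 1.25 planted incompatible
pair occurrences per included patient, drawn from the fixture KB's
incompatible set with a randomized mode profile (both short /
continuous-vs-short / both continuous) so that all four avoidance steps
are exercised.

The construction is deliberately *separable*: sessions on one lumen
never overlap, and filler sessions draw only from a clique of drugs the
fixture KB asserts pairwise compatible. Consequently the incompatible
(lumen, pair) occurrences recovered by `analyze_cohort()` equal the
planted multiset exactly, at every seed — that is the generator's whole
point as a test instrument. It is also what the generator does **not**
share with real charts: real schedules have overlapping sessions, pairs
with no evidence either way, documentation errors, and incompatibilities
that are not planted but emergent. Passing the planted-truth suite
therefore demonstrates that the detection and resolution machinery is
correct, not that any particular real-world prevalence would be
reproduced.

Problem sizes in the shipped tests and acceptance script — cohorts of 8
patients over 20 seeds, 200 random lumens against the minute-grid
oracle, exhaustive assignment enumeration up to 8 nodes — were chosen as
the smallest sizes at which every code path (all four steps, both policy
modes, inclusion and exclusion) is exercised on every run.

## Degenerate inputs and numerical corners

* A pair of a drug with itself is an error, never `NO_DATA`.
* Duplicate assertions with identical verdicts collapse; with different
  verdicts they are a hard error listing both rows.
* An empty lumen yields an empty window list; empty findings yield empty
  tables (not errors), and `percent1()` refuses a zero denominator.
* `round_half_up()` adds a tiny offset (1e-9 at the kept digit) so that
  values sitting a binary ulp below .5 still round up; this cannot
  affect any honestly computed ratio at the printed precisions.
* Bolus events are capped at 15 minutes by default; the cap, the flush
  gap, the horizon, and the backtracking limit are all configuration,
  not constants.

## Limitations

The package screens *documented schedules*: it does not model doses,
concentrations, diluents, flow rates, or contact times, and the
knowledge-base format deliberately stores none of these — published
compatibility calls rarely specify them, and pretending otherwise would
suggest a precision the evidence lacks. Peripheral lines and mixing bags
are out of scope. The resolution policy decides from whatever assertions
it is given; it cannot detect that a source is *wrong*, only that
sources disagree. Finally, the command-line interface (`lc_main()`, and
the `inst/scripts/lumencheck` wrapper) is a thin layer over the exported
functions — anything it does is available, and tested, as ordinary R
calls.
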