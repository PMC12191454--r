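---
title: "Methods: association-rule screening and exact disproportionality for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association-rule screening and exact disproportionality for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvmine)
```

## The problem

Spontaneous-report databases such as FAERS collect unsolicited adverse-event
reports for marketed drugs. They have no denominator and heavy reporting
biases, so the standard way to screen them is *relative*: does event Y
appear together with item X more often than the two items' overall
reporting frequencies predict? `pvmine` implements a two-stage version of
that screen for a single drug cohort — here illustrated throughout with
dexmedetomidine, an α2-adrenergic sedative whose signature adverse event is
bradycardia — followed by an optional gene-set enrichment stage for
transcriptomic follow-up of a flagged event.

## Report cleaning

A report enters the cohort when the normalized cohort drug appears in its
suspect product names **or** suspect active ingredients; mentions in the
indication field do not count. Normalization is case-folding plus an
explicit synonym table (`default_synonyms()` maps the hydrochloride salt
and the Precedex brand name onto `dexmedetomidine`); we deliberately avoid
fuzzy matching so that every term mapping is auditable.

Two deduplication rules are applied, in this order:

1. **Literature reports are removed entirely.** A single published case can
   be entered by several reporters under different case IDs, inflating
   joint counts and fabricating disproportionality where none exists.
   Exports mark provenance in the report-source column; any value matching
   a configurable pattern set (default: contains "literature") is treated
   as indirect.
2. **Remaining reports sharing a case ID are collapsed** to the one with
   the latest received date (ties keep the first in input order). Public
   dashboards can surface the same case more than once; latest-wins is the
   conventional choice because follow-up reports supersede initial ones.

Whether a given source applies rule 2 at all is often undocumented; we
apply both because rule 2 is a no-op on exports that are already one row
per case, and the audit log reports the two removal counts separately so
the effect is visible. `deduplicate()` is idempotent and commutes with
cohort filtering for genuine duplicates (duplicates that agree on their
suspect-drug fields), a property the test suite exercises on random sets.

## Rule mining

Each report becomes a transaction whose items are its adverse-event terms
and/or its co-reported drugs. The cohort drug itself is excluded from the
vocabulary: it occurs in 100% of the cohort by construction, so every rule
involving it would be pure noise around lift 1. For a rule X → Y over N
transactions with joint count n(XY):

* support = n(XY)/N,
* confidence = n(XY)/n(X),
* coverage = n(X)/N,
* lift = n(XY)·N / (n(X)·n(Y)).

`mine_rules()` fixes the consequent Y (default `bradycardia`) and
enumerates antecedents of one kind level-wise: a candidate survives only if
its **joint count with the consequent** reaches `min_count`, a quantity
anti-monotone in the antecedent, so supersets of failing sets are pruned
Apriori-style. Survivors are emitted when lift also reaches `min_lift`.
Defaults are `min_lift = 1.5` and `min_count = 10` — a conventional screen
for cohorts of order 10³ reports, where a count of 10 keeps the consequent
marginal estimable and lift 1.5 is far enough from 1 to be interesting.
Antecedents default to single items (`max_antecedent_size = 1`), which is
how drug–drug interaction screening within a cohort is usually read: the
cohort drug is the implicit first partner, the antecedent drug the second.
Rules are ordered by lift, then count, then label; all tie-breaks are
deterministic. Display rounding (support/coverage 4 dp, confidence/lift
3 dp) is applied only by `format_rules()`/`write_rules()`; full precision
is kept internally.

The miner's output is checked against exhaustive subset enumeration on
small vocabularies (≤ 13 items, antecedents up to size 2) in the test
suite, along with lift symmetry, the invariant confidence/lift =
support(Y) across rules sharing a consequent, and threshold monotonicity.

## Why a second stage: exact disproportionality

A lift threshold alone carries no error control: with many candidate items
and small joint counts, lifts well above 1 arise by chance. Each mined rule
is therefore re-tested on its 2×2 table (rows: consequent present/absent;
columns: antecedent present/absent). Conditioning on both margins, the
n₁₁ cell follows Fisher's noncentral hypergeometric distribution with
noncentrality ψ equal to the odds ratio. `odds_ratio()` reports:

* the **conditional MLE** — the ψ at which the conditional expectation of
  n₁₁ equals the observed value — as the point estimate,
* the **exact central CI**: the lower limit solves P(X ≥ n₁₁; ψ) = α/2,
  the upper solves P(X ≤ n₁₁; ψ) = α/2,
* the unconditional cross-product estimate n₁₁n₂₂/(n₁₂n₂₁) alongside, for
  transparency (the two agree within 1% once all cells are ≥ 20).

Roots are found on the log-odds scale by bracketed bisection to a relative
tolerance of 1e-8 — far beyond the 2-dp reporting precision, chosen so that
results are bit-reproducible across platforms. Boundary tables (n₁₁ at the
edge of its support) return 0 or ∞ with the corresponding one-sided
interval; no continuity correction is used because the exact framework
needs none. A table with a degenerate margin (an empty row or column)
carries no information about ψ and returns `NA` with the vacuous interval.
α defaults to 0.05 two-sided, and significance is simply "the CI excludes
1", with no multiplicity adjustment — matching how such validation tables
are conventionally read rule-by-rule. Because that convention is
contestable, `validate_rules(adjust = "BH")` optionally adds exact
two-sided p-values (summing conditional probabilities no larger than the
observed one) with Benjamini–Hochberg control.

The estimator and CI are validated against `stats::fisher.test` (an
independent implementation of the same conditional inference) on random
tables, and the CI's coverage is checked empirically: drawing n₁₁ from the
noncentral hypergeometric at a known ψ = 3 and fixed margins, the 95%
interval covers the truth in ≥ 95% of 400 seeded draws (exact intervals
are conservative).

## Gene-set enrichment

The enrichment stage deliberately starts from a finished gene list:
upstream read alignment, counting and differential-expression testing are
standard tool runs with their own ecosystems, and the statistics a
published pathway table exposes are exactly the ones computed here. For a
list of n genes and a pathway with K genes inside a background of N,
`enrich()` reports fold enrichment (k/n)/(K/N), the hypergeometric upper
tail P(X ≥ k) (computed via the log-space tail of `phyper`), and BH FDR
across all pathways actually tested (those with non-zero overlap — the
tested-set count of external web tools is generally unknowable, so FDR
values are comparable only within one run). Every set is intersected with
the background before testing; the background defaults to the union of the
collection when the user has no better universe, but supplying the actual
assay universe is always preferable. Gene symbols are case-insensitive
strings; no ortholog mapping is attempted.

## The synthetic generator

`generate_exact()` realizes a `cohort_spec` — cohort size N, consequent
count C, and per item a marginal count a and joint count j with the
consequent — such that every configured (item, consequent) 2×2 table is
met **exactly**: consequent-bearing report slots are allocated first, each
item is packed into j of them and into a − j of the remaining slots. This
greedy packing satisfies any spec with j ≤ min(a, C) and a − j ≤ N − C
without integer programming; pairwise joints between two *antecedent*
items are not constrained (they are irrelevant to single-antecedent rules
and to the pair-vs-consequent tables). Slots are shuffled under the seed
so downstream code cannot depend on construction order, and reports that
would otherwise carry no event term are padded round-robin from a fixed
synthetic vocabulary (`ade_001` …) — fillers never co-occur with the
consequent, so they cannot surface as rules. Optional literature
duplicates exercise the deduplication stage.

The bundled spec `table4_table6.json` is the package's worked example: a
1,611-report dexmedetomidine cohort with a 209-report bradycardia
consequent, nine ADE margins and seven drug margins chosen so that every
screening statistic and validation interval lands on realistic, easily
checked values. One deliberate wrinkle is retained: the consequent margin
used by the rules (209) differs from what a raw top-event ranking of a real
dashboard export can show (a nearby count such as 199), because raw event
counts and rule marginals are computed at different stages of cleaning.
`top_items()` therefore reports raw item counts while rule sets carry
their consequent marginal as an attribute — both are visible, neither is
silently reconciled. The companion spec `table8.json` builds a 13,256-gene
background with a 248-gene list and ten pathways realizing fixed overlaps;
13,256 is the smallest universe consistent with all ten of the example's
2-dp fold enrichments.

`generate_stochastic()` samples the same margins instead of packing them:
the consequent is Bernoulli(C/N) per report and each item is drawn
conditionally on it from the configured 2×2 joint, so realized lifts
converge to their targets as N grows (the suite checks the error shrinks
from N = 500 to N = 5,000 and that a null pair stays near lift 1). Both
generators take a single seed and leave the caller's RNG state untouched.

What the generator does **not** emulate: reporting biases, secular trends,
demographic structure, correlated antecedents, and MedDRA term hierarchy.
Passing tests on synthetic cohorts therefore demonstrate the *arithmetic*
of the pipeline — counts, rule statistics, exact inference — not the
epidemiological validity of any particular signal on real data.

## Problem sizes and determinism

The test suite and acceptance script run entirely on generated data: the
1,611-report worked example (seconds end to end), random 25–50-transaction
databases for the brute-force oracles, 400 draws for CI coverage, and
6-replicate stochastic calibrations at N ≤ 5,000 — sizes chosen so the full
suite completes in about a minute on one CPU while still exercising every
code path. All randomness flows through explicit seeds; `run_pipeline()`
reruns are byte-identical, and the exact-marginal statistics are
seed-invariant by construction.

## Known limitations

* Single-consequent, single-direction rules; no conviction/leverage or
  other interestingness measures.
* No PRR, IC/BCPNN or EBGM disproportionality statistics, and no
  stratified or adjusted odds ratios.
* Flat preferred-term strings only; no MedDRA hierarchy traversal.
* The DDI screen is associational: a significant drug antecedent marks a
  co-reporting signal within the cohort, not a confirmed pharmacological
  interaction.
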