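---
title: "Methods: disproportionality, onset, blood-pressure transitions and pan-cancer correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, onset, blood-pressure transitions and pan-cancer correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegfpv)
```

This vignette is the package's own account of its statistical methods:
the models, the tunable parameters and their defaults, the numerical
decisions taken where conventions differ, what the synthetic-data
generators do and do not emulate, and the known limitations.

## Report preprocessing

Spontaneous adverse-event reports arrive either in the FAERS quarterly
`$`-delimited ASCII layout (DEMO/DRUG/REAC/INDI/THER, joined into one
case report per primaryid × suspect drug) or in a simplified flat CSV
dialect (one row per report, reaction PTs joined by `";"`). The
preprocessing chain is:

1. **Deduplication** removes reports sharing identical sex, age (value
   and unit compared verbatim — no unit conversion, which could merge
   non-identical records), country, event date, *sorted reaction-PT
   set*, drug and indication. The set-of-reactions interpretation is a
   deliberate choice: comparing each reaction individually would split
   one report into several dedup decisions. The first occurrence in
   input order is kept, making the operation deterministic, order-stable
   and idempotent.
2. **Malignancy filtering** keeps reports whose indication contains any
   of an editable keyword list (carcinoma, cancer, sarcoma, lymphoma,
   leukemia, melanoma, ...) by case-insensitive substring match. A
   MedDRA system-organ-class mapping would be cleaner but requires a
   license; a keyword list is transparent and auditable. Reports without
   an indication cannot be confirmed malignant and are excluded, counted
   separately in the stage log.
3. **Class assignment** maps normalized drug names (lowercased, trimmed,
   trade-name parentheticals stripped) to VEGFi / VEGFRi / other via a
   configurable catalog. Restriction to primary-suspect reports is a
   config flag: whether concomitant-role reports should be excluded
   entirely or only for counting is genuinely ambiguous in practice, so
   the choice is explicit rather than silent.

## Disproportionality statistics

For a drug (or class) × event pair the 2×2 table is `a` (exposed, case),
`b` (exposed, non-case), `c` (comparator, case), `d` (comparator,
non-case), `N = a+b+c+d`. The comparator universe is everything in the
analyzed report set outside the target set — a within-database
comparison, standard for reporting odds ratios. The statistics:

* `ROR = ad/(bc)` with the Woolf interval
  `exp(ln ROR ± z·√(1/a+1/b+1/c+1/d))`, `z = 1.96`.
* `IC = log2(aN / ((a+b)(a+c)))`, the log2 observed/expected ratio under
  row–column independence, with `IC025 = IC − z·√(1/a+1/b+1/c+1/d)` on
  the log2 scale.
* Signal flag: `a ≥ 3` AND `ROR CI lower bound > 1` AND `IC025 > 0`,
  all strict.

Three numerical decisions deserve comment:

* **Zero cells.** The formulas are undefined at 0, yet pharmacovigilance
  practice reports `ROR = 0` for an unobserved exposed-event cell while
  still quoting a finite (negative) IC. The package therefore reports
  the raw 0 as the ROR point estimate when `a = 0`, and computes CI, IC
  and IC025 on a Haldane–Anscombe +0.5-corrected table whenever any
  cell is zero. The policy actually applied is recorded in every result
  (`zero_cell_policy_used`).
* **IC denominator.** League-table write-ups sometimes print the IC
  denominator as `(a+b)/(c+d)`, which is dimensionally inconsistent with
  an observed/expected ratio and does not vanish at independence. The
  default here is the standard expected-count form `aN/((a+b)(a+c))`
  (IC = 0 exactly when `aN = (a+b)(a+c)`); `literal_ic = TRUE` evaluates
  the league-table variant for auditability.
* **IC025 on the log scale.** The lower bound is additive on the log2
  scale. An exponentiated bound can never be negative, whereas genuinely
  protective or rare pairs need negative IC025 values; the additive form
  provides them.

A consequence worth knowing: the ROR is strictly increasing in `a` with
`b, c, d` fixed, but the expected-count IC is not globally monotone in
`a` (the expected count grows too); only the league-table variant is.
The test suite asserts exactly that.

No multiplicity adjustment is applied to signal flags; the three-part
rule itself is the error control, as is conventional for signal
detection.

**Per-cancer ROR.** Reports are stratified by an indication-derived
cancer type; within each stratum the exposed margin is the inhibitor
classes and the event is the hypertension PT group. Strata with
`a < min_cases` (default 5; "fewer than" is strict, so `a = 5` is kept)
are omitted and listed in an attribute rather than silently dropped.

## Time to onset

Onset is the whole-day difference between event date and the *first*
therapy start date (FAERS has no sub-day resolution; for multi-course
therapy the first start is used, a documented choice). Records with a
missing date or negative difference are excluded and counted; same-day
onsets (0 days) are retained since no lower cutoff is imposed.

Summaries use the linear-interpolation quantile convention
(`stats::quantile` type 7), the default in mainstream statistical
software; all IQRs in the package are under this convention.

Group comparisons are two-sided Mann–Whitney U tests. The U statistic
counts pairs with `x > y` (ties contribute one half). The p-value is an
exact enumeration over all assignments of the pooled values to the two
groups whenever `choose(n1+n2, n1) ≤ 1e5` — this covers every design
with a group smaller than 8 and handles ties exactly — and otherwise the
tie-corrected normal approximation without continuity correction. Two
identical samples give p = 1 by construction. Pairwise drug comparisons
report raw p-values by default (matching reporting practice for
descriptive onset comparisons); Holm adjustment is available by flag.

## Clinical blood pressure

Readings are the maximum systolic with its paired diastolic value before
and after the first dose, validated to the (30, 300) mmHg plausibility
window with systolic > diastolic. Categories follow the European
guideline cutpoints. The printed scheme ("130–139/85–89" versus
"> 140/90") leaves the open interval (139, 140) and (89, 90) formally
unassigned; the package resolves the boundary as hypertension iff
`sbp ≥ 140` or `dbp ≥ 90`, with high-normal covering [130, 140) /
[85, 90), in line with the guideline convention. A patient's category is
the maximum of the systolic-implied and diastolic-implied categories —
the usual reading of "X/Y mmHg" notation.

The pre/post comparison is a Wilcoxon signed-rank test on post − pre
differences (robust, and consistent with median/IQR reporting); a paired
t-test is available by flag. No test is inferred to have been the
original authors' choice — this is a documented package decision.
Transition matrices are 3×3 counts (rows pre, columns post); combining
cohorts is an elementwise sum, associative and commutative, with totals
conserved.

## Pan-cancer enrichment and correlation

`fpkm_to_tpm` rescales each sample column to sum to 10^6 (TPM is a
per-sample renormalization of FPKM). `ssgsea_score` implements the
single-sample enrichment statistic: within each sample, genes are ranked
by expression (average ranks for ties), the list is walked in decreasing
expression order, and the score is the *integrated* difference between
the weighted ECDF of in-set genes (weights `rank^α`, normalized) and the
uniform ECDF of out-of-set genes. Decisions:

* `α = 0.25`, the conventional ssGSEA weighting; configurable.
* Integrated statistic by default (`stat = "max_dev"` switches to the
  maximum deviation), matching the single-sample method family rather
  than the permutation-based two-group original.
* Ties that span the in/out-set boundary are broken by gene order when
  building the running sum (the average-rank *weights* are unaffected);
  with continuous expression values ties are measure-zero.
* No cross-sample normalization by default — the score is a
  single-sample contract; a min-max rescaling across samples can be
  applied downstream if desired.

Scores are aggregated to one value per cancer type by the arithmetic
mean (the aggregation statistic is not dictated by the method; the mean
is the documented choice), then correlated with the per-cancer ROR by
Spearman's rank correlation (Pearson on average ranks, hence
tie-corrected). The two-sided p-value uses the t-approximation
`t = ρ√((n−2)/(1−ρ²))` for `n ≥ 10` cancer types and the exact
permutation distribution (all `n!` arrangements) below; at least 4
shared types are required for any p-value.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their configs (seed included) and
return truth records sufficient to compute expected values of every
downstream statistic without re-reading the data.

* **Reports** (`simulate_reports`): a drug mix dominated by the focal
  inhibitors over a background of oncology and non-oncology drugs;
  per-report PT-group assignment whose odds are scaled by planted
  relative rates (so a planted value of 8 is a planted reporting odds
  ratio of 8 against baseline); malignant-indication fraction 0.6 over
  a weighted cancer-type pool with two deliberately rare types (to
  exercise minimum-case exclusions); 5% injected duplicates that copy a
  source report's full dedup key; 20% missing therapy dates; log-normal
  time to onset with class medians 59 days (VEGFi) and 21 days (VEGFRi)
  and log-sd 1.6, the right-skew implied by median–IQR spreads of
  roughly 21 [7–66] and 59 [21–171] days.
* **Clinical cohort** (`simulate_clinical`): cohort sizes 1087 (VEGFi)
  and 529 (VEGFRi); pre-treatment (sbp, dbp) bivariate normal with
  means 128/78 and 125/77 mmHg, sds 15/10, correlation 0.6, truncated to
  the plausibility window by rejection; additive post shifts +12/+2
  (VEGFi) and +7/+4 (VEGFRi) mmHg with noise sds 8/5. The truth record
  carries the expected 3×3 transition probabilities computed by grid
  quadrature over the pre-treatment density (truncation ignored — its
  mass is negligible at these means).
* **Expression** (`simulate_expression`): 24 cancer types × 4 samples,
  600 genes, disjoint 25-gene sets; the per-cancer ROR is log-normal
  spanning roughly 2.4–18; each pathway's type-level activity is
  *rank-planted per dataset*: a permutation is constructed by accepted
  pair swaps until its sample Spearman correlation with the ROR ranks is
  within 0.015 of the planted ρ (defaults −0.38, −0.66, +0.39, −0.44).
  Per-dataset planting, rather than drawing from a population copula,
  makes the planted correlation a property of every generated dataset —
  at 24 types an iid copula draw would leave the realized sample
  correlation fluctuating with sd ≈ 0.21, swamping the quantity the
  recovery tests are supposed to probe.

What the generators do **not** emulate: MedDRA vocabulary structure and
PT granularity, FAERS case versioning across quarters, reporting-source
and notoriety biases, time trends in reporting, antihypertensive
co-medication, correlated gene-gene expression structure beyond the
planted sets, and batch effects. Passing recovery tests therefore shows
that the estimators recover what was planted under a clean mechanism —
it does not certify performance on real FAERS or TCGA data.

## Problem sizes and numerical tolerances in the test suite

The suite verifies the closed-form statistics against independent
brute-force evaluation on all 2×2 tables with cells 1–50 (relative error
below 1e-12), interval coverage on 2000 multinomial draws of size 5000,
signal-rule behavior over 100 seeds at 10,000 reports per run (null
planted odds 1; alternative planted odds 8), onset-median recovery at
roughly 1400 records per class, shift recovery at 5000 patients, and
sign recovery of planted pathway correlations over 100 seeds at 24
cancer types with 200 genes and 4 samples per type. These sizes were
chosen so each property has clear statistical resolution while the whole
suite stays quick to run.

## Limitations

* The keyword-based malignancy filter approximates, but is not, a
  MedDRA SOC classification.
* Disproportionality measures reporting association, not incidence or
  causation; the package inherits every limitation of spontaneous
  reporting.
* The exact Mann–Whitney path enumerates combinations and is only used
  below `choose(n1+n2, n1) ≤ 1e5`; the approximation boundary is
  visible in the returned `method` field.
* Hypertension grading beyond the three guideline categories, censoring
  or competing-risk onset models, and Bayesian shrinkage estimators
  (EBGM, full BCPNN posteriors) are out of scope.
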