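---
title: "Prioritizing germline panel variants in familial prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing germline panel variants in familial prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prcapanel)
```

## The problem

Early-onset and familial prostate cancer (PrCa) has a clear heritable
component, but the known predisposition genes (HOXB13, BRCA2, mismatch
repair genes) explain only a small minority of cases. Panel sequencing of
many cancer predisposition genes across a selected cohort produces
thousands of raw calls per patient; the scientific content of such a
study lies almost entirely in the *prioritization policy* — which calls
are trusted, which are rare enough to matter, which are predicted
deleterious, and how carriers are counted against the cohort's
family-history structure. prcapanel implements that policy as a tested,
auditable pipeline, so that the same rules can be re-applied, perturbed,
or criticized.

## The pipeline and its assumptions

### Filter cascade

Five conjunctive rules, each with the boundary semantics stated by its
phrase: coverage strictly greater than 20 reads; alternative allele
fraction within the inclusive band [0.30, 0.70] (germline heterozygous
calls cluster near 0.5; values outside the band suggest mosaicism or
artifact); minor allele frequency at most 0.1% (inclusive), taken as the
*maximum* over the available reference databases — a variant common in
any one population is not rare; in-house cohort frequency strictly above
10% excluded (recurrent platform artifacts and local polymorphisms);
synonymous variants and intronic variants strictly more than 12 bp from
an exon-intron boundary excluded; and variants asserted benign or likely
benign by any clinical database discarded. Two deliberate asymmetries:
*missing* annotations never remove a variant (absence of evidence is kept
for review, matching the retention of database-absent variants), and
conflicting or VUS assertions are kept.

Because the rules are conjunctive, the kept set is invariant to filter
order; the test suite checks this over all 120 orderings. The audit
table records every removal with the first failed rule, so
`|input| = |kept| + |audit|` always holds.

Calls from multiple aligner/caller combinations are merged by *union*
with per-caller provenance recorded. The alternative (intersection, or a
2-of-3 vote) is stricter but silently discards caller-specific
sensitivity; with union, the support level remains visible in the
`caller_set` column for manual review.

### Predictor consensus

Missense variants are promoted to the "potentially pathogenic" tier when
at least 12 of the 15 in-silico predictors call them pathogenic and at
least three of those are conservation tools. Missing predictor output
counts *against* qualification: the denominator stays fixed at 15. An
alternative mode (`consensus_denominator = "available"`) rescales the
majority to the non-missing tools; it is off by default because a
variant scored by only a handful of tools should not qualify on thin
evidence. Where only percentile-normalized rankscores are available, a
call is pathogenic at rankscore ≥ 0.5 (per-tool cutoffs configurable);
rankscores are percentile-normalized to [0, 1], so 0.5 is the natural
exchangeable default, but it is a package decision, not a property of
the tools.

Splice-region variants qualify at 3 of 4 affected calls, or — at weaker
predictor support — when a clinical database already asserts the variant
(likely) pathogenic; a database assertion is treated as corroborating
evidence equivalent to the missing predictor majority. In-frame indels
are unclassified unless asserted pathogenic (the incidental-finding
route).

The consensus rule is checked against a brute-force counter over all
2^15 binary profiles, and single-call promotions (benign → pathogenic)
are property-tested never to disqualify a variant.

### ACMG-AMP engine

The engine implements the standard combining rules over the 28 evidence
codes. Three behaviors matter for reproducing panel-study practice:

* **Conflict rule.** The verdict is VUS only when a *complete*
  pathogenic-side rule and a *complete* benign-side rule fire
  simultaneously. A lone supporting-benign code (e.g. BP1 next to
  PS4 + PM1 + PM2 + PP3) does not block a likely-pathogenic call. This
  matches the behavior of the widely used automated interpreters.
* **Manual overlay.** All codes except PS4 are inputs — automated
  criterion assignment from raw annotations is out of scope. Manually
  curated codes (PS3 from published functional studies, PS4 from the
  case-control comparison) are overlaid as a provenance-tracked union,
  idempotently.
* **PS4.** `evaluate_ps4()` requires a two-sided Fisher p below alpha
  *and* a case carrier fraction above the control fraction, so
  significant depletion can never fire PS4.

PP5/BP6 (reputable source) are accepted for fidelity to existing
datasets even though later guidance deprecates them. Variants with no
evidence codes at all (e.g. entries recorded "N/D") are left
undetermined rather than defaulted to VUS.

The engine is verified by exhaustive agreement with an independent
rule-table oracle over every evidence set of size ≤ 6 (about half a
million sets).

### Case-control tests

Carrier-level 2x2 tables (individual resolution) are used against
genotyped control panels; allele-count tables are used against reference
populations where only aggregate allele counts exist. The two-sided
Fisher exact p is the conventional minimum-likelihood sum, delegated to
`stats::fisher.test` and verified against a from-scratch hypergeometric
enumeration for every table with N ≤ 60. No multiplicity adjustment is
applied anywhere — deliberately, to match how such screens are reported;
users scanning many features should adjust downstream.

### Family-history criteria and accounting

The six eligibility clauses are implemented literally, with two
interpretive decisions documented here because the clause wording is
open:

* Age averages ("average age at diagnosis ≤ 65", "three younger cases")
  are computed over the affected set *including the index case*; "the
  three youngest" means exactly that, index included.
* A1's "three first-degree relatives" is counted exclusive of the index
  (a flag flips to the inclusive reading).
* B3's "relatives with early-onset and/or rare cancer types and/or
  clustering of other cancer types" fires on: a non-prostate relative
  diagnosed at or before 45; a relative with a rare type (bilateral
  breast, male breast, brain); or at least two relatives with cancers
  from the clustering list (breast, colon, gastric). Prostate cancer in
  relatives never triggers B3 — familial PrCa aggregation is the A
  group's domain. The 45-year bound for relatives is deliberately
  stricter than the 55-year bound defining an early-onset index case:
  family-history clauses B1 (which already absorbs relatives diagnosed
  in their early fifties through its average-age condition) and B3 would
  otherwise be nearly redundant, and "early-onset" for the mostly
  breast/colorectal cancers seen in relatives conventionally means
  forty-something. Both lists and both bounds are arguments of
  `classify_criteria()`.
* "Early-onset" for the index case means diagnosis at or before 55;
  B1's "before the age of 56" is the same bound.

Carrier accounting applies two exclusions before counting: missense
variants in mismatch-repair genes whose matched tumor
immunohistochemistry shows retained protein expression (the variant then
has no somatic correlate arguing for causality), and variants flagged as
incidental findings (clinically reportable but unrelated to the
phenotype). A patient stays a carrier if another qualifying variant
survives. When a carrier holds several qualifying variants, one gene is
attributed: truncating beats missense, then smaller case-control p, then
alphabetical order. Reported percentages round to one decimal, ties away
from zero.

## The fixture cohort and what it can show

`load_fixture_cohort()` rebuilds a 121-patient cohort around the two
published variant tables: 19 carrier patients with their variants,
criteria flags, ACMG codes, IHC flags and control-panel counts, plus 102
deterministic filler patients whose family structures realize the
printed marginals (45 group A, 86 group B, 10 dual, 64 early-onset).
Several details are synthetic placeholders, clearly marked in the code:
indel REF/ALT alleles, the genomic position of the incidental MSH6
in-frame deletion, pedigree ages beyond the published narratives, read
depths/VAFs, and the predictor rankscore profiles (encoded so that every
tabulated missense variant qualifies, 13/15 by default). Consequently,
end-to-end tests on the fixtures demonstrate that the *rules* reproduce
the published accounting from the published inputs — they say nothing
about variant calling, annotation accuracy, or predictor behavior on
real data, all of which are upstream of this package.

## The simulator and what it does not emulate

`simulate_cohort()` draws family-history personas from per-clause
weights (defaults approximate the study composition: roughly 37% group
A), plants one recurrent qualifying missense variant per gene at the
configured carrier frequency, perturbs predictor calls with a
configurable flip probability, and attaches a clean control panel.
`simulate_predictor_matrix()` generates rankscore matrices with known
ground-truth qualification and returns the flip log so recovery accuracy
can be recounted independently. Fixed seeds give byte-identical output.

The simulator does not emulate: sequencing reads or base quality, linkage
between variants, relatives' genotypes, population stratification in
controls, or correlated predictor errors (flips are independent, while
real predictors share training data and fail together). Recovery tests
calibrate the pipeline's bookkeeping, not the biology.

## Numerical and scale choices

Problem sizes used by the test suite were chosen to exercise each
property at full coverage where the space is small (2^15 predictor
profiles; all ACMG sets of size ≤ 6; every 2x2 table with N ≤ 60) and at
seeded sampling elsewhere (10^4 monotonicity probes, 1000-replicate null
simulation for the clinicopathological screen at n = 500, carrier
recovery at n = 2000 against a 3-binomial-SE band). The exact null
rejection rate of a Fisher test sits slightly below nominal alpha by
discreteness; the acceptance band allows for that conservatism.

## Known limitations

* The ACMG engine combines codes; it does not derive them (except PS4).
  Groups using automated interpreters should feed those codes in and
  overlay manual evidence explicitly.
* Carrier-mode control comparisons assume one genotyped individual per
  count; allele-mode exists for reference populations, and both are
  exposed so supplementary genotype tables can be slotted in when
  available.
* The criteria classifier trusts the relative table; it cannot detect
  under-reported family history, and clauses whose ages are missing
  evaluate false (with a warning) rather than guessing.
* Attribution picks exactly one gene per carrier; for genuinely
  ambiguous double carriers both the raw and attributed per-gene counts
  are reported.
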