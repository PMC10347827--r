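---
title: "Auditing variant-classification accuracy over time: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing variant-classification accuracy over time: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classaudit)
```

## The audit in one paragraph

Highly penetrant recessive and X-linked disorders — the motivating panel
is newborn-screened inborn errors of metabolism, with an aggregate
incidence near 1 in 3200 — are rare enough that a healthy adult reference
cohort of a few thousand individuals should contain *less than one* truly
affected member (`expected_affected(2504, 1/3200)` = 0.78). Any
individual in such a cohort who is homozygous, hemizygous, or compound
heterozygous for variants a database classifies as pathogenic is
therefore very likely a database false positive. Counting these
*indicated affected* individuals across dated database snapshots turns a
classification database into a measurable time series: specificity over
time, ancestry skew of the errors, and the rate at which variants are
recategorized.

## Category ladders and harmonization

ClinVar-style snapshots are harmonized onto a 10-level ladder: four B/LB
star levels, VUS, Conflicting, four P/LP star levels
(`clinvar_ladder()`). Archive-1.0 snapshots carry per-submission numeric
codes (0 VUS, 2 B, 3 LB, 4 LP, 5 P); a variant whose submissions span two
or more of the groups {B/LB}, {VUS}, {P/LP} is inferred Conflicting
(`infer_conflicting()`), otherwise the single group's strongest assertion
wins (P over LP, B over LB). Archive-2.0 snapshots carry one aggregate
label; comma-joined multi-labels resolve only when exactly one component
is a recognized category ("Pathogenic,_risk_factor" is P;
"Pathogenic,Benign" is unmapped and skipped). Review statuses group to
0 / 1 / 2+ stars per dialect; "2+" (including expert panel) is stored
as 2. HGMD-style snapshots use the 5-level ladder DM > DM? > DFP > DP >
R; a variant with several labels takes the most severe.

Two harmonization decisions deserve emphasis:

* **The review-star reliability boundary (2015-06-15).** Star annotation
  in archive-1.0 files before this date is inconsistent, so stars are
  stored as missing there: such records cannot be placed on the
  star-resolved ladder, are excluded from star-dependent set selection,
  and contribute no recategorization events or variant-months. The
  boundary doubles as the archive-1 to archive-2 cutover in the synthetic
  generator and is configurable (`cutover`). For real archive-1.0 data
  where stars were curated by hand, a per-variant `star_override` table
  can assert them.
* **Variant identity.** Keys are minimal left-aligned
  (chrom, pos, ref, alt) tuples (`normalize_variant()`), multiallelic
  records are split, and somatic-only or null-alt records are dropped, so
  databases, cohort and frequency tables join exactly.

## Variant sets

Four audited sets, per snapshot date (`select_variant_set()`):
*Select ClinVar* — Pathogenic with ≥ 1 star and no VUS/B/LB submission
with ≥ 1 star (evaluated at submission level where the dialect provides
it; an aggregate Conflicting always excludes); *Full ClinVar* — P or LP,
Conflicting excluded; *Select HGMD* — DM; *Full HGMD* — DM or DM?.
Select ⊆ Full holds by construction and is property-tested.

## Genotype scan

`detect_affected()` requires phased genotypes: a compound heterozygote is
two *distinct* same-gene variants on *opposite* haplotypes (alt|ref at
one, ref|alt at the other); two variants in cis are not a pathogenic
genotype. Unphased genotypes are skipped with a warning by default
(`unphased = "error"` makes them fatal) — no unphased presumption is
applied. Hemizygous calls are males with any alt allele in an X-linked
panel gene; male X genotypes in phased panels are commonly coded diploid
(1|1), so sex comes from the sample sheet, not ploidy. Females homozygous
in an X-linked gene count as homozygous. Pseudoautosomal regions are not
modeled. One call is emitted per (sample, gene) with the most specific
mechanism (hemi over hom over comphet); an individual affected in several
genes counts once in totals. BA1 filtering precedes detection, so both
partners of a compound heterozygote must individually survive the filter.

Yearly figures report the *maximum* count of distinct indicated-affected
individuals over the year's snapshots, and the false-positive rate is
affected individuals per 1000 cataloged set variants (1 decimal).

## Frequency filters and ancestry assignment

Population MAFs below the floor `1/(2·min N)` — one allele in the
smallest population; 6.152e-5 for the default gnomAD v2.1 exome
continental sizes — are set to zero before any use, equalizing resolution
across unequally sized populations. BA1-2015 removes variants with global
MAF strictly above 5% in any configured reference dataset; BA1-2018
instead checks the continental populations of the aggregation dataset
(gate: ≥ 2000 alleles, configurable — the published rule's "additional
constraints" beyond allele count are not enumerated and not modeled).
Both thresholds are strict (`>`), because the guideline text reads
"MAF > 5%": a variant at exactly 5% is kept. On any table whose globals
are weighted means of its populations, the 2018 removals are a superset
of the 2015 removals (pigeonhole; property-tested). Each variant's
principal ancestry is the argmax of floored population MAFs; all-zero
variants are excluded from ancestry analyses; exact ties resolve to the
lexicographically first label and are logged.

## Exact statistics

Ancestry-composition tests follow the published protocol: an r×2 omnibus
of affected counts against cohort composition — Pearson chi-squared
*only* when every expected count exceeds 40, otherwise the exact
conditional test (`fisher.test`'s network algorithm for totals up to
5000, a fixed-seed Monte Carlo estimate with 10^6 resamples beyond) —
followed, when the omnibus is nominally significant (p < 0.05), by
one-sided per-population 2×2 tests of `[affected_pop, affected_rest;
cohort_pop, cohort_rest]`. This 2×2 construction — population totals, not
affected-excluded complements — is inferred from arithmetic on the
published odds ratios rather than stated protocol, and the package
documents it as such. Odds ratios are conditional MLEs with exact
two-sided confidence intervals; two-sided 2×2 p-values use the
probability-mass criterion. Every test performed is appended to a test
ledger, and the Bonferroni threshold is `0.05 / ledger$n` — the published
222-test count is an input one can reproduce (`bonferroni(0.05, 222)` =
2.25e-4, printed as 2.2e-4), never a hard-coded constant. Zero-height
bars are not tested. Because the exact CI solves discrete tail equations,
it does not collapse to a point as the level shrinks; tests assert
shrinkage and bracketing of the MLE, not collapse.

## Recategorization and variant-months

Snapshot series are downsampled to one representative per calendar month;
the default representative is the *last* snapshot of the month
(configurable: first | last | nearest-to-month-end — the choice is a
package decision, since only "approximately monthly" is specified).
Events are adjacent category changes on that grid. Removal emits nothing;
re-entry under a new category emits one event from the pre-removal
category (flagged); a variant's first placement is not an event; ClinVar
events before 2015-06-15 are not counted. A *reclassification* is an
event that crosses major tiers (P/LP vs VUS/Conflicting vs B/LB);
star-only moves are recategorizations. VUS and Conflicting are adjacent,
unordered levels: moves between them have confidence change "neither",
while direction always follows the ladder-index sign. Confidence
*increases* from VUS/Conflicting to any P/LP or B/LB level and
*decreases* on the reverse.

Exposure is measured in variant-months: a month contributes one unit per
variant classified in a filter category that month (2 variants × 1 month
= 1 variant × 2 months = 2). Partition conservation — summing
variant-months over a partition of the ladder equals total classified
variant-months — is property-tested. Rates divide events of a confidence
class by the variant-months of the *source* categories; intervals are
Wald, `p ± 1.96·√(p(1−p)/n)`, clipped at 0. Cross-ancestry comparisons
use the same omnibus/pairwise exact machinery on
`[events, variant-months]` tables. For cross-database comparisons an
option collapses ClinVar star levels (`collapse_star_levels()`) onto a
star-less ladder comparable with HGMD.

## The synthetic-data generator

`gen_study()` composes the four generators under one master seed (derived
per-artifact seeds are recorded in the ledger) and emulates the study
conditions: a 2504-sample phased cohort in the reference five-ancestry
composition (661/347/504/503/489), monthly ClinVar-dialect snapshots
2014-04 through 2020-12 spanning the dialect cutover, three HGMD archive
dates, and gnomAD-shaped frequency tables. The default planted-affected
composition mirrors the audited Select-HGMD 2014 pattern: 37 individuals,
25 of African ancestry, none European, across all three mechanisms.
Background pathogenic-classified alleles are sprinkled as *isolated
heterozygotes only* (default 0.01 per sample-gene, at most one variant
per sample per gene, never in males for X-linked genes), so non-planted
samples can never form a pathogenic genotype and the ledger is exact.
Sample sex is drawn at 0.5 (configurable — reference-panel sex ratios per
population are taken as configuration, not data). Planted BA1 variants
trip the rules through the emitted table's own arithmetic, computed in
the generator independently of the filter implementation.

What the generator does *not* emulate — real linkage structure, site
spectra, submission-record richness, weekly archive cadence, condition
vocabularies — bounds what green tests mean: they certify the pipeline's
bookkeeping (recovery of planted truth, invariants, exact statistics),
not robustness to the full messiness of real archives. The ingest surface
(dialect maps, condition filter, star overrides, normalization against a
reference FASTA) is exercised on constructed corner cases instead.

## Problem sizes and numerical choices

The test suite runs the full pipeline at two scales: micro fixtures
(tens of samples) for oracle equivalence against quadratic brute-force
scanners and enumeration oracles (every 2×2 table with total ≤ 30; small
5×2 tables against full fixed-margin enumeration), and a
250–2504-sample study for end-to-end ground-truth recovery; the
acceptance script runs the full default study. Exact-test tolerances are
1e-7–1e-9 against enumeration; the Monte Carlo fallback is fixed-seed
(20150615) and method-labelled, so downstream consumers can tell which
path produced a p-value. Flooring, assignment and set selection are
deterministic and order-independent; generator output is byte-identical
under a fixed seed.

## Known limitations

* The exact per-figure enumeration behind the published 222-test count
  cannot be reconstructed; the ledger-driven count is the principled
  substitute, and thresholds therefore depend on which bars a given run
  tests.
* Manual star re-assessment of early archive-1.0 hits is inherently
  non-algorithmic; the star-override table is the hook for it.
* Ancestry assignment is fixed per run (one frequency-table version); a
  variant whose assignment would drift across frequency releases keeps
  its single assignment.
* The incidence side of the audit stops at the expected-affected
  baseline; no incidence inference is attempted.
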