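---
title: "Family-based mitochondrial genome analysis with mitofam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based mitochondrial genome analysis with mitofam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofam)
```

## The problem

Every cell carries hundreds to thousands of copies of the 16,569-bp
mitochondrial genome, so different sequence variants can coexist within one
individual (*heteroplasmy*), measured as the fraction of sequencing reads
carrying the alternative allele. Deep amplicon sequencing of families — both
parents, affected children, and unaffected siblings — makes three kinds of
questions tractable:

1. **Population structure.** Which mtDNA haplogroup does each family line
   carry, and do haplogroup frequencies differ between case lines and a
   control population?
2. **Rare variation.** Which variants are *private* (not part of the
   carrier's haplogroup-defining motif), and which of those have pathogenic
   potential?
3. **Transmission.** Which low-level heteroplasmies in a child are absent
   from the mother's blood — putatively *de novo* — and at what per-site,
   per-transmission rate do they arise?

`mitofam` implements this pipeline end to end, together with the
family-matched statistics used to relate the molecular measurements to a
dichotomous diagnosis and to a clinical severity grading, and a seeded
synthetic cohort generator so every stage is testable without any external
download.

## Consensus heteroplasmy calling

Candidate site calls (per sample, possibly from up to three callers) pass
through four filters, each contributing a reason code
(`apply_site_filters()`):

* mean base quality ≥ 20 and mean mapping quality ≥ 20;
* **mono-allelicity**: a position with two alternative alleles, each above
  `mono_allelic_floor`, is rejected. The floor (default = the 0.2% detection
  floor) exists because at several-thousand-fold depth essentially every
  position shows trace levels of all four bases; without a floor the filter
  would reject everything;
* **strand bias**: the strand odds ratio (`compute_sor()`) with a
  pseudocount of 1 on each of the four strand-split counts,
  $R = \frac{r_1 a_2}{r_2 a_1} + \frac{r_2 a_1}{r_1 a_2}$, $\mathrm{SOR} =
  \ln R + \ln\frac{\min(r_1,r_2)}{\max(r_1,r_2)} -
  \ln\frac{\min(a_1,a_2)}{\max(a_1,a_2)}$, rejected above 4. The formula is
  frozen in the package (rather than delegated to an external toolkit) so
  results do not depend on tool versions; calls lacking strand-split counts
  skip this filter with a warning rather than failing;
* zero-depth sites fail `no_coverage`.

`consensus_merge()` then keys calls by `(position, alt allele)` and retains
those supported under the configured rule. The default is the most
conservative reading, `strict_intersection` (all supplied callers);
`majority` (≥ 2 of 3) is available because the source analyses describe "a
consensus" without defining it — we implement both and claim neither as
canonical. The merged heteroplasmy fraction is the median across supporting
callers, which always lies inside their range.

Samples whose contamination report shows a level **strictly above 1%**
together with a positive "used minor heteroplasmies" count are excluded
from all low-level heteroplasmy analyses but retained for haplogroup
assignment (`contamination_gate()`), since percent-level contamination does
not perturb major-allele calls.

## Haplogroup classification

`classify_from_markers()` types a sample against a fixed diagnostic marker
panel (23 clade markers plus three U5a/U5b refinement markers; see
`default_marker_panel()`), arranged as a forest. A clade is *matched* when
all of its markers are typed with the marker allele and *blocked* when any
is typed otherwise; the call is the deepest clade whose path contains no
blocked ancestor. Untyped ancestors do not block, because array-style
panels rarely type every backbone position. The shared marker 3010A is
context-dependent: it defines J1 under a matched J and H1 under a matched
H, and carries no evidence otherwise.

Design choices the marker data do not determine by themselves:

* **Tie-breaking.** Candidates are ranked by matched-marker count, then
  matched-clade count, then context-dependent refinements first. The last
  key makes a genotype carrying 2706A, 1438A and 3010A resolve to H1 rather
  than its equally deep sibling H2: the context-resolved refinement encodes
  strictly more information (its match required the parent context). A
  residual tie between incompatible branches yields `undetermined` with the
  branches listed as conflicts.
* **Conflicts.** Matched clades incompatible with the winning path (caused
  by, e.g., cross-sample contamination) are reported, not silently ignored;
  the winning branch is the one with more matched markers.
* A U5 sample without its refinement markers stays at the `U5a'b` level and
  is counted under U in haplogroup-level reports.

Super-haplogroup aggregation (`super_haplogroup()`) follows the reporting
scheme of the frequency tables: H clades → `H`, J/T clades → `JT`, U/K
clades → `UK`, everything else (including HV/HV0) → `Others`. The `H*` and
`U*` buckets ("all H clades except H1…", etc.) are report-time aggregations
(`haplogroup_frequency_table()`), not classifier labels.

## Private-variant triage

For each sample, consensus variants partition into exactly one of three
streams (`partition_private()`): *haplogroup-defining* (on the sample's
marker path), *private* (off-path, heteroplasmy **strictly above 15%** —
the threshold below which even a confirmed pathogenic variant is unlikely
to express phenotypically in blood), and *low-level* (≤ 15%, routed to the
heteroplasmy module). A variant at exactly 15% is low-level.

Pathogenic potential (`classify_pathogenicity()`) is assessed from a
user-supplied annotation table: `confirmed_pathogenic` iff the MITOMAP
status is "confirmed"; otherwise `predicted_deleterious` iff the variant
has never been observed in GenBank (`genbank_count == 0` — a count in the
supplied table, never a live query, for version independence) *and* its
class-appropriate predictors clear their thresholds (missense: CADD
Phred > 20 **and** MToolBox score > 0.43; tRNA: MitoTip raw > 12.66, all
strict). Every `not_flagged` verdict names its first failed criterion.

`complex_burden()` tabulates private missense (or predicted-pathogenic)
variants per OXPHOS complex (MT-ND\* → CI, MT-CYB → CIII, MT-CO1/2/3 → CIV,
MT-ATP6/8 → CV, frozen in `mt_gene_map()`), deduplicated **per family
line**: a variant shared by a mother and her children is one observation
for that maternal line; the same variant in another family counts again.

## De novo heteroplasmy and the mutational rate

Low-level variants are binned on the percent scale
(`bin_heteroplasmy()`): coarse regression classes 15%–5% (`[5,15]`),
4.9%–1%, 0.9%–0.5%, 0.4%–0% (lower-closed, upper-open, topmost closed),
and fine 0.1%-wide classes up to 5% plus a single 5–15% class for
profile plots.

A child variant is putatively de novo (`detect_denovo_mtdna()`) when its
fraction lies in `[0.002, 0.15]` and the same `(position, alt)` is not seen
in the mother **at or above the 0.2% floor**. "Not inherited" is
operationalized against the detection floor, not literal absence —
sequencing cannot certify a zero — and a different alternative allele at
the same position in the mother does not count as inheritance. Each child
with a sequenced mother forms one mother–offspring pair, so a multiplex
family contributes several pairs.

The mutational rate is `n_denovo / (n_pairs × 16,569)` substitutions per
site per transmission (`mutational_rate()`), with an optional seeded
nonparametric bootstrap over pairs (1,000 resamples) for a percentile CI —
an addition beyond the point estimates the field usually reports.

The nuclear counterpart (`filter_nuclear_dnm()`) applies the standard
trio high-confidence filter: both callers must support the call; DP ≥ 12
and GQ > 20 in all three members; child allele balance in `[0.30, 0.70]`;
parents homozygous reference, child heterozygous; and a population-
frequency filter. The filter's published description is ambiguous about
direction ("excluding all sites … with a MAF < 0.1%" would drop *rare*
sites); the default here follows standard de novo practice and excludes
sites with MAF ≥ 0.1%, with the direction configurable.

## Cohort statistics

* `bh_adjust()` is an in-package Benjamini–Hochberg step-up
  ($q_{(i)} = \min_{j\ge i} m\,p_{(j)}/j$, capped at 1), kept in-repo so it
  can be checked against independent implementations; significance is
  declared at q < 0.10.
* `frequency_compare()` tests one category's presence between two groups in
  a 2×2 table; `auto` uses Fisher's exact test when any expected cell is
  below 5 and the chi-square test (no continuity correction) otherwise —
  the sources say "chi-square/Fisher's exact" without stating the switch,
  so the standard expected-count rule is adopted. q-values are adjusted
  **within each taxonomic level** (super-haplogroup rows together,
  haplogroup rows together, sub-haplogroup rows together) by default; the
  published tables do not state their correction family, so exact
  reproduction of published q-values is not claimed.
* `content_compare()` uses the two-sided Mann-Whitney test for two groups
  and Kruskal–Wallis with an in-package Dunn post-hoc (rank-sum z with tie
  correction; no pre-installed package provides Dunn's test) otherwise. A
  normality screen (in-package D'Agostino–Pearson omnibus, Shapiro–Wilk,
  Lilliefors) is reported as advisory only.
* `fit_conditional_logistic()` implements the **exact stratum-conditional
  likelihood** by subset enumeration (families are small), maximized with
  BFGS and analytic gradients; SEs come from the analytic observed
  information. Conditioning on the family eliminates everything shared
  within it, including the maternal haplogroup, which is why
  family-constant covariates are dropped (with a warning) rather than
  estimated. The implementation is in-repo so it can be cross-checked — the
  test suite verifies exact agreement with `survival::clogit`'s exact
  partial likelihood, which is never itself the implementation. Complete
  separation is flagged and the covariate reported non-estimable.
* `fit_mixed_logistic()` fits a family-random-intercept logistic GLMM via
  `lme4::glmer` for the severity outcome ("mild" and "moderate" aggregated
  against "severe", because the mild class is small). The
  likelihood-ratio statistic against the plain logistic model halves the
  chi-square(1) tail (boundary-variance null). Non-convergence is reported,
  never silently replaced. The conditional model's "LR vs plain logistic"
  diagnostic compares non-nested likelihoods and is labelled advisory; it
  mirrors the comparison style of the source analyses.
* Pseudo-R² is McFadden's (the sources report an unnamed R²; the flavour is
  labelled in the output).
* `stepwise_select()` ranks candidates by ascending univariable p, enters
  those with p < 0.2 one at a time, and retains each only while its
  multivariable p stays below 0.2, recording the full decision trace.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the pipeline assumes:

* 98 families by default, with exactly `round(n × simplex_fraction)` = 73
  simplex (one affected child) and the rest multiplex (two); unaffected
  siblings Poisson with mean 59/98. Proband sex is male with probability
  93/117, matching the cohort's composition.
* Haplogroups drawn from the control-population distribution **aggregated
  onto panel-resolvable labels**: clades the marker panel cannot
  distinguish (H3/H5, U1–U4, W, X, R0a, HV) are folded into their nearest
  resolvable ancestor so classifier round-trips are exact by construction.
* Mean coverage 16,718× (Poisson per site), the stated deep amplicon
  coverage of the emulated design; alt-read counts are binomial in the true
  fraction with a configurable strand skew (`simulate_site_counts()`).
* Mothers carry Poisson(3) shared low-level heteroplasmies with
  Beta-distributed fractions (mean ≈ 1%, floored at 0.4% so that true
  events sit inside the detectable window); children resample them through
  a binomial bottleneck of 200 effective segregating copies. No
  distributional form for either is established in the literature we
  emulate — both are explicit, configurable placeholders.
* De novo variants per transmission are Poisson(μ × 16,569), default
  μ = 1.5 × 10⁻⁴, with log-uniform fractions on `[0.003, 0.145]` — away
  from the 0.2% floor and the 15% ceiling so binomial observation noise
  cannot move true events across the window boundaries one-sidedly.
* Somatic variants accrue linearly with age (0.05/yr) at sub-percent
  fractions, reproducing the age-related excess of <1% variants in parents.
  Note that somatic variants in a child are *correctly* counted by the de
  novo detector (they are absent from the mother), so pipeline-level rates
  on cohorts with somatic noise sit above the configured germline μ;
  estimator-recovery checks therefore run with the somatic rate at 0.
* mtDNA content is log-normal with a lower location in affected subjects
  (default shift log(505/564), the direction and magnitude of the emulated
  medians); nuclear DNM counts are Poisson(20 + 1.5 × paternal age at
  conception); severity is logistic with default log-odds log(3.32) for
  carrying a 5–15% heteroplasmy and log(0.32)/log(0.15) for paternal
  super-haplogroups H/JT.
* Indels are not simulated: the heteroplasmy analyses are SNV-only.
* The reference sequence is *synthetic* (panel positions carry the
  ancestral allele; elsewhere the base cycles by coordinate); coordinates
  and genome length match the real reference but the base identities do
  not, and files derived from it are labelled synthetic.

The generator emits a truth record (true haplogroup, de novo positions,
inherited heteroplasmies, covariates) alongside the data, enabling
parameter-recovery tests. Identical configuration and seed give
byte-identical output files.

**What passing tests do and do not show.** The generator's binomial count
model has no sequencing-error component beyond sampling noise, no
alignment or amplification artifacts, no indels, and a clean marker panel;
recovery results on it validate the pipeline's logic and estimators, not
their robustness to real-data artifacts (which upstream tools handle in
the emulated design).

## Problem sizes and numerical choices

The test suite exercises: estimator recovery on 100 replicate cohorts of
100 mother–offspring pairs; conditional-logistic CI coverage on 200
replicates of 500 matched pairs (true OR 4) and type-I error on 200 null
replicates; the global-null FDR check on 200 replicated frequency tables;
SOR/Fisher/BH oracle sweeps (1,000 random strand-count quadruples;
exhaustive 2×2 tables to total 40 plus 1,000 random tables to total 60;
1,000 random p-vectors); and a full 98-family end-to-end run. These sizes
were chosen to give stable Monte-Carlo assertions at conventional
tolerances. Optimization uses `stats::optim` (BFGS, analytic gradients,
relative tolerance 1e-12); subset enumeration per stratum is capped at
5,000 subsets (far above any family size); the conditional-model
separation guard flags |β| > 15 or SE > 50.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
cohort <- simulate_cohort(cfg)
res <- run_cohort_analysis(cohort)

res$rates$pooled
head(res$frequency_report)
res$risk_model$trace
```

## Known limitations

* The marker panel resolves only the clades it types; full-tree
  classification is out of scope, and `undetermined` calls are reported,
  not imputed.
* Published cohort-level odds ratios, medians and q-values are not
  reproducible from summary data and are not acceptance surfaces; the
  regression machinery is validated by simulation with known truth
  instead.
* The per-line deduplication rule for burden tables cannot be validated
  against published per-line counts without individual-level data; it
  implements the stated counting convention.
* Conditional-vs-plain "LR" comparisons are advisory diagnostics of
  clustering, not formal nested tests.
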