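---
title: "The maternal-liver choline screening funnel: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The maternal-liver choline screening funnel: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholscreen)
```

## The scientific question

Choline given together with ethanol on embryonic day 9 reduces
ethanol-induced cell death in the mouse neural tube, but the degree of
protection differs between genotypes. At that stage the embryonic liver is
not yet metabolically active, so the dam's liver is the dominant site of
choline metabolism; genetic variation in maternal liver choline-metabolism
genes is therefore a candidate explanation for the differential rescue.
`cholscreen` encodes a screening funnel over a BXD recombinant-inbred panel
(B6, BXD51, BXD73, BXD2): each stage applies one elimination criterion, and
only genes surviving all stages are called candidates. The funnel is a
prioritization device, not an inference procedure — it makes no claims of
statistical significance, and neither does this package.

## The phenotype statistic

Cell death is measured per litter (the litter, not the embryo, is the unit
of analysis) and averaged to strain-condition means. For a strain, brain
region and choline dose, with CE the choline + ethanol group mean, E0 the
ethanol no-choline mean, and MD the pooled maltose-dextrin control mean,

$$\rho = \frac{CE - MD}{E0 - MD}$$

is the fraction of ethanol-induced cell death still present under choline.
`percent_reduction()` reports `100 * rho` under the `REMAINING` convention
or `100 * (1 - rho)` under `REDUCTION`; the two always sum to 100 and the
convention is stamped on every reduction matrix. Two deliberate choices:

* **Default convention is `REMAINING`** — the formula exactly as written.
  The label "percent reduction" suggests the complement, but the sign
  conventions implied elsewhere in the source analyses conflict with one
  another, so the literal formula is the default and both conventions are
  first-class. With strain-level data the choice flips the sign of every
  correlation; the absolute-value selection mode (below) is insensitive to
  it.
* **MD controls are pooled unconditionally** across choline doses, weighted
  by litter count, with no significance pre-test. A pre-test would make the
  estimator's definition data-dependent and the pipeline non-reproducible.

Values are never clamped to [0, 100]: rescue beyond control level is a
negative `REMAINING`, enhancement beyond ethanol-alone exceeds 100. A strain
in which E0 equals MD has no ethanol-induced death to reduce; that is a
classed error (`degenerate_denominator_error`), not a silent `NA`.

## The four stages and their parameters

**1. Haplotype variability** (`filter_by_haplotype`). A gene is variable if
at least two distinct codes among B6/D2/H/R occur across the panel. H and R
count as distinct states. `NV` is a gene-level "no variation" flag and
always eliminates; mixing NV with per-strain calls violates the table
contract and errors. A uniform-H profile (every strain heterozygous) is
*not* variable — the criterion is variation between strains, not within a
genome — though the case is undocumented in the source material and is
flagged here as a package decision.

**2. Proteome detection** (`filter_by_background`, threshold 7 on the log2
scale). The detection rule requires *every* non-missing panel abundance to
be strictly above the threshold, the conservative reading of "levels above
background"; requiring only the panel mean to clear it would admit genes
undetected in individual strains. Strains with missing cells (the proteome
reference set lacks BXD2 entirely) are excluded gene-wise rather than
failing the gene, and at least two non-missing values are required for a
gene to proceed — fewer cannot support the variation criterion.

**3. Abundance variation** (`filter_by_cv`). The coefficient of variation
uses the sample (n−1) standard deviation: this is the estimator that
reproduces the published per-gene values exactly (1.136, 0.707, 1.200 for
Aldh7a1, Cept1, Slc44a1; 0 for Bhmt and Bhmt2):

```{r cv}
round_half_away(coefficient_of_variation(c(17.8, 17.4, 17.6)))  # Aldh7a1
round_half_away(coefficient_of_variation(c(16.4, 16.4, 16.2)))  # Cept1
```

Reporting rounds half away from zero to 3 decimals (`round_half_away`);
`base::round()`'s half-to-even rule differs at exactly representable
midpoints. The retention tolerance (default `1e-9` percent) is an
exact-zero test with a numerical guard, not a variability threshold: the
stage removes flat profiles, nothing more.

**4. Correlation screen** (`screen_correlations`). Pearson's r between
per-strain abundance and the reduction statistic, one coefficient per
region × dose condition. Selection requires `r > 0.7` (strict, signed) in
at least 3 of 4 conditions. The 0.7 cutoff is the conventional
"strong linear correlation" benchmark and is configurable
(`screen_config(r_threshold =)`). A signed rule is the literal reading of
"coefficients above 0.7"; because protein effects on a rescue phenotype can
plausibly act in either direction, `use_absolute_r = TRUE` selects on |r|
instead, and is never stricter than the signed rule at the same threshold.
Degenerate variance on either axis (a constant vector) is an error, never a
skip; duplicated-but-not-constant values are legal (two strains sharing an
abundance of 16.4 is real data, not degeneracy). Strains missing either
measurement are dropped per gene with a record; fewer than 3 common strains
aborts the screen.

The t-transform p-values (`correlation_pvalue`) are informational output
only. At n = 3 strains they have 1 degree of freedom and essentially no
power, and the p-value ranges printed in the source analyses cannot be
reconciled with any n available to this design — another reason the screen
selects on r, never on p.

**SNP annotation** (`categorize_phenotype`, `count_categories`). Survivors
are annotated, not filtered: association rows with p ≤ 0.05 (only values
strictly over the cutoff are excluded) are classified by an ordered,
first-match-wins, case-insensitive rule set: ICD-style prefixes K70 and F10
→ alcohol, then the substring "alcohol"; then a guard rule mapping
"delivery" to developmental — the word contains "liver", and obstetric
labels would otherwise be miscounted — then liver keywords (liver, gamma
glutamyltransferase, lipid, cholesterol, triglyceride); everything else is
developmental. This is the minimal ordered ruleset consistent with all six
published per-gene category counts; it ships as an editable file and users
with different nosological views can substitute their own. Rows, not unique
variants, are the counting unit: a variant reported against two phenotypes
contributes to both categories, which is required for the published totals
to balance.

## Reproducibility split

The published Pearson grid cannot be recomputed from public numbers because
the underlying litter-level cell-death values are not printed. The pipeline
therefore runs in two modes: the fixture mode consumes the published
correlation grid directly for stage 4, and the full computational path
(observations → reduction matrix → correlations) runs on synthetic or user
data. Both routes share the selection code, and a test confirms they agree
when the grid equals the computed coefficients.

## What the generator emulates

`sim_params()` defaults mirror the study design: 22 candidate genes, a
4-strain panel, 12/22 of genes haplotype-variable, proteome coverage for
5/12 of variable genes over 3 of the 4 strains (the fourth strain is an
all-missing column), log2 abundances near 16 with across-strain SD 0.2,
control cell death 20 (arbitrary TUNEL units), an ethanol effect of +20
(a doubling), a baseline remaining fraction of 0.4, litter-mean noise SD 2,
and 5–8 litters per treatment group drawn uniformly. Planted genes shift
the choline + ethanol group mean linearly with the strain's centered
protein level at 100 reduction-percent per log2 unit by default, set
per-region so the 3-of-4 rule can be exercised asymmetrically; with protein
SD 0.2 and ~6 litters per group this puts the planted signal at roughly
three times the phenotype noise. In the noiseless limit the planted
arithmetic is exact: every planted correlation is ±1.

What the generator does *not* emulate: litter means are Gaussian around
group means, while real TUNEL counts are skewed non-negative; haplotype
calls are drawn independently per gene with no linkage or shared descent;
proteome noise is homoscedastic; and GWAS rows are labels with p-values,
not genotypes — no linkage disequilibrium, no catalog-specific significance
policies. Passing tests on synthetic data therefore demonstrate that the
pipeline recovers planted structure under its own assumptions, not that the
biological conclusions are robust to realistic noise.

## Problem sizes in the test suite

The property tests use 1,000 random vectors for the statistic-vs-oracle
comparisons (at 1e−12 relative tolerance), 100 random panels for funnel
nesting, 20 noiseless replicates for exact planted recovery, and 500
noisy replicates for the null-selection comparison, with the matched null
estimated from the non-planted genes of the same runs — the reduction cells
within a region share pooled-control and ethanol-only groups, so an
independent-Gaussian null would understate the selection rate. These sizes
give Monte-Carlo standard errors comfortably below the 3-standard-error
guard bands the tests assert.

## Known limitations

* Three strains with both proteome and phenotype data means n = 3
  correlations; the screen ranks hypotheses and nothing more.
* The background threshold is dataset-specific (log2 scale of the liver
  proteome reference); applying the default to differently normalized data
  is meaningless.
* Gene symbols are matched case-insensitively but strain identifiers
  exactly; inputs mixing strain naming schemes must be harmonized upstream.
* The category ruleset encodes one defensible nosology; counts are
  sensitive to it, which is why it is a visible, editable input rather than
  a constant.
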