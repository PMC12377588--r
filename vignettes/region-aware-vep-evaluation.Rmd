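---
title: "Region-aware evaluation of variant effect predictors in disordered regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-aware evaluation of variant effect predictors in disordered regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrvep)
```

## The problem

Intrinsically disordered regions (IDRs) lack a stable fold, and both the
distribution of disease variants and the behaviour of variant effect
predictors (VEPs) differ there from ordered domains. Pathogenic missense
variants are rare in IDRs, benign variation is common, and predictors
trained largely on structured proteins assign systematically lower scores
to disordered residues of *both* classes. A single, globally derived
decision threshold then produces a striking dissociation: ranking metrics
(AUROC) can look excellent in IDRs while the actual sensitivity for
pathogenic IDR variants collapses. `idrvep` packages the machinery needed
to measure this effect and to derive region-specific operating points.

## Residue classification model

Residues are classified from AlphaFold-style per-residue pLDDT confidence
values (0&ndash;100). The three-state rule, with all thresholds exposed as
parameters of `classifier_params()`:

* **disordered** &mdash; pLDDT < `disorder_plddt_max` (default 50, strict)
  *and* the residue lies inside a contiguous low-confidence stretch of at
  least `stretch_min_len` residues (default 30, inclusive) whose mean
  pLDDT is below `stretch_mean_max` (default 70, strict);
* **ordered** &mdash; pLDDT &ge; `ordered_plddt_min` (default 70, inclusive);
* **intermediate** &mdash; everything else, including short low-confidence
  dips.

"Contiguous stretch" admits two readings, and both are implemented. The
default, `maximal_run`, takes maximal runs of consecutive residues with
pLDDT < 70 and keeps those at least 30 long. The alternative,
`any_window`, marks a residue as stretch-eligible if any 30-residue
window containing it has mean pLDDT < 70; it is strictly more permissive
(every residue disordered under `maximal_run` is disordered under
`any_window`) and will label a deep 20-residue dip between confident
domains as disordered, because flanking windows can still average below
70. We default to `maximal_run` precisely because short low-confidence
segments are meant to be an intermediate category, not disorder;
`any_window` is retained for sensitivity analysis.

A protein is *highly disordered* when at least 30% (inclusive) of its
residues are disordered. Proteome-level fractions are residue-weighted,
not protein-averaged. Values must be on the 0&ndash;100 scale; inputs on
0&ndash;1 are only rescaled under an explicit `rescale = TRUE` opt-in,
because a silent unit error would flip every classification. All
coordinates are 1-based with inclusive segment ends (the segment TSV is
therefore *not* genomic BED). Proteins shorter than 30 residues can never
contain a disordered residue under either mode; that is accepted
behaviour, not an error.

```{r classify-demo}
x <- c(rep(90, 50), rep(40, 40), rep(90, 30))
ann <- classify_residues(plddt_profile("demo", x))
table(ann$label)
find_low_confidence_stretches(plddt_profile("demo", x))
```

## Variant stratification and statistics

Variant tables carry a class label (`clinvar_pathogenic`,
`clinvar_benign`, `gnomad_benign`), optional inheritance mode (AD/AR) and
molecular mechanism (LOF/GOF/DN); these annotations are inputs, never
re-derived. Collagen-helix genes are removed via a user-supplied
exclusion list (case-folded exact symbol match, no alias resolution):
collagens are fibrous, consistently predicted disordered, and otherwise
dominate the disordered pathogenic set. Variants without pLDDT coverage
stay `unassigned` and are excluded from all denominators, with counts
reported.

Enrichment between strata uses Fisher's exact test with the conventional
two-sided minimum-likelihood rule (the sum of hypergeometric
probabilities no larger than the observed table's); the odds ratio is the
sample cross-product ratio, `Inf`/0 when one cross product vanishes and
undefined for a zero margin. Proportions are accompanied by Wilson score
intervals (default level 0.95), chosen over the Wald interval for
small-count coverage and over Clopper&ndash;Pearson (available by flag) to
avoid over-conservatism.

## VEP evaluation

Evaluation distinguishes pathogenic (ClinVar pathogenic, outcome 1) from
putatively benign population variants (gnomAD, outcome 0); clinically
labelled benign variants are kept out of the evaluation classes to limit
allele-frequency circularity. Two normative filtering steps, in this
order:

1. **Coverage filter** (`filter_by_coverage()`): keep VEPs scoring at
   least 75% (inclusive) of the variant set;
2. **Intersection** (`intersect_complete()`): keep exactly the variants
   scored by every retained VEP, so no comparison is confounded by
   coverage differences.

Reversing the order genuinely changes the retained sets, which the test
suite asserts on a constructed toy. Scores are oriented by explicit
per-VEP metadata so that higher always means more pathogenic; orientation
is never inferred from the data (that would be a form of label leakage),
but an audit mode warns when an oriented VEP's AUROC falls below 0.5.

AUROC uses the rank (Mann&ndash;Whitney) formulation with ties counted one
half. Decision thresholds maximise the Youden J statistic over the
observed score values plus `+Inf` (the ROC vertices; no interpolation, so
results are exactly reproducible), under the fixed call rule *pathogenic
iff score &ge; threshold*. J ties are broken towards higher sensitivity
and then lower threshold, since the motivating failure mode is missed
pathogenic IDR variants. Region-specific thresholds repeat the scan
within each region's variants; they are prioritisation aids, not clinical
cutoffs. Agreement between predictors uses Cohen's kappa on calls
binarized at each VEP's *global* threshold, summarised per group pair as
the mean over unordered predictor pairs with the SEM taken over pairs.

## The synthetic-data generator

The generator exists so the full pipeline &mdash; and its acceptance checks
&mdash; run without any external download, with known ground truth:

* **pLDDT profiles** (`simulate_plddt_profiles()`): alternating
  ordered/disordered blocks, 3&ndash;9 per protein, ordered blocks
  100&ndash;400 aa and disordered blocks 25&ndash;80 aa, emissions
  independent truncated (clamped) normals &mdash; ordered mean 90 sd 4,
  disordered mean 40 sd 6. Independence within a block is the simplest
  model that exercises the run-based classifier; the block structure
  supplies the long-range correlation that matters. Sub-30 disordered
  blocks are truthed intermediate, mirroring the classification rule.
  These defaults place roughly one-sixth of simulated residues in long
  disordered regions &mdash; within the range of strict proteome-level
  estimates &mdash; while keeping the truth recoverable: with sd 6 about
  5% of disordered-block residues emit pLDDT &ge; 50 and legitimately
  classify intermediate, so a substantially larger disordered fraction
  would degrade headline truth-recovery accuracy for reasons that have
  nothing to do with classifier correctness.
* **Variants** (`simulate_variants()`): Poisson counts per
  (region, class) around expected counts (a fixed-count mode exists for
  golden tests), placed uniformly on the region's residues, one reference
  amino acid per residue, duplicate substitutions dropped. Default
  proportions follow the published pattern: pathogenic
  3.6/15.1/81.3% across disordered/intermediate/ordered, ClinVar benign
  39.8% disordered, gnomAD 27.2% disordered; totals 2000/600/3000 give
  desk-scale statistical resolution. Pathogenic variants draw AD/AR
  inheritance with AD enriched in disorder, and AD variants draw a
  LOF/GOF/DN mechanism.
* **VEP scores** (`simulate_vep_scores()`): per (VEP, region, class)
  normal distributions with closed-form AUROC
  `pnorm((mu_path - mu_ben)/sqrt(sigma_path^2 + sigma_ben^2))`
  (`expected_auroc()`). The `paper-like` preset shifts *both* classes
  down in disordered regions &mdash; benign much further &mdash; with a
  tighter spread (ordered: benign 0 / pathogenic 2, sd 1; disordered:
  benign &minus;1.8 / pathogenic 0, sd 0.6). The raw mean separation is
  *smaller* in disorder, yet the standardized separation is larger, so
  the preset reproduces the dissociation: higher AUROC in disordered
  regions alongside a collapse of sensitivity at a global threshold. One
  preset VEP has an inverted score orientation and one has 30%
  missingness, so orientation handling and the coverage filter are
  exercised end to end. `null` and `separable` presets provide the
  degenerate comparisons.

One master seed fans out to per-component substreams
(`substream_seeds()`), so adding a generator never perturbs existing
fixtures, and identical seeds give byte-identical output files.

What the simulation does *not* emulate: real sequence composition and
mutational spectra, autocorrelated pLDDT within blocks, multi-fragment
AlphaFold entries for very long proteins, per-gene variant clustering,
and real VEP score distributions (which are bounded, multimodal and
correlated across predictors). Passing tests therefore demonstrate that
the machinery is correct and that the dissociation follows from the
modelled mechanism &mdash; not that any particular real VEP behaves this way.

```{r sim-demo, eval = FALSE}
sim <- simulate_dataset("paper-like", seed = 1)
flt <- filter_by_coverage(sim$scoresets,
                          sim$variants[sim$variants$region != "unassigned", ])
ds <- intersect_complete(sim$variants[sim$variants$region != "unassigned", ],
                         lapply(flt$scoresets, orient_scores))
head(vep_performance(ds))
```

## Numerical choices and degenerate inputs

* Candidate thresholds are the observed scores plus `+Inf`; the
  threshold scan uses `findInterval()` on sorted class scores, so exact
  ties are handled without floating-point comparisons.
* A Youden tie on J is resolved by (higher sensitivity, lower
  threshold); with all scores identical this yields the common value as
  threshold, sensitivity 1, specificity 0.
* Cohen's kappa with two constant call vectors: 1 when identical, 0
  otherwise.
* Fisher's minimum-likelihood rule compares probabilities with relative
  slack 1e-7 to avoid dropping ties to rounding.
* Empty strata yield flagged `NA` proportions, never errors; a region
  stratum missing one outcome class is skipped with a warning; a class
  vanishing globally is an error.
* Truncation of pLDDT emissions is implemented by clamping to [0, 100];
  at the default parameters the clipped mass is negligible (&lt; 1e-13
  for ordered emissions).

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data: 100 proteins (&asymp;90,000 residues), &asymp;5,600 variants, seven
simulated VEPs (six surviving the coverage filter), 2,000 replicates for
interval calibration, and exhaustive oracle sweeps over all 2&times;2 tables
with total &le; 40 and 200 random AUROC instances. These sizes were chosen
so every statistical check has comfortable resolution while the whole
suite completes in well under a minute.

## Known limitations

* Pfam-based collagen detection, ClinVar/gnomAD parsing and
  genome-to-protein mapping are out of scope; the variant table and
  exclusion list are inputs.
* Multi-fragment AlphaFold entries (proteins &gt; 2700 aa split across
  files) are not merged; supply a consolidated per-residue table for
  such proteins.
* Inheritance and mechanism labels are taken at face value from the
  input.
* Region-specific thresholds optimise J on the supplied dataset; they
  are not calibrated clinical evidence thresholds, which would need to
  be far stricter.
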