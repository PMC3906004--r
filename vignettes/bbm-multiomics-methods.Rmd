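---
title: "Methods: integrated multi-omics analysis of breast-cancer brain metastases"
author: "bbmomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated multi-omics analysis of breast-cancer brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbmomics)
options(bbmomics.verbose = FALSE)
```

# Scope and data model

The package analyses a cohort profiled on three array layers: copy-number
log2 ratios on a dense genomic probe grid, two-color expression log2
ratios collapsed from probes to genes, and methylation β-values (β =
M/(M+U), a proportion in [0, 1]). Samples belong to four groups: breast
brain metastases (BBM), non-neoplastic brain (NBn), non-neoplastic breast
(NBr), and early-stage primary breast tumors (PRIMARY). Tumor samples may
carry an intrinsic-subtype label; the analyses that stratify by subtype use
the three well-represented classes LumB, Her2ER− (written `Her2ER-` in all
outputs, a file-safe token) and Basal.

All genomic coordinates are 0-based half-open internally; the SEG format
boundary is the single place where 1-based inclusive coordinates appear.
Missing values propagate (tests drop them pairwise); nothing is imputed.
Strand is ignored throughout, as every quantity used is strand-symmetric.
Gene intervals are the span of the gene's annotated probes, since no gene
model is assumed. Probes annotated to several symbols are resolved to the
first listed symbol, and the resolution is logged.

# Copy number

## Segmentation

`segment_profile()` is a recursive binary segmentation in the circular
style: for the segment under test, every arc of consecutive probes is
compared with its complement by the pooled-variance two-sample t
statistic, and the best-scoring arc boundary pair is accepted when its
permutation p-value — recomputed maxima over `cbs_nperm` within-segment
label permutations — is at most `cbs_alpha`. Accepted pieces are
segmented recursively; segment means are arithmetic probe means, so the
probe-weighted mean of segment means reproduces the profile mean exactly.

Numerical choices:

* For fixed data and segment length the t statistic is strictly monotone
  in the between-group sum of squares *B* with *t² = B·df/(SS − B)*, so
  the O(n²) boundary scan and all permutation comparisons run on *B*
  (compiled code, three floating-point operations per candidate pair) and
  *t* is materialised once per split.
* Noise-free data make the residual variance vanish; a split with zero
  residual and unequal means receives a large sentinel statistic so exact
  steps always dominate, while constant segments score zero and are never
  split.
* The permutation loop stops early as soon as the exceedance count
  guarantees p > α; the reported p-value (1 + exceedances)/(1 + draws)
  remains valid under the stopping rule.
* Defaults `cbs_alpha = 0.01`, `cbs_nperm = 1000` are conventional
  segmentation settings; segments need at least 3 probes to be testable.

## Aberration calling

`call_aberrations()` keeps segments with at least `adm2_min_probes` (3)
probes and |mean log2| ≥ `adm2_min_abs_mean` (0.58), merging adjacent
qualifying segments of equal direction. These two published gates are the
reproducible content of the commercial ADM-2 detector; its proprietary
quality score (threshold 5.5 in a 5 Mb window) is intentionally not
reimplemented, and `adm2_window_mb` is carried in the configuration only
to document the provenance of the gates.

## Recurrence scoring

`recurrent_regions()` scores each probe and direction with the G-score,
G = aberration frequency × mean |log2| amplitude among aberrant samples
(algebraically the mean |amplitude| over all samples). The null preserves
each sample's aberration length structure by circularly shifting each
sample's call track by an independent uniform offset; per-probe p-values
are pooled exceedance probabilities over all probes × permutations, and
Benjamini–Hochberg conversion gives q-values. Maximal runs of probes with
q < `gistic_q` (0.25) become regions; a region is *broad* when it covers
at least `broad_arm_fraction` (0.5, the usual convention) of its
containing arm, *focal* otherwise. Arbitrated peak deconvolution and
purity/ploidy correction are out of scope. At least 100 permutations are
enforced — below that the pooled null is too coarse for q < 0.25
decisions.

The homozygous-deletion level `homozygous_del_log2 = −1.3` separates
one-copy from homozygous losses; it corresponds approximately to a single
remaining copy at 50% tumor purity and is a documented default, not a
published value.

# Expression

## Tri-group differential expression

`deg_trigroup()` encodes the dual-reference rule: a gene qualifies when it
differs *evidently* from both NBn and NBr with concordant direction, and
does **not** differ evidently between the two references. "Evident" is
the joint criterion p ≤ `deg_p` (0.05, Welch two-sample t test on log2
values) *and* |FC| ≥ `deg_fc` (2; FC = 2^difference of group means). The
Welch test is used because the two reference tissues cannot be assumed
homoskedastic with tumor tissue; no multiplicity correction is applied
inside the rule, matching the published criteria (BH q-values are
available behind `adjust = TRUE`). Treating the reference-equivalence
gate as the same joint criterion (rather than p alone) matters: a p-only
exclusion would remove ~5% of genuinely tumor-specific genes by type-I
noise on the null reference contrast, capping attainable sensitivity.

## Subtype stratification

`anova_subtypes()` restricts to LumB/Her2ER−/Basal tumors (the two
sparse classes are excluded upstream for sample-size reasons), runs a
per-feature one-way ANOVA, screens features at BH q ≤ 0.05, and applies
Tukey HSD to the survivors; pairwise records are kept at Tukey p ≤ 0.05
with |effect| ≥ an effect floor (log2 2 for expression, 0.2 β for
methylation). Screen-then-posthoc is the standard composition of the two
corrections when their order is not specified. The union output is the
deduplicated feature set over the three pairwise lists.

## Intrinsic subtyping

`classify_subtype()` is a nearest-centroid classifier: Spearman
correlation of each sample with each subtype centroid over shared genes,
argmax assignment. Rank correlation makes calls invariant to monotone
per-sample transforms and robust to platform scale; ties break by
centroid column order with a warning; fewer than 5 shared genes is an
error. Centroid values are an input table — the published centroid
parameters are deliberately not reproduced here.

# Methylation

`call_dml()` combines a two-sided Mann–Whitney test with the effect gate
|Δβ| ≥ `dml_delta_beta` (0.2), where Δβ is the difference of group *mean*
β ("average β difference"). The test is exact — full enumeration of all
C(n₁+n₂, n₁) labelings — when both groups have at most 8 samples, and a
tie-corrected normal approximation with 0.5 continuity correction above
that. The cutoff of 8 keeps exact enumeration below 12 870 labelings; in
the decision-relevant region (exact p ≤ 0.1) the two routes agree within
0.01 at the 8 vs 8 boundary, which the test suite checks by exhaustive
enumeration; deeper in the distribution centre the corrected
approximation is deliberately conservative, where no call can change.

`tumor_specific_dml()` mirrors the expression dual-reference logic: a
locus qualifies when called against both NBn and NBr with the same
direction (a pooled-reference mode is available behind a flag, since the
published description does not fix this choice). Each DML carries its
CpG-island flag, and hyper/hypo × island counts are tallied.

`derive_cihmp()` reconstructs the CpG-island hypomethylator signature:
among subtype-discriminating island loci, loci are ranked by the basal
median β minus the non-basal median β (medians, matching how the
signature is displayed), ascending, and the `k = 15` most negative are
returned; fewer qualifying loci are an error unless `allow_fewer = TRUE`.
`roc_locus()` fixes the positive class to the metastasis group and
reports it alongside AUC = U/(n₁n₂) so polarity is always auditable.

# Integration

`sample_gene_layers()` builds per-tumor gene-level tracks: expression as
the sample log2 ratio minus the mean of the pooled non-neoplastic
references (either reference alone selectable — pooling mirrors the
dual-reference differential logic), methylation as per-gene Δβ with
multi-locus genes summarised by the locus of maximum |Δβ| (preserving the
strongest signal; mean available), and copy number by length-weighted
mapping of called aberrant regions onto gene intervals (genes outside any
call are missing and therefore never pass a gate).

The congruency filters are direct threshold conjunctions:
amplified+overexpressed (CN ≥ 0.5, expr ≥ 2), deleted+underexpressed
(CN ≤ −0.8, expr ≤ −2), hypermethylated+downregulated (Δβ ≥ 0.2, expr ≤
−2), hypomethylated+upregulated, and the triple rules: a
*tsg_candidate* requires a one-copy deletion (−1.3 < CN ≤ −0.8) with
downregulation and hypermethylation; an *oncogene_candidate*
amplification with upregulation and hypomethylation; CN ≤ −1.3 with
silencing is reported separately as *homozygous_del_silent*. By
construction the triple categories are subsets of the corresponding
pairwise intersections, which the suite verifies as a property test.
Every tumor with all three layers is integrated. `recurrence()` counts
distinct samples per gene and category.

# qPCR quantification

ΔCt is the target Ct minus the arithmetic mean of the per-assay reference
Cts — exactly the log2 of the geometric mean of the linear reference
quantities, which is the numerically stable way to implement
multi-reference geometric-mean normalisation. Replicates are averaged
before ΔCt; fold-change is 2^(−ΔΔCt) against a calibrator (in the
emulated validation, the average of the non-neoplastic samples).
Amplification efficiency is fixed at perfect doubling, as the ΔΔCt
equation assumes.

# The synthetic cohort generator

`simulate_cohort()` emulates the structure of the study's arrays at
reduced scale, with every planted effect recorded as ground truth:

* **Genome**: 4 chromosomes × 40 Mb with a centromere at 45%, giving 8
  arms — the smallest layout on which the broad/focal distinction is
  exercised. Default feature counts (4000 CN probes ≈ one per 40 kb, 3000
  expression probes over 2000 genes, 2000 CpG loci) scale the 1M-probe
  aCGH grid and the 27K methylation array down by roughly two orders of
  magnitude while keeping every downstream statistic well-conditioned.
* **Samples**: 15 tumors (the copy-number cohort size), 10 + 10
  non-neoplastic references (the expression reference arms), 16 primaries
  (the primary series scaled to the cohort), subtype mix 12:8:11 over
  LumB:Her2ER−:Basal — the published subtype split after excluding the
  two sparse classes.
* **Copy number**: piecewise-constant per-sample signal — whole-arm
  gains/losses (±0.6), focal amplifications (+1.5), focal deletions
  (−1.0), homozygous deletions (−2.5) — plus Gaussian probe noise
  (sd 0.2). Carrier sets are random tumor subsets at configurable
  penetrance (0.6 for passenger events, 0.8 for drivers). An explicit
  `cn_event_spec` table overrides automatic placement for targeted
  experiments.
* **Expression**: per-gene baseline, +3/−3 log2 tumor effects at planted
  DEG, ±2 brain-specific effects at tissue genes (so the
  reference-equivalence gate is exercised), +2 disjoint signature blocks
  per subtype (block structure mimicking the clustered subtype
  signatures), a coupling term of 0.3 × amplitude for genes inside
  planted events (gain→up, loss→down), and Gaussian noise (sd 0.3). The
  subtype centroids returned with the cohort are the expected signature
  profiles.
* **Methylation**: β drawn from Beta(μκ, (1−μ)κ) around per-locus means —
  the mean-precision parameterisation respects the [0, 1] support, and
  shifts are applied on μ so no clipping artifacts arise; κ defaults to
  100 (≈ sd 0.05 at μ = 0.5). Hypermethylated DML sit mostly in islands
  at low baseline (0.15) and shift +0.3 in tumors, hypomethylated DML the
  mirror image, matching the published hyper-dominant island-skewed
  composition; a +0.05 brain/breast offset at DML loci reproduces the
  slightly different reference medians. Primaries receive 0.4 × the
  tumor effect so the metastasis-vs-primary ROC has signal. Signature
  island loci at baseline 0.6 shift by `basal_hypomethylation_shift`
  (−0.3) in basal tumors; LumB-hypermethylated island loci widen the
  subtype union beyond the signature.
* **Drivers**: genes under dedicated one-copy-deletion (−1.0) or
  amplification (+1.5) events with explicit ∓3 expression and ±0.35 Δβ
  effects in carriers — triple-concordant by construction. Planted
  expression/methylation gene pools are drawn disjointly from each other
  and from genes overlapping any copy-number event, so effects never
  cancel.

`simulate_null_cohort()` zeroes every planted effect and keeps the group
structure — the calibration harness for the differential callers and the
recurrence FDR. Identical parameters (including the seed) give
bit-identical cohorts. Noise-free settings (`cn_noise_sd = 0`,
`beta_concentration = Inf`, meaning β equals its mean exactly) are
deliberately allowed and used by the exactness tests.

What the generator does *not* emulate — and what passing tests therefore
do not show about real arrays: dye-bias/batch structure, probe-type
chemistry differences, copy-number–methylation coupling, cell-composition
mixtures, genuine LD-like correlation between neighbouring CpGs, and
outlier-heavy noise. Calibration and recovery results demonstrate the
correctness of the statistical machinery under its stated model, not
robustness to array artifacts.

# Problem sizes and determinism in the test and acceptance runs

The suite and `scripts/acceptance.R` run the stages at deliberately
scaled sizes chosen once: null calibrations on 2000 loci (10 vs 10, 10
seeds) and 500-probe/8-tumor cohorts (20 seeds, 1000 permutations);
segmentation recovery over 100 seeded replicates of a 100-probe noisy
step; planted-truth integration and the end-to-end pipeline on a
2000-gene, 30-sample cohort (12 BBM / 4 NBn / 4 NBr / 10 primaries).
Every stochastic step takes its seed from the configuration or the
script's `--seed`, so runs are reproducible; derived sub-seeds stay well
below 2³¹.

# Known limitations

* The segmentation boundary scan is exhaustive O(n²) per split — adequate
  for the scaled probe grids used here; very dense grids would want the
  windowed-scan refinements of production segmenters.
* The recurrence null pools exceedances over probes, which assumes
  approximate exchangeability of probes under the null; arm-scale
  correlation enters only through the circular-shift design.
* One-copy vs homozygous deletion thresholds are purity-naïve constants;
  no allele-specific or ploidy-adjusted calling is attempted.
* The ANOVA/Tukey machinery treats subtypes as fixed, known labels; no
  uncertainty from the upstream classifier is propagated.
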