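# bbmomics

Integrated copy-number, expression and DNA-methylation analysis of
breast-cancer brain metastasis cohorts, built as a tested R package plus a
numbered analysis workflow.

Breast-cancer brain metastases (BBM) are profiled on three array layers —
aCGH copy-number log2 ratios, two-color expression log2 ratios, and
Infinium-style methylation β-values (β = M/(M+U) ∈ [0,1]) — against
non-neoplastic brain (NBn), non-neoplastic breast (NBr) and early-stage
primary-tumor reference arms. The package implements the full analysis
chain over these layers:

* **Copy number** — recursive circular-style binary segmentation: each
  candidate split maximises the pooled two-sample t statistic between a
  probe arc and its complement and is accepted when its permutation
  p-value ≤ α (default 0.01, 1000 permutations); per-sample aberration
  calls gated at ≥ 3 probes and |mean log2| ≥ 0.58; cohort recurrence by
  the G-score G = frequency × mean |amplitude|, assessed against a null of
  within-sample circular shifts with Benjamini–Hochberg FDR (regions at
  q < 0.25, classified focal/broad at 50% of the containing arm).
* **Expression** — tri-group differential expression: a gene is a DEG when
  it differs from *both* references (Welch p ≤ 0.05 and |FC| ≥ 2,
  concordant direction) while the references do not differ from each
  other; nearest-centroid intrinsic subtyping by Spearman correlation;
  subtype-stratified one-way ANOVA (BH-screened) with Tukey post-hoc and
  a deduplicated union across the three subtype pairs.
* **Methylation** — Mann–Whitney differential methylation (exact
  enumeration when both groups ≤ 8, tie/continuity-corrected normal
  approximation otherwise) with a |Δβ| ≥ 0.2 effect gate, applied against
  both references; a CpG-island hypomethylator signature: the 15
  island loci most hypomethylated in basal-like tumors (ranked by basal
  minus non-basal median β); per-locus ROC of metastases vs primaries
  with AUC = U/(n₁n₂).
* **Integration (n-of-1)** — per-sample gene-level congruency:
  amplified+overexpressed / deleted+underexpressed (CN ≥ 0.5 / ≤ −0.8
  with expression |log2| ≥ 2), hypermethylated+downregulated /
  hypomethylated+upregulated (|Δβ| ≥ 0.2), and the triple-concordance
  nomination of tumor-suppressor candidates (one-copy deletion −1.3 < CN
  ≤ −0.8, downregulation, hypermethylation) and oncogene candidates
  (amplification, upregulation, hypomethylation), with homozygous
  deletions (CN ≤ −1.3, silenced) reported separately and a cohort
  recurrence tally.
* **qPCR** — relative expression and copy number by 2^(−ΔΔCt) with
  multi-reference geometric-mean normalisation on the Ct scale.

A synthetic-cohort generator (`simulate_cohort()`) produces matched
matrices for all three layers with planted, fully recorded ground truth —
broad/focal copy-number events, tumor-specific DEG/DML, subtype signature
blocks, a basal hypomethylation signature, and triple-concordant driver
genes — so every stage has a quantitative recovery surface without any
array downloads.

## Worked example: the analysis workflow

The `analysis/` scripts run the whole study end to end on a simulated
cohort at study-like scale (15 BBM / 10 NBn / 10 NBr / 16 primaries; 4000
CN probes, 3000 expression probes over 2000 genes, 2000 CpG loci):

```sh
Rscript analysis/01_simulate_cohort.R --seed 1
Rscript analysis/02_copy_number.R
Rscript analysis/03_expression_subtypes.R
Rscript analysis/04_methylation.R
Rscript analysis/05_integration.R
Rscript analysis/06_qpcr_validation.R
```

Output actually printed by a run (seed 1):

```
Segmenting 15 tumor profiles ...
  409 segments (6.8 per sample-chromosome)
  195 aberrant regions across samples (93 gains, 102 losses)
Recurrent regions at q < 0.25: 19 (15 focal, 4 broad)
Planted events recovered as recurrent regions: 19 / 19

Tri-group DEG: 109 selected (52 up, 57 down) of 2000 genes
  planted effects recovered: 100 / 100
Intrinsic subtype calls: Basal=5, Her2ER-=4, LumB=6; agreement with simulated truth 1.00

Tumor-specific DML: 109 (77 hyper / 32 hypo); islands: 68 of hyper, 11 of hypo
  median beta over DML: BBM 0.42, NBn 0.22, NBr 0.17
Hypomethylator signature: 15 island loci; basal median 0.31 vs LumB 0.60 / Her2ER- 0.61

Planted drivers among top 8 tally entries: 8 / 8
Median fold-change vs non-neoplastic calibrator: BBM 11.9, primary 1.2
```

Reading these numbers: every planted copy-number event resurfaces as a
significant recurrent region; the tri-group rule recovers all planted
expression effects while rejecting brain-vs-breast tissue genes; the
metastasis cohort is hypermethylated relative to both references over its
DML (median β 0.42 vs 0.22/0.17) while basal-like tumors are
hypomethylated over the island signature (0.31 vs ≈ 0.6); the
triple-concordance tally ranks exactly the planted driver genes on top;
and the ΔΔCt quantification separates metastases from the non-neoplastic
calibrator for the top amplified candidate.

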