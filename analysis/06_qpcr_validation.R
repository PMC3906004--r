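#!/usr/bin/env Rscript
# Stage 6: ddCt validation arithmetic. Emulates the qPCR confirmation of a
# top amplified/overexpressed candidate: per-sample Ct values are derived
# from the simulated gene-level expression of the most recurrent oncogene
# candidate (one cycle per log2 unit under perfect doubling), with two
# internal reference assays, and quantified relative to the average of the
# non-neoplastic samples.

suppressMessages(library(bbmomics))

indir <- "results/cohort"
intdir <- "results/integration"
outdir <- "results/qpcr"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

expr <- read_matrix(file.path(indir, "expr_log2.tsv"), "expr_log2")
ann <- read_annotation(file.path(indir, "ann_expr.tsv"))
meta <- read_metadata(file.path(indir, "metadata.tsv"))
tal <- read.delim(file.path(intdir, "recurrence_tally.tsv"))

gene <- tal$gene_symbol[tal$category == "oncogene_candidate"][1L]
g <- collapse_probes_to_genes(expr, ann)
cat("Validating candidate:", gene, "\n")

# Ct emulation: 25 cycles at the reference level, minus one cycle per log2
# unit of target abundance; references flat at 20/21 cycles
make_cts <- function(sample) {
  data.frame(
    assay_id = c("TARGET", "REF1", "REF2"),
    role = c("target", "reference", "reference"),
    ct = c(25 - unclass(g)[gene, sample], 20, 21),
    replicate = 1L, stringsAsFactors = FALSE)
}
refs <- meta$sample_id[meta$group %in% c("NBn", "NBr")]
calibrator <- data.frame(
  assay_id = c("TARGET", "REF1", "REF2"),
  role = c("target", "reference", "reference"),
  ct = c(25 - mean(unclass(g)[gene, refs]), 20, 21),
  replicate = 1L, stringsAsFactors = FALSE)

samples <- meta$sample_id[meta$group %in% c("BBM", "PRIMARY")]
folds <- data.frame(
  sample_id = samples,
  group = meta$group[match(samples, meta$sample_id)],
  fold_change = vapply(samples, function(s) {
    relative_expression(make_cts(s), calibrator)
  }, 1),
  stringsAsFactors = FALSE)
write.table(folds, file.path(outdir, "relative_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

med <- tapply(folds$fold_change, folds$group, median)
cat(sprintf(
  "Median fold-change vs non-neoplastic calibrator: BBM %.1f, primary %.1f\n",
  med["BBM"], med["PRIMARY"]))
cat(sprintf("BBM samples above 2-fold: %d / %d\n",
            sum(folds$fold_change[folds$group == "BBM"] > 2),
            sum(folds$group == "BBM")))
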