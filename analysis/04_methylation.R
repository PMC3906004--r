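#!/usr/bin/env Rscript
# Stage 4: methylation analysis. Calls tumor-specific differentially
# methylated loci against both references (Mann-Whitney + |delta beta| >=
# 0.2), summarises hyper/hypo x CpG-island composition and group medians,
# runs the subtype ANOVA union, derives the CpG-island hypomethylator
# signature of basal-like tumors, and compares metastases to primary
# tumors by per-locus ROC.

suppressMessages(library(bbmomics))

indir <- "results/cohort"
outdir <- "results/methylation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- read_config(file.path(indir, "config.yaml"))
beta <- read_matrix(file.path(indir, "beta.tsv"), "beta")
ann <- read_annotation(file.path(indir, "ann_meth.tsv"), methylation = TRUE)
meta <- read_metadata(file.path(indir, "metadata.tsv"))
truth_dml <- read.delim(file.path(indir, "truth_dml.tsv"))
truth_cihmp <- readLines(file.path(indir, "truth_cihmp_loci.txt"))

groups <- split(meta$sample_id, meta$group)

dml <- tumor_specific_dml(beta, meta, ann, cfg)
write.table(dml, file.path(outdir, "tumor_specific_dml.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
tally <- attr(dml, "tally")
cat(sprintf("Tumor-specific DML: %d (%d hyper / %d hypo); islands: %d of hyper, %d of hypo\n",
            nrow(dml), sum(dml$direction == "hyper"),
            sum(dml$direction == "hypo"),
            tally["hyper", "TRUE"], tally["hypo", "TRUE"]))
cat(sprintf("  planted DML recovered: %d / %d\n",
            sum(truth_dml$locus_id %in% dml$locus_id), nrow(truth_dml)))
meds <- vapply(c("BBM", "NBn", "NBr"), function(g) {
  median_methylation(beta, groups[[g]], dml$locus_id)
}, 1)
cat(sprintf("  median beta over DML: BBM %.2f, NBn %.2f, NBr %.2f\n",
            meds["BBM"], meds["NBn"], meds["NBr"]))

sub <- anova_subtype_dml(beta, meta, cfg)
writeLines(sub$union, file.path(outdir, "subtype_dml_union.txt"))
cat(sprintf("Subtype DML union: %d loci (pairwise %s)\n", length(sub$union),
            paste(names(sub$pairwise), vapply(sub$pairwise, nrow, 1L),
                  sep = "=", collapse = ", ")))

sig <- derive_cihmp(beta, meta, ann, sub$union, k = 15, allow_fewer = TRUE)
write.table(sig, file.path(outdir, "cihmp_signature.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Hypomethylator signature: %d island loci; basal median %.2f vs LumB %.2f / Her2ER- %.2f\n",
            nrow(sig), median(sig$median_Basal), median(sig$median_LumB),
            median(sig$`median_Her2ER-`)))
cat(sprintf("  overlap with planted signature loci: %d / %d\n",
            sum(sig$locus_id %in% truth_cihmp), length(truth_cihmp)))

roc <- roc_locus(beta, groups$BBM, groups$PRIMARY,
                 loci = intersect(truth_dml$locus_id, rownames(beta)))
roc <- roc[order(-abs(roc$auc - 0.5)), ]
write.table(roc, file.path(outdir, "roc_bbm_vs_primary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("ROC (BBM vs primary) over %d planted loci: %d with p < 0.01, median |AUC - 0.5| = %.2f\n",
            nrow(roc), sum(roc$p < 0.01), median(abs(roc$auc - 0.5))))
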