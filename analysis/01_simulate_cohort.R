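#!/usr/bin/env Rscript
# Stage 1: generate the matched multi-omics cohort the downstream stages
# analyse. Study-scale defaults: 15 breast-brain-metastasis tumors, 10
# non-neoplastic brain and 10 non-neoplastic breast references, 16 primary
# breast tumors; 4000 CN probes / 3000 expression probes over 2000 genes /
# 2000 CpG loci on a 4-chromosome synthetic genome. All planted signal is
# recorded as ground truth so later stages can report recovery.

suppressMessages(library(bbmomics))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
outdir <- "results/cohort"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

params <- simulation_params(seed = seed)
cohort <- simulate_cohort(params)
print(cohort)

write_matrix(cohort$cn, file.path(outdir, "cn_log2.tsv"))
write_matrix(cohort$expr, file.path(outdir, "expr_log2.tsv"))
write_matrix(cohort$beta, file.path(outdir, "beta.tsv"))
write_annotation(cohort$ann$cn, file.path(outdir, "ann_cn.tsv"))
write_annotation(cohort$ann$expr, file.path(outdir, "ann_expr.tsv"))
write_annotation(cohort$ann$meth, file.path(outdir, "ann_meth.tsv"))
write_metadata(cohort$meta, file.path(outdir, "metadata.tsv"))
write_centroids(cohort$centroids, file.path(outdir, "centroids.tsv"))
write.table(cohort$genome, file.path(outdir, "genome_arms.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_config(analysis_config(seed = seed), file.path(outdir, "config.yaml"))

# ground truth, one table per planted signal class
for (nm in c("cn_events", "deg", "subtype_genes", "dml", "drivers")) {
  write.table(cohort$truth[[nm]],
              file.path(outdir, paste0("truth_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(cohort$truth$cihmp_loci, file.path(outdir, "truth_cihmp_loci.txt"))

cat(sprintf(
  "Planted: %d CN events, %d DEG, %d DML, %d drivers; subtype mix %s\n",
  nrow(cohort$truth$cn_events), nrow(cohort$truth$deg),
  nrow(cohort$truth$dml), nrow(cohort$truth$drivers),
  paste(names(table(cohort$meta$subtype[cohort$meta$group == "BBM"])),
        table(cohort$meta$subtype[cohort$meta$group == "BBM"]),
        collapse = ", ")))
cat("Cohort written to", outdir, "\n")
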