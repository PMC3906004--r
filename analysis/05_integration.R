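#!/usr/bin/env Rscript
# Stage 5: per-sample multi-layer congruency integration. Builds gene-level
# copy-number / expression / delta-beta tracks per tumor, applies the
# pairwise congruency filters and the triple-concordance nomination of
# tumor-suppressor and oncogene candidates, tallies cohort recurrence, and
# lists homozygously deleted, silenced genes.

suppressMessages(library(bbmomics))

indir <- "results/cohort"
cndir <- "results/copy_number"
outdir <- "results/integration"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- read_config(file.path(indir, "config.yaml"))
expr <- read_matrix(file.path(indir, "expr_log2.tsv"), "expr_log2")
beta <- read_matrix(file.path(indir, "beta.tsv"), "beta")
ann_expr <- read_annotation(file.path(indir, "ann_expr.tsv"))
ann_meth <- read_annotation(file.path(indir, "ann_meth.tsv"),
                            methylation = TRUE)
meta <- read_metadata(file.path(indir, "metadata.tsv"))
calls <- read.delim(file.path(cndir, "aberrations.tsv"))
truth_drv <- read.delim(file.path(indir, "truth_drivers.tsv"))

g <- collapse_probes_to_genes(expr, ann_expr)
lay <- sample_gene_layers(g, beta, calls, meta, ann_meth,
                          gene_intervals(ann_expr))

ce <- congruent_cn_expr(lay$cn, lay$expr, cfg)
em <- congruent_expr_meth(lay$expr, lay$delta_beta, cfg)
noms <- nominate_tsg_oncogene(lay$cn, lay$expr, lay$delta_beta, cfg)
all_calls <- rbind(ce, em, noms)
write.table(all_calls, file.path(outdir, "integration_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Integration calls: %s\n",
            paste(names(table(all_calls$category)),
                  table(all_calls$category), sep = "=", collapse = ", ")))

tal <- recurrence(all_calls)
write.table(tal, file.path(outdir, "recurrence_tally.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
drivers <- tal[tal$category %in% c("tsg_candidate", "oncogene_candidate"), ]
cat("Top nominated driver candidates (gene, category, samples):\n")
print(head(drivers[, 1:3], 10), row.names = FALSE)
planted <- truth_drv$gene[truth_drv$role %in% c("tsg", "onco")]
cat(sprintf("Planted drivers among top %d tally entries: %d / %d\n",
            length(planted),
            sum(planted %in% head(drivers$gene_symbol, length(planted))),
            length(planted)))

hd <- homozygous_deletions(lay$cn, lay$expr, cfg)
write.table(hd, file.path(outdir, "homozygous_deletions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Homozygously deleted + silenced genes: %d calls over %d genes\n",
            nrow(hd), length(unique(hd$gene_symbol))))
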