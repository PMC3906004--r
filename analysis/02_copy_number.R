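#!/usr/bin/env Rscript
# Stage 2: copy-number analysis. Segments each tumor profile (recursive
# max-t segmentation with permutation split tests), calls per-sample
# aberrations with the 3-probe / |log2| >= 0.58 gates, scores cohort
# recurrence with the G-score + circular-shift permutation FDR, and
# reports recovery of the planted events.

suppressMessages(library(bbmomics))

indir <- "results/cohort"
outdir <- "results/copy_number"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- read_config(file.path(indir, "config.yaml"))
cn <- read_matrix(file.path(indir, "cn_log2.tsv"), "cn_log2")
ann <- read_annotation(file.path(indir, "ann_cn.tsv"))
meta <- read_metadata(file.path(indir, "metadata.tsv"))
arms <- read.delim(file.path(indir, "genome_arms.tsv"))
genes <- gene_intervals(read_annotation(file.path(indir, "ann_expr.tsv")))
truth_ev <- read.delim(file.path(indir, "truth_cn_events.tsv"))

tumors <- meta$sample_id[meta$group == "BBM"]
cat("Segmenting", length(tumors), "tumor profiles ...\n")
segs <- segment_cohort(cn, ann, tumors, cfg)
write_seg(segs[, c("sample_id", "chrom", "start", "end", "n_probes",
                   "seg_mean")],
          file.path(outdir, "segments.seg"))
cat(sprintf("  %d segments (%.1f per sample-chromosome)\n", nrow(segs),
            nrow(segs) / (length(tumors) * length(unique(ann$chrom)))))

calls <- call_aberrations(segs, cfg)
write.table(calls, file.path(outdir, "aberrations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("  %d aberrant regions across samples (%d gains, %d losses)\n",
            nrow(calls), sum(calls$direction == "gain"),
            sum(calls$direction == "loss")))

rec <- recurrent_regions(calls, ann, tumors, arms, cfg, gene_ann = genes)
write.table(rec, file.path(outdir, "recurrent_regions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Recurrent regions at q < %.2f: %d (%d focal, %d broad)\n",
            cfg$gistic_q, nrow(rec), sum(rec$scope == "focal"),
            sum(rec$scope == "broad")))

# planted-event recovery: a planted event counts as recovered when a
# significant region of the right direction overlaps half of it
dir_of <- c(broad_gain = "gain", focal_amp = "gain", tsg = "loss",
            onco = "gain", broad_loss = "loss", focal_del = "loss",
            homozygous_del = "loss")
recovered <- vapply(seq_len(nrow(truth_ev)), function(r) {
  cand <- rec[rec$chrom == truth_ev$chrom[r] &
                rec$direction == dir_of[truth_ev$type[r]], , drop = FALSE]
  if (!nrow(cand)) return(FALSE)
  ov <- pmax(0, pmin(cand$end, truth_ev$end[r]) -
               pmax(cand$start, truth_ev$start[r]))
  any(ov >= 0.5 * (truth_ev$end[r] - truth_ev$start[r]))
}, logical(1))
cat(sprintf("Planted events recovered as recurrent regions: %d / %d\n",
            sum(recovered), nrow(truth_ev)))
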