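#' Collapse probe-level values to gene level by the per-gene median
#'
#' Probes with an empty gene symbol are dropped (and counted in the log);
#' each gene's value per sample is the median over its probes, missing values
#' removed pairwise. Output rows are ordered by gene symbol, so the result is
#' invariant to probe input order.
#'
#' @param m probe-level [omics_matrix()].
#' @param ann probe annotation (see [validate_annotation()]); only probes
#'   present in `m` are used.
#' @return A gene-level [omics_matrix()] of the same modality.
#' @export
collapse_probes_to_genes <- function(m, ann) {
  ann <- validate_annotation(ann)
  idx <- match(rownames(m), ann$probe_id)
  gene <- ann$gene_symbol[idx]
  keep <- !is.na(idx) & !is.na(gene) & nzchar(gene)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    .bbm_log(dropped, " probe(s) without a gene symbol dropped before collapse")
  }
  if (!any(keep)) stop("no annotated probes left to collapse")
  vals <- unclass(m)[keep, , drop = FALSE]
  gene <- gene[keep]
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  rows <- split(seq_along(gene), gene)
  for (g in names(rows)) {
    block <- vals[rows[[g]], , drop = FALSE]
    out[g, ] <- apply(block, 2L, median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  omics_matrix(out, modality(m))
}

#' Gene intervals spanned by a platform's probes
#'
#' The study supplies no gene model, so a gene's interval is the span of its
#' annotated probes: `[min(start), max(end))` on the gene's chromosome.
#'
#' @param ann probe annotation.
#' @return data.frame with `gene_symbol`, `chrom`, `start`, `end`.
#' @export
gene_intervals <- function(ann) {
  ann <- validate_annotation(ann)
  keep <- !is.na(ann$gene_symbol) & nzchar(ann$gene_symbol)
  ann <- ann[keep, , drop = FALSE]
  if (!nrow(ann)) stop("no gene-annotated probes")
  pieces <- split(ann, ann$gene_symbol)
  out <- do.call(rbind, lapply(pieces, function(p) {
    data.frame(gene_symbol = p$gene_symbol[1L], chrom = p$chrom[1L],
               start = min(p$start), end = max(p$end),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_symbol), , drop = FALSE]
}

#' Map a sample's segments onto genes
#'
#' Each gene receives the length-weighted mean of the `seg_mean` of every
#' segment overlapping the gene interval; genes overlapping no segment get
#' `NA`. Overlaps are computed with GenomicRanges.
#'
#' @param segments segmented profile of a single sample (see [write_seg()] for
#'   the columns); may also be aberration calls with a `mean_log2` column.
#' @param ann probe annotation of the platform whose probes define the gene
#'   intervals, or a precomputed [gene_intervals()] table.
#' @return Named numeric vector of per-gene copy-number log2 values.
#' @export
map_segments_to_genes <- function(segments, ann) {
  if (length(unique(segments$sample_id)) > 1L) {
    stop("map_segments_to_genes expects segments of a single sample")
  }
  genes <- if (all(c("gene_symbol", "chrom", "start", "end") %in% names(ann)) &&
               !"probe_id" %in% names(ann)) ann else gene_intervals(ann)
  value_col <- if ("seg_mean" %in% names(segments)) "seg_mean" else "mean_log2"
  out <- setNames(rep(NA_real_, nrow(genes)), genes$gene_symbol)
  if (!nrow(segments)) return(out)
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  gr_seg <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1L, segments$end))
  hits <- GenomicRanges::findOverlaps(gr_gene, gr_seg)
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_gene)[qi], IRanges::ranges(gr_seg)[si]))
  v <- segments[[value_col]][si]
  num <- tapply(w * v, qi, sum)
  den <- tapply(w, qi, sum)
  out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  out
}
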