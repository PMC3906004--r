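#' Per-sample gene-level layers for integration
#'
#' Builds the three per-sample gene-level tracks the congruency filters
#' consume:
#' * expression: sample log2 ratio minus the mean of the reference samples
#'   (pooled non-neoplastic brain + breast by default; either reference alone
#'   behind `reference`),
#' * methylation: per-gene delta beta = sample beta - mean reference beta,
#'   genes with several loci summarised by the locus of maximum |delta beta|
#'   (configurable to the mean),
#' * copy number: aberration calls mapped onto genes with
#'   [map_segments_to_genes()] (`NA` where a gene overlaps no called region).
#'
#' @param expr gene-level expression [omics_matrix()].
#' @param beta locus-level beta [omics_matrix()].
#' @param calls per-sample aberration calls ([call_aberrations()]).
#' @param meta sample metadata.
#' @param ann_meth methylation annotation (locus -> gene).
#' @param gene_iv gene intervals ([gene_intervals()] of the expression
#'   platform) used for the copy-number mapping.
#' @param samples samples to integrate (default: every BBM sample).
#' @param reference `"pooled"`, `"NBn"` or `"NBr"`.
#' @param meth_summary `"max"` (locus of max |delta beta|) or `"mean"`.
#' @return list of genes x samples matrices `cn`, `expr`, `delta_beta`
#'   (shared gene universe, intersected).
#' @export
sample_gene_layers <- function(expr, beta, calls, meta, ann_meth, gene_iv,
                               samples = NULL,
                               reference = c("pooled", "NBn", "NBr"),
                               meth_summary = c("max", "mean")) {
  reference <- match.arg(reference)
  meth_summary <- match.arg(meth_summary)
  meta <- validate_metadata(meta)
  if (is.null(samples)) samples <- group_samples(meta, "BBM")
  refs <- switch(reference,
                 pooled = c(group_samples(meta, "NBn"),
                            group_samples(meta, "NBr")),
                 NBn = group_samples(meta, "NBn"),
                 NBr = group_samples(meta, "NBr"))
  refs_e <- intersect(refs, colnames(expr))
  refs_b <- intersect(refs, colnames(beta))
  if (!length(refs_e) || !length(refs_b)) stop("no reference samples found")

  e <- unclass(expr)
  expr_delta <- e[, samples, drop = FALSE] -
    rowMeans(e[, refs_e, drop = FALSE], na.rm = TRUE)

  b <- unclass(beta)
  db_locus <- b[, samples, drop = FALSE] -
    rowMeans(b[, refs_b, drop = FALSE], na.rm = TRUE)
  gene_of <- ann_meth$gene_symbol[match(rownames(b), ann_meth$probe_id)]
  keep <- !is.na(gene_of) & nzchar(gene_of)
  db_locus <- db_locus[keep, , drop = FALSE]
  gene_of <- gene_of[keep]
  genes_m <- sort(unique(gene_of))
  db <- matrix(NA_real_, length(genes_m), length(samples),
               dimnames = list(genes_m, samples))
  rows <- split(seq_along(gene_of), gene_of)
  for (g in names(rows)) {
    block <- db_locus[rows[[g]], , drop = FALSE]
    db[g, ] <- if (meth_summary == "mean") {
      colMeans(block, na.rm = TRUE)
    } else {
      apply(block, 2L, function(v) {
        if (all(is.na(v))) NA_real_ else v[which.max(abs(v))]
      })
    }
  }

  cn <- matrix(NA_real_, nrow(gene_iv), length(samples),
               dimnames = list(gene_iv$gene_symbol, samples))
  for (s in samples) {
    sc <- calls[calls$sample_id == s, , drop = FALSE]
    cn[, s] <- map_segments_to_genes(sc, gene_iv)
  }

  shared <- Reduce(intersect, list(rownames(expr_delta), rownames(db),
                                   rownames(cn)))
  if (!length(shared)) stop("empty gene intersection across layers")
  list(cn = cn[shared, , drop = FALSE],
       expr = expr_delta[shared, , drop = FALSE],
       delta_beta = db[shared, , drop = FALSE])
}

integration_call_frame <- function() {
  data.frame(sample_id = character(0), gene_symbol = character(0),
             category = character(0), cn_log2 = numeric(0),
             expr_log2 = numeric(0), delta_beta = numeric(0),
             stringsAsFactors = FALSE)
}

build_calls <- function(sample_id, genes, category, cn = NA_real_,
                        expr = NA_real_, db = NA_real_) {
  if (!length(genes)) return(integration_call_frame())
  data.frame(sample_id = sample_id, gene_symbol = genes, category = category,
             cn_log2 = cn, expr_log2 = expr, delta_beta = db,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Congruent copy-number / expression calls per sample
#'
#' Applies the published filters gene by gene and sample by sample:
#' expression |log2 ratio| >= `integ_expr_log2` (2), copy number >= `cn_gain`
#' (0.5) or <= `cn_loss` (-0.8), and congruency of direction — a gene is
#' kept only as amplified+overexpressed (`amp_over`) or
#' deleted+underexpressed (`del_under`); discordant pairs are dropped.
#'
#' @param cn,expr genes x samples matrices of per-sample gene-level
#'   copy-number log2 and expression log2 ratios
#'   ([sample_gene_layers()]).
#' @param cfg [analysis_config()].
#' @return data.frame of integration calls (`sample_id`, `gene_symbol`,
#'   `category`, layer values).
#' @export
congruent_cn_expr <- function(cn, expr, cfg = analysis_config()) {
  shared <- intersect(rownames(cn), rownames(expr))
  samples <- intersect(colnames(cn), colnames(expr))
  if (!length(shared)) stop("empty gene intersection")
  out <- list()
  for (s in samples) {
    cnv <- cn[shared, s]
    ex <- expr[shared, s]
    ok <- !is.na(cnv) & !is.na(ex)
    amp <- which(ok & ex >= cfg$integ_expr_log2 & cnv >= cfg$cn_gain)
    del <- which(ok & ex <= -cfg$integ_expr_log2 & cnv <= cfg$cn_loss)
    out[[length(out) + 1L]] <- rbind(
      build_calls(s, shared[amp], "amp_over", cn = cnv[amp], expr = ex[amp]),
      build_calls(s, shared[del], "del_under", cn = cnv[del], expr = ex[del]))
  }
  if (!length(out)) return(integration_call_frame())
  do.call(rbind, out)
}

#' Congruent expression / methylation calls per sample
#'
#' Canonical epigenetic regulation: hypermethylated + downregulated
#' (`hyper_down`, delta beta >= +0.2 with expression <= -2) or
#' hypomethylated + upregulated (`hypo_up`). With
#' `require_anticorrelation = FALSE`, same-direction pairs are also emitted
#' under the categories `hyper_up` and `hypo_down`.
#'
#' @param expr,delta_beta genes x samples matrices ([sample_gene_layers()]).
#' @param cfg [analysis_config()].
#' @param require_anticorrelation drop same-direction pairs (default TRUE).
#' @return data.frame of integration calls.
#' @export
congruent_expr_meth <- function(expr, delta_beta, cfg = analysis_config(),
                                require_anticorrelation = TRUE) {
  shared <- intersect(rownames(expr), rownames(delta_beta))
  samples <- intersect(colnames(expr), colnames(delta_beta))
  if (!length(shared)) stop("empty gene intersection")
  out <- list()
  for (s in samples) {
    ex <- expr[shared, s]
    db <- delta_beta[shared, s]
    ok <- !is.na(ex) & !is.na(db)
    hyper <- ok & db >= cfg$dml_delta_beta
    hypo <- ok & db <= -cfg$dml_delta_beta
    up <- ok & ex >= cfg$integ_expr_log2
    down <- ok & ex <= -cfg$integ_expr_log2
    pieces <- list(
      build_calls(s, shared[hyper & down], "hyper_down",
                  expr = ex[hyper & down], db = db[hyper & down]),
      build_calls(s, shared[hypo & up], "hypo_up",
                  expr = ex[hypo & up], db = db[hypo & up]))
    if (!require_anticorrelation) {
      pieces <- c(pieces, list(
        build_calls(s, shared[hyper & up], "hyper_up",
                    expr = ex[hyper & up], db = db[hyper & up]),
        build_calls(s, shared[hypo & down], "hypo_down",
                    expr = ex[hypo & down], db = db[hypo & down])))
    }
    out[[length(out) + 1L]] <- do.call(rbind, pieces)
  }
  if (!length(out)) return(integration_call_frame())
  do.call(rbind, out)
}

#' Triple-concordance nomination of tumor suppressor and oncogene candidates
#'
#' Combines all three layers per sample and gene:
#' * `tsg_candidate`: one-copy deletion (`homozygous_del_log2 < cn <=
#'   cn_loss`), downregulation (expr <= -`integ_expr_log2`) and
#'   hypermethylation (delta beta >= +`dml_delta_beta`);
#' * `oncogene_candidate`: amplification (cn >= `cn_gain`), upregulation and
#'   hypomethylation;
#' * `homozygous_del_silent`: cn at or below `homozygous_del_log2` with loss
#'   of expression, reported separately (the deeper-deletion partition of
#'   the deleted/silenced genes).
#'
#' By construction `tsg_candidate` calls are a subset of the
#' `del_under`/`hyper_down` pairwise intersection, and `oncogene_candidate`
#' of `amp_over`/`hypo_up`.
#'
#' @param cn,expr,delta_beta genes x samples matrices
#'   ([sample_gene_layers()]).
#' @param cfg [analysis_config()].
#' @return data.frame of integration calls.
#' @export
nominate_tsg_oncogene <- function(cn, expr, delta_beta,
                                  cfg = analysis_config()) {
  shared <- Reduce(intersect, list(rownames(cn), rownames(expr),
                                   rownames(delta_beta)))
  samples <- Reduce(intersect, list(colnames(cn), colnames(expr),
                                    colnames(delta_beta)))
  if (!length(shared)) stop("empty gene intersection")
  out <- list()
  for (s in samples) {
    cnv <- cn[shared, s]
    ex <- expr[shared, s]
    db <- delta_beta[shared, s]
    ok <- !is.na(cnv) & !is.na(ex) & !is.na(db)
    down <- ex <= -cfg$integ_expr_log2
    up <- ex >= cfg$integ_expr_log2
    hyper <- db >= cfg$dml_delta_beta
    hypo <- db <= -cfg$dml_delta_beta
    tsg <- which(ok & down & hyper & cnv <= cfg$cn_loss &
                   cnv > cfg$homozygous_del_log2)
    onc <- which(ok & up & hypo & cnv >= cfg$cn_gain)
    hom <- which(!is.na(cnv) & !is.na(ex) & down &
                   cnv <= cfg$homozygous_del_log2)
    out[[length(out) + 1L]] <- rbind(
      build_calls(s, shared[tsg], "tsg_candidate", cn = cnv[tsg],
                  expr = ex[tsg], db = db[tsg]),
      build_calls(s, shared[onc], "oncogene_candidate", cn = cnv[onc],
                  expr = ex[onc], db = db[onc]),
      build_calls(s, shared[hom], "homozygous_del_silent", cn = cnv[hom],
                  expr = ex[hom], db = db[hom]))
  }
  if (!length(out)) return(integration_call_frame())
  do.call(rbind, out)
}

#' Cohort recurrence tally of integration calls
#'
#' Counts, per gene and category, the number of distinct samples carrying the
#' call (a gene called twice in one sample through two loci counts once).
#' Sorted by count descending, then gene name.
#'
#' @param calls integration-call data.frame.
#' @return data.frame: `gene_symbol`, `category`, `n_samples`, `samples`
#'   (comma-separated ids).
#' @export
recurrence <- function(calls) {
  if (!nrow(calls)) {
    return(data.frame(gene_symbol = character(0), category = character(0),
                      n_samples = integer(0), samples = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- unique(calls[, c("sample_id", "gene_symbol", "category")])
  agg <- split(key$sample_id, paste(key$gene_symbol, key$category, sep = "\r"))
  out <- do.call(rbind, lapply(names(agg), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    ss <- sort(unique(agg[[k]]))
    data.frame(gene_symbol = parts[1L], category = parts[2L],
               n_samples = length(ss), samples = paste(ss, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out[order(-out$n_samples, out$gene_symbol), , drop = FALSE]
}
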