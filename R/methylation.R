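#' Beta value from methylated/unmethylated intensities
#'
#' beta = M / (M + U), the methylation fraction in \[0, 1\]. Vectorised;
#' `M + U = 0` yields `NA` with a warning (no signal at the locus).
#'
#' @param M,U non-negative signal intensities.
#' @return Numeric vector of beta values.
#' @export
#' @examples
#' beta_from_intensities(300, 100) # 0.75
beta_from_intensities <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  tot <- M + U
  zero <- !is.na(tot) & tot == 0
  if (any(zero)) {
    warning(sum(zero), " locus/loci with M + U = 0 set to missing")
  }
  out <- M / tot
  out[zero] <- NA_real_
  out
}

#' Call differentially methylated loci between two groups
#'
#' Per locus, a two-sided Mann-Whitney test ([mann_whitney_test()]; exact
#' enumeration when both groups have at most 8 samples, tie- and
#' continuity-corrected normal approximation otherwise) plus an effect gate:
#' the locus is a DML iff p <= `dml_p` and |mean beta(A) - mean beta(B)| >=
#' `dml_delta_beta`. Direction is `hyper` when group A is more methylated.
#'
#' @param beta locus-level beta [omics_matrix()].
#' @param group_a,group_b sample ids of the two groups (>= 2 each).
#' @param cfg [analysis_config()].
#' @param apply_delta_filter disable to test significance alone (used for
#'   null calibration).
#' @return data.frame per locus: `locus_id`, `delta_beta`, `U`, `p`,
#'   `direction`, `selected`.
#' @export
call_dml <- function(beta, group_a, group_b, cfg = analysis_config(),
                     apply_delta_filter = TRUE) {
  group_a <- intersect(group_a, colnames(beta))
  group_b <- intersect(group_b, colnames(beta))
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 samples")
  }
  m <- unclass(beta)
  mw <- row_mann_whitney(m, group_a, group_b)
  delta <- rowMeans(m[, group_a, drop = FALSE], na.rm = TRUE) -
    rowMeans(m[, group_b, drop = FALSE], na.rm = TRUE)
  selected <- mw$p <= cfg$dml_p
  if (apply_delta_filter) selected <- selected & abs(delta) >= cfg$dml_delta_beta
  data.frame(locus_id = rownames(m), delta_beta = unname(delta),
             U = mw$U, p = mw$p,
             direction = ifelse(delta > 0, "hyper", "hypo"),
             selected = selected & !is.na(selected),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tumor-specific differentially methylated loci (dual-reference rule)
#'
#' A locus qualifies when it is called a DML against BOTH non-neoplastic
#' references (brain and breast) with the same direction, mirroring the
#' dual-reference differential-expression rule. Each DML is annotated with
#' its CpG-island flag, and hyper/hypo x island counts are attached as the
#' `"tally"` attribute. A pooled mode (both references merged into one group)
#' is available behind `pooled_reference`.
#'
#' @param beta locus-level beta [omics_matrix()].
#' @param meta sample metadata (groups BBM, NBn, NBr required).
#' @param ann methylation probe annotation (for the island flag).
#' @param cfg [analysis_config()].
#' @param pooled_reference compare BBM against NBn+NBr merged instead.
#' @return data.frame of qualifying loci: `locus_id`, `gene_symbol`,
#'   `cpg_island`, `delta_beta` (vs the pooled reference mean), per-reference
#'   p-values, `direction`.
#' @export
tumor_specific_dml <- function(beta, meta, ann, cfg = analysis_config(),
                               pooled_reference = FALSE) {
  meta <- validate_metadata(meta)
  bbm <- group_samples(meta, "BBM")
  nbn <- group_samples(meta, "NBn")
  nbr <- group_samples(meta, "NBr")
  m <- unclass(beta)
  pooled_delta <- rowMeans(m[, intersect(bbm, colnames(m)), drop = FALSE],
                           na.rm = TRUE) -
    rowMeans(m[, intersect(c(nbn, nbr), colnames(m)), drop = FALSE],
             na.rm = TRUE)
  if (pooled_reference) {
    one <- call_dml(beta, bbm, c(nbn, nbr), cfg)
    sel <- one$selected
    p_nbn <- p_nbr <- one$p
    direction <- one$direction
  } else {
    vs_nbn <- call_dml(beta, bbm, nbn, cfg)
    vs_nbr <- call_dml(beta, bbm, nbr, cfg)
    sel <- vs_nbn$selected & vs_nbr$selected &
      vs_nbn$direction == vs_nbr$direction
    p_nbn <- vs_nbn$p
    p_nbr <- vs_nbr$p
    direction <- vs_nbn$direction
  }
  idx <- match(rownames(m), ann$probe_id)
  out <- data.frame(
    locus_id = rownames(m),
    gene_symbol = ann$gene_symbol[idx],
    cpg_island = ann$cpg_island[idx],
    delta_beta = unname(pooled_delta),
    p_vs_nbn = p_nbn, p_vs_nbr = p_nbr,
    direction = direction, stringsAsFactors = FALSE,
    row.names = NULL)[which(sel), , drop = FALSE]
  rownames(out) <- NULL
  tally <- table(direction = out$direction,
                 cpg_island = factor(out$cpg_island, levels = c(FALSE, TRUE)))
  attr(out, "tally") <- tally
  out
}

#' Subtype-stratified differential methylation (ANOVA + Tukey + union)
#'
#' The methylation counterpart of [anova_subtypes()]: identical screening and
#' post-hoc machinery applied to beta values with the effect floor on the
#' beta scale (`dml_delta_beta`).
#'
#' @inheritParams anova_subtypes
#' @param beta locus-level beta [omics_matrix()].
#' @return As [anova_subtypes()].
#' @export
anova_subtype_dml <- function(beta, meta, cfg = analysis_config(),
                              screen_q = 0.05) {
  anova_subtypes(beta, meta, effect_floor = cfg$dml_delta_beta, cfg = cfg,
                 screen_q = screen_q)
}

#' Derive the CpG-island hypomethylator signature
#'
#' Among subtype-discriminating CpG-island loci, ranks loci by the median
#' beta in basal-like tumors minus the median beta in the other subtyped
#' tumors (ascending) and returns the `k` most hypomethylated-in-basal loci,
#' together with per-subtype median beta values. Only loci whose basal
#' median lies below the non-basal median qualify. The result is invariant
#' to locus input order.
#'
#' @param beta locus-level beta [omics_matrix()].
#' @param meta metadata (subtyped tumor samples are used).
#' @param ann methylation annotation carrying `cpg_island`.
#' @param candidate_loci subtype-discriminating loci (typically the union
#'   from [anova_subtype_dml()]).
#' @param k signature size (default 15).
#' @param allow_fewer return all qualifying loci with a warning when fewer
#'   than `k` qualify instead of erroring.
#' @return data.frame of the signature loci in rank order: `locus_id`,
#'   `gene_symbol`, `delta_median`, and per-subtype medians
#'   (`median_Basal`, `median_LumB`, `median_Her2ER-`).
#' @export
derive_cihmp <- function(beta, meta, ann, candidate_loci, k = 15L,
                         allow_fewer = FALSE) {
  meta <- validate_metadata(meta)
  idx <- match(candidate_loci, ann$probe_id)
  if (anyNA(idx)) stop("candidate loci missing from annotation")
  island <- candidate_loci[which(ann$cpg_island[idx])]
  island <- intersect(island, rownames(beta))
  tum <- meta[meta$group %in% c("BBM", "PRIMARY") &
                meta$subtype %in% ANOVA_SUBTYPES, , drop = FALSE]
  basal <- intersect(tum$sample_id[tum$subtype == "Basal"], colnames(beta))
  other <- intersect(tum$sample_id[tum$subtype != "Basal"], colnames(beta))
  if (!length(island)) stop("no CpG-island candidate loci")
  if (!length(basal) || !length(other)) stop("need basal and non-basal tumors")
  m <- unclass(beta)[island, , drop = FALSE]
  med_basal <- apply(m[, basal, drop = FALSE], 1L, median, na.rm = TRUE)
  med_other <- apply(m[, other, drop = FALSE], 1L, median, na.rm = TRUE)
  delta <- med_basal - med_other
  qual <- which(delta < 0)
  if (!length(qual)) stop("no loci hypomethylated in basal-like tumors")
  if (length(qual) < k) {
    msg <- sprintf("only %d of %d requested signature loci qualify",
                   length(qual), k)
    if (!allow_fewer) stop(msg)
    warning(msg)
    k <- length(qual)
  }
  ord <- qual[order(delta[qual], island[qual])][seq_len(k)]
  med_by <- function(samples) {
    apply(m[ord, intersect(samples, colnames(beta)), drop = FALSE], 1L,
          median, na.rm = TRUE)
  }
  out <- data.frame(
    locus_id = island[ord],
    gene_symbol = ann$gene_symbol[match(island[ord], ann$probe_id)],
    delta_median = unname(delta[ord]),
    median_Basal = unname(med_basal[ord]),
    stringsAsFactors = FALSE, row.names = NULL)
  for (s in setdiff(ANOVA_SUBTYPES, "Basal")) {
    out[[paste0("median_", s)]] <-
      unname(med_by(tum$sample_id[tum$subtype == s]))
  }
  out
}

#' Median beta over a sample/locus restriction
#'
#' @param beta locus-level beta [omics_matrix()].
#' @param samples,loci restriction (defaults: all).
#' @return Scalar median of all (locus, sample) beta values in the
#'   restriction; empty restrictions are an error.
#' @export
median_methylation <- function(beta, samples = colnames(beta),
                               loci = rownames(beta)) {
  samples <- intersect(samples, colnames(beta))
  loci <- intersect(loci, rownames(beta))
  if (!length(samples) || !length(loci)) stop("empty restriction")
  vals <- unclass(beta)[loci, samples, drop = FALSE]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("restriction holds no non-missing values")
  median(vals)
}

#' Per-locus ROC comparison of two groups
#'
#' AUC is the Mann-Whitney U statistic divided by n1*n2 (midrank ties), with
#' the positive class fixed to the first group (metastasis by convention,
#' reported so polarity is auditable); the p-value comes from the same
#' Mann-Whitney machinery as [call_dml()]. Loci constant in both groups give
#' AUC 0.5 with a warning.
#'
#' @param beta locus-level beta [omics_matrix()] (or plain matrix).
#' @param group_pos,group_neg sample ids (>= 2 each); `group_pos` is the
#'   positive class.
#' @param loci loci to evaluate (default all rows).
#' @return data.frame: `locus_id`, `auc`, `p`, `n_pos`, `n_neg`,
#'   `positive_class`.
#' @export
roc_locus <- function(beta, group_pos, group_neg, loci = rownames(beta)) {
  group_pos <- intersect(group_pos, colnames(beta))
  group_neg <- intersect(group_neg, colnames(beta))
  if (length(group_pos) < 2L || length(group_neg) < 2L) {
    stop("each group needs >= 2 samples")
  }
  m <- unclass(beta)[loci, , drop = FALSE]
  out <- lapply(seq_len(nrow(m)), function(i) {
    x <- m[i, group_pos]
    y <- m[i, group_neg]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(unique(c(x, y))) == 1L) {
      warning("constant values in both groups at locus ", loci[i],
              "; AUC set to 0.5")
      return(data.frame(locus_id = loci[i], auc = 0.5, p = 1,
                        n_pos = length(x), n_neg = length(y),
                        stringsAsFactors = FALSE))
    }
    mw <- mann_whitney_test(x, y)
    data.frame(locus_id = loci[i], auc = mw$U / (length(x) * length(y)),
               p = mw$p, n_pos = length(x), n_neg = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$positive_class <- "group_pos (metastasis convention)"
  out
}
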