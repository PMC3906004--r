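#' Call per-sample copy-number aberrations from segments
#'
#' ADM-2-style calling reduced to its reproducible content: a segment is
#' aberrant when it holds at least `adm2_min_probes` probes and its
#' |mean log2| reaches `adm2_min_abs_mean`; adjacent qualifying segments of
#' the same direction are merged (probe-weighted mean). Direction follows the
#' sign of the mean.
#'
#' @param segments segmented profile(s) as returned by [segment_profile()] /
#'   [segment_cohort()].
#' @param cfg [analysis_config()].
#' @return data.frame of aberrant regions: `sample_id`, `chrom`, `start`,
#'   `end`, `n_probes`, `mean_log2`, `direction` (`gain`/`loss`).
#' @export
call_aberrations <- function(segments, cfg = analysis_config()) {
  segments <- segments[order(segments$sample_id, segments$chrom,
                             segments$start), , drop = FALSE]
  qual <- segments$n_probes >= cfg$adm2_min_probes &
    abs(segments$seg_mean) >= cfg$adm2_min_abs_mean
  segs <- segments[qual, , drop = FALSE]
  out <- list()
  if (nrow(segs)) {
    segs$direction <- ifelse(segs$seg_mean > 0, "gain", "loss")
    # merge runs of adjacent qualifying segments with equal direction
    key <- paste(segs$sample_id, segs$chrom, segs$direction, sep = "\r")
    new_run <- c(TRUE, key[-1L] != key[-nrow(segs)] |
                   segs$start[-1L] != segs$end[-nrow(segs)])
    run <- cumsum(new_run)
    for (r in split(seq_len(nrow(segs)), run)) {
      block <- segs[r, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = block$sample_id[1L], chrom = block$chrom[1L],
        start = min(block$start), end = max(block$end),
        n_probes = sum(block$n_probes),
        mean_log2 = sum(block$seg_mean * block$n_probes) / sum(block$n_probes),
        direction = block$direction[1L], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), mean_log2 = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Per-probe signed aberration amplitude matrix
#'
#' Expands aberration calls onto the probe grid: entry (probe, sample) is the
#' call's mean log2 where the probe lies inside an aberrant region of that
#' sample, 0 elsewhere.
#'
#' @param calls output of [call_aberrations()].
#' @param ann copy-number probe annotation (defines the probe grid and order).
#' @param samples column order of the result.
#' @return probes x samples numeric matrix (rownames = probe ids in genome
#'   order).
#' @export
aberration_probe_matrix <- function(calls, ann, samples) {
  ord <- order(ann$chrom, ann$start)
  ann <- ann[ord, , drop = FALSE]
  A <- matrix(0, nrow(ann), length(samples),
              dimnames = list(ann$probe_id, samples))
  for (r in seq_len(nrow(calls))) {
    s <- calls$sample_id[r]
    if (!s %in% samples) next
    sel <- ann$chrom == calls$chrom[r] & ann$start >= calls$start[r] &
      ann$start < calls$end[r]
    A[sel, s] <- calls$mean_log2[r]
  }
  A
}

#' G-score: aberration frequency times mean amplitude
#'
#' For each probe, G = (fraction of samples aberrant in the direction) x
#' (mean |log2| amplitude among those samples); 0 where no sample is
#' aberrant. Equivalently the mean |amplitude| over all samples, zeros
#' included, which is how it is computed.
#'
#' @param amp probes x samples signed amplitude matrix
#'   ([aberration_probe_matrix()]).
#' @param direction `"gain"` or `"loss"`.
#' @return Named per-probe numeric G vector (non-negative).
#' @export
g_score <- function(amp, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (ncol(amp) < 2L) stop("G-score needs >= 2 samples")
  dirmat <- if (direction == "gain") pmax(amp, 0) else pmax(-amp, 0)
  rowSums(dirmat) / ncol(amp)
}

# pooled empirical exceedance p-values: for each observed G, the fraction of
# null G values (all probes x all permutations) at least as large
null_exceedance_p <- function(g_obs, perm_fun, nperm) {
  np <- length(g_obs)
  ord <- order(g_obs)
  sorted <- g_obs[ord]
  counts <- numeric(np + 1L)
  for (b in seq_len(nperm)) {
    v <- perm_fun()
    idx <- findInterval(v + 1e-12, sorted)  # number of observed G <= null value
    counts <- counts + tabulate(idx + 1L, nbins = np + 1L)
  }
  # exceedances for the r-th smallest observed G = null values with idx >= r
  suffix <- rev(cumsum(rev(counts)))
  exceed <- suffix[seq_len(np) + 1L]
  out <- numeric(np)
  out[ord] <- (1 + exceed) / (1 + nperm * np)
  out
}

#' Recurrently aberrant regions with permutation FDR
#'
#' Scores cohort recurrence per direction by the G-score and assesses it
#' against a null built from independent within-sample circular shifts of
#' each sample's aberration track (preserving per-sample aberration length
#' structure). Per-probe p-values are pooled empirical exceedance
#' probabilities, converted to q-values by Benjamini-Hochberg; maximal runs
#' of probes with q below `gistic_q` become regions, classified focal or
#' broad by the arm-fraction rule.
#'
#' @param calls per-sample aberration calls ([call_aberrations()]).
#' @param ann copy-number probe annotation.
#' @param samples cohort sample ids (>= 4 required).
#' @param arms arm table ([synthetic_genome()] layout: `chrom`, `arm`,
#'   `start`, `end`).
#' @param cfg [analysis_config()]; `cfg$permutations` < 100 is an error.
#' @param gene_ann optional gene intervals (or probe annotation) used to
#'   attach the genes overlapping each region.
#' @return data.frame of regions: `chrom`, `start`, `end`, `direction`,
#'   `g_score` (region maximum), `q_value` (region minimum), `n_probes`,
#'   `scope` (`focal`/`broad`), `genes` (comma-separated, possibly empty).
#'   The per-probe scores are attached as attribute `"probe_scores"`.
#' @export
recurrent_regions <- function(calls, ann, samples, arms,
                              cfg = analysis_config(), gene_ann = NULL) {
  if (length(samples) < 4L) stop("recurrence scoring needs >= 4 samples")
  if (cfg$permutations < 100L) stop("permutations must be >= 100")
  set.seed(cfg$seed)
  ord <- order(ann$chrom, ann$start)
  ann <- ann[ord, , drop = FALSE]
  A <- aberration_probe_matrix(calls, ann, samples)
  np <- nrow(A)
  genes <- if (!is.null(gene_ann)) {
    if ("probe_id" %in% names(gene_ann)) gene_intervals(gene_ann) else gene_ann
  }
  probe_scores <- data.frame(probe_id = ann$probe_id, chrom = ann$chrom,
                             start = ann$start, stringsAsFactors = FALSE)
  regions <- list()
  for (direction in c("gain", "loss")) {
    dirmat <- if (direction == "gain") pmax(A, 0) else pmax(-A, 0)
    g_obs <- rowSums(dirmat) / ncol(dirmat)
    perm_fun <- function() {
      shifted <- dirmat
      off <- sample.int(np, ncol(dirmat), replace = TRUE)
      for (s in seq_len(ncol(dirmat))) {
        shifted[, s] <- dirmat[((seq_len(np) - 1L + off[s]) %% np) + 1L, s]
      }
      rowSums(shifted) / ncol(shifted)
    }
    p <- null_exceedance_p(g_obs, perm_fun, cfg$permutations)
    q <- p.adjust(p, method = "BH")
    probe_scores[[paste0("g_", direction)]] <- g_obs
    probe_scores[[paste0("p_", direction)]] <- p
    probe_scores[[paste0("q_", direction)]] <- q
    sig <- which(q < cfg$gistic_q & g_obs > 0)
    if (!length(sig)) next
    run <- cumsum(c(TRUE, diff(sig) != 1L |
                      ann$chrom[sig][-1L] != ann$chrom[sig][-length(sig)]))
    for (idx in split(sig, run)) {
      start <- ann$start[idx[1L]]
      end <- ann$start[idx[length(idx)]] + 1L
      arm <- containing_arm(arms, ann$chrom[idx[1L]], start, end)
      scope <- if (!is.null(arm) &&
                   (end - start) >= cfg$broad_arm_fraction * (arm$end - arm$start))
        "broad" else "focal"
      gtxt <- ""
      if (!is.null(genes)) {
        hit <- genes$chrom == ann$chrom[idx[1L]] & genes$end > start &
          genes$start < end
        gtxt <- paste(genes$gene_symbol[hit], collapse = ",")
      }
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ann$chrom[idx[1L]], start = start, end = end,
        direction = direction, g_score = max(g_obs[idx]),
        q_value = min(q[idx]), n_probes = length(idx), scope = scope,
        genes = gtxt, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               direction = character(0), g_score = numeric(0),
               q_value = numeric(0), n_probes = integer(0),
               scope = character(0), genes = character(0),
               stringsAsFactors = FALSE)
  attr(out, "probe_scores") <- probe_scores
  out
}

#' Homozygously deleted and silenced genes per sample
#'
#' A gene qualifies in a sample when its copy-number log2 is at or below the
#' homozygous-deletion level and its expression log2 ratio is at or below
#' minus the integration expression gate (deleted with loss of expression).
#'
#' @param gene_cn genes x samples copy-number log2 matrix (NA = no call).
#' @param gene_expr genes x samples expression log2 matrix, same gene
#'   universe.
#' @param cfg [analysis_config()].
#' @return data.frame (`sample_id`, `gene_symbol`, `cn_log2`, `expr_log2`).
#' @export
homozygous_deletions <- function(gene_cn, gene_expr, cfg = analysis_config()) {
  shared <- intersect(rownames(gene_cn), rownames(gene_expr))
  samples <- intersect(colnames(gene_cn), colnames(gene_expr))
  if (!length(shared)) stop("empty gene intersection")
  out <- list()
  for (s in samples) {
    cnv <- gene_cn[shared, s]
    ex <- gene_expr[shared, s]
    sel <- which(!is.na(cnv) & !is.na(ex) &
                   cnv <= cfg$homozygous_del_log2 &
                   ex <= -cfg$integ_expr_log2)
    if (length(sel)) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, gene_symbol = shared[sel],
        cn_log2 = cnv[sel], expr_log2 = ex[sel],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(0), gene_symbol = character(0),
                      cn_log2 = numeric(0), expr_log2 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
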