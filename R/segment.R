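#' Segment a per-sample copy-number profile
#'
#' Recursive binary segmentation in the circular style: at each step the pair
#' of window boundaries maximising the pooled two-sample t statistic between
#' the probes inside and outside the arc is located; the split is accepted
#' when its permutation p-value (label permutations of the probe values
#' within the segment under test) is at most `alpha`, and the accepted pieces
#' are segmented recursively. Chromosomes are segmented independently;
#' segment means are arithmetic means of member probes, so the probe-count
#' weighted mean of segment means reproduces the profile mean exactly.
#'
#' @param values numeric vector of copy-number log2 ratios, probe order.
#' @param positions integer probe positions (0-based), sorted within each
#'   chromosome; unsorted input is an error.
#' @param chrom chromosome of each probe (single string recycled, or vector).
#' @param sample_id label written into the output.
#' @param alpha split-acceptance significance level.
#' @param nperm permutations per split test.
#' @param seed optional seed set before the permutation stream.
#' @return Segment data.frame (`sample_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `seg_mean`, plus 1-based probe index bounds `first_probe`,
#'   `last_probe` within the chromosome).
#' @export
#' @examples
#' x <- c(rep(0, 25), rep(1, 25))
#' segment_profile(x, seq_along(x) * 100L, "chr1", nperm = 200)
segment_profile <- function(values, positions, chrom = "chr1",
                            sample_id = "sample", alpha = 0.01,
                            nperm = 1000L, seed = NULL) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(values))
  stopifnot(length(values) == length(positions),
            length(values) == length(chrom))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    pos <- positions[sel]
    if (is.unsorted(pos, strictly = FALSE)) {
      stop("probes must be sorted by position within chromosome ", ch)
    }
    if (length(sel) < 2L) stop("need >= 2 probes on chromosome ", ch)
    x <- values[sel]
    bounds <- cbs_recurse(x, alpha, nperm)  # list of c(first, last), 1-based
    for (b in bounds) {
      i <- b[1L]:b[2L]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = ch,
        start = pos[b[1L]], end = pos[b[2L]] + 1L,
        n_probes = length(i), seg_mean = mean(x[i]),
        first_probe = b[1L], last_probe = b[2L],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# returns list of 1-based (first, last) probe-index bounds tiling 1..n
cbs_recurse <- function(x, alpha, nperm) {
  n <- length(x)
  if (n < 3L) return(list(c(1L, n)))
  sp <- .cbs_best_split(x, as.integer(nperm), alpha)
  if (sp$p > alpha || sp$t <= 0) return(list(c(1L, n)))
  cuts <- sort(unique(c(0L, sp$i, sp$j, n)))
  cuts <- cuts[cuts > 0L & cuts < n]
  if (!length(cuts)) return(list(c(1L, n)))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  out <- list()
  for (k in seq_along(starts)) {
    sub <- cbs_recurse(x[starts[k]:ends[k]], alpha, nperm)
    for (b in sub) {
      out[[length(out) + 1L]] <- b + starts[k] - 1L
    }
  }
  out
}

#' Segment every tumor sample of a copy-number matrix
#'
#' @param cn probe-level copy-number [omics_matrix()].
#' @param ann copy-number probe annotation (positions define probe order).
#' @param samples samples to segment (default: all columns).
#' @param cfg [analysis_config()] supplying `cbs_alpha`, `cbs_nperm`, `seed`.
#' @return Combined segment data.frame over the samples.
#' @export
segment_cohort <- function(cn, ann, samples = colnames(cn),
                           cfg = analysis_config()) {
  idx <- match(rownames(cn), ann$probe_id)
  if (anyNA(idx)) stop("copy-number matrix contains unannotated probes")
  ord <- order(ann$chrom[idx], ann$start[idx])
  set.seed(cfg$seed)
  segs <- lapply(samples, function(s) {
    segment_profile(unclass(cn)[ord, s], ann$start[idx][ord],
                    ann$chrom[idx][ord], sample_id = s,
                    alpha = cfg$cbs_alpha, nperm = cfg$cbs_nperm)
  })
  do.call(rbind, segs)
}
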