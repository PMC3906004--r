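#' Synthetic genome layout
#'
#' A compact genome of a few metacentric chromosomes, each split into a p and
#' q arm at a recorded centromere, so that arm-level (broad) and sub-arm
#' (focal) copy-number events can be distinguished exactly. Coordinates are
#' 0-based half-open.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @param centromere_fraction fractional position of the centromere.
#' @return data.frame with one row per arm: `chrom`, `arm` (`"p"`/`"q"`),
#'   `start`, `end`.
#' @export
synthetic_genome <- function(n_chrom = 4L, chrom_length = 4e7,
                             centromere_fraction = 0.45) {
  stopifnot(n_chrom >= 1L, chrom_length > 0, centromere_fraction > 0,
            centromere_fraction < 1)
  cen <- round(chrom_length * centromere_fraction)
  do.call(rbind, lapply(seq_len(n_chrom), function(k) {
    data.frame(chrom = rep(paste0("chr", k), 2L),
               arm = c("p", "q"),
               start = c(0, cen),
               end = c(cen, chrom_length),
               stringsAsFactors = FALSE)
  }))
}

# arm containing (by maximal overlap) an interval [start, end) on chrom
containing_arm <- function(arms, chrom, start, end) {
  cand <- arms[arms$chrom == chrom, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  ov <- pmax(0, pmin(end, cand$end) - pmax(start, cand$start))
  cand[which.max(ov), , drop = FALSE]
}
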