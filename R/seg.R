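#' Segmented copy-number profiles and SEG interchange
#'
#' A segmented profile is a data.frame with columns `sample_id`, `chrom`,
#' `start`, `end` (0-based half-open internally), `n_probes` and `seg_mean`.
#' [write_seg()] emits the canonical six-column SEG format (sample, chromosome,
#' start, end, num probes, segment mean) with 1-based inclusive coordinates;
#' [read_seg()] converts back, so a write/read round trip is the identity.
#' Overlapping segments within a sample and chromosome are an error.
#'
#' @param segments a segmented-profile data.frame (one or more samples).
#' @param path file path.
#' @return `write_seg` returns `path` invisibly; `read_seg` returns the
#'   internal segment data.frame.
#' @export
write_seg <- function(segments, path) {
  segments <- validate_segments(segments)
  out <- data.frame(
    Sample = segments$sample_id,
    Chromosome = segments$chrom,
    Start = segments$start + 1L,   # SEG convention: 1-based inclusive
    End = segments$end,
    Num_Probes = segments$n_probes,
    Segment_Mean = segments$seg_mean,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "integer", "integer", "numeric"))
  segs <- data.frame(
    sample_id = raw[[1L]], chrom = raw[[2L]],
    start = raw[[3L]] - 1L, end = raw[[4L]],
    n_probes = raw[[5L]], seg_mean = raw[[6L]],
    stringsAsFactors = FALSE
  )
  validate_segments(segs)
}

validate_segments <- function(segments) {
  need <- c("sample_id", "chrom", "start", "end", "n_probes", "seg_mean")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segments lack column(s): ", paste(miss, collapse = ", "))
  if (any(segments$start >= segments$end)) {
    stop("segment intervals must satisfy start < end")
  }
  if (any(segments$n_probes < 1L)) stop("segments must contain >= 1 probe")
  for (key in split(seq_len(nrow(segments)),
                    paste(segments$sample_id, segments$chrom, sep = "\r"))) {
    if (length(key) < 2L) next
    o <- key[order(segments$start[key])]
    if (any(segments$start[o][-1L] < segments$end[o][-length(o)])) {
      stop(sprintf("overlapping segments in sample '%s' chromosome '%s'",
                   segments$sample_id[o[1L]], segments$chrom[o[1L]]))
    }
  }
  segments[order(segments$sample_id, segments$chrom, segments$start), ,
           drop = FALSE]
}
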