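#' Probe annotation tables
#'
#' Annotation maps platform probes to gene symbols and genomic coordinates
#' (0-based half-open internally). Columns: `probe_id`, `gene_symbol` (may be
#' empty), `chrom`, `start`, `end`, and `cpg_island` (logical; required for
#' methylation platforms, `NA` elsewhere). Probes carrying several symbols
#' separated by `;` or `,` are resolved to the first listed symbol, and the
#' resolution is logged.
#'
#' @param ann a data.frame with the columns above.
#' @param methylation if `TRUE`, require a non-missing `cpg_island` flag on
#'   every probe.
#' @return The validated annotation data.frame (first-symbol resolved).
#' @export
validate_annotation <- function(ann, methylation = FALSE) {
  need <- c("probe_id", "gene_symbol", "chrom", "start", "end")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (!"cpg_island" %in% names(ann)) ann$cpg_island <- NA
  if (anyDuplicated(ann$probe_id)) {
    stop("duplicate probe id(s): ",
         paste(unique(ann$probe_id[duplicated(ann$probe_id)]), collapse = ", "))
  }
  if (any(!is.na(ann$start) & !is.na(ann$end) & ann$start >= ann$end)) {
    stop("annotation intervals must satisfy start < end (0-based half-open)")
  }
  if (any(is.na(ann$chrom) | !nzchar(ann$chrom))) stop("empty chromosome name")
  if (methylation && any(is.na(ann$cpg_island))) {
    stop("cpg_island flag must be defined for every methylation probe")
  }
  multi <- grepl("[;,]", ann$gene_symbol)
  if (any(multi)) {
    ann$gene_symbol <- sub("[;,].*$", "", ann$gene_symbol)
    .bbm_log(sum(multi), " probe(s) mapped to multiple symbols; first symbol kept")
  }
  ann$cpg_island <- as.logical(ann$cpg_island)
  ann
}

#' @rdname validate_annotation
#' @param path file path of a tab-delimited annotation table.
#' @export
read_annotation <- function(path, methylation = FALSE) {
  ann <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE,
                    colClasses = c(probe_id = "character",
                                   gene_symbol = "character",
                                   chrom = "character"))
  validate_annotation(ann, methylation = methylation)
}

#' @rdname validate_annotation
#' @export
write_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample metadata
#'
#' Columns: `sample_id`, `group` (one of BBM, NBn, NBr, PRIMARY) and optional
#' `subtype` (LumA, LumB, Her2ER-, Basal, NormalLike, unknown; only meaningful
#' for tumor groups).
#'
#' @param meta a data.frame with the columns above.
#' @return The validated metadata data.frame.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample id in metadata")
  bad <- setdiff(unique(meta$group), BBM_GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!"subtype" %in% names(meta)) meta$subtype <- "unknown"
  meta$subtype[is.na(meta$subtype)] <- "unknown"
  bad <- setdiff(unique(meta$subtype), BBM_SUBTYPES)
  if (length(bad)) stop("unknown subtype label(s): ", paste(bad, collapse = ", "))
  meta
}

#' @rdname validate_metadata
#' @param path file path of a tab-delimited metadata table.
#' @export
read_metadata <- function(path) {
  validate_metadata(read.delim(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

#' @rdname validate_metadata
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

group_samples <- function(meta, group) meta$sample_id[meta$group == group]
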