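OMICS_MODALITIES <- c("cn_log2", "expr_log2", "beta")

#' Labeled single-modality omics matrix
#'
#' A feature x sample numeric matrix tagged with its modality. Beta-value
#' matrices must lie in \[0, 1\] (missing values allowed, encoded as `NA`);
#' out-of-range values are an error, never silently clamped. Feature and
#' sample identifiers must be unique.
#'
#' @param values numeric matrix with feature rownames and sample colnames.
#' @param modality one of `"cn_log2"`, `"expr_log2"`, `"beta"`.
#' @return An `omics_matrix`: the matrix with a `modality` attribute.
#' @export
#' @examples
#' m <- omics_matrix(matrix(runif(6), 3, 2,
#'   dimnames = list(paste0("cg", 1:3), c("s1", "s2"))), "beta")
#' modality(m)
omics_matrix <- function(values, modality = c("cn_log2", "expr_log2", "beta")) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("values must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(fid)) {
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (modality == "beta") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "beta value out of [0,1] at feature '%s', sample '%s' (value %g)",
        fid[bad[1, 1]], sid[bad[1, 2]], values[bad[1, , drop = FALSE]]))
    }
  }
  structure(values, modality = modality, class = c("omics_matrix", "matrix", "array"))
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`.
#' @export
modality <- function(x) attr(x, "modality")

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples (%d missing)\n",
              modality(x), nrow(x), ncol(x), sum(is.na(x))))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 4L))
  invisible(x)
}

#' Read a tab-delimited omics matrix
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers; the body must be numeric apart from the missing-value token.
#' Duplicated identifiers and non-numeric cells are hard errors reporting the
#' offending coordinates; beta values outside \[0, 1\] are rejected.
#'
#' @param path file path.
#' @param modality matrix modality, as in [omics_matrix()].
#' @param na_token string representing missing values (default `"NA"`).
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, modality = c("cn_log2", "expr_log2", "beta"),
                        na_token = "NA") {
  modality <- match.arg(modality)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("matrix file needs a feature column plus samples: ", path)
  fid <- raw[[1L]]
  if (anyDuplicated(fid)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  sid <- colnames(raw)[-1L]
  if (anyDuplicated(sid)) {
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  body[body == na_token] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric cell in %s at feature '%s' (row %d), sample '%s': '%s'",
      path, fid[bad[1, 1]], bad[1, 1], sid[bad[1, 2]],
      body[bad[1, , drop = FALSE]]))
  }
  dimnames(num) <- list(fid, sid)
  omics_matrix(num, modality)
}

#' Write an omics matrix as tab-delimited text
#'
#' Inverse of [read_matrix()]: first column `feature_id`, one column per
#' sample, missing values as the token.
#'
#' @param m an [omics_matrix()] (or plain named matrix).
#' @param path output file path.
#' @param na_token missing-value token.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, na_token = "NA") {
  df <- data.frame(feature_id = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = na_token)
  invisible(path)
}
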