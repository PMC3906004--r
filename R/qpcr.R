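#' Delta-Ct of a Ct record set
#'
#' Replicate Ct values are averaged per assay first; the reference level is
#' the arithmetic mean of the per-assay reference Ct values — the log2 of the
#' geometric mean of the linear reference quantities, which is how a
#' multi-reference geometric mean enters the Ct scale. Delta-Ct is the
#' target Ct minus that combined reference Ct.
#'
#' @param cts data.frame with columns `assay_id`, `role`
#'   (`"target"`/`"reference"`), `ct`, and optionally `replicate`.
#' @return list: `dct`, `ct_target`, `ct_reference`.
#' @export
delta_ct <- function(cts) {
  need <- c("assay_id", "role", "ct")
  miss <- setdiff(need, names(cts))
  if (length(miss)) stop("Ct records lack column(s): ", paste(miss, collapse = ", "))
  if (any(cts$ct <= 0)) stop("Ct values must be positive")
  per_assay <- tapply(cts$ct, cts$assay_id, mean)
  roles <- tapply(cts$role, cts$assay_id, function(r) unique(r))
  if (any(lengths(roles) != 1L)) stop("assay with inconsistent role")
  targets <- names(roles)[unlist(roles) == "target"]
  refs <- names(roles)[unlist(roles) == "reference"]
  if (length(targets) != 1L) stop("need exactly one target assay, got ",
                                  length(targets))
  if (!length(refs)) stop("missing reference assay")
  ct_t <- unname(per_assay[targets])
  ct_r <- mean(per_assay[refs])
  list(dct = ct_t - ct_r, ct_target = ct_t, ct_reference = ct_r)
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = dCt(sample) - dCt(calibrator); the returned fold-change is
#' 2^-ddCt, assuming perfect doubling per cycle. In the published assays the
#' calibrator is the average of the non-neoplastic breast and brain samples.
#'
#' @param sample_cts,calibrator_cts Ct record sets (see [delta_ct()]).
#' @return Scalar fold-change.
#' @export
#' @examples
#' s <- data.frame(assay_id = c("T", "R"), role = c("target", "reference"),
#'                 ct = c(25, 20))
#' cal <- data.frame(assay_id = c("T", "R"), role = c("target", "reference"),
#'                   ct = c(27, 20))
#' relative_expression(s, cal) # dCt 5 vs 7 -> fold 4
relative_expression <- function(sample_cts, calibrator_cts) {
  ddct <- delta_ct(sample_cts)$dct - delta_ct(calibrator_cts)$dct
  2^(-ddct)
}

#' Relative copy number by the 2^-ddCt method
#'
#' Same machinery against a multicopy reference assay; with
#' `diploid_calibrator = TRUE` the ratio is scaled so the calibrator
#' represents 2 copies and absolute copy number is returned.
#'
#' @inheritParams relative_expression
#' @param diploid_calibrator return copies assuming a diploid calibrator.
#' @return Scalar copy ratio (or copy number).
#' @export
relative_copy_number <- function(sample_cts, calibrator_cts,
                                 diploid_calibrator = FALSE) {
  ratio <- relative_expression(sample_cts, calibrator_cts)
  if (diploid_calibrator) 2 * ratio else ratio
}
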