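#' Tri-group differential expression against dual references
#'
#' Implements the study's selection rule for tumor-specific genes: a gene is
#' differentially expressed when it separates tumors from BOTH non-neoplastic
#' references while the references do not differ from each other. Per gene,
#' three two-sided Welch t-tests are run on log2 values (BBM vs NBn, BBM vs
#' NBr, NBn vs NBr); "evident" differential expression in a comparison means
#' p <= `deg_p` together with |FC| >= `deg_fc` (FC = 2^ difference of group
#' means). The gene is selected iff expression differs evidently from both
#' references with concordant direction and does NOT differ evidently
#' between the two references. No multiplicity correction
#' is applied inside the rule (matching the published criteria); BH q-values
#' over the pooled-reference test are attached when `adjust = TRUE`.
#'
#' @param expr gene-level expression [omics_matrix()] (log2 ratios).
#' @param meta sample metadata; each of BBM, NBn, NBr needs >= 2 samples.
#' @param cfg [analysis_config()].
#' @param adjust attach BH q-values computed across genes (off by default).
#' @return data.frame, one row per gene: per-comparison log2 fold-changes and
#'   p-values, pooled-reference effect (`log2fc`), `direction`, `selected`.
#' @export
deg_trigroup <- function(expr, meta, cfg = analysis_config(), adjust = FALSE) {
  meta <- validate_metadata(meta)
  g <- lapply(c(BBM = "BBM", NBn = "NBn", NBr = "NBr"), function(grp) {
    intersect(group_samples(meta, grp), colnames(expr))
  })
  short <- names(g)[vapply(g, length, 1L) < 2L]
  if (length(short)) {
    stop("group(s) with < 2 samples: ", paste(short, collapse = ", "))
  }
  m <- unclass(expr)
  welch <- function(v, a, b) {
    va <- v[a][!is.na(v[a])]
    vb <- v[b][!is.na(v[b])]
    if (length(va) < 2L || length(vb) < 2L ||
        (stats::var(va) == 0 && stats::var(vb) == 0)) {
      return(c(mean(va) - mean(vb),
               if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0))
    }
    tt <- t.test(va, vb)
    c(unname(tt$estimate[1L] - tt$estimate[2L]), tt$p.value)
  }
  res <- t(apply(m, 1L, function(v) {
    c(welch(v, g$BBM, g$NBn), welch(v, g$BBM, g$NBr), welch(v, g$NBn, g$NBr))
  }))
  lfc <- log2(cfg$deg_fc)
  d1 <- res[, 1L]; p1 <- res[, 2L]
  d2 <- res[, 3L]; p2 <- res[, 4L]
  d3 <- res[, 5L]; p3 <- res[, 6L]
  pooled <- rowMeans(m[, g$BBM, drop = FALSE], na.rm = TRUE) -
    rowMeans(m[, c(g$NBn, g$NBr), drop = FALSE], na.rm = TRUE)
  ref_differ <- p3 <= cfg$deg_p & abs(d3) >= lfc
  selected <- p1 <= cfg$deg_p & p2 <= cfg$deg_p & !ref_differ &
    abs(d1) >= lfc & abs(d2) >= lfc & sign(d1) == sign(d2)
  out <- data.frame(
    gene = rownames(m),
    log2fc = pooled, fold_change = sign(pooled) * 2^abs(pooled),
    log2fc_bbm_nbn = d1, p_bbm_nbn = p1,
    log2fc_bbm_nbr = d2, p_bbm_nbr = p2,
    log2fc_nbn_nbr = d3, p_nbn_nbr = p3,
    direction = ifelse(pooled > 0, "up", "down"),
    selected = selected & !is.na(selected),
    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust) {
    pmax2 <- pmax(p1, p2)
    out$q <- p.adjust(pmax2, method = "BH")
  }
  out
}

#' Subtype-stratified one-way ANOVA with Tukey post-hoc and union
#'
#' Restricted to the three well-represented intrinsic subtypes (LumB,
#' Her2ER-, Basal; LumA and normal-like tumors are excluded for sample-size
#' reasons upstream). Per feature a one-way ANOVA is computed; features are
#' screened at BH q <= 0.05 across features; Tukey HSD pairwise comparisons
#' are then kept when the Tukey-adjusted p is <= 0.05 and the absolute
#' pairwise effect reaches `effect_floor` (log2(deg_fc) for expression, the
#' delta-beta gate for methylation). The union is the deduplicated feature
#' set over the three pairwise lists.
#'
#' @param x feature x sample matrix (gene-level expression or locus-level
#'   beta) restricted implicitly to subtyped tumor samples via `meta`.
#' @param meta metadata carrying `subtype`; each retained subtype needs >= 2
#'   samples, a missing subtype is an error.
#' @param effect_floor minimum |pairwise effect|.
#' @param cfg [analysis_config()].
#' @param screen_q BH screening level across features.
#' @return list: `anova` (feature, p, q), `pairwise` (named list of
#'   data.frames feature/effect/p_tukey), `union` (character vector).
#' @export
anova_subtypes <- function(x, meta, effect_floor, cfg = analysis_config(),
                           screen_q = 0.05) {
  meta <- validate_metadata(meta)
  keep <- meta$subtype %in% ANOVA_SUBTYPES &
    meta$sample_id %in% colnames(x) & meta$group %in% c("BBM", "PRIMARY")
  meta <- meta[keep, , drop = FALSE]
  counts <- table(factor(meta$subtype, levels = ANOVA_SUBTYPES))
  if (any(counts < 2L)) {
    stop("subtype group(s) missing or with < 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  m <- unclass(x)[, meta$sample_id, drop = FALSE]
  grp <- factor(meta$subtype, levels = ANOVA_SUBTYPES)
  pvals <- apply(m, 1L, function(v) {
    ok <- !is.na(v)
    fit <- aov(v[ok] ~ grp[ok])
    summary(fit)[[1L]][["Pr(>F)"]][1L]
  })
  q <- p.adjust(pvals, method = "BH")
  pairs <- utils::combn(ANOVA_SUBTYPES, 2L)
  pair_names <- apply(pairs, 2L, function(p) paste(p[2L], "vs", p[1L]))
  pairwise <- setNames(vector("list", ncol(pairs)), pair_names)
  for (nm in pair_names) {
    pairwise[[nm]] <- data.frame(feature = character(0), effect = numeric(0),
                                 p_tukey = numeric(0), stringsAsFactors = FALSE)
  }
  for (f in which(q <= screen_q)) {
    v <- m[f, ]
    ok <- !is.na(v)
    fit <- aov(v[ok] ~ g, data = data.frame(g = grp[ok]))
    tk <- TukeyHSD(fit)[[1L]]
    for (r in rownames(tk)) {
      # subtype tokens may themselves end in '-', so resolve the comparison
      # label against the known level set rather than splitting on dashes
      lv <- resolve_tukey_pair(r, levels(grp))
      nm <- paste(lv[1L], "vs", lv[2L])
      if (!nm %in% pair_names) nm <- paste(lv[2L], "vs", lv[1L])
      eff <- tk[r, "diff"]
      if (!is.na(tk[r, "p adj"]) && tk[r, "p adj"] <= 0.05 &&
          abs(eff) >= effect_floor) {
        pairwise[[nm]] <- rbind(pairwise[[nm]], data.frame(
          feature = rownames(m)[f], effect = unname(eff),
          p_tukey = unname(tk[r, "p adj"]), stringsAsFactors = FALSE))
      }
    }
  }
  list(anova = data.frame(feature = rownames(m), p = pvals, q = q,
                          row.names = NULL, stringsAsFactors = FALSE),
       pairwise = pairwise,
       union = sort(unique(unlist(lapply(pairwise, `[[`, "feature")))))
}

# TukeyHSD names comparisons "B-A"; subtype labels can contain '-', so match
# against the actual level set instead of splitting on the first dash
resolve_tukey_pair <- function(label, levels) {
  for (a in levels) {
    for (b in levels) {
      if (a != b && identical(label, paste0(b, "-", a))) return(c(b, a))
    }
  }
  stop("cannot resolve Tukey comparison label: ", label)
}

#' Nearest-centroid intrinsic subtype classification
#'
#' Assigns each tumor sample the subtype whose centroid has the highest
#' Spearman correlation with the sample over the genes shared between the
#' expression matrix and the centroid table. Rank correlation makes the call
#' invariant to monotone transforms of the sample profile. Ties are broken
#' by centroid column order with a warning.
#'
#' @param expr gene-level expression matrix (samples to classify in columns).
#' @param centroids gene x subtype centroid matrix; >= 5 shared genes are
#'   required (an error otherwise); shortfalls against the full centroid
#'   gene list are logged.
#' @return data.frame: `sample_id`, `subtype`, plus one correlation column
#'   per centroid (`cor_<subtype>`), for audit.
#' @export
classify_subtype <- function(expr, centroids) {
  shared <- intersect(rownames(expr), rownames(centroids))
  if (length(shared) < 5L) {
    stop("need >= 5 genes shared with the centroid table, got ",
         length(shared))
  }
  if (length(shared) < nrow(centroids)) {
    .bbm_log(nrow(centroids) - length(shared),
             " centroid gene(s) absent from the expression matrix")
  }
  e <- unclass(expr)[shared, , drop = FALSE]
  ce <- centroids[shared, , drop = FALSE]
  cors <- cor(e, ce, method = "spearman", use = "pairwise.complete.obs")
  best <- apply(cors, 1L, function(v) {
    top <- which(v == max(v))
    if (length(top) > 1L) {
      warning("centroid correlation tie; first subtype in column order kept")
    }
    top[1L]
  })
  out <- data.frame(sample_id = colnames(e),
                    subtype = colnames(ce)[best],
                    stringsAsFactors = FALSE, row.names = NULL)
  for (s in colnames(ce)) out[[paste0("cor_", s)]] <- cors[, s]
  out
}

#' Read or write a subtype centroid table
#'
#' Tab-delimited, first column `gene_symbol`, one column per subtype; no
#' missing entries and at least two subtypes.
#'
#' @param path file path.
#' @param centroids gene x subtype numeric matrix.
#' @return `read_centroids` returns the centroid matrix.
#' @export
read_centroids <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- raw[[1L]]
  if (ncol(m) < 2L) stop("centroid table needs >= 2 subtypes")
  if (anyNA(m)) stop("centroid table must have no missing entries")
  m
}

#' @rdname read_centroids
#' @export
write_centroids <- function(centroids, path) {
  df <- data.frame(gene_symbol = rownames(centroids), centroids,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
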