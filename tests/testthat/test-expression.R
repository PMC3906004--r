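make_trigroup_matrix <- function(n_genes, n_per_group, effects, sd = 0.1,
                                 seed = 1L) {
  # effects: list(bbm=, nbn=, nbr=) vectors of per-gene group shifts
  set.seed(seed)
  ids <- sprintf("G%03d", seq_len(n_genes))
  cols <- c(sprintf("BBM%02d", seq_len(n_per_group)),
            sprintf("NBn%02d", seq_len(n_per_group)),
            sprintf("NBr%02d", seq_len(n_per_group)))
  m <- matrix(rnorm(n_genes * 3 * n_per_group, 0, sd), n_genes,
              dimnames = list(ids, cols))
  m[, 1:n_per_group] <- m[, 1:n_per_group] + effects$bbm
  m[, n_per_group + 1:n_per_group] <- m[, n_per_group + 1:n_per_group] +
    effects$nbn
  m[, 2 * n_per_group + 1:n_per_group] <- m[, 2 * n_per_group +
                                              1:n_per_group] + effects$nbr
  meta <- data.frame(sample_id = cols,
                     group = rep(c("BBM", "NBn", "NBr"), each = n_per_group),
                     stringsAsFactors = FALSE)
  list(expr = omics_matrix(m, "expr_log2"), meta = meta)
}

test_that("tri-group rule selects tumor-specific genes and excludes reference-only ones", {
  eff <- list(bbm = c(3, 0, 0), nbn = c(0, 2, 0), nbr = c(0, 0, 0))
  d <- make_trigroup_matrix(3, 10, eff, sd = 0.1, seed = 2L)
  res <- deg_trigroup(d$expr, d$meta)
  expect_true(res$selected[1L])               # planted extreme tumor effect
  expect_identical(res$direction[1L], "up")
  expect_false(res$selected[2L])              # differs only between references
  expect_false(res$selected[3L])              # null gene

  # any group below 2 samples is an error
  meta_bad <- d$meta[-(11:19), ]
  expect_error(deg_trigroup(d$expr, meta_bad), "< 2 samples")
})

test_that("tri-group rule is invariant to sample order and global shifts", {
  eff <- list(bbm = rep(c(3, 0), 5), nbn = rep(0, 10), nbr = rep(0, 10))
  d <- make_trigroup_matrix(10, 6, eff, sd = 0.2, seed = 3L)
  base <- deg_trigroup(d$expr, d$meta)
  perm <- sample(ncol(d$expr))
  shuffled <- omics_matrix(unclass(d$expr)[, perm], "expr_log2")
  expect_equal(deg_trigroup(shuffled, d$meta)$selected, base$selected)
  shifted <- omics_matrix(unclass(d$expr) + 5, "expr_log2")
  shifted_res <- deg_trigroup(shifted, d$meta)
  expect_equal(shifted_res$selected, base$selected)
  expect_equal(shifted_res$log2fc, base$log2fc, tolerance = 1e-12)
})

make_subtype_matrix <- function(n_feat, n_per, effects_basal = NULL,
                                sd = 0.2, seed = 1L, beta_scale = FALSE) {
  set.seed(seed)
  subtypes <- rep(c("LumB", "Her2ER-", "Basal"), each = n_per)
  cols <- sprintf("T%02d", seq_along(subtypes))
  m <- matrix(rnorm(n_feat * length(cols), 0, sd), n_feat,
              dimnames = list(sprintf("F%03d", seq_len(n_feat)), cols))
  if (!is.null(effects_basal)) {
    m[seq_along(effects_basal), subtypes == "Basal"] <-
      m[seq_along(effects_basal), subtypes == "Basal"] + effects_basal
  }
  if (beta_scale) m <- pmin(pmax(m, 0), 1)
  meta <- data.frame(sample_id = cols, group = "BBM", subtype = subtypes,
                     stringsAsFactors = FALSE)
  list(x = m, meta = meta)
}

test_that("subtype ANOVA finds a basal-only contrast in exactly the basal pairs", {
  d <- make_subtype_matrix(40, 5, effects_basal = c(3, 0), sd = 0.2,
                           seed = 4L)
  res <- anova_subtypes(d$x, d$meta, effect_floor = 1)
  basal_pairs <- grep("Basal", names(res$pairwise), value = TRUE)
  other_pair <- setdiff(names(res$pairwise), basal_pairs)
  expect_length(basal_pairs, 2L)
  for (nm in basal_pairs) {
    expect_true("F001" %in% res$pairwise[[nm]]$feature)
  }
  expect_false("F001" %in% res$pairwise[[other_pair]]$feature)
  expect_true("F001" %in% res$union)
  # union bounds: at most the sum, at least the max, of pairwise sizes
  sizes <- vapply(res$pairwise, nrow, 1L)
  expect_lte(length(res$union), sum(sizes))
  expect_gte(length(res$union), max(sizes))

  meta_missing <- d$meta[d$meta$subtype != "Basal", ]
  expect_error(anova_subtypes(d$x, meta_missing, effect_floor = 1),
               "Basal")
})

test_that("balanced null data produce no subtype features after BH screening", {
  d <- make_subtype_matrix(300, 5, sd = 0.3, seed = 6L)
  res <- anova_subtypes(d$x, d$meta, effect_floor = 1)
  expect_equal(length(res$union), 0L)
  expect_equal(sum(res$anova$q <= 0.05), 0L)
})

test_that("nearest-centroid classification recovers self-matches and survives monotone maps", {
  set.seed(8)
  cents <- matrix(rnorm(50 * 3), 50, 3,
                  dimnames = list(sprintf("G%03d", 1:50),
                                  c("LumB", "Her2ER-", "Basal")))
  x <- cbind(sample1 = cents[, "Basal"],
             sample2 = tanh(cents[, "LumB"]) * 3 + 1)  # monotone transform
  res <- classify_subtype(x, cents)
  expect_identical(res$subtype, c("Basal", "LumB"))
  expect_equal(res$cor_Basal[1L], 1.0)
  expect_error(classify_subtype(x[1:3, , drop = FALSE], cents), ">= 5")
  # two identical centroids correlate identically with their own profile:
  # the tie is broken by column order with a warning
  cents_tie <- cents[, c(1, 1, 2)]
  colnames(cents_tie) <- c("A", "B", "C")
  y <- cents[, 1, drop = FALSE]
  colnames(y) <- "s"
  expect_warning(res_tie <- classify_subtype(y, cents_tie), "tie")
  expect_identical(res_tie$subtype, "A")
})

test_that("centroid tables round-trip through TSV", {
  cents <- matrix(rnorm(20), 10, 2,
                  dimnames = list(sprintf("G%02d", 1:10), c("A", "B")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_centroids(cents, f)
  expect_equal(read_centroids(f), cents, tolerance = 1e-12)
})
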