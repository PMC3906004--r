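test_that("beta values follow M/(M+U) with boundary and zero-signal handling", {
  expect_equal(beta_from_intensities(300, 100), 0.75)
  expect_equal(beta_from_intensities(57, 57), 0.5)
  expect_equal(beta_from_intensities(0, 10), 0)
  expect_equal(beta_from_intensities(10, 0), 1)
  expect_warning(b <- beta_from_intensities(0, 0), "missing")
  expect_true(is.na(b))
  expect_error(beta_from_intensities(-1, 5), "non-negative")
})

test_that("Mann-Whitney exact enumeration matches hand and wilcox.test oracles", {
  # 3 vs 3 fully separated: U = 9 and exact two-sided p = 2/20 = 0.1
  mw <- mann_whitney_test(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1))
  expect_identical(mw$method, "exact")
  expect_equal(mw$U, 9)
  expect_equal(mw$p, 0.1, tolerance = 1e-12)

  # tie-free random cases agree with the exact wilcox.test distribution
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(5)
    y <- rnorm(6)
    ours <- mann_whitney_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_identical(ours$method, "exact")
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p-values agree near the 8 vs 8 boundary", {
  # agreement matters where calls are decided: enumerate every possible
  # tie-free 8 vs 8 outcome and compare the two p-values wherever the exact
  # p is at or below twice the 0.05 significance gate
  n1 <- 8; n2 <- 8; mu <- n1 * n2 / 2
  for (U in 0:(n1 * n2)) {
    dev <- abs(U - mu)
    p_exact <- pwilcox(mu - dev, n1, n2) +
      (1 - pwilcox(mu + dev - 1e-9, n1, n2))
    sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    z <- (U - mu - 0.5 * sign(U - mu)) / sigma
    p_norm <- min(1, 2 * pnorm(-abs(z)))
    if (p_exact <= 0.1) expect_lt(abs(p_exact - p_norm), 0.01)
  }
  # and the implementation reproduces both formulas on concrete data
  set.seed(32)
  x <- rnorm(8)
  y <- rnorm(8, 3)  # strong separation -> small p on both routes
  pe <- mann_whitney_test(x, y, exact_max = 8L)$p
  pn <- mann_whitney_test(x, y, exact_max = 0L)$p
  expect_lt(abs(pe - pn), 0.01)
})

test_that("DML calling combines the Mann-Whitney and delta-beta gates", {
  d <- random_beta_groups(50, 10, 10, mu_a = 0.6, mu_b = 0.3, kappa = 150,
                          seed = 33L)
  res <- call_dml(d$beta, d$group_a, d$group_b)
  expect_true(mean(res$selected) > 0.9)       # planted 0.3 shift, ample n
  expect_true(all(res$direction[res$selected] == "hyper"))
  expect_true(all(abs(res$delta_beta) <= 1))

  # identical groups: delta 0, nothing selected
  same <- random_beta_groups(50, 6, 6, 0.4, 0.4, 500, seed = 34L)
  res0 <- call_dml(same$beta, same$group_a, same$group_b)
  expect_equal(sum(res0$selected), 0L)
  expect_error(call_dml(d$beta, d$group_a[1], d$group_b), ">= 2")
})

test_that("tumor-specific DML require agreement against both references", {
  set.seed(35)
  ids <- c(sprintf("BBM%02d", 1:8), sprintf("NBn%02d", 1:6),
           sprintf("NBr%02d", 1:6))
  meta <- data.frame(sample_id = ids,
                     group = rep(c("BBM", "NBn", "NBr"), c(8, 6, 6)),
                     stringsAsFactors = FALSE)
  k <- 400
  mu <- cbind(matrix(0.8, 3, 8), matrix(0.2, 3, 12))
  mu[2, 9:14] <- 0.8   # locus 2: differs from NBr only (NBn matches BBM)
  mu[3, ] <- 0.5       # locus 3: null
  m <- matrix(rbeta(length(mu), mu * k, (1 - mu) * k), nrow(mu),
              dimnames = list(paste0("cg", 1:3), ids))
  ann <- data.frame(probe_id = paste0("cg", 1:3),
                    gene_symbol = paste0("G", 1:3), chrom = "chr1",
                    start = 1:3 * 100L, end = 1:3 * 100L + 2L,
                    cpg_island = c(TRUE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  res <- tumor_specific_dml(omics_matrix(m, "beta"), meta, ann)
  expect_identical(res$locus_id, "cg1")       # dual-reference gate
  expect_identical(res$direction, "hyper")
  expect_true(res$cpg_island)
  tally <- attr(res, "tally")
  expect_equal(sum(tally), 1L)
})

test_that("hypomethylator signature derivation ranks island loci by basal deficit", {
  set.seed(36)
  n_loci <- 25
  subtypes <- rep(c("LumB", "Her2ER-", "Basal"), each = 5)
  cols <- sprintf("T%02d", seq_along(subtypes))
  mu <- matrix(0.7, n_loci, length(cols), dimnames = list(
    sprintf("cg%03d", 1:n_loci), cols))
  mu[1:15, subtypes == "Basal"] <- 0.1       # planted signature
  mu[16:20, subtypes == "Basal"] <- 0.4      # weaker basal deficit
  m <- matrix(rbeta(length(mu), mu * 2000, (1 - mu) * 2000), n_loci,
              dimnames = dimnames(mu))
  meta <- data.frame(sample_id = cols, group = "BBM", subtype = subtypes,
                     stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = rownames(m), gene_symbol = rownames(m),
                    chrom = "chr1", start = seq_len(n_loci) * 10L,
                    end = seq_len(n_loci) * 10L + 2L,
                    cpg_island = c(rep(TRUE, 20), rep(FALSE, 5)),
                    stringsAsFactors = FALSE)
  beta <- omics_matrix(m, "beta")
  sig <- derive_cihmp(beta, meta, ann, candidate_loci = rownames(m), k = 15)
  expect_setequal(sig$locus_id, sprintf("cg%03d", 1:15))
  expect_true(all(diff(sig$delta_median) >= 0))  # ascending basal deficit
  # order invariance of the candidate list
  sig2 <- derive_cihmp(beta, meta, ann,
                       candidate_loci = rev(rownames(m)), k = 15)
  expect_identical(sig$locus_id, sig2$locus_id)
  # island filter: non-island loci can never enter the signature
  expect_true(all(ann$cpg_island[match(sig$locus_id, ann$probe_id)]))
  # k larger than the qualifying pool
  expect_error(derive_cihmp(beta, meta, ann, rownames(m), k = 21),
               "qualify")
  expect_warning(
    sig_all <- derive_cihmp(beta, meta, ann, rownames(m), k = 21,
                            allow_fewer = TRUE),
    "qualify")
  expect_lte(nrow(sig_all), 20)
})

test_that("median methylation is a plain median over the restriction", {
  m <- matrix(c(0.1, 0.4, 0.9, 0.2, 0.2, 0.2), 3, 2,
              dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
  b <- omics_matrix(m, "beta")
  expect_equal(median_methylation(b, "s1"), 0.4)
  expect_equal(median_methylation(b, "s2"), 0.2)
  expect_equal(median_methylation(b, c("s2", "s1")),
               median_methylation(b, c("s1", "s2")))
  expect_error(median_methylation(b, character(0)), "empty")
})

test_that("ROC AUC equals the trapezoidal area and behaves antisymmetrically", {
  set.seed(37)
  for (i in 1:20) {
    pos <- rnorm(7, 0.5, 1)
    neg <- rnorm(9, 0, 1)
    m <- matrix(c(pos, neg), 1,
                dimnames = list("L1", sprintf("s%02d", 1:16)))
    r <- roc_locus(m, colnames(m)[1:7], colnames(m)[8:16])
    expect_equal(r$auc, trapezoid_auc(pos, neg), tolerance = 1e-9)
    r_swap <- roc_locus(m, colnames(m)[8:16], colnames(m)[1:7])
    expect_equal(r_swap$auc, 1 - r$auc, tolerance = 1e-12)
  }
  # perfect separation and constant degenerate input
  m <- matrix(c(rep(0.9, 4), rep(0.1, 4)), 1,
              dimnames = list("L1", sprintf("s%d", 1:8)))
  expect_equal(roc_locus(m, colnames(m)[1:4], colnames(m)[5:8])$auc, 1.0)
  mc <- matrix(0.5, 1, 8, dimnames = dimnames(m))
  expect_warning(rc <- roc_locus(mc, colnames(mc)[1:4], colnames(mc)[5:8]),
                 "constant")
  expect_equal(rc$auc, 0.5)
})

test_that("ROC AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(38)
  vals <- c(rnorm(10, 1), rnorm(12))
  m <- matrix(vals, 1, dimnames = list("L1", sprintf("s%02d", 1:22)))
  ours <- roc_locus(m, colnames(m)[1:10], colnames(m)[11:22])$auc
  ref <- suppressMessages(pROC::auc(
    response = rep(c(1, 0), c(10, 12)), predictor = vals))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})
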