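layer_matrices <- function(cn_vals, expr_vals, db_vals, sample = "S1") {
  genes <- sprintf("G%02d", seq_along(cn_vals))
  list(cn = matrix(cn_vals, ncol = 1, dimnames = list(genes, sample)),
       expr = matrix(expr_vals, ncol = 1, dimnames = list(genes, sample)),
       db = matrix(db_vals, ncol = 1, dimnames = list(genes, sample)))
}

test_that("copy-number/expression congruency enforces the published gates", {
  l <- layer_matrices(cn_vals = c(0.6, -0.9, 0.4, -0.85),
                      expr_vals = c(2.5, 2.5, 2.5, -2.2),
                      db_vals = rep(0, 4))
  calls <- congruent_cn_expr(l$cn, l$expr)
  expect_setequal(calls$gene_symbol, c("G01", "G04"))
  expect_identical(calls$category[calls$gene_symbol == "G01"], "amp_over")
  expect_identical(calls$category[calls$gene_symbol == "G04"], "del_under")
  # G02: direction clash dropped; G03: cn 0.4 below the 0.5 gain gate
  expect_error(congruent_cn_expr(l$cn[0, , drop = FALSE], l$expr),
               "empty gene intersection")
})

test_that("expression/methylation congruency keeps anti-correlated pairs", {
  l <- layer_matrices(cn_vals = rep(0, 3),
                      expr_vals = c(-2.6, 2.2, 2.6),
                      db_vals = c(0.35, -0.3, 0.35))
  calls <- congruent_expr_meth(l$expr, l$db)
  expect_identical(calls$category[calls$gene_symbol == "G01"], "hyper_down")
  expect_identical(calls$category[calls$gene_symbol == "G02"], "hypo_up")
  expect_false("G03" %in% calls$gene_symbol)  # same-direction pair dropped
  relaxed <- congruent_expr_meth(l$expr, l$db,
                                 require_anticorrelation = FALSE)
  expect_identical(relaxed$category[relaxed$gene_symbol == "G03"],
                   "hyper_up")
})

test_that("triple concordance separates one-copy TSG candidates from homozygous losses", {
  l <- layer_matrices(cn_vals = c(-0.9, -1.8, 0.7),
                      expr_vals = c(-2.5, -2.5, 2.4),
                      db_vals = c(0.3, 0.3, -0.25))
  noms <- nominate_tsg_oncogene(l$cn, l$expr, l$db)
  expect_identical(noms$category[noms$gene_symbol == "G01"], "tsg_candidate")
  expect_identical(noms$category[noms$gene_symbol == "G02"],
                   "homozygous_del_silent")
  expect_identical(noms$category[noms$gene_symbol == "G03"],
                   "oncogene_candidate")
})

test_that("nominations are contained in the pairwise congruency intersections", {
  set.seed(51)
  for (rep in 1:20) {
    n <- 60
    genes <- sprintf("G%03d", 1:n)
    samples <- c("S1", "S2", "S3")
    cn <- matrix(rnorm(n * 3, 0, 1.2), n, dimnames = list(genes, samples))
    ex <- matrix(rnorm(n * 3, 0, 2.2), n, dimnames = list(genes, samples))
    db <- matrix(runif(n * 3, -0.5, 0.5), n, dimnames = list(genes, samples))
    noms <- nominate_tsg_oncogene(cn, ex, db)
    ce <- congruent_cn_expr(cn, ex)
    em <- congruent_expr_meth(ex, db)
    for (s in samples) {
      tsg <- noms$gene_symbol[noms$sample_id == s &
                                noms$category == "tsg_candidate"]
      onc <- noms$gene_symbol[noms$sample_id == s &
                                noms$category == "oncogene_candidate"]
      del_under <- ce$gene_symbol[ce$sample_id == s &
                                    ce$category == "del_under"]
      amp_over <- ce$gene_symbol[ce$sample_id == s &
                                   ce$category == "amp_over"]
      hyper_down <- em$gene_symbol[em$sample_id == s &
                                     em$category == "hyper_down"]
      hypo_up <- em$gene_symbol[em$sample_id == s & em$category == "hypo_up"]
      expect_true(all(tsg %in% intersect(del_under, hyper_down)))
      expect_true(all(onc %in% intersect(amp_over, hypo_up)))
    }
  }
})

test_that("recurrence tallies distinct samples and sorts by count then gene", {
  calls <- data.frame(
    sample_id = c("S1", "S2", "S3", "S1", "S1", "S2"),
    gene_symbol = c("GA", "GA", "GA", "GB", "GB", "GZ"),
    category = c(rep("amp_over", 3), "amp_over", "amp_over", "amp_over"),
    cn_log2 = 1, expr_log2 = 2.5, delta_beta = NA_real_,
    stringsAsFactors = FALSE)
  tal <- recurrence(calls)
  expect_equal(tal$n_samples[tal$gene_symbol == "GA"], 3L)
  expect_equal(tal$n_samples[tal$gene_symbol == "GB"], 1L)  # duplicate in S1
  expect_identical(tal$gene_symbol, c("GA", "GB", "GZ"))    # count, then name
  expect_equal(nrow(recurrence(calls[0, ])), 0L)
})

test_that("per-sample layers reproduce planted values on a noise-free cohort", {
  p <- small_cohort_params(seed = 61L, cn_noise_sd = 0, expr_noise_sd = 0,
                           beta_concentration = Inf)
  co <- simulate_cohort(p)
  cfg <- analysis_config(cbs_nperm = 300L)
  tum <- co$meta$sample_id[co$meta$group == "BBM"]
  segs <- segment_cohort(co$cn, co$ann$cn, tum, cfg)
  calls <- call_aberrations(segs, cfg)
  g <- collapse_probes_to_genes(co$expr, co$ann$expr)
  lay <- sample_gene_layers(g, co$beta, calls, co$meta, co$ann$meth,
                            gene_intervals(co$ann$expr))
  drv <- co$truth$drivers
  tsg <- drv[drv$role == "tsg", ][1L, ]
  carr <- strsplit(tsg$carriers, ",")[[1L]][1L]
  expect_equal(lay$cn[tsg$gene, carr], tsg$cn_amplitude, tolerance = 1e-6)
  expect_lt(lay$expr[tsg$gene, carr], -2)
  expect_gt(lay$delta_beta[tsg$gene, carr], 0.2)
})
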