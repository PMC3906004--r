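# quiet package logging during tests
options(bbmomics.verbose = FALSE)

# small cohort parameter presets used across test files ------------------

# compact default-shaped cohort: fast but with every signal class planted
small_cohort_params <- function(seed = 101L, ...) {
  simulation_params(
    n_tumor = 12L, n_nbn = 4L, n_nbr = 4L, n_primary = 10L,
    n_probes_cn = 2000L, n_probes_expr = 2500L, n_genes = 2000L,
    n_loci_meth = 2000L, seed = seed, ...)
}

# minimal feature space for copy-number-only scenarios
cn_only_params <- function(seed = 1L, ...) {
  simulation_params(
    n_tumor = 8L, n_nbn = 2L, n_nbr = 2L, n_primary = 0L,
    n_probes_cn = 500L, n_probes_expr = 100L, n_genes = 100L,
    n_loci_meth = 100L,
    n_deg = 0L, n_tissue_genes = 0L, n_subtype_genes = 0L, n_dml = 0L,
    n_cihmp = 0L, n_lumb_hyper = 0L, n_tsg = 0L, n_onco = 0L,
    n_broad_gain = 0L, n_broad_loss = 0L, n_focal_amp = 0L,
    n_focal_del = 0L, n_homozygous_del = 0L,
    seed = seed, ...)
}

# a beta matrix with two labelled groups drawn from Beta(mu*k, (1-mu)*k)
random_beta_groups <- function(n_loci, n_a, n_b, mu_a, mu_b, kappa,
                               seed = 1L) {
  set.seed(seed)
  a <- matrix(rbeta(n_loci * n_a, mu_a * kappa, (1 - mu_a) * kappa), n_loci)
  b <- matrix(rbeta(n_loci * n_b, mu_b * kappa, (1 - mu_b) * kappa), n_loci)
  m <- cbind(a, b)
  dimnames(m) <- list(sprintf("cg%04d", seq_len(n_loci)),
                      c(sprintf("A%02d", seq_len(n_a)),
                        sprintf("B%02d", seq_len(n_b))))
  list(beta = omics_matrix(m, "beta"),
       group_a = colnames(m)[seq_len(n_a)],
       group_b = colnames(m)[n_a + seq_len(n_b)])
}

# trapezoidal area under the empirical ROC curve: independent oracle for
# the U-statistic AUC (sweep every threshold, integrate TPR over FPR)
trapezoid_auc <- function(pos, neg) {
  th <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), 1)
  fpr <- vapply(th, function(t) mean(neg >= t), 1)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# brute-force G-score: frequency of aberrant samples times their mean |amp|
brute_g_score <- function(amp, direction) {
  apply(amp, 1L, function(v) {
    hit <- if (direction == "gain") v > 0 else v < 0
    if (!any(hit)) return(0)
    mean(hit) * mean(abs(v[hit]))
  })
}
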