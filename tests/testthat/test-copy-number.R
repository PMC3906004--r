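test_that("constant and step signals segment exactly", {
  pos <- seq_len(50L) * 1000L
  flat <- segment_profile(rep(0, 50), pos, "chr1", nperm = 300, seed = 1L)
  expect_equal(nrow(flat), 1L)
  expect_equal(flat$seg_mean, 0)
  expect_equal(flat$n_probes, 50L)

  step <- segment_profile(c(rep(0, 25), rep(1, 25)), pos, "chr1",
                          nperm = 300, seed = 1L)
  expect_equal(nrow(step), 2L)
  expect_equal(step$last_probe[1L], 25L)
  expect_equal(step$seg_mean, c(0, 1))

  expect_error(segment_profile(rnorm(10), rev(seq_len(10L)), "chr1"),
               "sorted")
})

test_that("segment means conserve the profile mean (probe-weighted)", {
  set.seed(99)
  x <- c(rnorm(40, 0, 0.2), rnorm(30, 1, 0.2), rnorm(30, -0.5, 0.2))
  segs <- segment_profile(x, seq_along(x) * 10L, "chr1", nperm = 300,
                          seed = 2L)
  expect_equal(sum(segs$seg_mean * segs$n_probes) / sum(segs$n_probes),
               mean(x), tolerance = 1e-12)
})

test_that("noisy step breakpoints land within two probes of the truth", {
  hits <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    x <- c(rnorm(50, 0, 0.2), rnorm(50, 1, 0.2))
    segs <- segment_profile(x, seq_len(100L) * 10L, "chr1", nperm = 500,
                            seed = 2000 + s)
    any(abs(segs$last_probe - 50L) <= 2L & segs$last_probe < 100L)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("aberration calling applies the probe-count and amplitude gates and merges runs", {
  segs <- data.frame(
    sample_id = "S1", chrom = "chr1",
    start = c(0L, 100L, 200L, 300L, 400L),
    end = c(100L, 200L, 300L, 400L, 500L),
    n_probes = c(10L, 10L, 2L, 10L, 10L),
    seg_mean = c(0.60, 0.50, -0.9, 0.7, 0.9),
    stringsAsFactors = FALSE)
  calls <- call_aberrations(segs)
  # 0.60 called; 0.50 below the 0.58 gate; -0.9 on 2 probes below the
  # 3-probe gate; 0.7 and 0.9 adjacent gains merge
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$direction, c("gain", "gain"))
  expect_equal(calls$start, c(0L, 300L))
  merged <- calls[calls$start == 300L, ]
  expect_equal(merged$n_probes, 20L)
  expect_equal(merged$mean_log2, 0.8)
})

test_that("G-score equals frequency times mean aberrant amplitude", {
  amp <- matrix(0, 3, 4, dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  amp[1L, 1:2] <- c(1.0, 0.6)  # 2 of 4 samples aberrant
  amp[3L, ] <- 0.5             # all samples aberrant
  g <- g_score(amp, "gain")
  expect_equal(unname(g[1L]), 0.5 * 0.8)  # hand computation: 0.4
  expect_equal(unname(g[2L]), 0)          # no sample aberrant
  expect_equal(unname(g[3L]), 0.5)        # frequency 1 -> amplitude itself
  expect_equal(unname(g), unname(brute_g_score(amp, "gain")))
  # non-negativity and sample-order invariance
  set.seed(7)
  r <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("p", 1:10),
                                                paste0("s", 1:4)))
  for (dir in c("gain", "loss")) {
    g1 <- g_score(r, dir)
    expect_true(all(g1 >= 0))
    expect_equal(unname(g1), unname(g_score(r[, sample(4)], dir)))
    expect_equal(unname(g1), unname(brute_g_score(r, dir)))
  }
})

test_that("recurrence q-values are a monotone step function of p-values", {
  spec <- data.frame(type = c("focal_amp", "focal_del"),
                     chrom = c("chr1", "chr2"), arm = c("p", "q"),
                     n_probes = c(40L, 40L), amplitude = c(1, -1),
                     penetrance = c(1, 0.6), stringsAsFactors = FALSE)
  co <- simulate_cohort(cn_only_params(seed = 21L, cn_event_spec = spec))
  cfg <- analysis_config(permutations = 200L, seed = 21L)
  segs <- segment_cohort(co$cn, co$ann$cn,
                         co$meta$sample_id[co$meta$group == "BBM"], cfg)
  rec <- recurrent_regions(call_aberrations(segs, cfg), co$ann$cn,
                           co$meta$sample_id[co$meta$group == "BBM"],
                           co$genome, cfg)
  ps <- attr(rec, "probe_scores")
  for (dir in c("gain", "loss")) {
    p <- ps[[paste0("p_", dir)]]
    q <- ps[[paste0("q_", dir)]]
    expect_true(all(q >= 0 & q <= 1))
    # BH property: q is a monotone non-decreasing step function of p, and
    # within a direction q never increases as G grows
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(diff(q[order(ps[[paste0("g_", dir)]],
                                 decreasing = TRUE)]) >= -1e-12))
    expect_equal(q, p.adjust(p, method = "BH"))
  }
  # the fully penetrant planted events surface as significant regions
  expect_true(any(rec$direction == "gain" & rec$q_value < 0.25))
  expect_error(
    recurrent_regions(call_aberrations(segs, cfg), co$ann$cn,
                      co$meta$sample_id[co$meta$group == "BBM"][1:3],
                      co$genome, cfg),
    ">= 4 samples")
})

test_that("homozygous deletion calls require both the deep-deletion and silencing gates", {
  cn <- matrix(c(-2.0, -2.0, -0.9), 3, 1,
               dimnames = list(c("GA", "GB", "GC"), "S1"))
  ex <- matrix(c(-3.0, 1.0, -3.0), 3, 1,
               dimnames = list(c("GA", "GB", "GC"), "S1"))
  hd <- homozygous_deletions(cn, ex)
  expect_equal(hd$gene_symbol, "GA")   # GB fails expression, GC fails depth
  expect_equal(hd$sample_id, "S1")
})
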