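test_that("matrix reader round-trips well-formed files and enforces invariants", {
  m <- omics_matrix(matrix(c(0.1, 0.5, 0.9, 0.2, 0.6, 1.0), 3, 2,
                           dimnames = list(paste0("cg", 1:3), c("s1", "s2"))),
                    "beta")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, f)
  back <- read_matrix(f, "beta")
  expect_equal(dim(back), c(3L, 2L))
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_identical(modality(back), "beta")

  # beta out of range names the offending cell
  writeLines(c("feature_id\ts1\ts2", "cg1\t0.2\t0.4", "cg2\t1.2\t0.3"), f)
  expect_error(read_matrix(f, "beta"), "cg2.*s1|s1.*cg2")

  # duplicated feature id is named
  writeLines(c("feature_id\ts1", "p1\t0.5", "p1\t0.7"), f)
  expect_error(read_matrix(f, "expr_log2"), "p1")

  # non-numeric body cell is located
  writeLines(c("feature_id\ts1\ts2", "p1\t0.5\tabc"), f)
  expect_error(read_matrix(f, "expr_log2"), "abc")
})

test_that("SEG writer emits 1-based inclusive rows and round-trips exactly", {
  segs <- data.frame(
    sample_id = "S1", chrom = "chr1",
    start = c(0L, 100L), end = c(100L, 250L),
    n_probes = c(10L, 15L), seg_mean = c(0.123456, -0.654321),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".seg")
  write_seg(segs, f)
  lines <- readLines(f)
  expect_length(lines, 3L)  # header + 2 segments
  first <- strsplit(lines[2L], "\t")[[1L]]
  expect_identical(first[3L], "1")    # internal 0 -> SEG start 1
  expect_identical(first[4L], "100")  # half-open end -> inclusive end
  back <- read_seg(f)
  expect_equal(back$start, segs$start)
  expect_equal(back$end, segs$end)
  expect_equal(back$seg_mean, segs$seg_mean, tolerance = 1e-6)

  overlapping <- segs
  overlapping$start <- c(0L, 50L)
  expect_error(write_seg(overlapping, f), "overlap")
})

test_that("probe-to-gene collapse takes per-sample medians and drops unannotated probes", {
  ann <- data.frame(probe_id = paste0("p", 1:6),
                    gene_symbol = c("GA", "GA", "GA", "GB", "GB", ""),
                    chrom = "chr1", start = (0:5) * 100L,
                    end = (0:5) * 100L + 50L, stringsAsFactors = FALSE)
  vals <- matrix(c(1, 3, 5, 1, 3, 99,
                   2, 4, 6, 10, 20, 99), 6, 2,
                 dimnames = list(ann$probe_id, c("s1", "s2")))
  m <- omics_matrix(vals, "expr_log2")
  g <- collapse_probes_to_genes(m, ann)
  expect_equal(nrow(g), 2L)            # two annotated genes, blank dropped
  expect_equal(unclass(g)["GA", "s1"], 3)   # odd-count median
  expect_equal(unclass(g)["GB", "s1"], 2)   # even-count median = midpoint
  expect_equal(unclass(g)["GB", "s2"], 15)

  # permutation invariance in probe order
  perm <- sample(nrow(vals))
  m2 <- omics_matrix(vals[perm, , drop = FALSE], "expr_log2")
  expect_equal(unclass(collapse_probes_to_genes(m2, ann)), unclass(g))

  ann_empty <- ann
  ann_empty$gene_symbol <- ""
  expect_error(collapse_probes_to_genes(m, ann_empty), "no annotated probes")
})

test_that("segment-to-gene mapping is the length-weighted mean of overlaps", {
  genes <- data.frame(gene_symbol = c("GA", "GB", "GC"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(10L, 0L, 0L), end = c(60L, 100L, 50L),
                      stringsAsFactors = FALSE)
  segs <- data.frame(sample_id = "S1", chrom = "chr1",
                     start = c(0L, 25L), end = c(25L, 100L),
                     n_probes = c(5L, 10L), seg_mean = c(0, 1),
                     stringsAsFactors = FALSE)
  v <- map_segments_to_genes(segs, genes)
  # GA [10,60): fully covered, 15 bases at 0 and 35 at 1 -> 0.7
  expect_equal(unname(v["GA"]), 0.7, tolerance = 1e-12)
  # GB [0,100): 25% of its length at 0, 75% at 1 -> hand-computed 0.75
  expect_equal(unname(v["GB"]), 0.75, tolerance = 1e-12)
  # brute-force per-base oracle for GB
  per_base <- c(rep(0, 25), rep(1, 75))
  expect_equal(unname(v["GB"]), mean(per_base))
  # chromosome without segments -> missing
  expect_true(is.na(v["GC"]))

  # property: weighted means bounded by overlapping segment means
  set.seed(42)
  for (rep in 1:10) {
    sm <- rnorm(2)
    segs$seg_mean <- sm
    v <- map_segments_to_genes(segs, genes)
    expect_true(all(v[c("GA", "GB")] >= min(sm) - 1e-12 &
                      v[c("GA", "GB")] <= max(sm) + 1e-12))
  }
})

test_that("configuration validates thresholds and round-trips through YAML", {
  cfg <- analysis_config(permutations = 250L, gistic_q = 0.1)
  expect_equal(cfg$adm2_min_abs_mean, 0.58)
  expect_equal(cfg$cn_loss, -0.8)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(analysis_config(deg_p = 1.5), "probability")
  expect_error(analysis_config(permutations = 10L), ">= 100")
  expect_error(analysis_config(nonsense = 1), "unknown")
})
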