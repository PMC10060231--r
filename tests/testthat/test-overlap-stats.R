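test_that("center-based overlap fraction matches the exhaustive oracle", {
  ## every peak contains a marker center
  A <- GRanges("chr1", IRanges(c(100, 300, 500), width = 50))
  B <- GRanges("chr1", IRanges(c(120, 320, 520), width = 4))
  expect_equal(center_overlap_fraction(A, B), 1)
  ## disjoint sets
  B2 <- GRanges("chr1", IRanges(c(1000, 2000), width = 10))
  expect_equal(center_overlap_fraction(A, B2), 0)
  ## hand-constructed 3-of-10 case, cross-checked exhaustively
  A10 <- GRanges("chr1", IRanges(seq(1000, 10000, by = 1000), width = 100))
  B3 <- GRanges("chr1", IRanges(c(1040, 3040, 7040, 500, 12000),
                                width = 10))
  expect_equal(center_overlap_fraction(A10, B3), 0.3)
  expect_equal(center_overlap_fraction(A10, B3),
               exhaustive_center_overlap(A10, B3))
  ## random cases against the oracle
  set.seed(11)
  for (i in 1:10) {
    A_r <- GRanges("chr1", IRanges(sample(9000, 20), width = sample(200, 20)))
    B_r <- GRanges("chr1", IRanges(sample(9000, 15), width = sample(50, 15)))
    expect_equal(center_overlap_fraction(A_r, B_r),
                 exhaustive_center_overlap(A_r, B_r))
  }
  expect_error(center_overlap_fraction(GRanges(), B), "empty")
  expect_equal(center_overlap_fraction(A, GRanges()), 0)
})

test_that("shuffle preserves lengths and chromosomes without overlaps", {
  cs <- c(chr1 = 1e5, chr2 = 5e4)
  peaks <- GRanges(rep(c("chr1", "chr2"), c(6, 4)),
                   IRanges(c(seq(1000, 51000, by = 10000),
                             seq(2000, 32000, by = 10000)),
                           width = rep(c(500, 250), c(6, 4))))
  sh1 <- shuffle_intervals(peaks, cs, seed = 5)
  sh2 <- shuffle_intervals(peaks, cs, seed = 5)
  expect_identical(sh1, sh2)
  key <- function(gr) sort(paste(seqnames(gr), width(gr)))
  expect_identical(key(sh1), key(peaks))
  expect_length(GenomicRanges::reduce(sh1), length(sh1))
  expect_true(all(start(sh1) >= 1))
  expect_true(all(end(sh1) <= cs[as.character(seqnames(sh1))]))

  ## dense chromosome: 90% occupancy still yields a valid packing
  dense <- GRanges("chr1", IRanges(seq(1, 90001, by = 10000), width = 9000))
  shd <- shuffle_intervals(dense, c(chr1 = 1e5), seed = 2)
  expect_length(GenomicRanges::reduce(shd), length(shd))
  expect_identical(sort(width(shd)), sort(width(dense)))
  ## infeasible packing is an explicit error, never a silent overlap
  over <- GRanges("chr1", IRanges(c(1, 2), width = 60000))
  expect_error(shuffle_intervals(over, c(chr1 = 1e5), seed = 1),
               "infeasible")
})

test_that("single-interval shuffle start positions are uniform", {
  one <- GRanges("chr1", IRanges(500, width = 100))
  cs <- c(chr1 = 10000)
  starts <- vapply(1:2000, function(i) {
    start(shuffle_intervals(one, cs, seed = i))
  }, numeric(1))
  ks <- suppressWarnings(
    stats::ks.test(starts, "punif", 1, 10000 - 100 + 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical p-values follow the add-one convention", {
  null1000 <- seq(0, 0.5, length.out = 1000)
  ## observed exceeds all null values: the floor 1/1001
  expect_equal(empirical_p(0.9, null1000, "greater"), 1 / 1001)
  expect_equal(empirical_p(0.9, null1000, "greater"), 0.000999001,
               tolerance = 1e-6)
  ## observed at the null median: p near 0.5
  expect_equal(empirical_p(0.25, null1000, "greater"), 0.5,
               tolerance = 0.01)
  ## raw mode can reach 0
  expect_equal(empirical_p(0.9, null1000, "greater", smoothing = "raw"), 0)
  ## direction less
  expect_equal(empirical_p(-1, null1000, "less"), 1 / 1001)
  ## n_iter = 10 floor
  expect_equal(empirical_p(2, rep(1, 10), "greater"), 1 / 11)
  expect_error(empirical_p(1, numeric(0)), "empty null")
})

test_that("enrichment test finds planted co-location and propagates the floor", {
  cfg <- tiny_cfg(seed = 21, segregation = 0)
  ann <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, ann)
  ## TREs sit at accessible-peak centers by construction: observed
  ## overlap far exceeds any chromosome-preserving shuffle
  res <- overlap_enrichment_test(pk$accessible, pk$tre, ann$chrom_sizes,
                                 n_iter = 1000, seed = 9)
  expect_gt(res$observed, max(res$null_values))
  expect_equal(res$p_empirical, 1 / 1001)
  expect_length(res$null_values, 1000)
  ## null statistic equals the observed statistic applied to a shuffle
  sh <- shuffle_intervals(pk$accessible, ann$chrom_sizes, seed = 1)
  expect_equal(center_overlap_fraction(sh, pk$tre),
               exhaustive_center_overlap(sh, pk$tre))
  ## n_iter = 10 gives the 1/11 floor
  res10 <- overlap_enrichment_test(pk$accessible, pk$tre, ann$chrom_sizes,
                                   n_iter = 10, seed = 9)
  expect_equal(res10$p_empirical, 1 / 11)
})

test_that("co-occurrence test detects planted segregation and degeneracy", {
  cfg <- tiny_cfg(seed = 23, segregation = 1)
  ann <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, ann)
  res <- cooccurrence_test(pk$accessible, pk$tre, pk$dsb,
                           n_iter = 1000, seed = 3,
                           chrom_sizes = ann$chrom_sizes)
  expect_equal(res$observed, 0)
  expect_equal(res$p_empirical, 1 / 1001)

  ## independent labels: observed within a wide CI of the product
  ## expectation p_TRE * p_DSB
  cfg0 <- tiny_cfg(seed = 24, segregation = 0)
  ann0 <- simulate_annotation(cfg0)
  pk0 <- simulate_peaks(cfg0, ann0)
  res0 <- cooccurrence_test(pk0$accessible, pk0$tre, pk0$dsb,
                            n_iter = 1000, seed = 3,
                            chrom_sizes = ann0$chrom_sizes)
  expect_gt(res0$p_empirical, 0.01)

  ## all-zero TRE column: null degenerate at 0, p = 1 under "less"
  resz <- cooccurrence_test(pk$accessible, GRanges(), pk$dsb,
                            n_iter = 100, seed = 1,
                            chrom_sizes = ann$chrom_sizes)
  expect_equal(resz$observed, 0)
  expect_equal(resz$p_empirical, 1)
  expect_error(cooccurrence_test(GRanges(), pk$tre, pk$dsb), "empty")
})

test_that("TSS overlap comparison counts planted enrichment exactly", {
  mk_genes <- function(starts, chrom = "chr1") {
    g <- GRanges(chrom, IRanges(starts, width = 2000), strand = "+")
    g$gene_id <- paste0(chrom, "_", seq_along(starts))
    g
  }
  setA <- mk_genes(seq(10000, 100000, by = 10000))   # 10 genes
  setB <- mk_genes(seq(10000, 100000, by = 10000), "chr2")
  ## peaks at 9/10 TSSs of A and 3/10 of B
  peaks <- GRanges(rep(c("chr1", "chr2"), c(9, 3)),
                   IRanges(c(seq(10000, 90000, by = 10000) - 50,
                             seq(10000, 30000, by = 10000) - 50),
                           width = 100))
  res <- tss_overlap_comparison(peaks, list(A = setA, B = setB))
  expect_equal(unname(res$percent["A"]), 90)
  expect_equal(unname(res$percent["B"]), 30)
  expect_equal(res$tables$A_vs_B["A", "hit"], 9)
  expect_true(res$fisher_p["A_vs_B"] < 0.05)
  ## peaks at every TSS -> 100%; no peaks -> 0%
  all_peaks <- GRanges(rep(c("chr1", "chr2"), each = 10),
                       IRanges(rep(seq(10000, 100000, by = 10000), 2),
                               width = 10))
  res2 <- tss_overlap_comparison(all_peaks, list(A = setA, B = setB))
  expect_true(all(res2$percent == 100))
  res3 <- tss_overlap_comparison(GRanges("chr3", IRanges(1, 10)),
                                 list(A = setA))
  expect_equal(unname(res3$percent["A"]), 0)
})

test_that("proximity assignment picks the nearest TSS with stable ties", {
  genes <- GRanges("chr1", IRanges(c(10000, 30000, 90000), width = 2000),
                   strand = "+")
  genes$gene_id <- c("near", "far", "veryfar")
  ## TRE exactly at a TSS
  tre1 <- GRanges("chr1", IRanges(9990, 10010))
  a1 <- proximity_assign(tre1, genes)
  expect_equal(a1$gene_id, "near")
  expect_equal(a1$distance, 0)
  ## TRE 60 kb from everything within max_dist 50 kb -> unassigned
  tre2 <- GRanges("chr1", IRanges(150000, 150100))
  a2 <- proximity_assign(tre2, genes)
  expect_true(is.na(a2$gene_id))
  ## equidistant between two TSSs: deterministic leftmost
  g2 <- GRanges("chr1", IRanges(c(10000, 30000), width = 2000),
                strand = "+")
  g2$gene_id <- c("left", "right")
  tre3 <- GRanges("chr1", IRanges(20000, 20000))
  a3 <- proximity_assign(tre3, g2)
  expect_equal(a3$gene_id, "left")
})
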