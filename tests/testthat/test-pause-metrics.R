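test_that("gene windows follow transcription direction on both strands", {
  ## plus-strand gene occupying [1000, 3000) in 0-based terms
  gp <- GRanges("chr1", IRanges(1001, 3000), strand = "+")
  wp <- gene_windows(gp, 250, 5000, c(chr1 = 1e5))
  expect_equal(unname(start(wp)), c(1001, 1251, 3001))
  expect_equal(unname(end(wp)), c(1250, 3000, 8000))
  expect_false(any(wp$clipped))

  ## minus-strand gene at the same coordinates: pause at the right end,
  ## post-PAS extending left, clipped at the chromosome start
  gm <- GRanges("chr1", IRanges(1001, 3000), strand = "-")
  wm <- gene_windows(gm, 250, 5000, c(chr1 = 1e5))
  expect_equal(unname(start(wm["pause"])), 2751)
  expect_equal(unname(end(wm["pause"])), 3000)
  expect_equal(unname(ranges(wm["body"])), IRanges(1001, 2750),
               ignore_attr = TRUE)
  expect_equal(unname(start(wm["postpas"])), 1)
  expect_equal(unname(end(wm["postpas"])), 1000)
  expect_true(wm["postpas"]$clipped)

  ## mirror-image check: reflect the plus-strand gene through the
  ## chromosome midpoint; its windows must mirror exactly
  L <- 1e5
  gm2 <- GRanges("chr1", IRanges(L - 3000 + 1, L - 1001 + 1), strand = "-")
  wm2 <- gene_windows(gm2, 250, 5000, c(chr1 = L))
  refl <- function(iv) c(L - unname(end(iv)) + 1, L - unname(start(iv)) + 1)
  for (k in c("pause", "body", "postpas")) {
    expect_equal(refl(wp[k]), c(unname(start(wm2[k])), unname(end(wm2[k]))),
                 info = k)
  }

  expect_error(gene_windows(GRanges("chr1", IRanges(1, 200), strand = "+"),
                            250), "shorter")
})

test_that("eligibility filter applies length and neighbour-distance rules", {
  genes <- GRanges("chr1",
                   IRanges(c(10000, 30000, 40500, 80000),
                           width = c(2000, 400, 2000, 2000)),
                   strand = c("+", "+", "+", "+"))
  genes$gene_id <- paste0("g", 1:4)
  ## g2 is 400 bp (too short); g3's 3' end (42500) is fine, but g2 sits
  ## 3' of nothing; make a crowding case explicitly:
  kept <- filter_eligible(genes)
  expect_true("g1" %in% kept$gene_id)   # isolated long gene
  expect_false("g2" %in% kept$gene_id)  # 400 bp gene dropped

  ## long gene with a neighbour TSS 3000 bp past its 3' end is dropped
  crowd <- GRanges("chr2", IRanges(c(10000, 15000), width = c(2000, 2000)),
                   strand = "+")
  crowd$gene_id <- c("a", "b")          # a ends 12000, b TSS 15000
  keptc <- filter_eligible(crowd)
  expect_false("a" %in% keptc$gene_id)
  ## b's 3' end (17000) is 7000 bp from a's TSS (10000): kept? its own
  ## 3'-to-neighbour-TSS distance is |10000 - 17000| = 7000 >= 5000
  expect_true("b" %in% keptc$gene_id)
})

test_that("gene summaries reproduce hand-computed indices and the oracle", {
  ## 10 reads in the 250-bp pause window, 40 in a 2000-bp body,
  ## 25 in the 5000-bp post-PAS window
  L <- 20000
  v <- numeric(L)
  gene_start <- 1001; gene_end <- 3250
  v[gene_start:(gene_start + 9)] <- 1                  # 10 pause reads
  v[seq(gene_start + 250, by = 43, length.out = 40)] <- 1   # 40 body reads
  v[seq(gene_end + 1, by = 199, length.out = 25)] <- 1      # 25 post reads
  tr <- make_base_track(v, chrom = "chr1")
  trm <- make_base_track(numeric(L), chrom = "chr1", strand = "-")
  g <- GRanges("chr1", IRanges(gene_start, gene_end), strand = "+")
  g$gene_id <- "g1"
  s <- summarize_gene(list(plus = tr, minus = trm), g)
  expect_equal(s$pause_count, 10)
  expect_equal(s$body_count, 40)
  expect_equal(s$postpas_count, 25)
  expect_equal(s$pausing_index, (10 / 250) / (40 / 2000))   # = 2.0
  expect_equal(s$pausing_index, 2)
  expect_equal(s$retention_index, (40 / 2000) / (25 / 5000)) # = 4.0
  expect_equal(s$retention_index, 4)
  ## naive per-base oracle agrees
  orc <- naive_indices(v, gene_start, gene_end)
  expect_equal(s$pausing_index, orc$pi)
  expect_equal(s$retention_index, orc$ri)

  ## zero body signal: pausing index is missing, not 0 or Inf
  v0 <- numeric(L); v0[gene_start:(gene_start + 9)] <- 1
  tr0 <- make_base_track(v0, chrom = "chr1")
  s0 <- summarize_gene(list(plus = tr0, minus = trm), g)
  expect_true(is.na(s0$pausing_index))
})

test_that("pausing index is exactly invariant under track rescaling", {
  cfg <- tiny_cfg(seed = 9)
  ann <- simulate_annotation(cfg)
  tr <- simulate_stage_tracks(cfg, ann)
  s1 <- summarize_genes(tr$LZ, ann$genes)
  for (f in c(2, 1 / 3, 2.7e-6, pi)) {
    scaled <- list(plus = rescale_track(tr$LZ$plus, f),
                   minus = rescale_track(tr$LZ$minus, f))
    s2 <- summarize_genes(scaled, ann$genes)
    expect_identical(s1$pausing_index, s2$pausing_index)
    expect_identical(s1$retention_index, s2$retention_index)
    ## counts do scale
    expect_equal(s2$pause_count, s1$pause_count * f)
  }
})

test_that("pausing-index table pairs genes across stages", {
  cfg <- tiny_cfg(seed = 13)
  ann <- simulate_annotation(cfg)
  tr <- simulate_stage_tracks(cfg, ann)
  summaries <- lapply(tr, summarize_genes, genes = ann$genes)
  pit <- pausing_index_table(summaries, ann$genes)
  ## planted ordering LZ > P > D in the default stage parameters
  med <- tapply(pit$pausing_index, pit$stage, median)
  expect_true(med[["LZ"]] > med[["P"]])
  expect_true(med[["P"]] > med[["D"]])
  ## paired: every gene appears once per stage
  expect_true(all(table(pit$gene_id) == 3))

  ## identical tracks across stages: all paired differences are zero
  same <- list(A = summaries$LZ, B = summaries$LZ)
  pit2 <- pausing_index_table(same, ann$genes)
  d <- with(pit2, pausing_index[stage == "A"] -
              pausing_index[stage == "B"])
  expect_true(all(d == 0))

  ## genes missing in one stage are excluded from pairing
  drop1 <- summaries
  drop1$P <- drop1$P[-1, ]
  pit3 <- pausing_index_table(drop1, ann$genes)
  expect_false(summaries$P$gene_id[1] %in% pit3$gene_id)
})

test_that("scaled metagene is flat on constant tracks and seed-stable", {
  genes <- GRanges("chr1", IRanges(c(20001, 40001), width = 3000),
                   strand = c("+", "-"))
  genes$gene_id <- c("g1", "g2")
  L <- 60000
  trp <- make_base_track(rep(2, L), chrom = "chr1")
  trm <- make_base_track(rep(2, L), chrom = "chr1", strand = "-")
  prof <- scaled_metagene(list(plus = trp, minus = trm), genes,
                          n_sub = 50, seed = 1)
  expect_true(all(abs(prof$value - 2) < 1e-12))

  ## profile invariant to gene order permutation (same seed)
  prof2 <- scaled_metagene(list(plus = trp, minus = trm), rev(genes),
                           n_sub = 50, seed = 1)
  expect_equal(prof$value, prof2$value)

  expect_error(scaled_metagene(list(plus = trp, minus = trm), genes[0],
                               n_sub = 10), "at least 2")
})

test_that("scaled metagene recovers a planted pause enrichment", {
  ## pause/body rate ratio of 3 planted in the simulator
  sp <- list(pause_rate = 0.3, body_rate = 0.1, postpas_rate = 0)
  ratios <- numeric(10)
  for (s in 1:10) {
    cfg <- tiny_cfg(seed = 300 + s, n_genes = 12,
                    stage_params = list(LZ = sp, P = sp, D = sp))
    ann <- simulate_annotation(cfg)
    tr <- simulate_stage_tracks(cfg, ann)
    prof <- scaled_metagene(tr$LZ, ann$genes, n_sub = 100,
                            body_bins = 40, seed = s)
    body <- prof$value[prof$region == "body"]
    ## first ~10% of body bins cover the 250-bp pause window of a
    ## 1.5-3 kb gene; compare peak bins to the tail of the body
    ratios[s] <- max(body[1:5]) / median(body[20:40])
  }
  expect_equal(mean(ratios), 3, tolerance = 0.25)
})

test_that("peak-centered metaplots localise and symmetrise signal", {
  L <- 50000
  centers <- c(10000, 25000, 40000)
  v <- numeric(L); v[centers] <- 100
  tr <- make_base_track(v, chrom = "chr1")
  peaks <- GRanges("chr1", IRanges(centers - 50, centers + 49))
  mp <- peak_centered_metaplot(tr, peaks, flank = 1000, bins = 20)
  spike <- which.max(mp$profile$value)
  ## all signal in the central bin(s)
  expect_true(abs(mp$profile$offset[spike]) <= 100)
  expect_equal(sum(mp$profile$value > 0), 1)

  ## symmetric signal -> symmetric profile
  v2 <- numeric(L)
  for (cc in centers) v2[(cc - 200):(cc + 199)] <- 1
  tr2 <- make_base_track(v2, chrom = "chr1")
  mp2 <- peak_centered_metaplot(tr2, peaks, flank = 1000, bins = 20)
  expect_equal(mp2$profile$value, rev(mp2$profile$value),
               tolerance = 1e-9)

  ## uniform track -> flat profile at the track rate
  tr3 <- make_base_track(rep(0.5, L), chrom = "chr1")
  mp3 <- peak_centered_metaplot(tr3, peaks, flank = 1000, bins = 20)
  expect_true(all(abs(mp3$profile$value - 0.5) < 1e-12))
})
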