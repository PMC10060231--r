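## Shared fixtures and independent oracles for the test suite.
## Oracles deliberately use naive per-base / exhaustive algorithms so they
## stay independent of the interval-arithmetic code paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## A track with explicit per-base values on one small chromosome.
make_base_track <- function(values, chrom = "chrT", strand = "*") {
  sizes <- setNames(length(values), chrom)
  signal_track(setNames(list(S4Vectors::Rle(values)), chrom), sizes,
               strand = strand)
}

## Expand a track to a plain per-base numeric vector (scaled values).
track_as_vector <- function(track, chrom) {
  as.numeric(track$cov[[chrom]]) * track$scale
}

## Naive oracle: per-base accumulation over a 1-based closed window.
naive_count <- function(track, chrom, start, end) {
  v <- track_as_vector(track, chrom)
  sum(v[start:end])
}

## Naive oracle for the pausing and retention indices of one plus-strand
## gene on a per-base vector.
naive_indices <- function(values, gene_start, gene_end,
                          pause_len = 250, postpas_len = 5000) {
  pause <- values[gene_start:(gene_start + pause_len - 1)]
  body <- values[(gene_start + pause_len):gene_end]
  post <- values[(gene_end + 1):min(length(values), gene_end + postpas_len)]
  pd <- sum(pause) / length(pause)
  bd <- sum(body) / length(body)
  qd <- sum(post) / length(post)
  list(pi = if (bd > 0) pd / bd else NA_real_,
       ri = if (qd > 0) bd / qd else NA_real_)
}

## Exhaustive oracle: fraction of peaks containing >= 1 marker center,
## by double loop over peaks and markers.
exhaustive_center_overlap <- function(peaks, marker) {
  if (!length(marker)) return(0)
  ctr <- floor((start(marker) - 1 + end(marker)) / 2) + 1
  mch <- as.character(seqnames(marker))
  hit <- vapply(seq_along(peaks), function(i) {
    ch <- as.character(seqnames(peaks[i]))
    any(mch == ch & ctr >= start(peaks[i]) & ctr <= end(peaks[i]))
  }, logical(1))
  mean(hit)
}

## Small simulated dataset reused across tests.
tiny_cfg <- function(seed = 1, n_chroms = 2, chrom_length = 4e5,
                     n_genes = 16, purity = default_purity(6), ...) {
  sim_config(seed = seed, n_chroms = n_chroms,
             chrom_length = chrom_length, n_genes = n_genes,
             purity = purity, ...)
}

## Planted two-archetype trajectory matrix: a pachytene-burst group and a
## steady-then-drop group, with Gaussian noise on the non-reference
## columns.
planted_trajectories <- function(n_per = 30, sigma = 0.25, seed = 1) {
  cols <- c("LZ.pause", "LZ.body", "LZ.postpas",
            "P.pause", "P.body", "P.postpas",
            "D.pause", "D.body", "D.postpas")
  set.seed(seed)
  arch_burst <- c(0, 0, 0, 1.5, 2.5, 1.5, 0.5, 0.5, 0.5)
  arch_drop <- c(0, 0, 0, 0.2, 0.2, 0.2, -1.5, -2, -1.5)
  M <- rbind(matrix(arch_burst, n_per, 9, byrow = TRUE),
             matrix(arch_drop, n_per, 9, byrow = TRUE))
  noise <- cbind(matrix(0, 2 * n_per, 3),
                 matrix(rnorm(2 * n_per * 6, 0, sigma), 2 * n_per, 6))
  M <- M + noise
  dimnames(M) <- list(sprintf("g%03d", seq_len(2 * n_per)), cols)
  attr(M, "stages") <- c("LZ", "P", "D")
  attr(M, "windows") <- c("pause", "body", "postpas")
  list(M = M, truth = rep(1:2, each = n_per))
}

## Adjusted Rand index between an assignment vector and planted labels.
ari <- function(assignments, truth) {
  mclust::adjustedRandIndex(assignments, truth)
}
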