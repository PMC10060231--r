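## countOverlaps without the seqlevel-mismatch warning: disjoint
## chromosome sets are a legitimate "no overlap"
.count_hits <- function(query, subject) {
  suppressWarnings(GenomicRanges::countOverlaps(query, subject,
                                                ignore.strand = TRUE))
}

#' Interval centers
#'
#' The center of a peak is `floor((start0 + end0) / 2)` in 0-based
#' half-open coordinates; returned here as a 1-based position.
#' @param gr A [GenomicRanges::GRanges].
#' @return Integer vector of center positions (1-based).
#' @export
interval_center <- function(gr) {
  as.integer(floor((GenomicRanges::start(gr) - 1 +
                      GenomicRanges::end(gr)) / 2) + 1)
}

#' Fraction of peaks containing a marker center
#'
#' Reduces marker intervals to their single-base centers and reports the
#' fraction of `peaks` containing at least one center.
#'
#' @param peaks [GenomicRanges::GRanges] of peaks (must be non-empty).
#' @param marker [GenomicRanges::GRanges] of marker intervals.
#' @return Fraction in \[0, 1\]; 0 when `marker` is empty.
#' @export
center_overlap_fraction <- function(peaks, marker) {
  if (!length(peaks)) stop_input("empty peak set")
  if (!length(marker)) return(0)
  ctr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(marker),
                                IRanges::IRanges(interval_center(marker),
                                                 width = 1))
  hit <- .count_hits(peaks, ctr)
  mean(hit > 0)
}

## -- fast internal interval machinery (plain integer vectors) ----------

## uniform non-overlapping placement of interval lengths `lens` on [0, L):
## rejection sampling, with an exact free-space partition sampler for
## dense chromosomes (occupancy > 0.5) or once retries are exhausted
.shuffle_chrom <- function(lens, L, max_retries = 10000) {
  n <- length(lens)
  if (n == 0) return(integer(0))
  tot <- sum(lens)
  if (tot > L) {
    stop_input("infeasible packing: intervals cover ", tot,
               " bp of a ", L, " bp chromosome")
  }
  if (n == 1) return(sample.int(L - lens + 1L, 1) - 1L)
  packing <- function() {
    free <- L - tot
    g <- sort(stats::runif(n, 0, free))
    ord <- sample.int(n)           # random interval-to-slot assignment
    starts <- integer(n)
    starts[ord] <- as.integer(floor(g)) +
      c(0L, cumsum(lens[ord])[-n])
    starts
  }
  if (tot / L > 0.5) return(packing())
  for (i in seq_len(max_retries)) {
    starts <- as.integer(floor(stats::runif(n, 0, L - lens + 1)))
    o <- order(starts)
    if (all(starts[o][-1] >= starts[o][-n] + lens[o][-n])) return(starts)
  }
  packing()
}

## peaks as list(chrom=, start0=, len=) split by chromosome for hot loops
.split_peaks <- function(gr) {
  ch <- as.character(GenomeInfoDb::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1L
  len <- GenomicRanges::width(gr)
  split(data.frame(start0 = s0, len = len), ch)
}

#' Chromosome-preserving interval shuffle
#'
#' Randomly relocates each interval on its own chromosome, preserving its
#' length, and forbidding overlaps among the shuffled intervals
#' (`bedtools shuffle -chrom -noOverlapping` semantics). Placement is
#' uniform: rejection sampling with a retry cap, falling back to an exact
#' uniform free-space partition sampler on dense chromosomes. Shuffled
#' intervals may overlap the original positions.
#'
#' @param peaks [GenomicRanges::GRanges] to shuffle.
#' @param chrom_sizes Named integer chromosome lengths.
#' @param seed Optional RNG seed.
#' @param max_retries Rejection-sampling cap per chromosome.
#' @return A [GenomicRanges::GRanges] of shuffled intervals, in
#'   chromosome order.
#' @export
shuffle_intervals <- function(peaks, chrom_sizes, seed = NULL,
                              max_retries = 10000) {
  byc <- .split_peaks(peaks)
  bad <- setdiff(names(byc), names(chrom_sizes))
  if (length(bad)) stop_input("peaks on unknown chromosome: ",
                              paste(bad, collapse = ", "))
  with_seed(seed, {
    parts <- lapply(names(byc), function(ch) {
      lens <- byc[[ch]]$len
      starts0 <- .shuffle_chrom(lens, as.integer(chrom_sizes[[ch]]),
                                max_retries)
      data.frame(chrom = ch, start = starts0 + 1L, len = lens)
    })
    df <- do.call(rbind, parts)
    GenomicRanges::sort(GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, width = df$len)))
  })
}

#' Empirical p-value from a permutation null
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of permutation replicates.
#' @param direction `"greater"` counts null values >= observed (tests
#'   enrichment), `"less"` counts null values <= observed (tests
#'   depletion).
#' @param smoothing `"add_one"` (default) reports
#'   `(k + 1) / (n_iter + 1)`, which is never exactly 0 and has floor
#'   `1 / (n_iter + 1)`; `"raw"` reports the plain fraction `k / n_iter`.
#' @return The empirical p-value.
#' @export
empirical_p <- function(observed, null_values,
                        direction = c("greater", "less"),
                        smoothing = c("add_one", "raw")) {
  direction <- match.arg(direction)
  smoothing <- match.arg(smoothing)
  n <- length(null_values)
  if (n == 0) stop_input("empty null distribution")
  k <- if (direction == "greater") sum(null_values >= observed)
  else sum(null_values <= observed)
  if (smoothing == "add_one") (k + 1) / (n + 1) else k / n
}

.permutation_result <- function(observed, null_values, direction, n_iter,
                                smoothing, seed, statistic) {
  structure(list(observed = observed, null_values = null_values,
                 direction = direction, n_iter = n_iter,
                 p_empirical = empirical_p(observed, null_values,
                                           direction, smoothing),
                 smoothing = smoothing, seed = seed,
                 statistic = statistic),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result (%s):\n", x$statistic))
  cat(sprintf("  observed = %.4g, null mean = %.4g (n_iter = %d)\n",
              x$observed, mean(x$null_values), x$n_iter))
  cat(sprintf("  empirical p (%s, %s) = %.6g\n",
              x$direction, x$smoothing, x$p_empirical))
  invisible(x)
}

#' Shuffle-based overlap enrichment test
#'
#' Tests whether the fraction of `peaks` containing a marker center
#' exceeds chance, by comparing the observed [center_overlap_fraction()]
#' against the same statistic over `n_iter` chromosome-preserving
#' shuffles of `peaks` (see [shuffle_intervals()]).
#'
#' @param peaks,marker [GenomicRanges::GRanges] interval sets.
#' @param chrom_sizes Named chromosome lengths.
#' @param n_iter Number of shuffle iterations (default 1000).
#' @param seed Optional RNG seed.
#' @param smoothing See [empirical_p()].
#' @return A `permutation_result` with `direction = "greater"`.
#' @export
overlap_enrichment_test <- function(peaks, marker, chrom_sizes,
                                    n_iter = 1000, seed = NULL,
                                    smoothing = "add_one") {
  observed <- center_overlap_fraction(peaks, marker)
  byc <- .split_peaks(peaks)
  bad <- setdiff(names(byc), names(chrom_sizes))
  if (length(bad)) stop_input("peaks on unknown chromosome: ",
                              paste(bad, collapse = ", "))
  ## sorted marker centers (0-based) per chromosome for fast counting
  ctr0 <- floor((GenomicRanges::start(marker) - 1 +
                   GenomicRanges::end(marker)) / 2)
  ctr_by <- split(ctr0, as.character(GenomeInfoDb::seqnames(marker)))
  ctr_by <- lapply(ctr_by, sort)
  n_peaks <- length(peaks)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      hits <- 0L
      for (ch in names(byc)) {
        ctr <- ctr_by[[ch]]
        lens <- byc[[ch]]$len
        starts0 <- .shuffle_chrom(lens, as.integer(chrom_sizes[[ch]]))
        if (is.null(ctr) || !length(ctr)) next
        ## center c in [start0, start0+len): count via sorted search
        lo <- findInterval(starts0 - 0.5, ctr)
        hi <- findInterval(starts0 + lens - 0.5, ctr)
        hits <- hits + sum(hi > lo)
      }
      hits / n_peaks
    }, numeric(1))
  })
  .permutation_result(observed, null_values, "greater", n_iter,
                      smoothing, seed, "center_overlap_fraction")
}

#' Co-occurrence permutation test in expanded accessibility windows
#'
#' Expands each accessible peak to a fixed window around its center,
#' builds per-peak indicator columns for containing a transcribed-element
#' (TRE) center and a DSB-marker center, and compares the observed
#' proportion of peaks carrying both indicators against a null obtained
#' by permuting the TRE indicator column across peaks. The default
#' direction `"less"` tests for depletion (transcription and DSBs
#' segregating into different accessible regions).
#'
#' @param atac_peaks Accessible-chromatin peaks
#'   ([GenomicRanges::GRanges]).
#' @param tre_marker,dsb_marker Marker interval sets.
#' @param window Total expanded-window width in bp around each peak
#'   center (default 5000).
#' @param n_iter Number of column permutations (default 1000).
#' @param seed Optional RNG seed.
#' @param direction,smoothing See [empirical_p()].
#' @param chrom_sizes Optional named lengths used to clip expanded
#'   windows.
#' @return A `permutation_result`; `observed` is the co-occurrence
#'   proportion.
#' @export
cooccurrence_test <- function(atac_peaks, tre_marker, dsb_marker,
                              window = 5000, n_iter = 1000, seed = NULL,
                              direction = "less", smoothing = "add_one",
                              chrom_sizes = NULL) {
  if (!length(atac_peaks)) stop_input("empty accessible peak set")
  ctr <- interval_center(atac_peaks)
  s <- pmax(1, ctr - floor(window / 2))
  e <- ctr + floor(window / 2)
  ch <- as.character(GenomeInfoDb::seqnames(atac_peaks))
  if (!is.null(chrom_sizes)) e <- pmin(as.integer(chrom_sizes[ch]), e)
  expanded <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, e))
  ind <- function(marker) {
    if (!length(marker)) return(rep(FALSE, length(expanded)))
    mc <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(marker),
                                 IRanges::IRanges(interval_center(marker),
                                                  width = 1))
    .count_hits(expanded, mc) > 0
  }
  tre_col <- ind(tre_marker)
  dsb_col <- ind(dsb_marker)
  observed <- mean(tre_col & dsb_col)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      mean(sample(tre_col) & dsb_col)
    }, numeric(1))
  })
  .permutation_result(observed, null_values, direction, n_iter,
                      smoothing, seed, "cooccurrence_proportion")
}

#' TSS overlap percentages across gene sets
#'
#' For each gene set, the percentage of genes whose TSS (expanded by
#' `tss_flank` bp on each side) intersects at least one peak
#' (`denominator = "genes"`), or the percentage of peaks overlapping at
#' least one TSS window of the set (`denominator = "peaks"`). Pairwise
#' 2x2 contingency tables are returned for Fisher's exact or chi-squared
#' comparison, and Fisher tests are run as a convenience.
#'
#' @param peaks [GenomicRanges::GRanges] of peaks (e.g. ChIP-seq).
#' @param gene_sets Named list of [GenomicRanges::GRanges] gene sets.
#' @param tss_flank Half-width of the TSS window in bp (default 500).
#' @param denominator Count overlaps per gene (default) or per peak.
#' @return A list: `percent` (named), `counts` (hit/total per set),
#'   `tables` (named list of pairwise 2x2 matrices), `fisher_p` (named).
#' @export
tss_overlap_comparison <- function(peaks, gene_sets, tss_flank = 500,
                                   denominator = c("genes", "peaks")) {
  denominator <- match.arg(denominator)
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  tss_windows <- function(genes) {
    str <- as.character(GenomicRanges::strand(genes))
    tss <- ifelse(str == "-", GenomicRanges::end(genes),
                  GenomicRanges::start(genes))
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                           IRanges::IRanges(pmax(1, tss - tss_flank),
                                            tss + tss_flank))
  }
  counts <- lapply(gene_sets, function(genes) {
    tw <- tss_windows(genes)
    if (denominator == "genes") {
      hit <- sum(.count_hits(tw, peaks) > 0)
      c(hit = hit, total = length(genes))
    } else {
      hit <- sum(.count_hits(peaks, tw) > 0)
      c(hit = hit, total = length(peaks))
    }
  })
  percent <- vapply(counts, function(x) 100 * x[["hit"]] / x[["total"]],
                    numeric(1))
  nm <- names(gene_sets)
  tables <- list(); fisher_p <- numeric(0)
  if (length(nm) > 1) {
    for (i in seq_len(length(nm) - 1)) for (j in seq(i + 1, length(nm))) {
      a <- counts[[i]]; b <- counts[[j]]
      tb <- matrix(c(a[["hit"]], a[["total"]] - a[["hit"]],
                     b[["hit"]], b[["total"]] - b[["hit"]]),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c(nm[i], nm[j]), c("hit", "miss")))
      key <- paste(nm[i], nm[j], sep = "_vs_")
      tables[[key]] <- tb
      fisher_p[key] <- stats::fisher.test(tb)$p.value
    }
  }
  list(percent = percent, counts = counts, tables = tables,
       fisher_p = fisher_p)
}

#' Assign regulatory elements to their nearest gene
#'
#' Maps each TRE to the nearest eligible gene TSS within `max_dist` bp
#' (interval-to-point distance; 0 when the TSS lies inside the TRE).
#' Ties are broken by the leftmost TSS coordinate, then by gene id.
#'
#' @param tres [GenomicRanges::GRanges] of TREs.
#' @param genes [GenomicRanges::GRanges] with `gene_id`.
#' @param max_dist Maximum assignment distance in bp (default 50000).
#' @return A data.frame: `tre` (index or name), `gene_id` (NA when
#'   unassigned), `distance`.
#' @export
proximity_assign <- function(tres, genes, max_dist = 50000) {
  ids <- genes$gene_id %||% names(genes) %||%
    as.character(seq_along(genes))
  str <- as.character(GenomicRanges::strand(genes))
  tss <- ifelse(str == "-", GenomicRanges::end(genes),
                GenomicRanges::start(genes))
  tss_gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                   IRanges::IRanges(tss, width = 1))
  tre_names <- names(tres) %||% as.character(seq_along(tres))
  out <- data.frame(tre = tre_names, gene_id = NA_character_,
                    distance = NA_integer_)
  if (!length(tres) || !length(genes)) return(out)
  ## candidate pairs within max_dist, then explicit tie-breaking
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::resize(tres, GenomicRanges::width(tres) + 2 * max_dist,
                          fix = "center"),
    tss_gr, ignore.strand = TRUE)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    d <- GenomicRanges::distance(tres[qi], tss_gr[si],
                                 ignore.strand = TRUE)
    keep <- !is.na(d) & d <= max_dist
    qi <- qi[keep]; si <- si[keep]; d <- d[keep]
    if (length(qi)) {
      ord <- order(qi, d, tss[si], ids[si])
      first <- !duplicated(qi[ord])
      sel_q <- qi[ord][first]; sel_s <- si[ord][first]
      out$gene_id[sel_q] <- ids[sel_s]
      out$distance[sel_q] <- d[ord][first]
    }
  }
  out
}
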