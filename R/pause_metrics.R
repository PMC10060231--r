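#' Strand-aware analysis windows for one gene
#'
#' Splits a gene into the three windows used for nascent-transcription
#' summaries: the promoter-proximal pause window (TSS to `pause_len` bp
#' downstream), the gene body (rest of the annotation), and the post-PAS
#' window (`postpas_len` bp downstream of the 3' end). "Downstream" follows
#' the direction of transcription: for a minus-strand gene the TSS is the
#' right-hand (end) coordinate and the post-PAS window extends leftwards
#' from the gene start. Post-PAS windows are clipped at chromosome ends
#' and flagged.
#'
#' @param gene A length-one [GenomicRanges::GRanges] with strand `+` or `-`.
#' @param pause_len Pause-window length in bp (default 250).
#' @param postpas_len Post-PAS window length in bp (default 5000).
#' @param chrom_sizes Optional named lengths used to clip the post-PAS
#'   window at the chromosome end.
#' @return A [GenomicRanges::GRanges] of three windows named `pause`,
#'   `body`, `postpas`, with a logical metadata column `clipped`.
#' @export
gene_windows <- function(gene, pause_len = 250, postpas_len = 5000,
                         chrom_sizes = NULL) {
  if (length(gene) != 1) stop_input("gene must be a single interval")
  w <- GenomicRanges::width(gene)
  if (w <= pause_len) {
    stop_input("gene shorter than the pause window (", pause_len, " bp)")
  }
  ch <- as.character(GenomeInfoDb::seqnames(gene))
  s <- GenomicRanges::start(gene); e <- GenomicRanges::end(gene)
  str <- as.character(GenomicRanges::strand(gene))
  if (!str %in% c("+", "-")) stop_input("gene must be stranded")
  L <- if (!is.null(chrom_sizes)) chrom_sizes[[ch]] else Inf
  clipped <- c(pause = FALSE, body = FALSE, postpas = FALSE)
  if (str == "+") {
    pause <- c(s, s + pause_len - 1)
    body  <- c(s + pause_len, e)
    post  <- c(e + 1, e + postpas_len)
    if (post[2] > L) { post[2] <- L; clipped["postpas"] <- TRUE }
    if (post[1] > L) stop_input("post-PAS window entirely off chromosome")
  } else {
    pause <- c(e - pause_len + 1, e)
    body  <- c(s, e - pause_len)
    post  <- c(s - postpas_len, s - 1)
    if (post[1] < 1) { post[1] <- 1; clipped["postpas"] <- TRUE }
    if (post[2] < 1) stop_input("post-PAS window entirely off chromosome")
  }
  gr <- GenomicRanges::GRanges(
    ch,
    IRanges::IRanges(start = c(pause[1], body[1], post[1]),
                     end = c(pause[2], body[2], post[2])),
    strand = str)
  names(gr) <- c("pause", "body", "postpas")
  gr$clipped <- clipped
  gr
}

## eligibility logical with reasons; neighbor TSSs are TSSs of *other*
## genes on the same chromosome, either strand
.gene_eligibility <- function(genes, min_length = 500,
                              min_neighbor_dist = 5000) {
  n <- length(genes)
  long_enough <- GenomicRanges::width(genes) > min_length
  isolated <- rep(TRUE, n)
  ch <- as.character(GenomeInfoDb::seqnames(genes))
  str <- as.character(GenomicRanges::strand(genes))
  tss <- ifelse(str == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  end3 <- ifelse(str == "+", GenomicRanges::end(genes),
                 GenomicRanges::start(genes))
  for (c1 in unique(ch)) {
    i <- which(ch == c1)
    if (length(i) < 2) next
    for (j in i) {
      d <- abs(tss[setdiff(i, j)] - end3[j])
      if (min(d) < min_neighbor_dist) isolated[j] <- FALSE
    }
  }
  data.frame(long_enough = long_enough, isolated = isolated,
             eligible = long_enough & isolated)
}

#' Filter genes eligible for windowed summaries
#'
#' Keeps genes longer than `min_length` bp whose 3' end lies at least
#' `min_neighbor_dist` bp from the TSS of every neighbouring gene, so that
#' the post-PAS window is not confounded by a downstream promoter.
#'
#' @param genes A [GenomicRanges::GRanges] of gene annotations.
#' @param min_length Minimum gene length in bp (exclusive; default 500).
#' @param min_neighbor_dist Minimum 3'-end-to-neighbour-TSS distance in bp
#'   (default 5000).
#' @return The eligible subset of `genes`.
#' @export
filter_eligible <- function(genes, min_length = 500,
                            min_neighbor_dist = 5000) {
  if (!length(genes)) return(genes)
  el <- .gene_eligibility(genes, min_length, min_neighbor_dist)
  genes[el$eligible]
}

#' Per-gene windowed signal summary
#'
#' Counts signal in the pause, body and post-PAS windows of each gene on
#' the gene's strand and derives the two density-ratio indices:
#' `pausing_index` = pause density / body density, and `retention_index` =
#' body density / post-PAS density. Both are ratios of densities from the
#' same track, so they are independent of any multiplicative track
#' normalization; they are computed from the unscaled counts and are
#' therefore exactly invariant under [rescale_track()]. Undefined ratios
#' (zero denominator) are reported as `NA`, never as 0 or `Inf`.
#'
#' @param tracks A list with elements `plus` and `minus`, each a
#'   [signal_track()] for one strand of one stage.
#' @param genes A [GenomicRanges::GRanges] with a `gene_id` metadata
#'   column (or names).
#' @param pause_len,postpas_len Window lengths in bp; see [gene_windows()].
#' @param min_count Minimum raw pause+body count required before a pausing
#'   index is reported (default 0 = no gate).
#' @return A data.frame with one row per gene: window counts and densities
#'   (reflecting the track scale), `pausing_index`, `retention_index`,
#'   `eligible` and `clipped` flags. Genes shorter than the pause window
#'   get `eligible = FALSE` and `NA` summaries.
#' @export
summarize_genes <- function(tracks, genes, pause_len = 250,
                            postpas_len = 5000, min_count = 0) {
  stopifnot(is.list(tracks), inherits(tracks$plus, "signal_track"),
            inherits(tracks$minus, "signal_track"))
  ids <- genes$gene_id %||% names(genes) %||% as.character(seq_along(genes))
  chrom_sizes <- tracks$plus$chrom_sizes
  el <- if (length(genes)) .gene_eligibility(genes) else NULL
  out <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    str <- as.character(GenomicRanges::strand(g))
    tr <- if (str == "-") tracks$minus else tracks$plus
    base <- data.frame(gene_id = ids[i],
                       pause_count = NA_real_, body_count = NA_real_,
                       postpas_count = NA_real_,
                       pause_density = NA_real_, body_density = NA_real_,
                       postpas_density = NA_real_,
                       pausing_index = NA_real_, retention_index = NA_real_,
                       eligible = FALSE, clipped = FALSE)
    if (GenomicRanges::width(g) <= pause_len) return(base)
    wins <- gene_windows(g, pause_len, postpas_len, chrom_sizes)
    raw <- vapply(seq_along(wins), function(k) {
      .raw_count(tr, as.character(GenomeInfoDb::seqnames(wins[k])),
                 GenomicRanges::start(wins[k]), GenomicRanges::end(wins[k]))
    }, numeric(1))
    names(raw) <- names(wins)
    wlen <- stats::setNames(GenomicRanges::width(wins), names(wins))
    dens_raw <- raw / wlen
    pi_val <- if (dens_raw["body"] > 0 &&
                  (raw["pause"] + raw["body"]) >= min_count) {
      dens_raw["pause"] / dens_raw["body"]
    } else NA_real_
    ri_val <- if (dens_raw["postpas"] > 0 && dens_raw["body"] >= 0) {
      dens_raw["body"] / dens_raw["postpas"]
    } else NA_real_
    base$pause_count <- raw["pause"] * tr$scale
    base$body_count <- raw["body"] * tr$scale
    base$postpas_count <- raw["postpas"] * tr$scale
    base$pause_density <- dens_raw["pause"] * tr$scale
    base$body_density <- dens_raw["body"] * tr$scale
    base$postpas_density <- dens_raw["postpas"] * tr$scale
    base$pausing_index <- pi_val
    base$retention_index <- ri_val
    base$eligible <- el$eligible[i]
    base$clipped <- any(wins$clipped)
    base
  })
  res <- do.call(rbind, out) %||%
    data.frame(gene_id = character(0))
  rownames(res) <- NULL
  res
}

#' @rdname summarize_genes
#' @param gene A single gene interval.
#' @export
summarize_gene <- function(tracks, gene, pause_len = 250,
                           postpas_len = 5000, min_count = 0) {
  summarize_genes(tracks, gene, pause_len, postpas_len, min_count)
}

#' Long-format pausing-index table across stages
#'
#' Binds per-stage gene summaries into a long table suitable for paired
#' per-gene stage comparisons (e.g. Wilcoxon matched-pairs tests via
#' [stats::wilcox.test()]), annotated with a chromosome class
#' (autosome vs sex chromosome).
#'
#' @param summaries Named list (stage -> data.frame from
#'   [summarize_genes()]).
#' @param genes The gene annotation used for the summaries (for chromosome
#'   class lookup).
#' @param sex_chroms Chromosome names classed as sex chromosomes.
#' @param paired If `TRUE` (default), keep only genes with a defined
#'   pausing index in every stage, so rows pair across stages.
#' @return A data.frame: `gene_id`, `stage`, `pausing_index`,
#'   `retention_index`, `chrom_class`.
#' @export
pausing_index_table <- function(summaries, genes,
                                sex_chroms = c("chrX", "chrY"),
                                paired = TRUE) {
  stopifnot(is.list(summaries), !is.null(names(summaries)))
  ids <- genes$gene_id %||% names(genes)
  cls <- ifelse(as.character(GenomeInfoDb::seqnames(genes)) %in% sex_chroms,
                "sex", "autosome")
  names(cls) <- ids
  long <- do.call(rbind, lapply(names(summaries), function(st) {
    s <- summaries[[st]]
    data.frame(gene_id = s$gene_id, stage = st,
               pausing_index = s$pausing_index,
               retention_index = s$retention_index,
               chrom_class = unname(cls[s$gene_id]))
  }))
  if (paired) {
    ok <- stats::aggregate(
      !is.na(long$pausing_index),
      by = list(gene_id = long$gene_id), FUN = all)
    keep_n <- table(long$gene_id)[ok$gene_id] == length(summaries)
    keep <- ok$gene_id[ok$x & keep_n]
    long <- long[long$gene_id %in% keep, ]
  }
  long$stage <- factor(long$stage, levels = names(summaries))
  rownames(long) <- NULL
  long
}

## per-gene binned profile oriented 5'->3'; flanks in fixed-size bins,
## body rescaled to body_bins equal-width bins
.gene_profile <- function(tracks, gene, chrom_sizes, flank, flank_bins,
                          body_bins) {
  str <- as.character(GenomicRanges::strand(gene))
  tr <- if (str == "-") tracks$minus else tracks$plus
  ch <- as.character(GenomeInfoDb::seqnames(gene))
  L <- chrom_sizes[[ch]]
  s <- GenomicRanges::start(gene); e <- GenomicRanges::end(gene)
  bin_mean <- function(from, to, nb) {
    br <- round(seq(from - 1, to, length.out = nb + 1))
    vapply(seq_len(nb), function(k) {
      a <- max(1, br[k] + 1); b <- min(L, br[k + 1])
      if (b < a) return(NA_real_)
      .raw_count(tr, ch, a, b) / (b - a + 1)
    }, numeric(1))
  }
  up <- bin_mean(s - flank, s - 1, flank_bins)
  body <- bin_mean(s, e, body_bins)
  dn <- bin_mean(e + 1, e + flank, flank_bins)
  prof <- if (str == "+") c(up, body, dn) else rev(c(up, body, dn))
  prof * tr$scale
}

#' Scaled metagene profile with subsample envelope
#'
#' Rescales each gene body to a fixed number of bins (flanks binned at
#' fixed width), then summarises the per-gene density profiles as the
#' per-bin median over `n_sub` random gene subsamples drawn without
#' replacement, with a quantile envelope.
#'
#' @param tracks `list(plus=, minus=)` of [signal_track()]s for one stage.
#' @param genes Gene annotation ([GenomicRanges::GRanges]); only eligible
#'   genes (see [filter_eligible()]) are profiled.
#' @param n_sub Number of subsamples (default 1000).
#' @param body_bins Bins across the gene body (default 50).
#' @param flank Flank length in bp (default 2000), `flank_bins` bins each.
#' @param flank_bins Bins per flank (default 20).
#' @param sub_size Genes per subsample; default 10% of the profiled genes
#'   (at least 2). Reduced with a warning if it exceeds the gene count.
#' @param seed Optional RNG seed for the subsampling.
#' @return A data.frame: `bin`, `region` (upstream/body/downstream),
#'   `value` (median), `lo`, `hi` (2.5%/97.5% envelope).
#' @export
scaled_metagene <- function(tracks, genes, n_sub = 1000, body_bins = 50,
                            flank = 2000, flank_bins = 20, sub_size = NULL,
                            seed = NULL) {
  genes <- filter_eligible(genes)
  ## deterministic gene order so profiles do not depend on input order
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  n <- length(genes)
  if (n < 2) stop_input("need at least 2 eligible genes")
  chrom_sizes <- tracks$plus$chrom_sizes
  mat <- t(vapply(seq_len(n), function(i) {
    .gene_profile(tracks, genes[i], chrom_sizes, flank, flank_bins,
                  body_bins)
  }, numeric(2 * flank_bins + body_bins)))
  if (is.null(sub_size)) sub_size <- max(2, ceiling(0.1 * n))
  if (sub_size > n) {
    warning("sub_size reduced to the number of profiled genes (", n, ")")
    sub_size <- n
  }
  sub_means <- with_seed(seed, {
    t(vapply(seq_len(n_sub), function(i) {
      colMeans(mat[sample.int(n, sub_size), , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(mat))))
  })
  region <- c(rep("upstream", flank_bins), rep("body", body_bins),
              rep("downstream", flank_bins))
  data.frame(bin = seq_len(ncol(mat)), region = region,
             value = apply(sub_means, 2, stats::median),
             lo = apply(sub_means, 2, stats::quantile, 0.025),
             hi = apply(sub_means, 2, stats::quantile, 0.975))
}

#' Peak-centered signal metaplot and matrix
#'
#' Bins signal in a fixed window around each peak center and returns the
#' mean profile plus the per-peak matrix (rows sortable by row sum, e.g.
#' by signal intensity in a chosen stage).
#'
#' @param track A [signal_track()] (unstranded signal such as ATAC), or a
#'   `list(plus=, minus=)` pair whose values are summed.
#' @param peaks [GenomicRanges::GRanges] of peaks.
#' @param flank Half-window in bp around each peak center (default 10000).
#' @param bins Number of bins across the window (default 100).
#' @param sort_decreasing If `TRUE`, order matrix rows by decreasing row
#'   sum.
#' @return A list: `profile` (data.frame bin, offset, value), `matrix`
#'   (peaks x bins), `order` (row order used).
#' @export
peak_centered_metaplot <- function(track, peaks, flank = 10000, bins = 100,
                                   sort_decreasing = TRUE) {
  trs <- if (inherits(track, "signal_track")) list(track) else track
  chrom_sizes <- trs[[1]]$chrom_sizes
  centers <- interval_center(peaks)
  ch <- as.character(GenomeInfoDb::seqnames(peaks))
  br <- round(seq(-flank, flank, length.out = bins + 1))
  mat <- t(vapply(seq_along(peaks), function(i) {
    L <- chrom_sizes[[ch[i]]]
    vapply(seq_len(bins), function(k) {
      a <- centers[i] + br[k]; b <- centers[i] + br[k + 1] - 1
      a <- max(1, a); b <- min(L, b)
      if (b < a) return(0)
      sum(vapply(trs, function(tr) {
        .raw_count(tr, ch[i], a, b) * tr$scale
      }, numeric(1))) / (b - a + 1)
    }, numeric(1))
  }, numeric(bins)))
  ord <- order(rowSums(mat), decreasing = sort_decreasing)
  list(profile = data.frame(bin = seq_len(bins),
                            offset = (br[-1] + br[-(bins + 1)]) / 2,
                            value = colMeans(mat)),
       matrix = mat, order = ord)
}
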