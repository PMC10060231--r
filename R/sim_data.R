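#' Configuration for the synthetic prophase-I data generator
#'
#' Bundles every planted parameter of the simulator: genome geometry, gene
#' annotation shape, per-stage signal rates, per-stage relative
#' transcriptional activities, run-on calibration standards, the
#' sample-composition (purity) matrix, and the degree to which DSB-marker
#' peaks segregate away from transcribed regulatory elements.
#'
#' Defaults emulate the study conditions this package targets: three
#' prophase-I substages (leptonema/zygonema `LZ`, pachynema `P`, diplonema
#' `D`); a pachytene burst of transcriptional activity (`P` = 2.7 relative
#' to `LZ` = 1, `D` = 1); promoter-proximal pausing that is strongest in
#' `LZ` and released through `P` and `D` (planted pause/body density
#' ratios 5, 3, 2); 17 mixed-composition run-on samples calibrated against
#' three 10-fold serial dilutions of a standard; and complete segregation
#' of DSB hotspots from transcribed elements (`segregation = 1`).
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_chroms,chrom_length Genome geometry (bp).
#' @param n_genes Number of genes to place.
#' @param stage_params Named list (one per stage) of
#'   `list(pause_rate=, body_rate=, postpas_rate=)` in reads/bp at
#'   activity 1.
#' @param activity Named per-stage planted relative activity.
#' @param purity Samples x stages composition matrix; rows must sum to 1.
#' @param segregation Probability in \[0,1\] that a DSB-marker peak avoids
#'   transcribed peaks.
#' @param frac_ineligible Fraction of genes deliberately failing the
#'   eligibility filters (placed as short genes).
#' @param background_rate Intergenic Poisson rate in reads/bp (default 0).
#' @param gene_length_range Range of eligible gene lengths (bp).
#' @param standards List: planted line `m` (CPM/ng), `b` (CPM), dilution
#'   points `dna_ng`, replicates `n_rep`, Gaussian `noise_sd` (CPM).
#' @param sample_dna_ng DNA input per run-on sample (ng).
#' @param runon_noise_sd Multiplicative noise sd on observed sample CPM.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 4,
                       chrom_length = 2e6,
                       n_genes = 60,
                       stage_params = list(
                         LZ = list(pause_rate = 0.25, body_rate = 0.05,
                                   postpas_rate = 0.01),
                         P  = list(pause_rate = 0.15, body_rate = 0.05,
                                   postpas_rate = 0.01),
                         D  = list(pause_rate = 0.10, body_rate = 0.05,
                                   postpas_rate = 0.01)),
                       activity = c(LZ = 1, P = 2.7, D = 1),
                       purity = default_purity(17),
                       segregation = 1,
                       frac_ineligible = 0,
                       background_rate = 0,
                       gene_length_range = c(1500, 3000),
                       standards = list(m = 120, b = 50,
                                        dna_ng = c(5, 50, 500),
                                        n_rep = 2, noise_sd = 0),
                       sample_dna_ng = 500,
                       runon_noise_sd = 0) {
  stages <- names(stage_params)
  if (is.null(stages) || !setequal(names(activity), stages)) {
    stop_input("stage_params and activity must share stage names")
  }
  rates <- unlist(stage_params)
  if (any(rates < 0)) stop_input("all rates must be >= 0")
  if (any(activity < 0)) stop_input("activities must be >= 0")
  purity <- as.matrix(purity)
  if (ncol(purity) != length(stages)) {
    stop_input("purity matrix needs one column per stage")
  }
  colnames(purity) <- colnames(purity) %||% stages
  if (any(abs(rowSums(purity) - 1) > 1e-9)) {
    stop_input("each purity row must sum to 1")
  }
  if (segregation < 0 || segregation > 1) {
    stop_input("segregation must be in [0,1]")
  }
  if (frac_ineligible < 0 || frac_ineligible >= 1) {
    stop_input("frac_ineligible must be in [0,1)")
  }
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes), stages = stages,
                 stage_params = stage_params, activity = activity,
                 purity = purity, segregation = segregation,
                 frac_ineligible = frac_ineligible,
                 background_rate = background_rate,
                 gene_length_range = gene_length_range,
                 standards = standards, sample_dna_ng = sample_dna_ng,
                 runon_noise_sd = runon_noise_sd),
            class = "sim_config")
}

#' Default mixed-composition purity matrix
#'
#' A deterministic full-rank design over the three stages: the three pure
#' corners, then progressively mixed rows cycling through stage-dominant
#' compositions. Used as the default 17-sample design.
#' @param n Number of samples (rows).
#' @return An `n` x 3 matrix with rows summing to 1, columns LZ, P, D.
#' @export
default_purity <- function(n = 17) {
  base <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8),
                c(0.6, 0.3, 0.1), c(0.1, 0.6, 0.3), c(0.3, 0.1, 0.6),
                c(0.5, 0.4, 0.1), c(0.1, 0.5, 0.4), c(0.4, 0.1, 0.5),
                c(0.34, 0.33, 0.33))
  m <- base[rep_len(seq_len(nrow(base)), n), , drop = FALSE]
  dimnames(m) <- list(paste0("S", seq_len(n)), c("LZ", "P", "D"))
  m
}

## gene placement geometry: fixed margin at each chromosome start and a
## minimum inter-gene gap wide enough that every full-length gene passes
## the 5-kb neighbour filter by construction
.SIM_MARGIN <- 12000L
.SIM_MIN_GAP <- 5500L

#' Generate a synthetic gene annotation and chromosome sizes
#'
#' Places non-overlapping genes on both strands with inter-gene gaps of at
#' least 5.5 kb, so every full-length gene passes the eligibility filters
#' by construction; a configurable fraction of deliberately ineligible
#' (400 bp) genes is interleaved for filter testing.
#'
#' @param cfg A [sim_config()].
#' @return A list: `genes` ([GenomicRanges::GRanges] with `gene_id`),
#'   `chrom_sizes` (named integer vector).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                 paste0("chr", seq_len(cfg$n_chroms)))
  if (cfg$n_genes == 0) {
    return(list(genes = GenomicRanges::GRanges(), chrom_sizes = chrom_sizes))
  }
  max_len <- max(cfg$gene_length_range)
  per_gene <- max_len + .SIM_MIN_GAP + 1000
  capacity <- cfg$n_chroms * (cfg$chrom_length - 2 * .SIM_MARGIN)
  if (cfg$n_genes * per_gene > capacity) {
    stop_input("genome too small for ", cfg$n_genes, " genes: need ",
               cfg$n_genes * per_gene, " bp, have ", capacity)
  }
  with_seed(cfg$seed, {
    n_inel <- ceiling(cfg$frac_ineligible * cfg$n_genes)
    inel <- rep(FALSE, cfg$n_genes)
    if (n_inel > 0) inel[sample.int(cfg$n_genes, n_inel)] <- TRUE
    lens <- ifelse(inel, 400L,
                   sample(seq(cfg$gene_length_range[1],
                              cfg$gene_length_range[2]),
                          cfg$n_genes, replace = TRUE))
    strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    chrom_of <- rep_len(seq_len(cfg$n_chroms), cfg$n_genes)
    starts <- integer(cfg$n_genes)
    pos <- rep(.SIM_MARGIN + 1L, cfg$n_chroms)
    for (i in seq_len(cfg$n_genes)) {
      c1 <- chrom_of[i]
      if (pos[c1] + lens[i] + .SIM_MARGIN > cfg$chrom_length) {
        stop_input("genome too small: chromosome ", c1, " overflowed")
      }
      starts[i] <- pos[c1]
      pos[c1] <- pos[c1] + lens[i] + .SIM_MIN_GAP +
        sample.int(1000L, 1)
    }
    genes <- GenomicRanges::GRanges(
      paste0("chr", chrom_of),
      IRanges::IRanges(start = starts, width = lens),
      strand = strands)
    genes$gene_id <- sprintf("gene%03d", seq_len(cfg$n_genes))
    genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
    list(genes = genes, chrom_sizes = chrom_sizes)
  })
}

## assemble a per-chromosome Rle from disjoint (start, counts) segments
.segments_to_rle <- function(segs, L) {
  if (!length(segs)) return(S4Vectors::Rle(0L, L))
  ord <- order(vapply(segs, `[[`, numeric(1), "start"))
  segs <- segs[ord]
  pieces <- list()
  cur <- 1L
  for (sg in segs) {
    if (sg$start > cur) {
      pieces[[length(pieces) + 1]] <- S4Vectors::Rle(0L, sg$start - cur)
    }
    pieces[[length(pieces) + 1]] <- S4Vectors::Rle(sg$counts)
    cur <- sg$start + length(sg$counts)
  }
  if (cur <= L) pieces[[length(pieces) + 1]] <- S4Vectors::Rle(0L, L - cur + 1L)
  do.call(c, pieces)
}

#' Simulate stage-resolved strand-specific signal tracks
#'
#' Deposits independent Poisson counts per base on each gene's strand at
#' rate = window rate x stage activity: the pause window (first 250 bp
#' downstream of the TSS), gene body, and post-PAS window each get their
#' configured rate, emulating single-base polymerase-position coverage.
#' Intergenic background is Poisson at `background_rate` on both strands.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @return Named list (one per stage) of `list(plus=, minus=)`
#'   [signal_track()]s.
#' @export
simulate_stage_tracks <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- ann$genes
  chrom_sizes <- ann$chrom_sizes
  with_seed(cfg$seed + 1L, {
    out <- lapply(cfg$stages, function(st) {
      p <- cfg$stage_params[[st]]
      act <- cfg$activity[[st]]
      segs <- list(`+` = lapply(names(chrom_sizes), function(x) list()),
                   `-` = lapply(names(chrom_sizes), function(x) list()))
      names(segs$`+`) <- names(chrom_sizes)
      names(segs$`-`) <- names(chrom_sizes)
      for (i in seq_along(genes)) {
        g <- genes[i]
        if (GenomicRanges::width(g) <= 250) next
        wins <- gene_windows(g, 250, 5000, chrom_sizes)
        str <- as.character(GenomicRanges::strand(g))
        ch <- as.character(GenomeInfoDb::seqnames(g))
        rates <- c(pause = p$pause_rate, body = p$body_rate,
                   postpas = p$postpas_rate) * act
        for (k in names(wins)) {
          w <- wins[k]
          n <- GenomicRanges::width(w)
          counts <- stats::rpois(n, rates[[k]])
          segs[[str]][[ch]][[length(segs[[str]][[ch]]) + 1]] <-
            list(start = GenomicRanges::start(w), counts = counts)
        }
      }
      mk <- function(sgn) {
        covs <- lapply(names(chrom_sizes), function(ch) {
          r <- .segments_to_rle(segs[[sgn]][[ch]], chrom_sizes[[ch]])
          if (cfg$background_rate > 0) {
            r <- r + S4Vectors::Rle(stats::rpois(chrom_sizes[[ch]],
                                                 cfg$background_rate * act))
          }
          r
        })
        names(covs) <- names(chrom_sizes)
        signal_track(covs, chrom_sizes,
                     strand = if (sgn == "+") "+" else "-")
      }
      list(plus = mk("+"), minus = mk("-"))
    })
    names(out) <- cfg$stages
    out
  })
}

#' Simulate a run-on measurement table with calibration standards
#'
#' Standards lie on the planted line `cpm = m * dna_ng + b` (optionally
#' with Gaussian noise). Each sample's observed CPM is
#' `expected CPM x (composition . activity) x (1 + eps)`,
#' `eps ~ N(0, runon_noise_sd^2)`, where expected CPM comes from the
#' planted line at the sample's DNA input.
#'
#' @param cfg A [sim_config()].
#' @return A list: `samples` (data.frame `sample, dna_ng, cpm, frac_LZ,
#'   frac_P, frac_D`), `standards` (data.frame `sample, dna_ng, cpm`),
#'   `planted` (list `activity, m, b`).
#' @export
simulate_runon_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  st <- cfg$standards
  with_seed(cfg$seed + 2L, {
    x <- rep(st$dna_ng, times = st$n_rep)
    y <- st$m * x + st$b
    if ((st$noise_sd %||% 0) > 0) {
      y <- y + stats::rnorm(length(y), 0, st$noise_sd)
    }
    standards <- data.frame(
      sample = paste0("std", seq_along(x)), dna_ng = x, cpm = y)
    n <- nrow(cfg$purity)
    expc <- st$m * cfg$sample_dna_ng + st$b
    ratio <- as.numeric(cfg$purity %*% cfg$activity[colnames(cfg$purity)])
    eps <- if (cfg$runon_noise_sd > 0) {
      stats::rnorm(n, 0, cfg$runon_noise_sd)
    } else rep(0, n)
    samples <- data.frame(
      sample = rownames(cfg$purity) %||% paste0("S", seq_len(n)),
      dna_ng = cfg$sample_dna_ng,
      cpm = expc * ratio * (1 + eps),
      frac_LZ = cfg$purity[, "LZ"],
      frac_P = cfg$purity[, "P"],
      frac_D = cfg$purity[, "D"])
    rownames(samples) <- NULL
    list(samples = samples, standards = standards,
         planted = list(activity = cfg$activity, m = st$m, b = st$b))
  })
}

#' Simulate accessible, transcribed-TRE, and DSB-marker peak sets
#'
#' Accessible peaks are placed at every gene TSS plus distal intergenic
#' sites; transcribed regulatory elements (TREs) sit at gene TSSs and at a
#' fraction of the distal accessible sites. Each DSB-marker peak is placed
#' at the center of an accessible peak chosen without replacement: with
#' probability `segregation` from the accessible peaks that carry no TRE,
#' otherwise uniformly from all remaining accessible peaks — so
#' `segregation = 1` plants complete exclusion of DSBs from transcribed
#' chromatin and `segregation = 0` plants independence.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @param n_distal Number of distal accessible peaks (default: one per
#'   gene, so non-transcribed accessible chromatin is plentiful).
#' @param distal_tre_frac Fraction of distal accessible peaks that also
#'   carry a TRE (default 0.3).
#' @param n_dsb Number of DSB-marker peaks (default 25% of accessible
#'   peaks; must not exceed the non-TRE accessible count when
#'   `segregation = 1`).
#' @param acc_width,tre_width,dsb_width Peak widths in bp.
#' @return A list of [GenomicRanges::GRanges]: `accessible`, `tre`, `dsb`;
#'   `accessible` carries a logical `has_tre` column.
#' @export
simulate_peaks <- function(cfg, ann, n_distal = NULL,
                           distal_tre_frac = 0.3, n_dsb = NULL,
                           acc_width = 1000, tre_width = 300,
                           dsb_width = 200) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- ann$genes
  chrom_sizes <- ann$chrom_sizes
  if (is.null(n_distal)) n_distal <- max(4, length(genes))
  with_seed(cfg$seed + 3L, {
    str <- as.character(GenomicRanges::strand(genes))
    tss <- ifelse(str == "+", GenomicRanges::start(genes),
                  GenomicRanges::end(genes))
    tss_ch <- as.character(GenomeInfoDb::seqnames(genes))
    ## distal sites: sampled away from genes (+/- 4 kb) and from each other
    avoid <- GenomicRanges::reduce(
      GenomicRanges::resize(genes, GenomicRanges::width(genes) + 8000,
                            fix = "center"))
    d_ch <- character(0); d_pos <- integer(0)
    tries <- 0
    while (length(d_pos) < n_distal && tries < 50000) {
      tries <- tries + 1
      ch <- sample(names(chrom_sizes), 1)
      pos <- sample.int(chrom_sizes[[ch]] - acc_width, 1) + acc_width / 2
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, width = 1))
      if (length(GenomicRanges::findOverlaps(cand, avoid)) > 0) next
      ## keep all accessible centers >= 3 kb apart so each 5-kb
      ## co-occurrence window contains a single peak center
      if (length(d_pos) &&
          any(d_ch == ch & abs(d_pos - pos) < max(acc_width + 200, 3000))) next
      d_ch <- c(d_ch, ch); d_pos <- c(d_pos, pos)
    }
    if (length(d_pos) < n_distal) {
      stop_input("could not place ", n_distal, " distal peaks")
    }
    centers_ch <- c(tss_ch, d_ch)
    centers <- c(tss, as.integer(d_pos))
    n_acc <- length(centers)
    has_tre <- c(rep(TRUE, length(tss)),
                 seq_len(n_distal) <= round(distal_tre_frac * n_distal))
    clip <- function(ch, center, w) {
      s <- pmax(1, round(center - w / 2))
      e <- pmin(chrom_sizes[ch], s + w - 1)
      GenomicRanges::GRanges(ch, IRanges::IRanges(s, e))
    }
    accessible <- clip(centers_ch, centers, acc_width)
    accessible$has_tre <- has_tre
    tre <- clip(centers_ch[has_tre], centers[has_tre], tre_width)
    if (is.null(n_dsb)) n_dsb <- max(5, round(0.25 * n_acc))
    if (n_dsb > n_acc) stop_input("n_dsb exceeds accessible peak count")
    avail <- rep(TRUE, n_acc)
    picked <- integer(0)
    for (i in seq_len(n_dsb)) {
      pool_free <- which(avail & !has_tre)
      pool_all <- which(avail)
      use_free <- stats::runif(1) < cfg$segregation && length(pool_free) > 0
      pool <- if (use_free) pool_free else pool_all
      j <- pool[sample.int(length(pool), 1)]
      picked <- c(picked, j)
      avail[j] <- FALSE
    }
    dsb <- clip(centers_ch[picked], centers[picked], dsb_width)
    list(accessible = GenomicRanges::sort(accessible),
         tre = GenomicRanges::sort(tre),
         dsb = GenomicRanges::sort(dsb))
  })
}
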