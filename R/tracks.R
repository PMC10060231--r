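#' Strand-specific single-base signal track
#'
#' A `signal_track` holds run-length-encoded, non-negative per-base coverage
#' for one strand of a genome, as produced by nascent-transcription assays
#' (ChRO-seq/PRO-seq style) in which each read contributes a single base at
#' the polymerase active site. Values are stored raw together with a
#' multiplicative `scale`; [rescale_track()] only updates the scale, so
#' scale-free statistics such as the pausing index (a ratio of densities
#' from the same track) are exactly invariant under renormalization.
#'
#' @param cov A named [IRanges::RleList] (one `Rle` per chromosome) of
#'   non-negative values, or a named list coercible to one.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param strand One of `"+"`, `"-"`, `"*"`. Minus-strand signal is stored
#'   non-negative; negative-value display is a rendering concern.
#' @param scale Multiplicative factor applied on top of the raw values.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(cov, chrom_sizes, strand = "*", scale = 1) {
  if (!methods::is(cov, "RleList")) cov <- methods::as(cov, "RleList")
  if (is.null(names(chrom_sizes)) || anyNA(chrom_sizes)) {
    stop_input("chrom_sizes must be a named vector of lengths")
  }
  if (!all(names(cov) %in% names(chrom_sizes))) {
    stop_input("coverage on unknown chromosome: ",
               paste(setdiff(names(cov), names(chrom_sizes)), collapse = ", "))
  }
  ## pad/validate: every chromosome present, Rle length == chromosome length
  full <- lapply(names(chrom_sizes), function(ch) {
    L <- as.integer(chrom_sizes[[ch]])
    if (ch %in% names(cov)) {
      r <- cov[[ch]]
      if (length(r) > L) stop_input("coverage exceeds length of ", ch)
      if (length(r) < L) r <- c(r, S4Vectors::Rle(0, L - length(r)))
      r
    } else {
      S4Vectors::Rle(0, L)
    }
  })
  names(full) <- names(chrom_sizes)
  cov <- methods::as(full, "RleList")
  if (any(vapply(full, function(r) any(S4Vectors::runValue(r) < 0),
                 logical(1)))) {
    stop_input("signal_track values must be non-negative")
  }
  strand <- match.arg(strand, c("+", "-", "*"))
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop_input("scale must be a single positive number")
  }
  structure(list(cov = cov,
                 chrom_sizes = stats::setNames(as.integer(chrom_sizes),
                                               names(chrom_sizes)),
                 strand = strand, scale = as.numeric(scale)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), strand '%s', scale %g\n",
              length(x$cov), x$strand, x$scale))
  cat(sprintf("  library size: %g\n", library_size(x)))
  invisible(x)
}

#' Build a signal track from interval scores
#'
#' @param gr A [GenomicRanges::GRanges] with a numeric `score` column of
#'   non-overlapping intervals (bedGraph semantics).
#' @inheritParams signal_track
#' @return A `signal_track`.
#' @export
signal_track_from_granges <- function(gr, chrom_sizes, strand = "*",
                                      scale = 1) {
  sc <- gr$score %||% rep(1, length(gr))
  cov <- GenomicRanges::coverage(gr, weight = as.numeric(sc))
  signal_track(cov, chrom_sizes, strand = strand, scale = scale)
}

#' Total signal of a track
#'
#' Sum over all bases of value times one, i.e. the mapped-read count when
#' each read contributes a single base.
#' @param track A `signal_track`.
#' @param raw If `TRUE`, ignore the track scale.
#' @return A number.
#' @export
library_size <- function(track, raw = FALSE) {
  stopifnot(inherits(track, "signal_track"))
  tot <- sum(vapply(as.list(track$cov), function(r) sum(as.numeric(r)),
                    numeric(1)))
  if (raw) tot else tot * track$scale
}

#' Multiply a track by a positive factor
#'
#' Used to apply run-on-derived normalization factors to coverage. The
#' factor is folded into the track's scale; exported bedGraph values and
#' all counts reflect it.
#' @param track A `signal_track`.
#' @param factor Positive multiplier.
#' @return The rescaled `signal_track`.
#' @export
rescale_track <- function(track, factor) {
  stopifnot(inherits(track, "signal_track"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0) {
    stop_input("rescale factor must be a single positive number")
  }
  track$scale <- track$scale * factor
  track
}

.check_window <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$chrom_sizes)) {
    stop_input("unknown chromosome: ", chrom)
  }
  L <- track$chrom_sizes[[chrom]]
  if (end <= start) stop_input("zero-length window on ", chrom)
  if (start < 1 || end > L) {
    stop_input("window [", start, ",", end, "] out of bounds on ", chrom)
  }
}

## raw (unscaled) signal sum over a 1-based closed window
.raw_count <- function(track, chrom, start, end) {
  .check_window(track, chrom, start, end)
  sum(as.numeric(S4Vectors::window(track$cov[[chrom]], start, end)))
}

#' Count signal in a genomic window
#'
#' Sums per-base signal over an interval on the track's strand.
#' @param track A `signal_track`.
#' @param iv A length-one [GenomicRanges::GRanges] window.
#' @param density If `TRUE`, return count divided by window width
#'   (signal per bp).
#' @return A number.
#' @export
count_in_window <- function(track, iv, density = FALSE) {
  stopifnot(inherits(track, "signal_track"))
  if (length(iv) != 1) stop_input("iv must be a single interval")
  chrom <- as.character(GenomeInfoDb::seqnames(iv))
  s <- GenomicRanges::start(iv); e <- GenomicRanges::end(iv)
  cnt <- .raw_count(track, chrom, s, e) * track$scale
  if (density) cnt / (e - s + 1) else cnt
}

#' Reads/signal per kilobase per million (RPKM) and per million (RPM)
#'
#' @param counts Numeric vector of window counts.
#' @param lengths Window lengths in bp (recycled).
#' @param library_size Total mapped signal of the library.
#' @return Numeric vector of scaled values.
#' @export
rpkm <- function(counts, lengths, library_size) {
  if (any(library_size <= 0)) stop_input("library_size must be positive")
  if (any(lengths <= 0)) stop_input("lengths must be positive")
  counts / (lengths / 1e3) / (library_size / 1e6)
}

#' @rdname rpkm
#' @export
rpm <- function(counts, library_size) {
  if (any(library_size <= 0)) stop_input("library_size must be positive")
  counts / (library_size / 1e6)
}

#' Fraction of signal in peaks (FRiP)
#'
#' @param track A `signal_track`.
#' @param peaks A [GenomicRanges::GRanges] of peak intervals.
#' @return Fraction of the track's total signal falling inside the union
#'   of the peaks, in \[0, 1\].
#' @export
frip <- function(track, peaks) {
  stopifnot(inherits(track, "signal_track"))
  tot <- library_size(track, raw = TRUE)
  if (tot == 0) return(0)
  red <- GenomicRanges::reduce(peaks)
  inside <- 0
  for (i in seq_along(red)) {
    ch <- as.character(GenomeInfoDb::seqnames(red[i]))
    if (!ch %in% names(track$chrom_sizes)) next
    s <- max(1L, GenomicRanges::start(red[i]))
    e <- min(track$chrom_sizes[[ch]], GenomicRanges::end(red[i]))
    if (e >= s) inside <- inside + .raw_count(track, ch, s, e)
  }
  inside / tot
}
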