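#' Read and write chromosome sizes
#'
#' Two-column whitespace-separated text: chromosome name, length in bp.
#' @param path File path.
#' @return `read_chrom_sizes` returns a named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$chrom)) stop_input("duplicate chromosome in ", path)
  stats::setNames(df$size, df$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Named integer vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes),
                                as.integer(chrom_sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a signal track
#'
#' Coordinates on disk are 0-based half-open; in memory, intervals follow
#' the usual GRanges 1-based convention. Records must be sorted and
#' non-overlapping within each chromosome.
#'
#' @param path bedGraph file (4 columns).
#' @param chrom_sizes Named integer vector of chromosome lengths. Required;
#'   records on unknown chromosomes are an error.
#' @param strand Strand label for the resulting track.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, strand = "*") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr)) {
    bad <- !as.character(GenomeInfoDb::seqnames(gr)) %in% names(chrom_sizes)
    if (any(bad)) {
      stop_input("record ", which(bad)[1], " in ", path,
                 ": unknown chromosome ",
                 as.character(GenomeInfoDb::seqnames(gr))[which(bad)[1]])
    }
    ## validate sortedness / non-overlap in file order, per chromosome
    ch <- as.character(GenomeInfoDb::seqnames(gr))
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    for (c1 in unique(ch)) {
      i <- which(ch == c1)
      if (length(i) > 1) {
        prev_end <- en[i][-length(i)]; nxt_start <- st[i][-1]
        off <- which(nxt_start <= prev_end)
        if (length(off)) {
          stop_input("record ", i[off[1] + 1], " in ", path,
                     ": unsorted or overlapping interval on ", c1)
        }
      }
      if (max(en[i]) > chrom_sizes[[c1]]) {
        stop_input("record ", i[which.max(en[i])], " in ", path,
                   ": interval beyond end of ", c1)
      }
    }
  }
  signal_track_from_granges(gr, chrom_sizes, strand = strand)
}

#' Write a signal track as bedGraph
#'
#' Zero-valued runs are omitted; the track scale is applied to the values.
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  grl <- lapply(names(track$cov), function(ch) {
    r <- track$cov[[ch]]
    rv <- S4Vectors::runValue(r)
    ir <- IRanges::ranges(r)[rv != 0]
    GenomicRanges::GRanges(rep(ch, length(ir)), ir,
                           score = rv[rv != 0] * track$scale)
  })
  gr <- suppressWarnings(do.call(c, grl))
  if (is.null(gr$score)) gr$score <- numeric(0)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read and write BED interval files
#'
#' Thin wrappers over [rtracklayer::import()]/[rtracklayer::export()]
#' (BED3/BED6; 0-based half-open on disk).
#' @param path File path.
#' @return `read_bed` returns a [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @param gr A [GenomicRanges::GRanges]; `name` and `strand` are written
#'   when present (BED6), otherwise BED3.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
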