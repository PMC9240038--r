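# BED / bedGraph I/O, via rtracklayer. Internally intervals travel as plain
# data.frames with 0-based half-open `start`/`end` (bp) and optional
# `strand`/`name`, matching BED semantics on disk.

#' Read a BED file of genomic intervals
#'
#' @param path BED (3+ column) file; column 6, when present, carries the
#'   motif orientation as strand.
#' @return data.frame with `chrom`, `start`, `end` (0-based, half-open),
#'   `name` and `strand` (`"+"`, `"-"` or `"*"`).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param df data.frame with `start`, `end` (0-based, half-open) and
#'   optional `name`, `score`, `strand`.
#' @param path Output path.
#' @param chrom Chromosome name (single value or per-row vector).
#' @export
write_bed <- function(df, path, chrom = "chrS") {
  gr <- GenomicRanges::GRanges(
    seqnames = if (!is.null(df$chrom)) df$chrom else chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (!is.null(df$strand)) df$strand else "*")
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Rasterize intervals to bins
#'
#' A bin is labeled by an interval when at least `min_overlap` of the bin is
#' covered by it.
#'
#' @param intervals data.frame with `start`/`end` in bp (0-based,
#'   half-open).
#' @param resolution Bin size in bp.
#' @param n_bins Number of bins on the chromosome.
#' @param min_overlap Minimum covered fraction of a bin (default 0.5).
#' @return Sorted unique 0-based bin indices.
#' @export
intervals_to_bins <- function(intervals, resolution, n_bins, min_overlap = 0.5) {
  if (nrow(intervals) == 0) return(integer(0))
  hits <- lapply(seq_len(nrow(intervals)), function(r) {
    s <- intervals$start[r]; e <- intervals$end[r]
    bins <- seq(bin_of(s, resolution), min(bin_of(e - 1, resolution), n_bins - 1L))
    cov <- pmin(e, (bins + 1) * resolution) - pmax(s, bins * resolution)
    bins[cov / resolution >= min_overlap]
  })
  sort(unique(as.integer(unlist(hits))))
}

#' Export a per-bin track as bedGraph
#'
#' @param score Numeric vector, one value per bin; `NA` bins are skipped.
#' @param resolution Bin size in bp.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_bedgraph <- function(score, resolution, path, chrom = "chrS") {
  keep <- which(!is.na(score))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = (keep - 1L) * resolution + 1,
                              width = resolution),
    score = score[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
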