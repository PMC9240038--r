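#' Construct a binned intra-chromosomal contact matrix
#'
#' A `contact_matrix` holds the symmetric bin-by-bin contact table for one
#' chromosome, its resolution and its kind (`"raw_counts"` or
#' `"probability"`). Bins are 0-based, half-open: bin `k` covers
#' `[k * resolution, (k + 1) * resolution)`.
#'
#' @param values Square numeric matrix (dense), `n_bins` x `n_bins`. `NA`
#'   entries mean "not modeled" (e.g. pairs outside any diagonal frame).
#' @param resolution Bin size in bp.
#' @param kind `"raw_counts"` or `"probability"`.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, resolution, kind = c("raw_counts", "probability")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("contact matrix must be square")
  stopifnot(is.numeric(resolution), length(resolution) == 1, resolution >= 1)
  fin <- values[!is.na(values)]
  if (kind == "raw_counts" && any(fin < 0))
    stop("raw counts must be >= 0")
  if (kind == "probability" && any(fin < 0 | fin > 1))
    stop("probabilities must lie in [0, 1]")
  structure(
    list(values = unname(values), resolution = as.numeric(resolution),
         n_bins = nrow(values), kind = kind),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d x %d bins at %g bp (%s), %d non-missing entries\n",
              x$n_bins, x$n_bins, x$resolution, x$kind, sum(!is.na(x$values))))
  invisible(x)
}

#' Map a genomic coordinate to its 0-based bin index
#'
#' @param coordinate Position(s) in bp, 0-based, `>= 0`.
#' @param resolution Bin size in bp.
#' @return `floor(coordinate / resolution)`, 0-based.
#' @examples
#' bin_of(67950000, 10000)  # 6795
#' @export
bin_of <- function(coordinate, resolution) {
  stopifnot(is.numeric(coordinate), is.numeric(resolution), resolution >= 1)
  if (any(coordinate < 0))
    stop("coordinates must be >= 0")
  floor(coordinate / resolution)
}

#' Bins covered by a genomic region
#'
#' Returns the inclusive 0-based bin range touched by `[start, end)` and its
#' length, reproducing e.g. 67.95-70.08 Mb at 10 kb -> bins 6795..7008,
#' 214 bins.
#'
#' @param start,end Region coordinates in bp, `start < end`.
#' @param resolution Bin size in bp.
#' @return List with `first`, `last` (0-based, inclusive) and `count`.
#' @export
region_bins <- function(start, end, resolution) {
  if (start >= end)
    stop("region start must be < end")
  first <- bin_of(start, resolution)
  last <- bin_of(end, resolution)
  list(first = first, last = last, count = last - first + 1)
}

#' Tile a chromosome into fixed-length diagonal frames
#'
#' Frames are consecutive half-open bin ranges of `frame_length` bins; the
#' decoder's hidden state is reinitialized at every frame boundary. The last
#' frame is padded up to `frame_length` with padding bins.
#'
#' @param n_bins Number of real bins (`>= 1`).
#' @param frame_length Frame length in bins (default 150).
#' @return An object of class `frame_spec` with fields `frame_length`,
#'   `n_frames`, `frames` (data.frame of 0-based `start`/`end`, end
#'   exclusive, including padding) and `padded_tail`.
#' @export
make_frames <- function(n_bins, frame_length = 150L) {
  stopifnot(is.numeric(n_bins), length(n_bins) == 1)
  if (n_bins < 1) stop("n_bins must be >= 1")
  stopifnot(frame_length >= 1)
  n_bins <- as.integer(n_bins); frame_length <- as.integer(frame_length)
  n_frames <- as.integer(ceiling(n_bins / frame_length))
  starts <- (seq_len(n_frames) - 1L) * frame_length
  structure(
    list(frame_length = frame_length, n_frames = n_frames,
         frames = data.frame(start = starts, end = starts + frame_length),
         padded_tail = n_frames * frame_length - n_bins,
         n_bins = n_bins),
    class = "frame_spec"
  )
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf("frame_spec: %d frame(s) of %d bins over %d bins (%d padded)\n",
              x$n_frames, x$frame_length, x$n_bins, x$padded_tail))
  invisible(x)
}

#' Read a juicer-dump contact list
#'
#' Parses the three-column text format emitted by `juicer dump observed`
#' (`pos1 <TAB> pos2 <TAB> value`, bin-start coordinates in bp, one
#' chromosome per file) into a symmetric dense [contact_matrix()] of raw
#' counts. Pairs may be listed in either orientation; each pair is mirrored.
#' Conflicting duplicate entries for the same pair are an error, absent pairs
#' are 0.
#'
#' @param path Path to the text file.
#' @param resolution Bin size in bp; positions must be multiples of it.
#' @param chrom_length Chromosome length in bp; determines `n_bins`.
#' @return A [contact_matrix()] of kind `"raw_counts"`.
#' @export
read_contacts <- function(path, resolution, chrom_length) {
  stopifnot(resolution >= 1, chrom_length >= resolution)
  if (!file.exists(path)) stop("contact file not found: ", path)
  if (file.size(path) == 0) stop("contact file is empty: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE)
  if (nrow(dt) == 0) stop("contact file is empty: ", path)
  if (ncol(dt) != 3)
    stop("expected 3 tab-separated columns (pos1 pos2 value) in ", path)
  pos1 <- suppressWarnings(as.numeric(dt[[1]]))
  pos2 <- suppressWarnings(as.numeric(dt[[2]]))
  val <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(!is.finite(pos1) | !is.finite(pos2) | !is.finite(val))
  if (length(bad))
    stop(sprintf("malformed row %d in %s: '%s'", bad[1], path,
                 paste(unlist(dt[bad[1]]), collapse = "\t")))
  if (any(val < 0))
    stop("negative contact value at row ", which(val < 0)[1])
  mis <- which(pos1 %% resolution != 0 | pos2 %% resolution != 0)
  if (length(mis))
    stop(sprintf("row %d: position not a multiple of resolution %g", mis[1], resolution))
  oob <- which(pos1 >= chrom_length | pos2 >= chrom_length | pos1 < 0 | pos2 < 0)
  if (length(oob))
    stop(sprintf("row %d: position beyond chromosome length %g", oob[1], chrom_length))
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  i <- as.integer(pos1 / resolution) + 1L
  j <- as.integer(pos2 / resolution) + 1L
  # canonical orientation, then check for conflicting duplicates
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  dup <- duplicated(key)
  if (any(dup)) {
    first_val <- val[match(key, key)]
    if (any(abs(val - first_val) > 0))
      stop("conflicting duplicate entries for bin pair ",
           key[which(dup & abs(val - first_val) > 0)[1]])
    keep <- !dup
    lo <- lo[keep]; hi <- hi[keep]; val <- val[keep]
  }
  m <- matrix(0, n_bins, n_bins)
  m[cbind(lo, hi)] <- val
  m[cbind(hi, lo)] <- val
  contact_matrix(m, resolution, "raw_counts")
}

#' Write a contact matrix as juicer-dump text
#'
#' Writes the non-zero upper triangle (including the diagonal) as
#' `pos1 <TAB> pos2 <TAB> value` with full double precision, so that
#' [read_contacts()] reproduces the matrix exactly. `NA` entries are skipped.
#'
#' @param m A [contact_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  idx <- which(upper.tri(m$values, diag = TRUE) & !is.na(m$values) & m$values != 0,
               arr.ind = TRUE)
  lines <- sprintf("%.0f\t%.0f\t%s",
                   (idx[, 1] - 1) * m$resolution,
                   (idx[, 2] - 1) * m$resolution,
                   formatC(m$values[idx], format = "g", digits = 17))
  writeLines(lines, path)
  invisible(path)
}
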