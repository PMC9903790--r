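#' Tile the genome into fixed-width bins
#'
#' Partitions every chromosome into consecutive, non-overlapping bins of
#' `binsize` bp (0-based, half-open).  The last bin of each chromosome may be
#' shorter than `binsize`.  Bin order is the chromosome order of
#' `chrom_sizes`, then genomic position; this order is the observation order
#' of the segmentation HMM.
#'
#' @param chrom_sizes either a named numeric vector (`c(chr1 = 1e6, ...)`) or
#'   a two-column data frame (chromosome, size in bp).
#' @param binsize bin width in bp (>= 1).  1000 bp is the usual resolution
#'   for per-cell feature identification, 500 bp for pseudo-bulk
#'   program identification.
#' @return an object of class `bin_index` with fields `binsize`,
#'   `chrom_order`, `chrom_sizes`, `offsets` (cumulative bin index at each
#'   chromosome start, 0-based) and `n_bins`.
#' @seealso [bin_table()], [count_matrix()]
#' @export
make_bins <- function(chrom_sizes, binsize) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- as.numeric(chrom_sizes[[2]])
    names(sizes) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- sizes
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must carry chromosome names")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicate chromosome name in chrom_sizes: ",
         paste(unique(names(chrom_sizes)[duplicated(names(chrom_sizes))]),
               collapse = ", "))
  if (length(binsize) != 1L || !is.finite(binsize) || binsize < 1)
    stop("binsize must be a single integer >= 1")
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("chromosome sizes must be positive")
  binsize <- as.integer(binsize)
  nb <- as.integer(ceiling(chrom_sizes / binsize))
  offsets <- c(0L, cumsum(nb))[seq_along(nb)]
  names(offsets) <- names(chrom_sizes)
  structure(
    list(binsize = binsize,
         chrom_order = names(chrom_sizes),
         chrom_sizes = chrom_sizes,
         offsets = offsets,
         n_bins = sum(nb)),
    class = "bin_index")
}

#' @export
print.bin_index <- function(x, ...) {
  cat(sprintf("bin_index: %d bins of %d bp over %d chromosome(s)\n",
              x$n_bins, x$binsize, length(x$chrom_order)))
  invisible(x)
}

#' Per-bin coordinate table
#'
#' @param bins a [make_bins()] index.
#' @return a `data.frame` with columns `chrom`, `start`, `end` (BED
#'   convention), one row per bin, in HMM observation order.
#' @export
bin_table <- function(bins) {
  stopifnot(inherits(bins, "bin_index"))
  nb <- ceiling(bins$chrom_sizes / bins$binsize)
  chrom <- rep(bins$chrom_order, nb)
  k <- unlist(lapply(nb, function(n) seq_len(n) - 1L), use.names = FALSE)
  start <- k * bins$binsize
  end <- pmin(start + bins$binsize, rep(unname(bins$chrom_sizes), nb))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Map genomic positions to bin indices
#'
#' @param bins a [make_bins()] index.
#' @param chrom,pos parallel vectors of chromosome names and 0-based
#'   positions.
#' @return 1-based bin indices; `NA` where the chromosome is absent from the
#'   index or the position lies beyond the chromosome end.
#' @export
bin_of <- function(bins, chrom, pos) {
  stopifnot(inherits(bins, "bin_index"))
  off <- bins$offsets[chrom]
  sz <- bins$chrom_sizes[chrom]
  idx <- unname(off) + pos %/% bins$binsize + 1L
  idx[is.na(off) | pos < 0 | pos >= unname(sz)] <- NA_integer_
  as.integer(idx)
}

#' Write bins as a BED file
#'
#' BED3 plus a name column `bin_<k>`; re-reading with [read_bins_bed()]
#' reproduces the index exactly.
#'
#' @param bins a [make_bins()] index.
#' @param path output file.
#' @export
write_bins_bed <- function(bins, path) {
  tb <- bin_table(bins)
  tb$name <- sprintf("bin_%d", seq_len(nrow(tb)) - 1L)
  data.table::fwrite(tb, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Rebuild a bin index from a BED file written by [write_bins_bed()]
#'
#' @param path BED file of consecutive fixed-width bins.
#' @return a `bin_index`.
#' @export
read_bins_bed <- function(path) {
  tb <- data.table::fread(path, header = FALSE, sep = "\t")
  chrom <- as.character(tb[[1]])
  start <- as.numeric(tb[[2]])
  end <- as.numeric(tb[[3]])
  binsize <- max(end - start)
  ord <- unique(chrom)
  sizes <- vapply(ord, function(cc) max(end[chrom == cc]), numeric(1))
  make_bins(sizes, binsize)
}
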