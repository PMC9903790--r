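#' Read a fragment file
#'
#' Fragment files are BED-like TSVs with one sequenced fragment per line:
#' chromosome, start, end, cell barcode, and (in the 5-column dialect) a
#' duplicate count.  Plain or gzip-compressed input is accepted; lines
#' starting with `#` are skipped.
#'
#' @param path fragment file (`.tsv`, `.bed`, optionally `.gz`).
#' @param dialect `"auto"` (default), `"4col"` or `"5col"`.  With `"auto"`
#'   the count column is used when present.  A missing count defaults to 1.
#' @return a `data.frame` of class `fragment_set` with columns `chrom`,
#'   `start`, `end`, `barcode`, `count`.
#' @export
read_fragments <- function(path, dialect = c("auto", "4col", "5col")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("fragment file not found: ", path)
  if (grepl("\\.gz$", path)) {
    dt <- data.table::fread(text = readLines(gzfile(path)), header = FALSE,
                            sep = "\t", fill = TRUE, data.table = FALSE,
                            colClasses = list(character = 1))
  } else {
    head_lines <- readLines(path, n = 1000)
    n_skip <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                            skip = n_skip, data.table = FALSE,
                            colClasses = list(character = 1))
  }
  # fread drops blank lines but keeps '#' comment lines; strip them
  if (nrow(dt) > 0 && is.character(dt[[1]]))
    dt <- dt[!startsWith(dt[[1]], "#"), , drop = FALSE]
  nc <- ncol(dt)
  if (nc < 4L) stop("fragment file must have at least 4 columns, found ", nc)
  if (dialect == "4col" && nc > 4L) dt <- dt[, 1:4, drop = FALSE]
  if (dialect == "5col" && nc < 5L)
    stop("5-column dialect requested but file has ", nc, " columns")
  frags <- data.frame(chrom = as.character(dt[[1]]),
                      start = dt[[2]], end = dt[[3]],
                      barcode = as.character(dt[[4]]),
                      stringsAsFactors = FALSE)
  frags$count <- if (ncol(dt) >= 5L) as.numeric(dt[[5]]) else 1
  frags$count[is.na(frags$count)] <- 1
  validate_fragments(frags)
  class(frags) <- c("fragment_set", "data.frame")
  frags
}

validate_fragments <- function(frags) {
  bad_num <- which(!is.finite(frags$start) | !is.finite(frags$end) |
                     frags$start != floor(frags$start) |
                     frags$end != floor(frags$end))
  if (length(bad_num))
    stop("non-integer coordinates at line ", bad_num[1])
  bad <- which(frags$end <= frags$start)
  if (length(bad))
    stop("end <= start at line ", bad[1])
  if (any(frags$start < 0))
    stop("negative start at line ", which(frags$start < 0)[1])
  if (any(!nzchar(frags$chrom)))
    stop("empty chromosome name at line ", which(!nzchar(frags$chrom))[1])
  if (any(frags$count <= 0))
    stop("non-positive count at line ", which(frags$count <= 0)[1])
  invisible(frags)
}

#' Build a fragment set from vectors
#'
#' In-memory constructor used by the simulator and tests; applies the same
#' validation as [read_fragments()].
#'
#' @param chrom,start,end,barcode,count parallel vectors (0-based, half-open
#'   coordinates; `count` defaults to 1 per record).
#' @return a `fragment_set`.
#' @export
fragment_set <- function(chrom, start, end, barcode, count = 1) {
  frags <- data.frame(chrom = as.character(chrom),
                      start = as.numeric(start), end = as.numeric(end),
                      barcode = as.character(barcode),
                      count = as.numeric(rep_len(count, length(chrom))),
                      stringsAsFactors = FALSE)
  validate_fragments(frags)
  class(frags) <- c("fragment_set", "data.frame")
  frags
}

#' Bin fragments into a bins-by-tracks count matrix
#'
#' Each fragment is assigned to the single bin containing its midpoint,
#' `floor((start + end) / 2)`.  Per-(bin, barcode) totals may be trimmed to a
#' cap (4 in the per-cell setting) to blunt spurious high-duplication
#' artifacts.  Fragments on chromosomes absent from `bins` are dropped and
#' tallied.
#'
#' @param frags a [fragment_set()].
#' @param bins a [make_bins()] index.
#' @param cap optional per-entry ceiling applied after summing duplicate
#'   records per (bin, barcode); `NULL` leaves counts untrimmed.
#' @return an object of class `seg_counts`: a list with the sparse
#'   `counts` matrix (bins x tracks), the `bin_index`, track names,
#'   pre-cap per-track fragment totals (`track_totals`, the quantity
#'   barcode quality filters operate on), per-bin totals, and the number of
#'   dropped fragments.
#' @export
count_matrix <- function(frags, bins, cap = NULL) {
  stopifnot(inherits(bins, "bin_index"))
  mid <- (frags$start + frags$end) %/% 2
  idx <- bin_of(bins, frags$chrom, mid)
  keep <- !is.na(idx)
  n_dropped <- sum(frags$count[!keep])
  if (n_dropped > 0)
    message(sprintf("count_matrix: dropped %g fragment(s) on chromosomes absent from bins",
                    n_dropped))
  tracks <- sort(unique(frags$barcode))
  j <- match(frags$barcode[keep], tracks)
  m <- Matrix::sparseMatrix(i = idx[keep], j = j, x = frags$count[keep],
                            dims = c(bins$n_bins, length(tracks)),
                            dimnames = list(NULL, tracks))
  track_totals <- Matrix::colSums(m)
  if (!is.null(cap)) {
    stopifnot(cap >= 1)
    m@x <- pmin(m@x, cap)
  }
  new_seg_counts(m, bins, track_totals, n_dropped = n_dropped)
}

new_seg_counts <- function(m, bins, track_totals = NULL, n_dropped = 0) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  if (is.null(track_totals)) track_totals <- Matrix::colSums(m)
  structure(
    list(counts = m,
         bins = bins,
         tracks = colnames(m),
         track_totals = unname(track_totals),
         bin_totals = unname(Matrix::rowSums(m)),
         n_dropped = n_dropped),
    class = "seg_counts")
}

#' @export
print.seg_counts <- function(x, ...) {
  cat(sprintf("seg_counts: %d bins x %d tracks, %d non-zero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' Retain barcodes by fragment count
#'
#' Poor-quality or doublet barcodes are excluded by requiring the per-track
#' fragment total to lie in `[min_fragments, max_fragments]` (both bounds
#' inclusive).  The filter operates on the uncapped totals recorded at
#' matrix construction, not on trimmed matrix entries.
#'
#' @param cm a [count_matrix()].
#' @param min_fragments,max_fragments inclusive bounds (1000 and 30000 are
#'   typical for per-cell matrices).
#' @return the filtered `seg_counts`, track order preserved.
#' @export
filter_barcodes <- function(cm, min_fragments = 1000, max_fragments = 30000) {
  stopifnot(inherits(cm, "seg_counts"), min_fragments <= max_fragments)
  keep <- cm$track_totals >= min_fragments & cm$track_totals <= max_fragments
  if (!any(keep)) stop("no barcodes survive filtering")
  new_seg_counts(cm$counts[, keep, drop = FALSE], cm$bins,
                 cm$track_totals[keep], cm$n_dropped)
}

#' Filter a region-restricted matrix by region and cell coverage
#'
#' Applied to a matrix already restricted to regions of interest: first
#' regions with a cross-cell sum below `min_region_count` are removed, then
#' cells with a cross-region sum (over the kept regions) below
#' `min_cell_count`.
#'
#' @param cm a `seg_counts` restricted to a region subset.
#' @param min_region_count,min_cell_count inclusive lower bounds (1 and 200
#'   are typical).
#' @return a list with the filtered sparse `counts`, logical `keep_regions`
#'   and `keep_cells` masks relative to the input.
#' @export
filter_regions_and_cells <- function(cm, min_region_count = 1,
                                     min_cell_count = 200) {
  stopifnot(inherits(cm, "seg_counts"))
  m <- cm$counts
  keep_r <- Matrix::rowSums(m) >= min_region_count
  m2 <- m[keep_r, , drop = FALSE]
  keep_c <- Matrix::colSums(m2) >= min_cell_count
  m2 <- m2[, keep_c, drop = FALSE]
  if (nrow(m2) == 0 || ncol(m2) == 0)
    stop("no regions or cells survive filtering")
  list(counts = m2, keep_regions = keep_r, keep_cells = keep_c)
}

#' Collapse cells into pseudo-bulk group tracks
#'
#' Sums per-cell counts within groups (e.g. density clusters) to produce a
#' bins-by-groups pseudo-bulk matrix.  Unlabeled barcodes are dropped with a
#' warning; group track order is sorted group name.
#'
#' @param cm a per-cell [count_matrix()] (typically built without a cap).
#' @param labels named character vector or 2-column data frame mapping
#'   barcode to group.
#' @return a `seg_counts` with one track per group.
#' @export
collapse_by_group <- function(cm, labels) {
  stopifnot(inherits(cm, "seg_counts"))
  if (is.data.frame(labels)) {
    lab <- as.character(labels[[2]])
    names(lab) <- as.character(labels[[1]])
    labels <- lab
  }
  if (length(labels) == 0) stop("empty label map")
  grp <- labels[cm$tracks]
  if (anyNA(grp)) {
    warning(sum(is.na(grp)), " unlabeled barcode(s) dropped")
  }
  keep <- !is.na(grp)
  if (!any(keep)) stop("no labeled barcodes present in matrix")
  groups <- sort(unique(unname(grp[keep])))
  empty <- setdiff(sort(unique(unname(labels))), groups)
  if (length(empty))
    warning("group(s) with zero member barcodes dropped: ",
            paste(empty, collapse = ", "))
  ind <- Matrix::sparseMatrix(i = which(keep),
                              j = match(grp[keep], groups),
                              x = 1,
                              dims = c(length(cm$tracks), length(groups)),
                              dimnames = list(NULL, groups))
  m <- cm$counts %*% ind
  new_seg_counts(m, cm$bins, n_dropped = cm$n_dropped)
}

#' Subset a count matrix to a set of bins
#'
#' @param cm a `seg_counts`.
#' @param bin_idx integer bin indices to keep (1-based, in matrix order).
#' @return list with `counts` and the index vector; the bin index itself is
#'   not re-derived because the subset is generally not a regular tiling.
#' @export
subset_bins <- function(cm, bin_idx) {
  stopifnot(inherits(cm, "seg_counts"))
  list(counts = cm$counts[bin_idx, , drop = FALSE], bin_idx = bin_idx)
}

#' Persist a count matrix as MTX plus sidecar files
#'
#' Writes `<prefix>.mtx` (MatrixMarket), `<prefix>.bins.bed` and
#' `<prefix>.tracks.tsv` (track name and uncapped fragment total).
#'
#' @param cm a `seg_counts`.
#' @param prefix output path prefix.
#' @export
write_counts <- function(cm, prefix) {
  stopifnot(inherits(cm, "seg_counts"))
  Matrix::writeMM(cm$counts, paste0(prefix, ".mtx"))
  write_bins_bed(cm$bins, paste0(prefix, ".bins.bed"))
  data.table::fwrite(
    data.frame(track = cm$tracks, total = cm$track_totals),
    paste0(prefix, ".tracks.tsv"), sep = "\t")
  invisible(prefix)
}

#' Load a count matrix written by [write_counts()]
#'
#' @param prefix path prefix used at write time.
#' @return a `seg_counts`.
#' @export
read_counts <- function(prefix) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  bins <- read_bins_bed(paste0(prefix, ".bins.bed"))
  tr <- data.table::fread(paste0(prefix, ".tracks.tsv"))
  colnames(m) <- tr$track
  new_seg_counts(m, bins, track_totals = tr$total)
}
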