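#' Genome-wide state frequencies
#'
#' Fraction of bins assigned to each state by the Viterbi path: the
#' state-frequency vector `b` used both to select rare foreground states and
#' as the genome-wide background of the cell-state association score.
#'
#' @param seg a [viterbi()] segmentation.
#' @return numeric vector of length `n_states` summing to 1.
#' @export
state_frequencies <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  tabulate(seg$state_call, nbins = seg$n_states) / length(seg$state_call)
}

#' Select rare foreground states
#'
#' States whose Viterbi calls cover at most `max_fraction` of the genome
#' (inclusive threshold) are considered informative foreground; broadly
#' covering states are background or ambiguous and are ignored downstream.
#'
#' @param seg a segmentation.
#' @param max_fraction genome-fraction ceiling, default 0.015.
#' @return integer vector of selected state indices (possibly empty, with a
#'   warning).
#' @export
select_foreground_states <- function(seg, max_fraction = 0.015) {
  b <- state_frequencies(seg)
  sel <- which(b <= max_fraction)
  if (length(sel) == 0)
    warning("no state covers <= ", max_fraction, " of the genome")
  sel
}

#' Extract high-confidence foreground regions
#'
#' Keeps bins whose called state is in `states` and whose posterior for the
#' called state is at least `min_posterior`, then merges bookended bins
#' (adjacent on the same chromosome, same state) into single intervals.
#' The interval posterior is the maximum over its member bins.
#'
#' @param seg a segmentation with posteriors.
#' @param states state indices to extract (e.g.
#'   [select_foreground_states()]).
#' @param min_posterior posterior floor, default 0.9 (inclusive).
#' @return a `data.frame` of class `region_set`: `chrom`, `start`, `end`,
#'   `state`, `max_posterior`, `score` (`round(1000 * max_posterior)`),
#'   sorted by genome position.
#' @export
extract_regions <- function(seg, states, min_posterior = 0.9) {
  stopifnot(inherits(seg, "segmentation"))
  tb <- bin_table(seg$bins)
  keep <- seg$state_call %in% states & seg$max_posterior >= min_posterior
  tb <- tb[keep, , drop = FALSE]
  st <- seg$state_call[keep]
  po <- seg$max_posterior[keep]
  if (nrow(tb) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = integer(),
                      max_posterior = numeric(), score = numeric())
    class(out) <- c("region_set", "data.frame")
    return(out)
  }
  # bins arrive in genome order; a new region starts wherever chromosome,
  # state, or adjacency breaks
  new_run <- c(TRUE, tb$chrom[-1] != tb$chrom[-nrow(tb)] |
                 st[-1] != st[-length(st)] |
                 tb$start[-1] != tb$end[-nrow(tb)])
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = tb$chrom[new_run],
    start = tb$start[new_run],
    end = as.numeric(tapply(tb$end, run, max)),
    state = st[new_run],
    max_posterior = as.numeric(tapply(po, run, max)))
  out$score <- round(1000 * out$max_posterior)
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

#' Write regions as BED6
#'
#' Name column `state_<k>`, score `round(1000 * posterior)`, strand `.`.
#'
#' @param regions a [extract_regions()] result.
#' @param path output BED file.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    name = sprintf("state_%d", regions$state),
                    score = regions$score,
                    strand = rep(".", nrow(regions)))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Cell-state association scores
#'
#' A bin is accessible in a cell when its count is positive.  For each cell
#' j, `a[i, j]` is the fraction of the cell's accessible bins called state
#' i; `b[i]` is the genome-wide state frequency.  The association
#' `log(a_ij / b_i)` is positive for states over-represented among the
#' cell's accessible bins.  Cells with no accessible bins yield an `NA`
#' column; `a_ij = 0` maps to an `NaN` log-ratio rather than `-Inf` so
#' heatmaps stay renderable.
#'
#' @param seg a segmentation.
#' @param cm the per-cell count matrix on the same bins.
#' @return list with `a` (states x cells), `b`, and `logratio`.
#' @export
cell_state_association <- function(seg, cm) {
  stopifnot(inherits(seg, "segmentation"), inherits(cm, "seg_counts"))
  if (nrow(cm$counts) != length(seg$state_call))
    stop("segmentation and counts cover different numbers of bins")
  K <- seg$n_states
  m <- methods::as(cm$counts, "TsparseMatrix")
  acc <- m@x > 0
  cell <- m@j[acc] + 1L
  st <- seg$state_call[m@i[acc] + 1L]
  a <- matrix(0, K, length(cm$tracks),
              dimnames = list(NULL, cm$tracks))
  tab <- table(factor(st, levels = seq_len(K)), factor(cell, levels = seq_along(cm$tracks)))
  a[] <- as.numeric(tab)
  n_acc <- colSums(a)
  empty <- n_acc == 0
  if (any(empty))
    warning(sum(empty), " cell(s) with zero accessible bins")
  a <- sweep(a, 2, pmax(n_acc, 1), "/")
  a[, empty] <- NA_real_
  b <- state_frequencies(seg)
  lr <- log(a / b)
  lr[!is.na(a) & a == 0] <- NaN
  list(a = a, b = b, logratio = lr)
}

#' Feature-identification pipeline
#'
#' Fits the per-cell Dirichlet-multinomial HMM (by default 50 states, up to
#' 300 iterations, 7 restarts), calls states by Viterbi, selects rare
#' foreground states and extracts high-confidence merged regions.
#'
#' @param cm a per-cell [count_matrix()] (1-kb bins, capped at 4, barcode
#'   filtered).
#' @param n_states,n_iter,n_restarts,seed model configuration.
#' @param max_fraction foreground genome-fraction ceiling.
#' @param min_posterior posterior floor for extracted regions.
#' @param ... passed to [baum_welch_fit()].
#' @return list with `model`, `segmentation`, `foreground_states`,
#'   `regions`.
#' @export
identify_features <- function(cm, n_states = 50, n_iter = 300,
                              n_restarts = 7, seed = 1,
                              max_fraction = 0.015, min_posterior = 0.9,
                              ...) {
  model <- fit_with_restarts(cm, n_states, n_restarts = n_restarts,
                             n_iter = n_iter, seed = seed, ...)
  seg <- viterbi(model, cm)
  fg <- select_foreground_states(seg, max_fraction)
  regions <- extract_regions(seg, fg, min_posterior)
  list(model = model, segmentation = seg, foreground_states = fg,
       regions = regions)
}
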