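#' Program-identification pipeline
#'
#' Segments cluster-collapsed pseudo-bulk accessibility tracks (typically
#' 500-bp bins) with the Dirichlet-multinomial HMM — by default 30 states,
#' up to 100 iterations, 7 restarts — and decodes the genome-wide state
#' calls that constitute the regulatory-program annotation.
#'
#' @param cluster_cm a pseudo-bulk [collapse_by_group()] matrix (tracks =
#'   clusters).
#' @param n_states,n_iter,n_restarts,seed model configuration.
#' @param ... passed to [baum_welch_fit()].
#' @return list with `model`, `segmentation` and the state-cluster
#'   `association` (see [state_cluster_association()]).
#' @export
segment_programs <- function(cluster_cm, n_states = 30, n_iter = 100,
                             n_restarts = 7, seed = 1, ...) {
  model <- fit_with_restarts(cluster_cm, n_states, n_restarts = n_restarts,
                             n_iter = n_iter, seed = seed, ...)
  seg <- viterbi(model, cluster_cm)
  assoc <- state_cluster_association(seg, cluster_cm)
  list(model = model, segmentation = seg, association = assoc)
}

#' State-cluster association scores
#'
#' Normalizes each state's read content by cluster depth: with
#' `reads(c, s)` the fragments from cluster c in bins called state s,
#' `Pcs[s, c] = reads(c, s) / reads(s)` is the state-specific coverage
#' profile (rows sum to 1) and `Pb[c] = reads(c) / total` the background
#' cluster coverage.  The association `log(Pcs / Pb)` is positive for
#' clusters over-contributing to a state; a regulatory program shared by
#' several cell types appears as several positive entries in a state's row.
#'
#' By default reads are tabulated over Viterbi-called bins, which makes the
#' score reproducible from the state-call BED plus the count matrix alone;
#' `use_expected = TRUE` weights bins by their posterior instead (the
#' expected sufficient statistics of the emission model).
#'
#' @param seg a segmentation of the pseudo-bulk matrix.
#' @param cluster_cm the pseudo-bulk count matrix on the same bins.
#' @param use_expected use posterior-weighted rather than hard-assigned
#'   counts.
#' @return list with `Pcs` (states x clusters), `Pb`, `logratio`; states
#'   with zero reads yield `NA` rows (flagged via a warning).
#' @export
state_cluster_association <- function(seg, cluster_cm,
                                      use_expected = FALSE) {
  stopifnot(inherits(seg, "segmentation"), inherits(cluster_cm, "seg_counts"))
  m <- cluster_cm$counts
  if (nrow(m) != length(seg$state_call))
    stop("segmentation and counts cover different numbers of bins")
  K <- seg$n_states
  if (use_expected) {
    reads <- as.matrix(Matrix::crossprod(seg$posterior, m))   # K x clusters
  } else {
    ind <- Matrix::sparseMatrix(i = seq_along(seg$state_call),
                                j = seg$state_call, x = 1,
                                dims = c(length(seg$state_call), K))
    reads <- as.matrix(Matrix::crossprod(ind, m))
  }
  colnames(reads) <- cluster_cm$tracks
  state_tot <- rowSums(reads)
  empty <- state_tot == 0
  if (any(empty))
    warning(sum(empty), " state(s) with zero reads")
  Pcs <- sweep(reads, 1, pmax(state_tot, 1), "/")
  Pcs[empty, ] <- NA_real_
  Pb <- colSums(reads) / sum(reads)
  lr <- log(sweep(Pcs, 2, Pb, "/"))
  lr[!is.na(Pcs) & Pcs == 0] <- NaN
  list(Pcs = Pcs, Pb = Pb, logratio = lr)
}
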