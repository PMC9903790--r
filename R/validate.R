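#' Match fitted states to ground-truth states
#'
#' Majority-vote matching: each fitted state is mapped to the true state it
#' most often co-occurs with along the bins (and vice versa on request).
#' Used to score parameter recovery on simulated data, where state labels
#' are arbitrary under the likelihood.
#'
#' @param fitted_path,true_path parallel per-bin state calls.
#' @param n_fitted,n_true numbers of states (default: observed maxima).
#' @return integer vector of length `n_fitted`: for each fitted state, the
#'   matched true state (`NA` for fitted states never called).
#' @export
match_states <- function(fitted_path, true_path,
                         n_fitted = max(fitted_path),
                         n_true = max(true_path)) {
  tab <- table(factor(fitted_path, levels = seq_len(n_fitted)),
               factor(true_path, levels = seq_len(n_true)))
  m <- apply(tab, 1, function(r) if (sum(r) == 0) NA_integer_ else which.max(r))
  as.integer(m)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions, corrected for
#' chance: 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b parallel label vectors.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Emission mean profiles of a fitted model
#'
#' The Dirichlet-multinomial's expected allocation of a bin's fragments
#' across tracks is the normalized concentration vector; one row per state.
#'
#' @param alpha states x tracks concentration matrix.
#' @return row-normalized matrix.
#' @export
emission_profiles <- function(alpha) {
  sweep(alpha, 1, rowSums(alpha), "/")
}

#' Total-variation distance between two probability vectors
#'
#' @param p,q probability vectors of equal length.
#' @return `0.5 * sum(|p - q|)`, in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  0.5 * sum(abs(p - q))
}

#' Score parameter recovery of a fit against simulation ground truth
#'
#' @param seg fitted [viterbi()] segmentation.
#' @param model fitted [hmm_params()].
#' @param truth `truth` element of a [simulate_dataset()] result.
#' @return list with `ari` (adjusted Rand index of the matched state
#'   paths), `mean_tv` (mean total-variation distance between matched
#'   emission mean profiles, averaged over true states) and the `matching`.
#' @export
recovery_score <- function(seg, model, truth) {
  K_true <- nrow(truth$alpha)
  matching <- match_states(seg$state_call, truth$path,
                           n_fitted = model$n_states, n_true = K_true)
  ari <- adjusted_rand_index(seg$state_call, truth$path)
  prof_fit <- emission_profiles(model$alpha)
  prof_true <- emission_profiles(truth$alpha)
  # for each true state, the best-covering fitted state's profile
  rev_match <- match_states(truth$path, seg$state_call,
                            n_fitted = K_true, n_true = model$n_states)
  tv <- vapply(seq_len(K_true), function(s) {
    f <- rev_match[s]
    if (is.na(f)) return(NA_real_)
    total_variation(prof_true[s, ], prof_fit[f, ])
  }, numeric(1))
  list(ari = ari, mean_tv = mean(tv, na.rm = TRUE), matching = matching)
}
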