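#' Dirichlet-multinomial log probability mass
#'
#' Log pmf of a count vector `x` over tracks under a Dirichlet-multinomial
#' with concentration `alpha`, conditioned on the total `n = sum(x)`:
#' `log [ C(n; x) * Gamma(A)/Gamma(n + A) * prod_c Gamma(x_c + a_c)/Gamma(a_c) ]`
#' with `A = sum(alpha)`.  Everything is computed through `lgamma`, so the
#' result is finite for any valid input; `x = 0` gives log(1) = 0 for every
#' state, which is how empty bins inherit their state from genomic context
#' through the transition structure.
#'
#' @param alpha positive concentration vector, one entry per track.
#' @param x non-negative integer counts, same length as `alpha`.
#' @return the log probability (scalar).
#' @export
dm_logpmf <- function(alpha, x) {
  if (any(alpha <= 0)) stop("all concentration parameters must be > 0")
  if (length(alpha) != length(x)) stop("alpha and x length mismatch")
  if (any(x < 0) || any(x != floor(x))) stop("x must be non-negative integers")
  n <- sum(x)
  A <- sum(alpha)
  lgamma(n + 1) - sum(lgamma(x + 1)) +
    lgamma(A) - lgamma(n + A) +
    sum(lgamma(x + alpha) - lgamma(alpha))
}

# Per-bin, per-state DM log-likelihood matrix (bins x states) from a sparse
# count matrix.  Zero entries contribute nothing to the x-dependent terms
# (lgamma(a) - lgamma(a) = 0, lgamma(1) = 0), so only the non-zero triplets
# are touched: cost O(nnz * n_states).  Inner loops in C++.
emission_loglik <- function(alpha, cm_counts, bin_totals = NULL) {
  m <- methods::as(cm_counts, "TsparseMatrix")
  if (ncol(alpha) != ncol(m))
    stop("alpha has ", ncol(alpha), " tracks but counts have ", ncol(m))
  if (any(alpha <= 0)) stop("all concentration parameters must be > 0")
  if (is.null(bin_totals)) bin_totals <- Matrix::rowSums(m)
  emission_loglik_cpp(alpha, m@i, m@j, m@x, bin_totals, nrow(m))
}

# sum `v` by integer group `g` into a dense length-n vector
rowsum_vec <- function(v, g, n) {
  out <- numeric(n)
  rs <- rowsum(v, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}
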