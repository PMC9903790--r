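#' Construct / validate HMM parameters
#'
#' A Dirichlet-multinomial HMM is parameterized by one positive
#' concentration vector per state (over tracks), a row-stochastic transition
#' matrix and an initial state distribution.  Each chromosome is treated as
#' an independent observation sequence sharing these parameters; transitions
#' never span chromosome boundaries.
#'
#' @param alpha numeric matrix, states x tracks, all entries > 0.
#' @param transition row-stochastic states x states matrix.
#' @param initial probability vector over states.
#' @param seed integer recorded for provenance.
#' @param meta optional list of fit metadata (loglik trace, iterations).
#' @return an object of class `seg_hmm`.
#' @export
hmm_params <- function(alpha, transition, initial, seed = NA_integer_,
                       meta = list()) {
  alpha <- as.matrix(alpha)
  transition <- as.matrix(transition)
  K <- nrow(alpha)
  stopifnot(nrow(transition) == K, ncol(transition) == K,
            length(initial) == K)
  if (any(alpha <= 0)) stop("all alpha must be > 0")
  if (any(abs(rowSums(transition) - 1) > 1e-10))
    stop("transition rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-10)
    stop("initial must sum to 1")
  structure(list(n_states = K, alpha = alpha, transition = transition,
                 initial = as.numeric(initial), seed = seed, meta = meta),
            class = "seg_hmm")
}

#' @export
print.seg_hmm <- function(x, ...) {
  cat(sprintf("seg_hmm: %d states over %d tracks", x$n_states, ncol(x$alpha)))
  if (!is.null(x$meta$loglik))
    cat(sprintf(", loglik %.2f after %d iteration(s)",
                x$meta$loglik, x$meta$iterations))
  cat("\n")
  invisible(x)
}

# index ranges of each chromosome's bins (independent HMM sequences)
chrom_sequences <- function(bins) {
  nb <- as.integer(ceiling(bins$chrom_sizes / bins$binsize))
  ends <- cumsum(nb)
  starts <- ends - nb + 1L
  Map(function(s, e) s:e, starts, ends)
}

resolve_counts <- function(cm) {
  if (inherits(cm, "seg_counts")) cm$counts else cm
}

#' Forward-backward posterior decoding
#'
#' Runs the scaled forward-backward recursion independently on every
#' chromosome (each re-initialized from the model's initial distribution)
#' and returns per-bin state posteriors together with the expected
#' sufficient statistics used by the Baum-Welch M-step.
#'
#' @param params a [hmm_params()] model.
#' @param cm a [count_matrix()] whose tracks match the model's alpha columns.
#' @return a list with `posterior` (bins x states; rows sum to 1), `loglik`
#'   (total over chromosomes), `trans_counts` (expected transition counts),
#'   `init_counts` (expected start-state counts) and `E` (per-bin emission
#'   log-likelihoods).
#' @export
forward_backward <- function(params, cm) {
  stopifnot(inherits(params, "seg_hmm"), inherits(cm, "seg_counts"))
  E <- emission_loglik(params$alpha, cm$counts, cm$bin_totals)
  fb_from_loglik(E, params$transition, params$initial,
                 chrom_sequences(cm$bins))
}

fb_from_loglik <- function(E, A, init, seqs) {
  K <- ncol(E)
  B <- nrow(E)
  gamma <- matrix(0, B, K)
  trans_counts <- matrix(0, K, K)
  init_counts <- numeric(K)
  loglik <- 0
  for (idx in seqs) {
    res <- fb_seq_cpp(E[idx, , drop = FALSE], A, init)
    if (!is.finite(res$loglik)) stop("non-finite log-likelihood on sequence")
    loglik <- loglik + res$loglik
    gamma[idx, ] <- res$gamma
    trans_counts <- trans_counts + res$trans_counts
    init_counts <- init_counts + res$gamma[1, ]
  }
  list(posterior = gamma, loglik = loglik,
       trans_counts = trans_counts, init_counts = init_counts, E = E)
}

#' Viterbi state calling
#'
#' Most probable state path per chromosome under the fitted model.  Ties in
#' the backtracking are broken deterministically toward the lowest state
#' index.
#'
#' @inheritParams forward_backward
#' @return an object of class `segmentation`: per-bin `state_call` (1-based
#'   state index), per-bin `posterior` matrix, per-bin `max_posterior`,
#'   total forward `loglik` and the `bin_index`.
#' @export
viterbi <- function(params, cm) {
  stopifnot(inherits(params, "seg_hmm"), inherits(cm, "seg_counts"))
  fb <- forward_backward(params, cm)
  path <- viterbi_from_loglik(fb$E, params$transition, params$initial,
                              chrom_sequences(cm$bins))
  structure(list(state_call = path,
                 posterior = fb$posterior,
                 max_posterior = fb$posterior[cbind(seq_along(path), path)],
                 loglik = fb$loglik,
                 n_states = params$n_states,
                 bins = cm$bins),
            class = "segmentation")
}

viterbi_from_loglik <- function(E, A, init, seqs) {
  logA <- log(A)
  loginit <- log(init)
  path <- integer(nrow(E))
  for (idx in seqs)
    path[idx] <- viterbi_seq_cpp(E[idx, , drop = FALSE], logA, loginit)
  path
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d bins, %d states, loglik %.2f\n",
              length(x$state_call), x$n_states, x$loglik))
  invisible(x)
}

#' Fit the Dirichlet-multinomial HMM by Baum-Welch
#'
#' Expectation-maximization from a random initialization: the E-step is the
#' forward-backward recursion; the M-step re-estimates transition and
#' initial probabilities from expected counts and updates each state's
#' concentration vector by a fixed-point iteration on the posterior-weighted
#' counts (a moment-matching update is available as a fallback).  The
#' log-likelihood trace is non-decreasing up to numerical tolerance.
#'
#' @param cm a [count_matrix()].
#' @param n_states number of states.
#' @param n_iter maximum EM iterations (upper bound; fitting stops early
#'   when the relative log-likelihood improvement falls below `tol`).
#' @param seed integer seed fully determining the initialization.
#' @param tol relative convergence tolerance on the log-likelihood.
#' @param em_alpha `"fixedpoint"` (default) or `"moments"` concentration
#'   update.
#' @param alpha_inner inner fixed-point iterations per M-step.
#' @param verbose print the log-likelihood every iteration.
#' @return a fitted [hmm_params()] with `meta$loglik_trace`.
#' @export
baum_welch_fit <- function(cm, n_states, n_iter = 100, seed = 1,
                           tol = 1e-6, em_alpha = c("fixedpoint", "moments"),
                           alpha_inner = 5, verbose = FALSE) {
  stopifnot(inherits(cm, "seg_counts"), n_states >= 1, n_iter >= 1)
  em_alpha <- match.arg(em_alpha)
  params <- init_params(cm, n_states, seed)
  seqs <- chrom_sequences(cm$bins)
  m <- methods::as(cm$counts, "TsparseMatrix")
  trip <- list(i = m@i + 1L, j = m@j + 1L, x = m@x)
  trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(n_iter)) {
    E <- emission_loglik(params$alpha, cm$counts, cm$bin_totals)
    fb <- fb_from_loglik(E, params$transition, params$initial, seqs)
    trace <- c(trace, fb$loglik)
    if (verbose)
      message(sprintf("iter %d: loglik %.4f", it, fb$loglik))
    # M-step
    occupancy <- colSums(fb$posterior)
    degenerate <- occupancy < 1e-8
    if (any(degenerate)) {
      warning("reinitializing ", sum(degenerate),
              " degenerate state(s) from perturbed global profile")
      params$alpha[degenerate, ] <-
        perturbed_global_alpha(cm, sum(degenerate), seed + 7919L * it)
    }
    tc <- fb$trans_counts
    rs <- rowSums(tc)
    newA <- params$transition
    ok <- rs > 0
    newA[ok, ] <- tc[ok, ] / rs[ok]
    params$transition <- newA
    params$initial <- fb$init_counts / sum(fb$init_counts)
    live <- which(!degenerate)
    params$alpha[live, ] <- update_alpha(
      params$alpha[live, , drop = FALSE],
      fb$posterior[, live, drop = FALSE],
      trip, cm$bin_totals, em_alpha, alpha_inner)
    if (is.finite(ll_prev) &&
        (fb$loglik - ll_prev) < tol * abs(fb$loglik) && !any(degenerate)) {
      ll_prev <- fb$loglik
      break
    }
    ll_prev <- fb$loglik
  }
  params$meta <- list(loglik = ll_prev, loglik_trace = trace,
                      iterations = length(trace), em_alpha = em_alpha)
  params$seed <- seed
  params
}

# alpha init: Gamma-perturbed global track profile; sticky near-uniform
# transitions; uniform initial distribution
init_params <- function(cm, n_states, seed, sticky = 0.9) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  alpha <- perturbed_global_alpha(cm, n_states, NULL)
  if (n_states > 1) {
    A <- matrix((1 - sticky) / (n_states - 1), n_states, n_states)
    diag(A) <- sticky
  } else {
    A <- matrix(1, 1, 1)
  }
  hmm_params(alpha, A, rep(1 / n_states, n_states), seed = seed)
}

# Weak total concentration (conc = 0.2 per track on average) keeps the
# initial emissions overdispersed, so early EM breaks symmetry on which
# tracks a bin hits rather than on the transition structure; this is what
# lets rare concentrated states be discovered at all.
perturbed_global_alpha <- function(cm, n_rows, seed = NULL, conc = 0.2) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  C <- ncol(cm$counts)
  p <- Matrix::colSums(cm$counts)
  p <- (p + 1e-3) / sum(p + 1e-3)
  g <- matrix(stats::rgamma(n_rows * C, shape = 5, rate = 5), n_rows, C)
  pmax(conc * C * g * rep(p, each = n_rows), 1e-6)
}

# Concentration M-step.  "fixedpoint": Minka-style bound-based update on the
# posterior-weighted Polya likelihood,
#   a_c <- a_c * sum_i w_i (psi(x_ic + a_c) - psi(a_c))
#             / sum_i w_i (psi(n_i + A) - psi(A)),
# monotone in the EM surrogate objective.  "moments": posterior-weighted
# mean proportions scaled by the previous total concentration.
update_alpha <- function(alpha, gamma, trip, bin_totals, method, inner) {
  K <- nrow(alpha)
  C <- ncol(alpha)
  for (s in seq_len(K)) {
    w <- gamma[, s]
    wtot <- sum(w * bin_totals)
    if (wtot <= 0) next   # state sits only on empty bins; leave alpha as is
    if (method == "moments") {
      num <- rowsum_vec(w[trip$i] * trip$x, trip$j, C)
      p <- (num + 1e-6) / sum(num + 1e-6)
      alpha[s, ] <- pmax(sum(alpha[s, ]) * p, 1e-6)
      next
    }
    alpha[s, ] <- alpha_fixed_point_cpp(alpha[s, ], w,
                                        trip$i - 1L, trip$j - 1L, trip$x,
                                        bin_totals, inner, 1e-6)
  }
  alpha
}

#' Fit with random restarts
#'
#' Repeats [baum_welch_fit()] from different random initializations (seeds
#' derived deterministically from `seed`) and keeps the model with the best
#' final log-likelihood; seven restarts are the usual configuration.
#'
#' @inheritParams baum_welch_fit
#' @param n_restarts number of independent fits.
#' @return the best fitted model; `meta$restart_logliks` records every
#'   restart's final log-likelihood.
#' @export
fit_with_restarts <- function(cm, n_states, n_restarts = 7, n_iter = 100,
                              seed = 1, ...) {
  stopifnot(n_restarts >= 1)
  seeds <- as.integer(seed) + seq_len(n_restarts) - 1L
  fits <- lapply(seeds, function(s)
    baum_welch_fit(cm, n_states, n_iter = n_iter, seed = s, ...))
  lls <- vapply(fits, function(f) f$meta$loglik, numeric(1))
  best <- fits[[which.max(lls)]]
  best$meta$restart_logliks <- lls
  best
}

#' Stationary distribution of the transition matrix
#'
#' Principal left eigenvector of the transition matrix, normalized to sum 1:
#' the long-run fraction of the genome each state occupies, and the basis of
#' the expected state counts `e_i = N * p_i` in enrichment scoring.
#'
#' @param transition row-stochastic matrix.
#' @return probability vector `p` with `p %*% transition == p`.
#' @export
stationary_distribution <- function(transition) {
  transition <- as.matrix(transition)
  K <- nrow(transition)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition matrix must be row-stochastic")
  if (K == 1) return(1)
  ev <- eigen(t(transition))
  near1 <- which(abs(ev$values - 1) < 1e-9)
  if (length(near1) > 1) {
    warning("stationary distribution not unique; returning uniform")
    return(rep(1 / K, K))
  }
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  p <- v / sum(v)
  if (any(p < -1e-8) || max(abs(as.numeric(p %*% transition) - p)) > 1e-8) {
    # fall back to power iteration
    p <- rep(1 / K, K)
    for (i in seq_len(100000)) {
      p2 <- as.numeric(p %*% transition)
      if (max(abs(p2 - p)) < 1e-14) { p <- p2; break }
      p <- p2
    }
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Save a fitted model
#'
#' JSON container for scalars, transition and initial vectors, plus a TSV of
#' concentration vectors; [read_hmm()] round-trips exactly.
#'
#' @param params a `seg_hmm`.
#' @param prefix output path prefix (`<prefix>.json`, `<prefix>.alpha.tsv`).
#' @export
write_hmm <- function(params, prefix) {
  stopifnot(inherits(params, "seg_hmm"))
  jsonlite::write_json(
    list(n_states = params$n_states,
         transition = params$transition,
         initial = params$initial,
         seed = params$seed,
         meta = params$meta["loglik"]),
    paste0(prefix, ".json"), digits = NA, auto_unbox = TRUE)
  utils::write.table(format(params$alpha, digits = 17),
                     paste0(prefix, ".alpha.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(prefix)
}

#' Load a model written by [write_hmm()]
#' @param prefix path prefix used at write time.
#' @return a `seg_hmm`.
#' @export
read_hmm <- function(prefix) {
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  alpha <- as.matrix(utils::read.table(paste0(prefix, ".alpha.tsv"),
                                       sep = "\t"))
  dimnames(alpha) <- NULL
  hmm_params(alpha, js$transition, js$initial,
             seed = if (is.null(js$seed)) NA_integer_ else js$seed,
             meta = as.list(js$meta))
}
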