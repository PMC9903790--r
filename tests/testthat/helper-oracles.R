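# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the Polya pmf is evaluated by plain products
# (no lgamma), and HMM quantities by exhaustive enumeration of all state
# paths.

# Dirichlet-multinomial pmf as a Polya urn product:
#   n! / prod(x!) * prod_c a_c (a_c+1)...(a_c+x_c-1) / [A (A+1)...(A+n-1)]
oracle_dm_pmf <- function(alpha, x) {
  n <- sum(x)
  A <- sum(alpha)
  rising <- function(a, k) if (k == 0) 1 else prod(a + 0:(k - 1))
  coef <- factorial(n) / prod(factorial(x))
  coef * prod(mapply(rising, alpha, x)) / rising(A, n)
}

# all K^T state paths as a matrix (rows = paths)
all_paths <- function(K, T) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T)))
}

# exhaustive forward-backward: joint probability of every path given
# per-bin emission log-likelihoods E (T x K), transition A, initial init
oracle_decode <- function(E, A, init) {
  T_ <- nrow(E)
  K <- ncol(E)
  paths <- all_paths(K, T_)
  logp <- log(init[paths[, 1]]) + E[cbind(1L, paths[, 1])]
  if (T_ > 1) {
    for (t in 2:T_) {
      logp <- logp + log(A[cbind(paths[, t - 1], paths[, t])]) +
        E[cbind(t, paths[, t])]
    }
  }
  m <- max(logp)
  w <- exp(logp - m)
  Z <- sum(w)
  post <- matrix(0, T_, K)
  for (t in seq_len(T_))
    for (k in seq_len(K))
      post[t, k] <- sum(w[paths[, t] == k]) / Z
  list(posterior = post,
       loglik = log(Z) + m,
       map_path = paths[which.max(logp), ])
}

# a random small DM-HMM instance with a count matrix over a single
# chromosome of T_ bins
random_instance <- function(K, T_, C, seed) {
  set.seed(seed)
  alpha <- matrix(runif(K * C, 0.2, 3), K, C)
  A <- matrix(runif(K * K, 0.1, 1), K, K)
  A <- A / rowSums(A)
  init <- runif(K, 0.1, 1)
  init <- init / sum(init)
  counts <- matrix(rpois(T_ * C, 1.2), T_, C)
  bins <- make_bins(c(chrT = T_ * 100), 100)
  cm <- segatac:::new_seg_counts(
    Matrix::Matrix(counts, sparse = TRUE,
                   dimnames = list(NULL, sprintf("t%d", seq_len(C)))),
    bins)
  params <- hmm_params(alpha, A, init)
  list(params = params, cm = cm, counts = counts)
}

# small deterministic simulation configs used by several test files;
# reduced problem sizes keep a full Baum-Welch fit around a second
small_recovery_cfg <- function(seed) {
  sim_config(n_chroms = 2, chrom_length = 4e5, binsize = 1000,
             n_states = 3, n_cells = 60, seed = seed)
}

# one rare cluster-specific state spiked in at exactly 1% of bins
# (single-bin CRE-scale sites) over a constitutive and a sporadic
# background, the planted-foreground benchmark
foreground_cfg <- function(seed) {
  sim_config(n_chroms = 2, chrom_length = 2e6, binsize = 1000,
             n_states = 3,
             state_frac = c(0.59, 0.40, 0.01),
             stickiness = c(0.95, 0.95, 0),
             state_cluster_access = list(1:4, integer(0), 1),
             depth_mean = c(15, 4, 50),
             n_cells = 60, n_clusters = 4,
             spike_states = 3, seed = seed)
}

# reduced fi fit used against foreground_cfg data
run_fi <- function(sim, seed) {
  cm <- count_matrix(sim$fragments, sim$bins, cap = 4)
  suppressWarnings(
    identify_features(cm, n_states = 3, n_iter = 100, n_restarts = 5,
                      seed = seed))
}

# two planted programs: one accessible in clusters 1-2, one in cluster 3
program_cfg <- function(seed) {
  sim_config(n_chroms = 2, chrom_length = 5e5, binsize = 500,
             n_states = 3,
             state_frac = c(0.6, 0.2, 0.2),
             state_cluster_access = list(1:4, 1:2, 3),
             depth_mean = c(15, 50, 50),
             n_cells = 120, n_clusters = 4, seed = seed)
}
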