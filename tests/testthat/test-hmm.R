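test_that("dm_logpmf matches the closed-form Polya evaluation", {
  # one category: any count has probability 1
  expect_equal(dm_logpmf(2.5, 7), 0)
  expect_equal(dm_logpmf(0.3, 0), 0)
  # symmetric two-category case is forced to 1/2
  expect_equal(dm_logpmf(c(1, 1), c(1, 0)), log(1 / 2))
  expect_equal(dm_logpmf(c(1, 1), c(1, 0)), dm_logpmf(c(1, 1), c(0, 1)))
  # alpha = (2, 1), x = (1, 1): 2 * [2 * 1] / [3 * 4] = 1/3
  expect_equal(dm_logpmf(c(2, 1), c(1, 1)), log(oracle_dm_pmf(c(2, 1), c(1, 1))))
  expect_equal(exp(dm_logpmf(c(2, 1), c(1, 1))), 1 / 3)
  # random cases against the urn-product oracle
  set.seed(7)
  for (r in 1:20) {
    a <- runif(sample(2:5, 1), 0.1, 4)
    x <- rpois(length(a), 2)
    expect_equal(dm_logpmf(a, x), log(oracle_dm_pmf(a, x)), tolerance = 1e-10)
  }
  expect_error(dm_logpmf(c(1, 0), c(0, 0)), "> 0")
  expect_error(dm_logpmf(c(1, 1), c(-1, 1)), "non-negative")
})

test_that("dm pmf sums to 1 over all count vectors with a fixed total", {
  a <- c(0.7, 1.3, 2.1)
  for (n in c(1, 3, 5)) {
    xs <- expand.grid(0:n, 0:n, 0:n)
    xs <- xs[rowSums(xs) == n, ]
    tot <- sum(apply(xs, 1, function(x) exp(dm_logpmf(a, as.numeric(x)))))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("single-state decoding is trivial", {
  inst <- random_instance(1, 6, 3, seed = 21)
  fb <- forward_backward(inst$params, inst$cm)
  expect_equal(as.numeric(fb$posterior), rep(1, 6))
  ll_direct <- sum(vapply(seq_len(6), function(i)
    dm_logpmf(inst$params$alpha[1, ], inst$counts[i, ]), numeric(1)))
  expect_equal(fb$loglik, ll_direct)
  seg <- viterbi(inst$params, inst$cm)
  expect_equal(seg$state_call, rep(1L, 6))
})

test_that("posteriors, loglik and Viterbi match exhaustive enumeration", {
  inst <- random_instance(2, 3, 2, seed = 5)
  E <- segatac:::emission_loglik(inst$params$alpha, inst$cm$counts)
  oracle <- oracle_decode(E, inst$params$transition, inst$params$initial)
  fb <- forward_backward(inst$params, inst$cm)
  expect_equal(fb$posterior, oracle$posterior, tolerance = 1e-10)
  expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
  seg <- viterbi(inst$params, inst$cm)
  expect_equal(seg$state_call, as.integer(oracle$map_path))

  for (seed in 1:25) {
    set.seed(seed + 1000)
    K <- sample(2:4, 1); T_ <- sample(2:8, 1); C <- sample(2:5, 1)
    inst <- random_instance(K, T_, C, seed = seed)
    E <- segatac:::emission_loglik(inst$params$alpha, inst$cm$counts)
    oracle <- oracle_decode(E, inst$params$transition, inst$params$initial)
    fb <- forward_backward(inst$params, inst$cm)
    expect_equal(fb$posterior, oracle$posterior, tolerance = 1e-8)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-8)
    expect_equal(viterbi(inst$params, inst$cm)$state_call,
                 as.integer(oracle$map_path))
  }
})

test_that("posteriors sum to one per bin", {
  inst <- random_instance(4, 8, 5, seed = 33)
  fb <- forward_backward(inst$params, inst$cm)
  expect_equal(rowSums(fb$posterior), rep(1, 8), tolerance = 1e-8)
})

test_that("total loglik is invariant to chromosome order", {
  sim <- simulate_dataset(sim_config(n_chroms = 3, chrom_length = 3e4,
                                     n_cells = 8, n_clusters = 2,
                                     state_cluster_access = list(1:2, 1, 2),
                                     seed = 4))
  cm <- count_matrix(sim$fragments, sim$bins)
  params <- segatac:::init_params(cm, 2, seed = 1)
  ll1 <- forward_backward(params, cm)$loglik
  # rebuild with chromosomes permuted
  sizes <- sim$chrom_sizes[c(3, 1, 2)]
  bins2 <- make_bins(sizes, sim$bins$binsize)
  cm2 <- count_matrix(sim$fragments, bins2)
  ll2 <- forward_backward(params, cm2)$loglik
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("viterbi breaks ties toward the lowest state index", {
  # two identical states, symmetric transitions: every path has equal
  # probability, so the call must be state 1 everywhere
  alpha <- rbind(c(1, 1), c(1, 1))
  A <- matrix(0.5, 2, 2)
  params <- hmm_params(alpha, A, c(0.5, 0.5))
  inst <- random_instance(2, 5, 2, seed = 2)
  seg <- viterbi(params, inst$cm)
  expect_equal(seg$state_call, rep(1L, 5))
})

test_that("Baum-Welch loglik trace is non-decreasing", {
  sim <- simulate_dataset(small_recovery_cfg(seed = 2))
  cm <- count_matrix(sim$fragments, sim$bins, cap = 4)
  for (method in c("fixedpoint", "moments")) {
    fit <- baum_welch_fit(cm, 3, n_iter = 20, seed = 3, em_alpha = method)
    tr <- fit$meta$loglik_trace
    expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])),
                info = method)
  }
})

test_that("a single-state fit recovers the pooled track profile", {
  sim <- simulate_dataset(sim_config(n_chroms = 1, chrom_length = 3e5,
                                     n_states = 1, state_frac = 1,
                                     state_cluster_access = list(1:2),
                                     depth_mean = 30, n_cells = 10,
                                     n_clusters = 2, seed = 8))
  cm <- count_matrix(sim$fragments, sim$bins)
  fit <- baum_welch_fit(cm, 1, n_iter = 30, seed = 2)
  prof <- emission_profiles(fit$alpha)[1, ]
  pooled <- Matrix::colSums(cm$counts) / sum(cm$counts)
  expect_lt(total_variation(prof, pooled), 0.02)
})

test_that("permuting state labels leaves the likelihood unchanged", {
  sim <- simulate_dataset(small_recovery_cfg(seed = 5))
  cm <- count_matrix(sim$fragments, sim$bins, cap = 4)
  fit <- baum_welch_fit(cm, 3, n_iter = 5, seed = 1)
  perm <- c(3, 1, 2)
  permuted <- hmm_params(fit$alpha[perm, ],
                         fit$transition[perm, perm],
                         fit$initial[perm])
  ll1 <- forward_backward(fit, cm)$loglik
  ll2 <- forward_backward(permuted, cm)$loglik
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("restarts return the best-scoring model deterministically", {
  sim <- simulate_dataset(small_recovery_cfg(seed = 6))
  cm <- count_matrix(sim$fragments, sim$bins, cap = 4)
  one <- fit_with_restarts(cm, 2, n_restarts = 1, n_iter = 5, seed = 11)
  direct <- baum_welch_fit(cm, 2, n_iter = 5, seed = 11)
  expect_equal(one$alpha, direct$alpha)
  expect_equal(one$meta$loglik, direct$meta$loglik)
  multi <- fit_with_restarts(cm, 2, n_restarts = 3, n_iter = 5, seed = 11)
  expect_equal(multi$meta$loglik, max(multi$meta$restart_logliks))
  multi2 <- fit_with_restarts(cm, 2, n_restarts = 3, n_iter = 5, seed = 11)
  expect_identical(multi$alpha, multi2$alpha)
})

test_that("stationary_distribution solves p = p A", {
  expect_equal(stationary_distribution(matrix(0.25, 4, 4)), rep(0.25, 4))
  # closed form for a 2-state chain, checked against power iteration
  a <- 0.3; b <- 0.1
  A <- rbind(c(1 - a, a), c(b, 1 - b))
  p <- stationary_distribution(A)
  expect_equal(p, c(b / (a + b), a / (a + b)), tolerance = 1e-10)
  pow <- c(0.5, 0.5)
  for (i in 1:2000) pow <- as.numeric(pow %*% A)
  expect_equal(p, pow, tolerance = 1e-10)
  expect_warning(pi_id <- stationary_distribution(diag(3)), "not unique")
  expect_equal(pi_id, rep(1 / 3, 3))
  expect_error(stationary_distribution(matrix(1, 2, 2)), "stochastic")
})

test_that("models round-trip through disk exactly", {
  sim <- simulate_dataset(small_recovery_cfg(seed = 3))
  cm <- count_matrix(sim$fragments, sim$bins, cap = 4)
  fit <- baum_welch_fit(cm, 2, n_iter = 3, seed = 5)
  prefix <- tempfile()
  write_hmm(fit, prefix)
  back <- read_hmm(prefix)
  expect_equal(back$alpha, fit$alpha)
  expect_equal(back$transition, fit$transition, tolerance = 1e-15)
  expect_equal(back$initial, fit$initial, tolerance = 1e-15)
})
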