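#' Simulation configuration
#'
#' Describes a synthetic single-cell accessibility experiment with known
#' ground truth: a hidden state path over genome bins drawn from a sticky
#' Markov chain with a chosen long-run state occupancy, per-state
#' Dirichlet-multinomial allocation of each bin's fragments across cells,
#' cluster-structured cells, and state-dependent sequencing depth
#' (accessible states carry more fragments per bin than background, as
#' observed for informative regions in real data).
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param binsize bin width in bp.
#' @param n_states number of hidden states.
#' @param stickiness per-state self-transition probability `d_s` (scalar
#'   recycled).  The chain is `A[s, ] = d_s * e_s + (1 - d_s) * re_entry`
#'   with `re_entry[t]` proportional to `state_frac[t] * (1 - d_t)`, which
#'   makes the stationary distribution exactly `state_frac` while letting
#'   run lengths differ by state — short CRE-scale runs for rare accessible
#'   states, long domains for background.
#' @param state_frac long-run genome fraction of each state (sums to 1).
#' @param n_cells,n_clusters cells and their (balanced) cluster structure.
#' @param state_cluster_access list of length `n_states` giving, per state,
#'   the cluster indices in which the state is accessible.
#' @param depth_mean per-state Poisson mean of fragments per bin.
#' @param alpha_on,alpha_off per-cell Dirichlet concentration for cells in
#'   accessible vs inaccessible clusters (1 vs 0.05 by default, i.e.
#'   overdispersed allocation concentrated in the accessible clusters).
#' @param fragment_length fixed fragment length in bp (only midpoints
#'   matter downstream).
#' @param spike_states optional integer vector of states planted at
#'   exactly `round(state_frac * n_bins)` single-bin sites placed uniformly
#'   at random (spike-in planting).  The remaining states follow the
#'   Markov chain over the rest of the genome.  Use this when a benchmark
#'   calls for a state planted at a stated genome fraction: under the
#'   chain, a rare state's realized occupancy is binomial-noisy across
#'   seeds, which turns recovery benchmarks into occupancy lotteries.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 1e6, binsize = 1000,
                       n_states = 3, stickiness = 0.95,
                       state_frac = c(0.6, 0.2, 0.2),
                       n_cells = 200, n_clusters = 4,
                       state_cluster_access = list(1:4, 1:2, 3:4),
                       depth_mean = c(15, 50, 50),
                       alpha_on = 1, alpha_off = 0.05,
                       fragment_length = 150, spike_states = NULL,
                       seed = 1) {
  stickiness <- rep_len(stickiness, n_states)
  stopifnot(n_states >= 1, length(state_frac) == n_states,
            abs(sum(state_frac) - 1) < 1e-8, all(state_frac > 0),
            all(stickiness >= 0), all(stickiness <= 1),
            length(state_cluster_access) == n_states,
            length(depth_mean) == n_states, all(depth_mean >= 0),
            alpha_on > 0, alpha_off > 0,
            n_clusters >= 1, n_cells >= n_clusters,
            fragment_length %% 2 == 0, binsize > fragment_length / 2,
            all(spike_states %in% seq_len(n_states)),
            length(spike_states) < n_states)
  structure(as.list(environment()), class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  repeat {
    g <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(g) > 0) return(g / sum(g))
  }
}

#' Simulate a single-cell fragment dataset with ground truth
#'
#' Draws the hidden state path, per-bin fragment totals
#' (`Poisson(depth_mean[state])`), allocates fragments across cells by the
#' state's Dirichlet-multinomial, and materializes fragments of fixed
#' length with midpoints uniform inside their bin.  Fully reproducible from
#' the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, writes `fragments.tsv.gz`,
#'   `chrom_sizes.tsv` and `cluster_labels.tsv`.
#' @return a list with `fragments` (a [fragment_set()]), `chrom_sizes`,
#'   `bins`, `labels` (barcode -> cluster name), and `truth` (state path,
#'   true per-state concentration over cells, cluster assignment, config).
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- cfg$n_states
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  bins <- make_bins(chrom_sizes, cfg$binsize)
  barcodes <- sprintf("cell_%04d", seq_len(cfg$n_cells))
  cluster_of <- rep_len(seq_len(cfg$n_clusters), cfg$n_cells)
  labels <- stats::setNames(sprintf("c%d", cluster_of), barcodes)
  # true per-state concentration over cells
  alpha <- matrix(cfg$alpha_off, K, cfg$n_cells)
  for (s in seq_len(K))
    alpha[s, cluster_of %in% cfg$state_cluster_access[[s]]] <- cfg$alpha_on
  # sticky Markov chain with stationary state_frac and state-specific
  # run lengths: re-entry weights f_t (1 - d_t) keep the long-run
  # occupancy at state_frac for any stickiness vector; spike states are
  # excluded from the chain and planted afterwards at their exact fraction
  chain <- setdiff(seq_len(K), cfg$spike_states)
  frac <- cfg$state_frac[chain] / sum(cfg$state_frac[chain])
  stick <- cfg$stickiness[chain]
  reentry <- frac * (1 - stick)
  if (sum(reentry) == 0) reentry <- frac  # all-absorbing chain
  path <- integer(bins$n_bins)
  for (idx in chrom_sequences(bins)) {
    z <- sample.int(length(chain), 1, prob = frac)
    for (t in seq_along(idx)) {
      if (t > 1 && stats::runif(1) >= stick[z])
        z <- sample.int(length(chain), 1, prob = reentry)
      path[idx[t]] <- chain[z]
    }
  }
  for (s in cfg$spike_states) {
    free <- which(!(path %in% cfg$spike_states))
    n_s <- round(cfg$state_frac[s] * bins$n_bins)
    path[sample(free, n_s)] <- s
  }
  # fragments
  tb <- bin_table(bins)
  half <- cfg$fragment_length / 2
  n_bin <- stats::rpois(bins$n_bins, cfg$depth_mean[path])
  frag_chrom <- vector("list", bins$n_bins)
  frag_mid <- vector("list", bins$n_bins)
  frag_cell <- vector("list", bins$n_bins)
  for (i in which(n_bin > 0)) {
    p <- rdirichlet1(alpha[path[i], ])
    cnt <- as.integer(stats::rmultinom(1, n_bin[i], p))
    nz <- which(cnt > 0)
    cells <- rep(nz, cnt[nz])
    lo <- max(tb$start[i], half)
    hi <- min(tb$end[i] - 1, cfg$chrom_length - half)
    frag_mid[[i]] <- sample(lo:hi, length(cells), replace = TRUE)
    frag_cell[[i]] <- cells
    frag_chrom[[i]] <- rep(tb$chrom[i], length(cells))
  }
  mid <- unlist(frag_mid)
  frags <- fragment_set(chrom = unlist(frag_chrom),
                        start = mid - half, end = mid + half,
                        barcode = barcodes[unlist(frag_cell)])
  sim <- list(fragments = frags, chrom_sizes = chrom_sizes, bins = bins,
              labels = labels,
              truth = list(path = path, alpha = alpha,
                           cluster_of = cluster_of, config = cfg))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(as.data.frame(frags)[c("chrom", "start", "end",
                                              "barcode", "count")],
                       file.path(out_dir, "fragments.tsv.gz"),
                       sep = "\t", col.names = FALSE)
    data.table::fwrite(data.frame(chrom = chroms,
                                  size = unname(chrom_sizes)),
                       file.path(out_dir, "chrom_sizes.tsv"),
                       sep = "\t", col.names = FALSE)
    data.table::fwrite(data.frame(barcode = barcodes,
                                  cluster = unname(labels)),
                       file.path(out_dir, "cluster_labels.tsv"),
                       sep = "\t", col.names = FALSE)
  }
  sim
}

#' Simulate gene annotation, gene sets and a chromatin-state BED
#'
#' For each planted gene set, TSSs are placed (at rate `placement_rate`)
#' within +/- `flank` of a bin whose true state is the set's target state;
#' decoy genes are placed uniformly.  Gene bodies extend downstream of the
#' TSS.  A chromatin-state annotation BED is derived from the true state
#' path through `state_labels`.
#'
#' @param sim a [simulate_dataset()] result.
#' @param set_targets named integer vector: gene-set name -> target state.
#' @param genes_per_set genes per planted set.
#' @param placement_rate probability a set gene is planted near its target
#'   state (1 = always; the background rate makes enrichment vanish in
#'   expectation).
#' @param n_decoys uniformly placed genes outside all sets.
#' @param flank placement window half-width in bp.
#' @param gene_body_length gene length in bp.
#' @param state_labels per-state annotation labels (defaults to
#'   `acc_state_<k>`).
#' @param seed seed for the placement draws.
#' @return list with `annotation` (a [gene_annotation()]) and `chrom_state`
#'   (BED-like data.frame of true-state runs).
#' @export
simulate_annotation <- function(sim, set_targets = c(setA = 2L, setB = 3L),
                                genes_per_set = 20, placement_rate = 1,
                                n_decoys = 100, flank = 10000,
                                gene_body_length = 2000,
                                state_labels = NULL, seed = 1) {
  set.seed(seed)
  cfg <- sim$truth$config
  tb <- bin_table(sim$bins)
  genes <- list()
  gid <- 0
  place_near_state <- function(s) {
    cand <- which(sim$truth$path == s)
    i <- cand[sample.int(length(cand), 1)]
    center <- (tb$start[i] + tb$end[i]) %/% 2
    pos <- center + sample(-flank:flank, 1)
    list(chrom = tb$chrom[i],
         pos = max(0, min(pos, cfg$chrom_length - gene_body_length)))
  }
  place_uniform <- function() {
    list(chrom = sprintf("chr%d", sample.int(cfg$n_chroms, 1)),
         pos = sample.int(cfg$chrom_length - gene_body_length, 1) - 1L)
  }
  gene_sets <- list()
  for (nm in names(set_targets)) {
    ids <- character(genes_per_set)
    for (g in seq_len(genes_per_set)) {
      gid <- gid + 1
      loc <- if (stats::runif(1) < placement_rate)
        place_near_state(set_targets[[nm]]) else place_uniform()
      ids[g] <- sprintf("gene_%04d", gid)
      genes[[gid]] <- data.frame(chrom = loc$chrom, pos = loc$pos,
                                 gene = ids[g])
    }
    gene_sets[[nm]] <- ids
  }
  for (g in seq_len(n_decoys)) {
    gid <- gid + 1
    loc <- place_uniform()
    genes[[gid]] <- data.frame(chrom = loc$chrom, pos = loc$pos,
                               gene = sprintf("gene_%04d", gid))
  }
  tss <- do.call(rbind, genes)
  gene_body <- data.frame(chrom = tss$chrom, start = tss$pos,
                          end = tss$pos + gene_body_length,
                          gene = tss$gene)
  if (is.null(state_labels))
    state_labels <- sprintf("acc_state_%d", seq_len(cfg$n_states))
  run_start <- c(TRUE, tb$chrom[-1] != tb$chrom[-nrow(tb)] |
                   sim$truth$path[-1] != sim$truth$path[-length(sim$truth$path)])
  run <- cumsum(run_start)
  chrom_state <- data.frame(
    chrom = tb$chrom[run_start],
    start = tb$start[run_start],
    end = as.numeric(tapply(tb$end, run, max)),
    state = state_labels[sim$truth$path[run_start]])
  list(annotation = gene_annotation(tss, gene_body, gene_sets),
       chrom_state = chrom_state)
}

#' Simulate condition labels with planted composition effects
#'
#' Assigns each cell to a condition (e.g. mutant) with probability
#' `baseline`, overridden per cluster by `cluster_effects` to plant
#' depletion or enrichment detectable by
#' [composition_binomial_test()].
#'
#' @param sim a [simulate_dataset()] result.
#' @param baseline condition probability for unaffected clusters.
#' @param cluster_effects named numeric vector of per-cluster condition
#'   probabilities (names are cluster names such as `"c1"`).
#' @param seed seed for the assignment draws.
#' @return data.frame `barcode`, `cluster`, `condition`
#'   (`"condition"`/`"reference"`).
#' @export
simulate_condition <- function(sim, baseline = 0.42,
                               cluster_effects = c(c1 = 0.05), seed = 1) {
  set.seed(seed)
  cl <- unname(sim$labels)
  pr <- rep(baseline, length(cl))
  for (nm in names(cluster_effects)) pr[cl == nm] <- cluster_effects[[nm]]
  data.frame(barcode = names(sim$labels), cluster = cl,
             condition = ifelse(stats::runif(length(cl)) < pr,
                                "condition", "reference"),
             stringsAsFactors = FALSE)
}
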