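#' Bundle gene annotation inputs
#'
#' @param tss data.frame with columns `chrom`, `pos` (0-based TSS
#'   coordinate), `gene`, optional `strand`.
#' @param gene_body optional data.frame `chrom`, `start`, `end`, `gene`.
#' @param gene_sets named list of gene-id vectors (e.g. anatomy terms or
#'   scRNA-seq marker sets).  Members absent from `tss` are dropped with a
#'   warning.
#' @return a list of class `gene_annotation`.
#' @export
gene_annotation <- function(tss, gene_body = NULL, gene_sets = list()) {
  stopifnot(all(c("chrom", "pos", "gene") %in% names(tss)))
  if (anyDuplicated(tss$gene))
    stop("duplicate gene ids in TSS table")
  gene_sets <- lapply(gene_sets, function(g) {
    missing <- setdiff(g, tss$gene)
    if (length(missing))
      warning(length(missing), " gene-set member(s) absent from annotation dropped")
    intersect(g, tss$gene)
  })
  structure(list(tss = tss, gene_body = gene_body, gene_sets = gene_sets),
            class = "gene_annotation")
}

#' Map regions to their nearest TSS
#'
#' Distance is `|region midpoint - TSS position|` on the same chromosome.
#' Equidistant TSSs are resolved toward the lower coordinate.  Regions on
#' chromosomes without any TSS are left unassigned with a warning.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (a `region_set`
#'   works directly).
#' @param ann a [gene_annotation()].
#' @return data.frame with one row per region: `chrom`, `start`, `end`,
#'   `gene`, `distance`.
#' @export
nearest_tss <- function(regions, ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  mid <- (regions$start + regions$end) %/% 2
  gene <- rep(NA_character_, nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  for (cc in unique(regions$chrom)) {
    rr <- which(regions$chrom == cc)
    tt <- ann$tss[ann$tss$chrom == cc, , drop = FALSE]
    if (nrow(tt) == 0) next
    ord <- order(tt$pos)
    pos <- tt$pos[ord]
    gn <- tt$gene[ord]
    iv <- findInterval(mid[rr], pos)
    left <- pmax(iv, 1L)
    right <- pmin(iv + 1L, length(pos))
    dl <- abs(mid[rr] - pos[left])
    dr <- abs(mid[rr] - pos[right])
    use_left <- dl <= dr   # tie -> lower coordinate
    pick <- ifelse(use_left, left, right)
    gene[rr] <- gn[pick]
    dist[rr] <- pmin(dl, dr)
  }
  if (anyNA(gene))
    warning(sum(is.na(gene)), " region(s) on chromosomes with no TSS left unassigned")
  data.frame(chrom = regions$chrom, start = regions$start,
             end = regions$end, gene = gene, distance = dist,
             stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(M, n, N)`: the probability of
#' observing at least `k` gene-set genes when `N` genes are drawn from a
#' universe of `M` genes of which `n` belong to the set.  The tail is
#' inclusive of the observed `k`.
#'
#' @param k gene-set genes hit by the region-to-gene mapping.
#' @param n gene-set size.
#' @param N genes hit by any region (each gene counted once).
#' @param M total genes in the universe.
#' @return the p-value.
#' @export
hypergeom_enrichment <- function(k, n, N, M) {
  if (any(c(k, n, N, M) < 0) || k > min(n, N) || n > M || N > M)
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, N); n, N <= M)")
  stats::phyper(k - 1, n, M - n, N, lower.tail = FALSE)
}

#' Gene-set enrichment of a region set
#'
#' Maps regions to nearest TSS genes (each gene counted once), then tests
#' every gene set with [hypergeom_enrichment()] against the annotation's
#' gene universe.  Benjamini-Hochberg FDR is reported alongside the raw
#' p-values, which remain primary.
#'
#' @param regions a region set (e.g. differentially accessible regions).
#' @param ann a [gene_annotation()] with `gene_sets`.
#' @return data.frame with one row per set: `set`, `k`, `n`, `N`, `M`,
#'   `pvalue`, `fdr`.
#' @export
gene_set_enrichment <- function(regions, ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  hits <- unique(stats::na.omit(nearest_tss(regions, ann)$gene))
  M <- nrow(ann$tss)
  N <- length(hits)
  res <- do.call(rbind, lapply(names(ann$gene_sets), function(nm) {
    set <- ann$gene_sets[[nm]]
    data.frame(set = nm,
               k = length(intersect(hits, set)),
               n = length(set), N = N, M = M)
  }))
  res$pvalue <- mapply(hypergeom_enrichment, res$k, res$n, res$N, res$M)
  res$fdr <- stats::p.adjust(res$pvalue, "BH")
  res
}

# 1-based bin indices overlapping [start, end) on chrom; empty when the
# chromosome is not in the index
bins_in_window <- function(bins, chrom, start, end) {
  if (!chrom %in% bins$chrom_order) return(integer(0))
  bs <- bins$binsize
  sz <- bins$chrom_sizes[[chrom]]
  start <- max(0, start)
  end <- min(sz, end)
  if (end <= start) return(integer(0))
  k <- (start %/% bs):((end - 1) %/% bs)
  unname(bins$offsets[[chrom]] + k + 1L)
}

#' Expand TSS positions into windows
#'
#' @param tss data.frame `chrom`, `pos`, `gene`.
#' @param flank half-width in bp (10 kb by default).
#' @param chrom_sizes optional named sizes used to clip at chromosome ends.
#' @return data.frame `chrom`, `start`, `end`, `gene`.
#' @export
expand_tss <- function(tss, flank = 10000, chrom_sizes = NULL) {
  start <- pmax(0, tss$pos - flank)
  end <- tss$pos + flank
  if (!is.null(chrom_sizes))
    end <- pmin(end, unname(chrom_sizes[tss$chrom]))
  data.frame(chrom = tss$chrom, start = start, end = end, gene = tss$gene,
             stringsAsFactors = FALSE)
}

#' Stationary-distribution state enrichment score
#'
#' Counts the Viterbi state calls inside a set of target windows (gene-set
#' TSSs expanded by +/- 10 kb).  With `o_i` the observed state-i calls,
#' `N` the total calls inside the windows and `e_i = N * p_i` the count
#' expected under the stationary distribution `p`, the score is
#' `(o_i - e_i)^2 / e_i^2` when `o_i > e_i` and 0 otherwise — depletion is
#' never scored.  Bins covered by several overlapping windows are counted
#' once.
#'
#' @param seg a segmentation.
#' @param regions data.frame `chrom`, `start`, `end` of target windows.
#' @param p stationary distribution of the fitted transition matrix.
#' @return data.frame per state: `state`, `observed`, `expected`, `score`.
#' @export
feature_enrichment_score <- function(seg, regions, p) {
  stopifnot(inherits(seg, "segmentation"), length(p) == seg$n_states)
  idx <- unique(unlist(mapply(bins_in_window,
                              chrom = regions$chrom,
                              start = regions$start, end = regions$end,
                              MoreArgs = list(bins = seg$bins),
                              SIMPLIFY = FALSE)))
  o <- tabulate(seg$state_call[idx], nbins = seg$n_states)
  N <- length(idx)
  e <- N * p
  score <- ifelse(o > e, (o - e)^2 / e^2, 0)
  inf <- e == 0 & o > 0
  if (any(inf)) {
    warning("state(s) with zero expected count but observed calls: ",
            paste(which(inf), collapse = ", "))
    score[inf] <- Inf
  }
  data.frame(state = seq_len(seg$n_states), observed = o, expected = e,
             score = score)
}

#' Marker-gene log-ratio for a state
#'
#' For each gene, compares the proportion of state-`state` calls in the
#' gene body expanded by +/- `flank` against the proportion expected by
#' chance in a window of the same size (the state's stationary probability
#' `p[state]`):  `log((o / N_g) / p_state)`.  High positive scores flag
#' genes whose neighborhood is saturated with that state's calls.
#'
#' @param seg a segmentation.
#' @param ann a [gene_annotation()] with `gene_body`.
#' @param state state index to query.
#' @param p stationary distribution.
#' @param flank window expansion in bp (default 10 kb).
#' @return data.frame `gene`, `observed`, `total`, `score`, ranked by
#'   descending score; genes whose window contains no bins are skipped with
#'   a warning.
#' @export
marker_gene_logratio <- function(seg, ann, state, p, flank = 10000) {
  stopifnot(inherits(seg, "segmentation"), inherits(ann, "gene_annotation"))
  gb <- ann$gene_body
  if (is.null(gb)) stop("annotation has no gene bodies")
  rows <- lapply(seq_len(nrow(gb)), function(i) {
    idx <- bins_in_window(seg$bins, gb$chrom[i],
                          gb$start[i] - flank, gb$end[i] + flank)
    if (length(idx) == 0) return(NULL)
    o <- sum(seg$state_call[idx] == state)
    data.frame(gene = gb$gene[i], observed = o, total = length(idx),
               score = log((o / length(idx)) / p[state]))
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    warning(skipped, " gene(s) with empty windows skipped")
  out <- do.call(rbind, rows)
  out[order(-out$score), , drop = FALSE]
}

#' Shannon-entropy cell-type specificity
#'
#' Per-region entropy of accessibility across clusters: a pseudocount is
#' added to every entry, each cluster column is depth-normalized by its
#' total, each region row is renormalized to a probability vector `p`, and
#' `SE = -sum_i p_i log2 p_i` is reported in bits.  Low entropy marks
#' cell-type-specific regions, high entropy constitutive ones; the maximum
#' is `log2(n_clusters)`.
#'
#' @param counts regions x clusters matrix of read counts.
#' @param pseudocount added to every entry before normalization (default 1).
#' @return list with `entropy` (per region, bits) and `p` (the normalized
#'   matrix).
#' @export
shannon_entropy <- function(counts, pseudocount = 1) {
  m <- as.matrix(counts) + pseudocount
  if (any(m < 0)) stop("counts must be non-negative")
  cs <- colSums(m)
  cs[cs == 0] <- 1           # clusters with no reads at all stay zero
  m <- sweep(m, 2, cs, "/")
  p <- m / rowSums(m)
  plogp <- ifelse(p > 0, p * log2(p), 0)   # 0 log 0 = 0
  list(entropy = -rowSums(plogp), p = p)
}

#' Exact binomial test of per-cluster composition
#'
#' Tests each cluster for enrichment or depletion of condition cells
#' (e.g. mutant vs sibling) against the pooled baseline: the success
#' probability is `p0 = sum(condition) / (sum(condition) + sum(reference))`
#' and each cluster's condition count out of its total is tested two-sided
#' with the exact binomial test (two-sidedness by summing point
#' probabilities not exceeding the observed one).
#'
#' @param counts_condition,counts_reference per-cluster integer vectors
#'   (parallel; names taken from `counts_condition`).
#' @return list with `p0` and `table` (cluster, counts, fraction,
#'   direction, pvalue, BH fdr); empty clusters are skipped with a warning.
#' @export
composition_binomial_test <- function(counts_condition, counts_reference) {
  stopifnot(length(counts_condition) == length(counts_reference),
            length(counts_condition) >= 1)
  tot_cond <- sum(counts_condition)
  tot_ref <- sum(counts_reference)
  if (tot_cond + tot_ref <= 0) stop("no cells in either condition")
  p0 <- tot_cond / (tot_cond + tot_ref)
  nm <- names(counts_condition)
  if (is.null(nm)) nm <- as.character(seq_along(counts_condition))
  n_k <- counts_condition + counts_reference
  empty <- n_k == 0
  if (any(empty))
    warning(sum(empty), " empty cluster(s) skipped")
  keep <- which(!empty)
  pv <- vapply(keep, function(k)
    stats::binom.test(counts_condition[k], n_k[k], p0)$p.value, numeric(1))
  frac <- counts_condition[keep] / n_k[keep]
  res <- data.frame(cluster = nm[keep],
                    condition = counts_condition[keep],
                    total = n_k[keep],
                    fraction = frac,
                    direction = ifelse(frac > p0, "enriched",
                                       ifelse(frac < p0, "depleted", "none")),
                    pvalue = pv,
                    fdr = stats::p.adjust(pv, "BH"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  list(p0 = p0, table = res)
}

#' Per-region, per-state base-pair coverage from a state annotation BED
#'
#' @param regions data.frame `chrom`, `start`, `end`.
#' @param annotation data.frame `chrom`, `start`, `end`, `state` (an
#'   external chromatin-state annotation, e.g. histone-PTM states).
#' @return matrix regions x states of overlapping bp; state columns in
#'   sorted label order.
#' @export
state_coverage <- function(regions, annotation) {
  states <- sort(unique(as.character(annotation$state)))
  rg <- data.table::data.table(chrom = regions$chrom,
                               start = regions$start, end = regions$end,
                               rid = seq_len(nrow(regions)))
  an <- data.table::data.table(chrom = annotation$chrom,
                               start = annotation$start,
                               end = annotation$end,
                               state = as.character(annotation$state))
  data.table::setkey(an, chrom, start, end)
  ov <- data.table::foverlaps(rg, an, type = "any", nomatch = NULL)
  out <- matrix(0, nrow(regions), length(states),
                dimnames = list(NULL, states))
  if (nrow(ov) > 0) {
    bp <- pmin(ov$end, ov$i.end) - pmax(ov$start, ov$i.start)
    for (s in states) {
      sel <- ov$state == s
      if (any(sel))
        out[, s] <- out[, s] +
          rowsum_vec(bp[sel], ov$rid[sel], nrow(regions))
    }
  }
  out
}

#' Classify regions by dominant annotation state
#'
#' Scores each region against each annotation state by comparing the
#' region's normalized observed coverage with the coverage expected for a
#' region of its size under the genome-wide state probabilities:
#' `score_s = log( (cov_s / C_s) / (p_s * L / Ctot) )` where `C_s` is the
#' state's total coverage over the region set, `L` the region length and
#' `Ctot` the region set's total covered bp.  The region is labelled with
#' the arg-max state (ties toward the lowest state index, flagged);
#' regions with no coverage by any state are labelled `"background"`.
#'
#' @param region_coverage regions x states bp matrix (see
#'   [state_coverage()]).
#' @param region_sizes region lengths in bp.
#' @param genome_probs per-state genome-wide probability (same state order
#'   as the coverage columns).
#' @param regionset_coverage per-state totals over the region set; defaults
#'   to `colSums(region_coverage)`.
#' @return data.frame with `label` and `tied` flag, plus the score matrix
#'   as attribute `"scores"`.
#' @export
classify_regions_by_state <- function(region_coverage, region_sizes,
                                      genome_probs,
                                      regionset_coverage = colSums(region_coverage)) {
  cov <- as.matrix(region_coverage)
  stopifnot(length(genome_probs) == ncol(cov),
            length(region_sizes) == nrow(cov))
  Ctot <- sum(regionset_coverage)
  obs <- sweep(cov, 2, pmax(regionset_coverage, 1e-300), "/")
  expd <- outer(region_sizes / Ctot, genome_probs)
  scores <- log(obs / expd)
  labels <- character(nrow(cov))
  tied <- logical(nrow(cov))
  st <- colnames(cov)
  if (is.null(st)) st <- as.character(seq_len(ncol(cov)))
  for (i in seq_len(nrow(cov))) {
    if (all(cov[i, ] == 0)) {
      labels[i] <- "background"
      next
    }
    best <- which(scores[i, ] == max(scores[i, ], na.rm = TRUE))
    tied[i] <- length(best) > 1
    labels[i] <- st[min(best)]
  }
  if (any(tied))
    warning(sum(tied), " tie(s) broken toward the lowest state index")
  out <- data.frame(label = labels, tied = tied, stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  out
}
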