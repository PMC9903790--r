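toy_annotation <- function() {
  tss <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    pos = c(1000, 5000, 2000),
                    gene = c("g1", "g2", "g3"))
  gene_body <- data.frame(chrom = tss$chrom, start = tss$pos,
                          end = tss$pos + 1000, gene = tss$gene)
  gene_annotation(tss, gene_body,
                  gene_sets = list(s12 = c("g1", "g2"), s3 = "g3"))
}

test_that("nearest_tss picks the closest same-chromosome gene, ties to lower coordinate", {
  ann <- toy_annotation()
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(900, 2900, 100), end = c(1100, 3100, 300))
  nt <- nearest_tss(regions, ann)
  # region 1: midpoint 1000 == TSS of g1, distance 0
  expect_equal(nt$gene[1], "g1")
  expect_equal(nt$distance[1], 0)
  # region 2: midpoint 3000 equidistant (2000) from g1 and g2 -> g1
  expect_equal(nt$gene[2], "g1")
  # region 3 is on chr2
  expect_equal(nt$gene[3], "g3")
  # chromosome without any TSS is flagged
  expect_warning(
    nt2 <- nearest_tss(data.frame(chrom = "chrX", start = 0, end = 100), ann),
    "no TSS")
  expect_true(is.na(nt2$gene))
})

test_that("nearest_tss agrees with the all-pairs search on random instances", {
  set.seed(71)
  tss <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                    pos = sample.int(1e5, 30),
                    gene = sprintf("g%02d", 1:30))
  ann <- gene_annotation(tss)
  regions <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                        start = sample.int(1e5, 50))
  regions$end <- regions$start + 200
  nt <- nearest_tss(regions, ann)
  for (i in seq_len(50)) {
    mid <- (regions$start[i] + regions$end[i]) %/% 2
    cand <- tss[tss$chrom == regions$chrom[i], ]
    d <- abs(mid - cand$pos)
    best <- cand[d == min(d), ]
    expect_equal(nt$gene[i], best$gene[which.min(best$pos)])
    expect_equal(nt$distance[i], min(d))
  }
})

test_that("hypergeometric p-values match exhaustive enumeration for all M <= 12", {
  direct <- function(k, n, N, M) {
    # P(X >= k) by summing the pmf written with binomial coefficients
    js <- k:min(n, N)
    sum(choose(n, js) * choose(M - n, N - js)) / choose(M, N)
  }
  expect_equal(hypergeom_enrichment(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_enrichment(0, 3, 2, 8), 1)
  expect_equal(hypergeom_enrichment(4, 10, 4, 10), 1)  # set = universe
  for (M in 2:12)
    for (n in 0:M)
      for (N in 0:M)
        for (k in 0:min(n, N))
          expect_equal(hypergeom_enrichment(k, n, N, M), direct(k, n, N, M),
                       tolerance = 1e-12)
  expect_error(hypergeom_enrichment(5, 3, 4, 10), "inconsistent")
})

test_that("gene_set_enrichment counts each gene once and ranks planted sets", {
  ann <- toy_annotation()
  # two regions both nearest to g1, one to g3: hits = {g1, g3}, N = 2
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(800, 1100, 1900), end = c(1000, 1300, 2100))
  res <- gene_set_enrichment(regions, ann)
  expect_equal(res$N, c(2, 2))
  expect_equal(res$M, c(3, 3))
  expect_equal(res$k[res$set == "s12"], 1)
  expect_equal(res$k[res$set == "s3"], 1)
  expect_equal(res$pvalue[res$set == "s3"],
               hypergeom_enrichment(1, 1, 2, 3))
})

test_that("feature_enrichment_score follows the squared-ratio rule", {
  bins <- make_bins(c(chr1 = 1e5), 1000)          # 100 bins
  calls <- c(rep(1, 50), rep(2, 25), rep(3, 25))
  seg <- fake_seg(bins, calls)
  windows <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  p <- c(0.25, 0.25, 0.5)
  fes <- feature_enrichment_score(seg, windows, p)
  expect_equal(fes$observed, c(50, 25, 25))
  expect_equal(fes$expected, c(25, 25, 50))
  # o = 2e -> ((2e-e)^2)/e^2 = 1 ; o = e -> 0 ; o < e -> 0
  expect_equal(fes$score, c(1, 0, 0))
  # strictly increasing in o above e, on a finer grid
  scores <- sapply(26:60, function(o) (o - 25)^2 / 25^2)
  expect_true(all(diff(scores) > 0))
})

test_that("feature_enrichment_score counts bins once under overlapping windows", {
  bins <- make_bins(c(chr1 = 10000), 1000)
  seg <- fake_seg(bins, rep(c(1, 2), 5))
  w <- data.frame(chrom = c("chr1", "chr1"), start = c(0, 2000),
                  end = c(6000, 8000))
  fes <- feature_enrichment_score(seg, w, c(0.5, 0.5))
  expect_equal(sum(fes$observed), 8)   # union covers bins 1-8
})

test_that("marker_gene_logratio scores gene windows against the stationary rate", {
  bins <- make_bins(c(chr1 = 4e4), 1000)
  calls <- c(rep(2, 20), rep(1, 20))
  seg <- fake_seg(bins, calls)
  ann <- gene_annotation(
    tss = data.frame(chrom = c("chr1", "chr1"), pos = c(5000, 30000),
                     gene = c("covered", "matched")),
    gene_body = data.frame(chrom = c("chr1", "chr1"),
                           start = c(5000, 30000), end = c(6000, 31000),
                           gene = c("covered", "matched")))
  p <- c(0.5, 0.25)
  mg <- marker_gene_logratio(seg, ann, state = 2, p = p, flank = 4000)
  # gene "covered": window 1000-10000 entirely state 2 -> log(1 / 0.25)
  expect_equal(mg$score[mg$gene == "covered"], log(1 / 0.25))
  # random-instance check against direct tabulation
  set.seed(5)
  calls_r <- sample(1:2, 40, replace = TRUE)
  seg_r <- fake_seg(bins, calls_r, n_states = 2)
  mg_r <- marker_gene_logratio(seg_r, ann, state = 2, p = p, flank = 4000)
  for (g in ann$gene_body$gene) {
    i <- which(ann$gene_body$gene == g)
    lo <- ann$gene_body$start[i] - 4000
    hi <- ann$gene_body$end[i] + 4000
    idx <- which(bin_table(bins)$start >= lo - 999 &
                   bin_table(bins)$start < hi)
    idx <- idx[bin_table(bins)$end[idx] > lo]
    o <- sum(calls_r[idx] == 2)
    expect_equal(mg_r$score[mg_r$gene == g],
                 log((o / length(idx)) / p[2]))
  }
  # a window fraction exactly equal to p gives score 0: the "covered"
  # window spans bins 2..10; put state 2 in exactly 3 of those 9 bins
  calls_third <- rep(1, 40)
  calls_third[c(2, 5, 8)] <- 2
  seg_t <- fake_seg(bins, calls_third, n_states = 2)
  ann1 <- gene_annotation(
    tss = data.frame(chrom = "chr1", pos = 5000, gene = "covered"),
    gene_body = data.frame(chrom = "chr1", start = 5000, end = 6000,
                           gene = "covered"))
  mg_t <- marker_gene_logratio(seg_t, ann1, state = 2, p = c(2 / 3, 1 / 3),
                               flank = 4000)
  expect_equal(mg_t$score, 0)
})

test_that("shannon_entropy follows pseudocount -> depth norm -> row norm", {
  # uniform profile over 17 clusters attains the maximum log2(17)
  u <- matrix(5, nrow = 3, ncol = 17)
  se <- shannon_entropy(u)
  expect_equal(se$entropy, rep(log2(17), 3), tolerance = 1e-12)
  # two equal clusters give exactly 1 bit
  expect_equal(shannon_entropy(matrix(c(4, 4), 1))$entropy, 1)
  # a degenerate one-hot probability vector has zero entropy
  expect_equal(shannon_entropy(matrix(c(9, 0), 1), pseudocount = 0)$entropy, 0)
  # depth normalization undoes cluster-size differences
  m <- rbind(c(10, 100), c(20, 200))
  se2 <- shannon_entropy(m, pseudocount = 0)
  expect_equal(se2$entropy, c(1, 1))
  # bounds and cluster-order invariance
  set.seed(2)
  r <- matrix(rpois(60, 4), 10, 6)
  e1 <- shannon_entropy(r)$entropy
  expect_true(all(e1 >= 0 & e1 <= log2(6) + 1e-12))
  expect_equal(shannon_entropy(r[, 6:1])$entropy, e1)
})

test_that("composition_binomial_test reproduces printed-total arithmetic and exact tails", {
  # background success probability from condition totals
  res <- composition_binomial_test(c(a = 3769), c(a = 5207))
  expect_equal(res$p0, 3769 / 8976)
  expect_equal(round(100 * res$p0), 42)
  # a cluster at exactly p0 is maximally compatible with the null
  res2 <- composition_binomial_test(c(10, 40), c(10, 40))
  expect_equal(res2$p0, 0.5)
  expect_equal(res2$table$pvalue[1], 1)
  # closed-form two-sided tail for 0 successes at p0 = 1/2
  res3 <- composition_binomial_test(c(0, 100), c(20, 80))
  expect_equal(res3$p0, 0.5)
  expect_equal(res3$table$pvalue[1], min(1, 2 * 0.5^20))
  expect_equal(res3$table$direction[1], "depleted")
  expect_warning(composition_binomial_test(c(0, 5), c(0, 5)), "empty")
})

test_that("composition test p-values are uniform under the null", {
  set.seed(91)
  n_clusters <- 2000
  n_per <- 5000
  cond <- rbinom(n_clusters, n_per, 0.4)
  res <- composition_binomial_test(cond, n_per - cond)
  ks <- suppressWarnings(stats::ks.test(res$table$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("state_coverage measures bp overlap per annotation state", {
  ann_bed <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                        start = c(0, 500, 800),
                        end = c(500, 800, 2000),
                        state = c("promoter", "enhancer", "background"))
  regions <- data.frame(chrom = c("chr1", "chr1"),
                        start = c(250, 700), end = c(600, 1200))
  cov <- state_coverage(regions, ann_bed)
  expect_equal(cov[1, ], c(background = 0, enhancer = 100, promoter = 250))
  expect_equal(cov[2, ], c(background = 400, enhancer = 100, promoter = 0))
})

test_that("classify_regions_by_state follows the normalized log-ratio rule", {
  # fully covered by one state whose shares equal the others' -> that state
  cov <- rbind(c(100, 0), c(0, 100), c(50, 50), c(0, 0))
  sizes <- c(100, 100, 100, 100)
  out <- suppressWarnings(
    classify_regions_by_state(cov, sizes, genome_probs = c(0.5, 0.5)))
  expect_equal(out$label, c("1", "2", "1", "background"))
  expect_true(out$tied[3])   # proportional coverage ties, lowest index wins
  # random instance against the direct formula
  set.seed(17)
  cov_r <- matrix(rpois(12, 40) + 1, 4, 3,
                  dimnames = list(NULL, c("e", "p", "b")))
  sizes_r <- rowSums(cov_r) + rpois(4, 10)
  gp <- c(0.2, 0.3, 0.5)
  out_r <- classify_regions_by_state(cov_r, sizes_r, gp)
  sc <- attr(out_r, "scores")
  Ctot <- sum(cov_r)
  for (i in 1:4)
    for (s in 1:3)
      expect_equal(sc[i, s],
                   log((cov_r[i, s] / sum(cov_r[, s])) /
                         (gp[s] * sizes_r[i] / Ctot)))
  expect_equal(out_r$label,
               colnames(cov_r)[apply(sc, 1, which.max)])
})
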