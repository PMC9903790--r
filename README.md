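# segatac

Genome segmentation of single-cell ATAC-seq with Dirichlet-multinomial
hidden Markov models.

## The problem

Single-cell ATAC-seq quantifies chromatin accessibility per cell barcode,
but unlike scRNA-seq there is no gene annotation that says *which genomic
regions* to quantify.  segatac addresses the feature-definition problem by
segmenting the genome directly from the data: the genome is tiled into
fixed-width bins (1 kb per-cell, 500 bp for cluster pseudo-bulks), and a
hidden Markov model with Dirichlet-multinomial (DM) emissions assigns each
bin to a *state* — a recurring pattern of how a bin's fragments distribute
across cells or clusters:

- emission of a count vector $x$ over tracks, conditioned on $n = \sum x$:
  $P(x\mid\alpha_s)=\binom{n}{x}\frac{\Gamma(A_s)}{\Gamma(n+A_s)}
  \prod_c\frac{\Gamma(x_c+\alpha_{sc})}{\Gamma(\alpha_{sc})}$,
  one concentration vector $\alpha_s$ per state;
- Baum-Welch fitting with random restarts, Viterbi state calling, and
  forward-backward posteriors per bin;
- **feature identification**: states covering at most 1.5% of the genome
  are informative *foreground*; their confident bins (posterior ≥ 0.9)
  merge into the regions used downstream for dimensionality reduction;
- **program identification**: segmentation of cluster pseudo-bulk tracks,
  with state-cluster associations $\log(P_{cs}/P_b)$ revealing regulatory
  programs shared across cell types;
- downstream statistics: nearest-TSS hypergeometric gene-set enrichment,
  stationary-distribution state enrichment scores $((o_i-e_i)^2/e_i^2$
  with $e_i = N p_i)$, marker-gene log-ratios, Shannon-entropy cell-type
  specificity, exact binomial composition tests, and classification of
  regions against an external chromatin-state annotation.

A fully specified synthetic-data generator (fragment files, cluster
labels, gene annotations, chromatin-state BEDs, with serialized ground
truth) makes every stage testable without external data.

## Worked example

Simulate a 4 Mb genome (two chromosomes, 1 kb bins) with 60 cells in four
clusters: a constitutive background, a sporadic low-coverage background,
and a rare accessible state spiked in at exactly 1% of bins, accessible
only in cluster 1.

```r
library(segatac)

cfg <- sim_config(n_chroms = 2, chrom_length = 2e6, binsize = 1000,
                  n_states = 3, state_frac = c(0.59, 0.40, 0.01),
                  stickiness = c(0.95, 0.95, 0),
                  state_cluster_access = list(1:4, integer(0), 1),
                  depth_mean = c(15, 4, 50), n_cells = 60, n_clusters = 4,
                  spike_states = 3, seed = 7)
sim <- simulate_dataset(cfg)
cm  <- count_matrix(sim$fragments, sim$bins, cap = 4)
cm
#> seg_counts: 4000 bins x 60 tracks, 35334 non-zero entries

fi <- identify_features(cm, n_states = 3, n_iter = 100, n_restarts = 5,
                        seed = 7)
round(state_frequencies(fi$segmentation), 4)
#> [1] 0.6710 0.3172 0.0118
fi$foreground_states
#> [1] 3
head(fi$regions, 3)
#>   chrom  start    end state max_posterior score
#> 1  chr1 100000 101000     3     1.0000000  1000
#> 2  chr1 197000 198000     3     0.9932358   993
#> 3  chr1 452000 453000     3     1.0000000  1000
nrow(fi$regions)
#> [1] 40
```

The fitted model calls state 3 on 1.18% of bins; it is the only state
under the 1.5% foreground ceiling, and its 40 high-confidence regions are
exactly the 40 spiked sites.  Against the generator's ground truth the
Viterbi path reaches an adjusted Rand index of 0.912.

Gene-set enrichment around TSSs planted near the rare state ranks it far
above the backgrounds (observed vs expected state calls in the set's
±10 kb windows, scored $(o-e)^2/e^2$ for $o>e$, else 0):

```r
p   <- stationary_distribution(fi$model$transition)
ann <- simulate_annotation(sim, set_targets = c(vasc = 3L),
                           genes_per_set = 15, n_decoys = 60, seed = 7)
tss <- ann$annotation$tss
w   <- expand_tss(tss[tss$gene %in% ann$annotation$gene_sets$vasc, ],
                  flank = 10000, chrom_sizes = sim$chrom_sizes)
feature_enrichment_score(fi$segmentation, w, p)
#>   state observed   expected        score
#> 1     1      177 174.752954 1.653388e-04
#> 2     2       64  77.091266 0.000000e+00
#> 3     3       14   3.155779 1.180819e+01
```

For cluster-level programs, collapse cells into pseudo-bulk tracks and
segment those (`segment_programs()`); the returned
`association$logratio` matrix shows which clusters drive each state —
shared programs appear as several positive entries in one state's row.

A thin command-line front end over the same functions is installed at
`inst/scripts/segatac-cli.R` (subcommands `counts`, `fit`, `segment`,
`fi`, `pi`, `entropy`, `simulate`).

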