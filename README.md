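# fmenet

Random-matrix-theory thresholded molecular ecological networks from
gene-by-sample abundance data.

## What it does, and for whom

Microbial ecologists profiling communities with functional-gene
microarrays (or comparable per-gene abundance assays) get a matrix of
hybridization intensities: thousands of gene probes by ~10 replicate
samples per condition. `fmenet` turns such a matrix into a co-occurrence
network and characterizes it the way the molecular-ecological-network
literature expects:

- **Similarity**: Pearson correlation of log10 intensity profiles across
  samples; the network works on `|r|` with the sign kept per edge.
- **Threshold selection by RMT**: the cutoff `s_t` is the transition
  point of the nearest-neighbor spacing distribution (NNSD) of the
  thresholded matrix's eigenvalues from Gaussian-orthogonal-ensemble
  statistics, `P(s) = (πs/2) exp(−πs²/4)` (random structure), to the
  Poisson law `P(s) = exp(−s)` (system-specific structure). No arbitrary
  correlation cutoff.
- **Topology indices**: size `n`, links `L`, average connectivity
  `avgK = 2L/n`, average geodesic distance, average clustering
  coefficient, and the log–log degree-distribution fit ("r of scale
  free").
- **Modules and node roles**: greedy modularity maximization
  (`M = Σ_s [l_s/L − (d_s/2L)²]`), then per-node within-module degree
  `Z_i` and participation coefficient `P_i = 1 − Σ_s (κ_is/κ_i)²`,
  classified as peripheral / connector / module hub / network hub at the
  conventional `Z = 2.5`, `P = 0.62` boundaries.
- **Null models**: Maslov–Sneppen degree-preserving rewiring ensembles
  with per-index means, standard deviations, Welch t contrasts between
  conditions, and empirical-vs-null z-scores.
- **Environmental traits and subnetworks**: gene significance (squared
  profile–trait correlation), degree–trait correlation tables,
  functional-category subnetworks (bundled alkane- and PAH-degradation
  gene sets) with negative-edge fractions and keystone rankings.
- **Synthetic data**: a generator with planted correlation blocks, a
  planted connectivity hub, a diffuse background web, detection-limit
  censoring, and trait drivers — so the whole pipeline is testable
  against known ground truth.

## Worked example

```r
library(fmenet)

# data with known truth: 1000 genes x 10 samples, 5 planted blocks,
# one planted hub, 3 trait drivers
dat <- generate_synthetic(synthetic_config(seed = 1))

bundle <- run_condition(dat$abundance, dat$traits,
                        scan_min = 0.75, step = 0.01,
                        R = 100, seed = 1)
print(bundle$summary, digits = 3)
#>   condition n_original  s_t   n     L scale_free_r avgK   GD avgCC     M
#> 1 synthetic       1000 0.87 961 61078       -0.146  127 2.07 0.808 0.689
#>   n_modules rand_GD_mean rand_GD_sd rand_avgCC_mean rand_avgCC_sd rand_M_mean rand_M_sd
#> 1        15         1.97    0.00134           0.235       0.00247      0.0530   0.00101
```

Reading the row: the NNSD transition selects `s_t = 0.87`; 961 of 1000
genes keep at least one edge; the network's modularity (0.689) towers
over its degree-preserving null ensemble (0.053 ± 0.001) — the planted
module structure — and the five blocks plus hub cluster dominate the 15
detected modules. Checking the ground truth:

```r
nodes <- igraph::V(bundle$network)$name
planted <- dat$truth$block[nodes] > 0
adjusted_rand_index(bundle$partition$membership[nodes][planted],
                    dat$truth$block[nodes][planted])
#> [1] 0.9888453

keystone_rank(bundle$network, k = 3, roles = bundle$roles)$node[1] == dat$truth$hub
#> [1] TRUE
```

Node roles and functional subnetworks:

```r
head(subset(bundle$roles, role != "peripheral"))
sub <- extract_subnetwork(bundle$network, degradation_gene_sets()$alk)
sub$negative_fraction
```

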