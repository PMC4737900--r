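---
title: "Methods: RMT-thresholded molecular ecological networks"
author: "fmenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RMT-thresholded molecular ecological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmenet)
```

## The problem

Functional-gene microarrays report, for each of thousands of gene probes,
a hybridization intensity in each of a handful of replicate soil (or
other environmental) samples. Co-occurrence analysis asks which genes
rise and fall together across those samples, on the premise that
concordant abundance profiles indicate positive association between the
populations carrying them and mutual exclusion indicates negative
association. The result is a *functional molecular ecological network*:
nodes are gene probes, edges are strong pairwise correlations, edge
signs carry the direction of the underlying association.

The statistical crux is the threshold: out of hundreds of thousands of
pairwise correlations estimated from only ~10 samples, which are signal?
`fmenet` implements the random-matrix-theory (RMT) answer, together with
the downstream characterization that practitioners expect: topology
index suites, modularity-based module detection, within-module degree
and participation-coefficient node roles, degree-preserving null
ensembles, trait associations, and functional-category subnetworks.

## Pipeline and model

Starting from a gene x sample intensity matrix (zeros/blanks meaning
"not detected"):

1. **Prevalence filter.** Genes detected in fewer than half the samples
   are removed (`min_fraction = 0.5`, configurable). Correlations
   estimated from sparsely shared detections reflect the detection floor
   rather than ecology.
2. **Log transform.** Intensities are log10-transformed. Undetected
   entries are by default filled with half the smallest detected
   intensity and marked detected (`fill_small`, `small_constant = 0.5`),
   yielding a complete matrix for the eigen-analysis; a `leave_missing`
   policy with pairwise-complete correlations (minimum overlap 5 of 10
   samples) is available.
3. **Similarity.** `S[i,j] = |r(x_i, x_j)|` with the sign of the Pearson
   correlation retained separately. Zero-variance genes are isolated
   (all similarities 0), not errors. Exactly duplicated correlation
   profiles — which produce exactly degenerate rows and spurious zero
   eigenvalue spacings — are collapsed to one representative with a
   mapping kept for re-expansion.
4. **RMT threshold.** For each candidate cutoff `t`, entries below `t`
   are zeroed (unit diagonal kept), genes without surviving neighbors
   dropped, and the eigenvalues of the thresholded matrix computed. The
   nearest-neighbor spacing distribution (NNSD) of the *unfolded*
   spectrum is tested against the two universal laws: the
   Gaussian-orthogonal-ensemble Wigner surmise
   `P(s) = (pi s / 2) exp(-pi s^2 / 4)` (random structure) and the
   Poisson law `P(s) = exp(-s)` (system-specific structure). The
   selected `s_t` is the smallest threshold at which the Poisson fit is
   accepted and stays accepted over consecutive usable thresholds — the
   GOE-to-Poisson transition.
5. **Network.** Every pair with `S >= s_t` becomes an edge weighted by
   its similarity and signed by its correlation; the topology index
   suite (size `n`, links `L`, average connectivity `avgK = 2L/n`,
   average geodesic distance `GD`, average clustering coefficient
   `avgCC`, and the log-log degree-distribution fit "r of scale free")
   is computed on the unweighted graph.
6. **Modules and roles.** Greedy agglomerative modularity maximization
   (merge tree cut at the maximum of
   `M = sum_s [l_s/L - (d_s/2L)^2]`) partitions the network; each node
   gets a within-module degree z-score `Z_i` (population standard
   deviation; `Z_i = 0` for zero spread) and participation coefficient
   `P_i = 1 - sum_s (k_is/k_i)^2`, and is classified peripheral /
   connector / module hub / network hub at the conventional boundaries
   `Z = 2.5`, `P = 0.62`.
7. **Null model.** Degree-preserving double-edge-swap rewiring
   (100 attempted swaps per link, 100 replicates by default) yields the
   null distribution of every index; conditions are contrasted with
   Welch t statistics built from the ensemble means and standard
   deviations, and each empirical index is scored against its own
   ensemble as a z-score.
8. **Traits and subnetworks.** Gene significance (squared correlation of
   a gene's profile with a standardized trait), its correlation with
   node degree, degree-trait correlation tables with significance stars,
   induced subnetworks for functional-category gene sets (bundled `alk`
   and PAH lists) with negative-edge fractions, and top-k keystone
   rankings by connectivity.

## Numerical choices in the RMT step

The literature that defines the threshold criterion leaves the spectral
procedure under-specified; these are the package's choices, each
configurable:

* **Unfolding.** A cubic smoothing spline is fit to the empirical
  cumulative eigenvalue count and eigenvalues are mapped through it; the
  spacings are the first differences, renormalized to mean exactly 1
  (unfolding fixes the mean density to 1 only asymptotically, so the
  sample mean is normalized outright — the mean-1 invariant is asserted
  to 1e-6 in the tests). The spline's effective degrees of freedom
  default to `n/10`, clamped to `[5, 40]`. This adaptivity matters: the
  thresholded similarity matrix is a mixture over many components whose
  secular density a stiff low-df fit cannot track, and the residual
  misfit masquerades as spurious level clustering.
* **Degenerate eigenvalues.** Inside the threshold scan, eigenvalues
  equal to within 1e-8 are collapsed before unfolding. Exact
  multiplicities arise combinatorially from isomorphic fragments of the
  thresholded matrix and would flood the zero-spacing bin with ties that
  say nothing about level repulsion. The standalone `unfold_spectrum()`
  keeps duplicates (a duplicated eigenvalue is one zero spacing) so that
  the two behaviours can be compared.
* **Goodness of fit.** Chi-square on spacing histograms with bins of
  width 0.1 on [0, 3] plus an open tail bin; adjacent bins are merged
  until every expected count reaches 1; degrees of freedom are the used
  bins minus one. The Poisson acceptance level defaults to
  `alpha = 0.01`: with several hundred pooled spacings the chi-square
  is sensitive enough that one minority substructure deviating mildly
  would, at 0.05, mask an otherwise unambiguous transition.
* **Transition rule.** Acceptance must persist for 2 consecutive usable
  thresholds (`persistence = 2`). Far past the transition the network
  shatters into micro-components whose structured spectra leave the
  Poisson regime again; requiring persistence over a short window rather
  than over the entire remaining scan keeps that end-of-scan artifact
  from hiding a clear transition. A threshold is usable only if at
  least `min_eigs = 100` distinct eigenvalues survive.

## Missing data

`fill_small` with `small_constant = 0.5` places fills just below the
detection floor. The constant is deliberately not tiny: with ~10
samples, a fill orders of magnitude below the data is a single
high-leverage outlier that can dominate a Pearson correlation, and any
two genes sharing a fill pattern acquire strong spurious similarity. A
fill near the floor represents "below detection" without inventing
leverage. Users wanting the eigen-analysis untouched by fills can use
`leave_missing`, which switches the correlation step to
pairwise-complete samples with a minimum overlap.

## What the synthetic generator emulates

`synthetic_config()` / `generate_synthetic()` produce data with the
statistical structure the analysis assumes, at the scale of a
10-replicate microarray condition: 1000 genes x 10 samples by default.

* **Blocks.** Five latent-factor blocks (200 + 4 x 100 genes) with
  within-block correlation 0.95 — the regime implied by empirical RMT
  cutoffs near 0.95 — and 30% negative loadings, giving the
  mixed-sign edge structure real networks show.
* **Background web.** The remaining genes load, each along a random unit
  direction, on a 3-dimensional shared factor space (`bg_cor = 0.8`), so
  their pairwise correlations form a continuum rather than a point mass.
  This diffuse community-wide covariation is what keeps the bulk
  spectrum in the GOE regime until high thresholds, as observed for real
  arrays; with i.i.d. noise genes instead, the spectrum is
  system-specific almost everywhere and no meaningful transition exists.
* **Planted hub.** A connectivity keystone is planted as the noiseless
  center of its own 250-gene star cluster (satellite-satellite
  correlation 0.92, hub-satellite `sqrt(0.92) ~ 0.959`). Two properties
  make it the top-connectivity node at whatever threshold the scan
  selects: its cluster outnumbers the largest block, and the hub reaches
  every satellite at a systematically higher correlation than any
  satellite-satellite or member-member pair. A subtler design (a
  low-noise copy of a block factor) fails at this sample size: with 10
  samples the sampling noise of a correlation (~0.38 on the atanh scale)
  exceeds the hub's structural advantage, and lucky ordinary members
  overtake it.
* **Detection floor.** The lowest 5% of intensities are masked as
  undetected — a floor, not random dropout, mimicking hybridization
  censoring.
* **Traits.** Three of five traits are linear in the factors of blocks
  1-3 (correlation 0.8); two are pure noise.

What passing the recovery tests shows — and does not. On this design the
full pipeline selects `s_t` between ~0.85 and 0.95, recovers the planted
blocks with adjusted Rand index >= 0.8 (usually ~1.0), and ranks the
planted hub in the top 3 by degree, in at least 8 of 10 seeds. That
validates the machinery: threshold selection, network construction,
module detection, and ranking do what they claim on data whose truth is
known. It does not show that real soil communities have block-factor
correlation structure, nor that a real network's hubs are ecological
keystones; those remain interpretive claims outside any package's reach.

## Reference fixtures and non-reproducible published values

The intensity data behind the published two-condition soil study that
motivates the acceptance surface are not deposited, so the package
bundles only its printed values (`reference_network_indices()`,
`reference_node_roles()`) and validates arithmetic consistency against
them: `avgK = 2L/n` reproduces the printed connectivities to two
decimals, the module-count and modularity reductions between conditions
reproduce 76.6% and 41.8%, and all printed (Z, P) pairs classify to
their reported roles under the stated boundaries — with one documented
exception: a connector row printing `P = 0.617`, below the stated
boundary of 0.62, which the strict rule classifies as peripheral. The
published average geodesic distances include a value below 1, which no
shortest-path definition can produce; `GD` here is the mean unweighted
geodesic over connected pairs, and the published `GD` values are treated
as non-reproducible.

## Determinism and problem sizes

Every stochastic step takes an explicit seed; rewiring replicates use
seed-derived streams recorded in the ensemble object, and reruns of
`run_condition()` with the same seed are identical. The test suite uses
the default 1000 x 10 synthetic design for end-to-end checks (scan
restricted to [0.75, 0.99], where this design's transition provably
lies), 200-level spectra for the 100-replicate NNSD discrimination
suite, and graphs of <= 8 nodes for exhaustive-search modularity
comparisons; `scripts/acceptance.R` runs one full condition with 100
rewired replicates.

## Known limitations

* Pearson correlation on log intensities is the only similarity
  implemented; rank-based or partial correlations are out of scope.
* Indices are computed on the unweighted graph (weights and signs are
  kept on the edges); weighted modularity and centralities are not
  implemented.
* `Z_i`/`P_i` use unweighted degrees, consistent with defining the
  within-module connectivity as a count of links.
* The exact pairing behind published per-gene degree x per-sample trait
  correlation tables is not stated in the source literature; the
  default here (degree against the gene's abundance-weighted mean trait
  exposure) is one documented construction, with degree-vs-gene-
  significance as an alternative, and no claim of reproducing the
  original tables is made.
* With ~10 samples the sampling noise of individual correlations is
  large; the RMT threshold controls the aggregate false-edge rate but
  individual edges remain uncertain, and the selected `s_t` varies by a
  few hundredths across replicate draws of the same design.
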