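# fccomm

Assumption-lean community detection for weighted functional-connectivity
networks.

Functional brain networks are usually summarized as a dense symmetric
matrix of pairwise temporal correlations between regions of interest
(ROIs). Most community-detection tools in neuroimaging threshold that
matrix and assume communities are assortative (internally dense,
externally sparse), which biases both the partitions and the choice of
the community count K. `fccomm` implements and benchmarks three methods
that need neither assumption, operating on the full weighted matrix:

* a **Gaussian weighted stochastic block model (WSBM)** — edge weights
  between communities *a* and *b* are modeled as
  N(μ<sub>ab</sub>, σ²<sub>ab</sub>) with conjugate
  normal-inverse-gamma priors per block pair, fitted by fast mean-field
  coordinate ascent (compiled inner loop; a 100-ROI fit takes
  milliseconds);
* **spectral clustering** on the unnormalized graph Laplacian
  L = D − S of the similarity S = exp(−d²), d = 1 − r (profile
  correlation), embedding each ROI in the K smallest-|eigenvalue|
  eigenvectors;
* **K-means under the correlation dissimilarity** on the rows of the FC
  matrix.

Around them:

* **K selection** by bootstrap confidence intervals on successive-K
  differences of model evidence (`select_k()`): fit many restarts per K,
  keep solutions that use exactly K communities, and stop at the
  smallest K where the 95% interval of the K→K+1 evidence difference
  reaches zero;
* **partition indices**: silhouette, weighted modularity, variation of
  information, NMI, Calinski–Harabasz, C-index, Dunn, and Hamming
  distance with optimal relabeling (Hungarian algorithm);
* **consensus clustering**: align many seeded solutions to a reference
  by optimal relabeling and take per-ROI majority labels;
* a **synthetic connectome generator** with planted block structure
  (default benchmark: 100 ROIs, five communities of sizes
  30/15/25/20/10) for calibrating everything above against known ground
  truth.

## Worked example

```r
library(fccomm)

# a planted 5-community connectome, block moments drawn from the default ranges
sim <- simulate_connectome(seed = 1)
sim$A
#> <fc_matrix> 100 ROIs, edge weights in [-0.487, 0.938]

# choose K by bootstrap evidence differences (reduced budget)
sel <- select_k(sim$A, k_grid = 2:8, n_runs = 100, n_boot = 500, seed = 1000)
sel
#> <k_selection> K grid 2..8, chosen K* = 5
#>  k k_next      lower     upper evaluable contains_zero stops
#>  2      3  671.26389 671.26389      TRUE         FALSE FALSE
#>  3      4  523.85423 523.85423      TRUE         FALSE FALSE
#>  4      5  444.60304 444.60304      TRUE         FALSE FALSE
#>  5      6  -47.31918 -42.26794      TRUE         FALSE  TRUE
#>  6      7  -75.52321 -62.57271      TRUE         FALSE  TRUE
#>  7      8 -691.15440 -44.50931      TRUE         FALSE  TRUE
```

Transitions 2→3 through 4→5 improve the evidence by hundreds of nats; at
5→6 the difference turns negative (an extra community no longer credibly
helps), so the scan stops and K\* = 5 — the planted value. The final
solution and its quality:

```r
pool <- sel$ensembles[["5"]]          # valid 5-community fits
z <- map_labels(best_fit(pool))       # maximum-likelihood solution
nmi(sim$partition, z)
#> [1] 1
cons <- consensus_partition(lapply(pool$fits, map_labels), scores = pool$loglik)
cons
#> <consensus_result> n=100, K=5 (5 labels used), mean agreement 0.942
```

NMI = 1 means the planted partition is recovered exactly; the consensus
over all valid restarts agrees with it on every ROI (mean per-ROI
agreement 0.94 across restarts). The numbered scripts under `analysis/`
run the full benchmark narrative — generation, K selection and its
stability over 10 instances, method fits and cross-method agreement,
silhouette curves and quality indices, consensus — writing their tables
under `results/`.

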