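---
title: "Assumption-lean community detection for weighted connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assumption-lean community detection for weighted connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fccomm` benchmarks three community-detection methods that operate directly
on a dense weighted functional-connectivity (FC) matrix — no thresholding,
no assumption that communities are assortative — together with a
likelihood-based rule for choosing the number of communities K, a battery
of partition-quality indices, and a consensus procedure. This vignette is
the package's account of the underlying models, the choices that were
genuinely open, and what the synthetic benchmark does and does not show.

## The data model

The observed object is an $n \times n$ symmetric matrix $A$ of pairwise
temporal correlations between $n$ regions of interest (ROIs), with unit
diagonal. The diagonal carries no randomness and is excluded from every
computation.

### Gaussian weighted stochastic block model

Each ROI $i$ carries a latent community label $z_i \in \{1,\dots,K\}$ with
flat prior $1/K$. Conditional on the labels, the edge weights over
unordered pairs are independent Gaussians with block-pair-specific moments:

$$P(A \mid z, \mu, \Sigma) = \prod_{i<j}
  \mathcal{N}\!\left(A_{ij} \mid \mu_{z_i z_j},\, \sigma^2_{z_i z_j}\right).$$

The $K \times K$ symmetric matrices $\mu$ and $\Sigma = (\sigma^2_{ab})$
are the mean and variance of connectivity between (and within) community
pairs. Nothing forces within-community means to exceed between-community
means, which is what lets the model express disassortative and
core–periphery structure. Each unique block pair $a \le b$ carries a
conjugate normal-inverse-gamma (NIG) prior — $\sigma^2 \sim
\mathrm{IG}(\alpha_0, \beta_0)$, $\mu \mid \sigma^2 \sim \mathcal{N}(m_0,
\sigma^2/\kappa_0)$ — the conjugate exponential family for the natural
parameters $\eta_{ab} = (\mu/\sigma^2, -1/\sigma^2, -\mu^2/\sigma^2)$.
Defaults are weakly informative ($m_0 = 0$, $\kappa_0 = 1$, $\alpha_0 = 2$,
$\beta_0 = 0.1$) and overridable via `wsbm_prior()`.

### Inference: two flavors of mean-field coordinate ascent

`vb_fit()` approximates the posterior under the mean-field factorization
$q(z)\,q(\eta)$. Responsibilities are updated **sequentially, node by
node** (exact coordinate updates, so the recorded objective is provably
non-decreasing; a synchronous sweep would lose that guarantee), and the
NIG factors are updated in closed form from responsibility-weighted
sufficient statistics. The inner loop is compiled (RcppArmadillo); one fit
of an $n = 100$ matrix takes a few milliseconds, which is what makes the
multi-restart selection protocol below affordable.

Two label-update flavors are exposed, and the difference matters more
than it first appears:

* `method = "vb"` — full variational Bayes: edges are scored by expected
  log densities under the NIG factor. The extra $-1/(2\kappa)$ and
  digamma terms act as a *per-edge complexity penalty* on thinly
  populated blocks. On clean block-structured data this Bayesian Occam
  effect is so strong that any community beyond the true number is
  emptied before convergence — even a run initialized *at* a valid
  (K+1)-community split collapses back. Statistically elegant at fixed
  K, but it starves the successive-K comparison: no valid overfitted
  solutions ever enter the pools.
* `method = "vem"` (default) — variational EM: edges are scored with the
  MAP block parameters ($\hat\mu = m$, $\hat\sigma^2 = \beta/(\alpha +
  3/2)$, the joint NIG maximizer); the objective is the EM lower bound
  including the log prior density at the MAP point. Surplus communities
  persist as ordinary local optima, which is exactly what the
  valid-solution bookkeeping of the K-selection protocol needs.

Whichever flavor fits, every returned object also carries `elbo`: the
full-VB evidence lower bound evaluated at the fitted posterior. The raw
VEM objective is *not* a usable evidence proxy — its parameter-prior term
is a density that can reward extra small-variance blocks — so model
comparison always goes through the ELBO.

Initialization is a k-means++-style prototype draw: K ROIs are chosen
with probability proportional to squared correlation distance from the
prototypes already picked, and every ROI is softly assigned by the
correlation of its connectivity profile with each prototype
(concentration 4). Restarts stay diverse (different prototype draws find
different local optima, including the overfitted ones), yet most starts
land in the basin of a well-separated planted structure. A plain
Dirichlet(1) draw per node is kept as `init = "dirichlet"`, but it almost
never reaches the planted optimum even at strong signal (5/100 runs on a
two-block instance where the prototype scheme scores 100/100): the
planted basin is wide — 20%-corrupted initializations fall back into
it — but a uniformly random start is simply never inside it.

## Choosing K: bootstrap intervals on successive evidence differences

The protocol (`select_k()`):

1. fit the model `n_runs` times at each K on the grid (reference budget:
   1000 restarts, K = 2..20; the benchmark uses 100 restarts, K = 2..8),
   keeping only *valid* solutions — those whose MAP labels use exactly K
   communities;
2. pool a per-fit model-fit statistic for each K — by default the ELBO,
   because the successive-K comparison is a Bayes factor
   $\log P(A \mid M_K) / P(A \mid M_{K+1})$ on marginal likelihoods,
   which the ELBO approximates. The plug-in likelihood is available but
   gains a spurious ~10 nats per overfit community from fitting noise,
   so it never flattens;
3. for each transition K→K+1, bootstrap the difference and take the
   percentile 95% interval. The default resampling unit is the
   *resampled-pool maximum* (`mode = "max_diff"`): the evidence estimate
   for a model is its best restart, and resampling pools propagates
   restart-to-restart optimizer uncertainty. Resampling single draws
   (`"pairwise"`) mixes distinct local optima whose spread at small K is
   hundreds of nats, which floods every interval;
4. the chosen K* is the smallest K whose interval *reaches* zero (lower
   bound ≤ 0): either the interval brackets 0, or it lies entirely below
   0 — meaning K+1 is credibly worse, a fortiori a reason to stop. If a
   pool is empty the transition is skipped; if nothing stops the scan,
   the grid maximum is returned with an explicit warning rather than a
   silent failure.

The final solution at K* is the valid fit with maximum plug-in
log-likelihood (ties broken toward the smaller seed).

On the benchmark configuration (below), this recovers K* = 5 on 10 of 10
independently generated instances at the reduced budget, in roughly 1.5 s
per selection.

## The baselines

**Correlation K-means** (`kmeans_fit()`): Lloyd iteration on the rows of
$A$ under the dissimilarity $d = 1 - r$ (Pearson correlation of
connectivity profiles). Centroids are arithmetic means of member rows —
a surrogate, since the correlation metric has no closed-form centroid
minimizer — so a centroid update can in principle raise the objective;
when it would, the previous assignment is kept and the restart stops,
which keeps the recorded objective non-increasing. Emptied clusters are
reseeded at the worst-fitting point to hold K fixed. Best of 10 restarts
by within-cluster dissimilarity.

**Spectral clustering** (`spectral_fit()`): similarity $S = \exp(-d^2)$,
unnormalized Laplacian $L = D - S$ with the similarity diagonal excluded
from the degrees (each row of $L$ then sums to zero), embedding by the K
eigenvectors whose eigenvalues are smallest in absolute value (taken
literally, though $L$ is PSD and plain smallest would coincide), and
Euclidean k-means on the embedded rows without length normalization.

For both baselines the final solution across seeded replications is the
one with the highest silhouette — the customary rule, used here even
though the silhouette curve itself is an unreliable K selector (see
below).

When row-correlations are computed between rows $i$ and $j$ of a matrix
with unit diagonal, coordinates $i$ and $j$ carry the forced value 1;
they are excluded by default (toggleable) to avoid diagonal-induced bias.

## Partition indices

`silhouette_index()`, `modularity_index()`, `vi_distance()`, `nmi()`,
`ch_index()`, `c_index()`, `dunn_index()` and `hamming_distance()` follow
the standard constructions on the correlation dissimilarity (natural
logarithms throughout). Conventions worth stating:

* VI is computed as $H_1 + H_2 - 2I$; the variant with a single $I$
  (which appears in some write-ups) fails the defining property
  $VI(C, C) = 0$ and is treated as a typo.
* NMI uses geometric-mean normalization $I/\sqrt{H_1 H_2}$
  (arithmetic-mean behind a flag); two trivial partitions score 1, one
  trivial partition scores 0.
* Silhouette assigns score 0 to vertices in singleton communities.
* Modularity zeroes the unit diagonal before computing weights and
  degrees (toggleable); negative weights enter as-is.
* The Hamming distance between partitions minimizes the mismatch
  proportion over all label permutations via an $O(K^3)$ Hungarian
  assignment (written in-package; tests cross-check it against
  exhaustive $K!$ search).

## Consensus

`consensus_partition()` aligns every solution to a reference (maximum
log-likelihood for model pools, maximum silhouette for baselines, or an
explicit index) by the Hamming-minimizing permutation and takes the
per-ROI majority label, ties toward the smaller label. Consensus of
relabeled copies of one partition reproduces it up to permutation; 100
copies with 5% corrupted labels are denoised exactly. If the consensus
uses fewer than K labels it is returned with `valid = FALSE` rather than
rejected, mirroring the valid-solution bookkeeping.

## The synthetic benchmark, and what it does not show

`simulate_connectome()` plants $n = 100$ ROIs in five communities of
sizes 30/15/25/20/10 and samples each edge from the Gaussian of its block
pair. Exact block moments for this design exist only as published
heatmaps, so the generator draws them from documented ranges chosen to
mimic the spread of within- and between-system connectivity in large
adult resting-state cohorts: within-community means uniform on
$[0.3, 0.6]$, between-community means on $[-0.05, 0.2]$, block standard
deviations on $[0.05, 0.15]$. A `"strong"` preset (within 0.6, between
0, sd 0.05) provides a regime where every method should recover the
planted partition exactly. Sampled weights are left un-clipped by default
so the generative model is exactly the Gaussian likelihood; `clip = TRUE`
truncates to $[-1, 1]$ when correlation-scale interpretability matters.

Two observed behaviors are worth recording honestly:

* The silhouette curve is an unreliable selector of K for the baselines.
  Across ten independently drawn default-range instances, the spectral
  silhouette peak lands at K = 5 only once (peaks 2–8); the K-means
  silhouette peak usually finds 5. Which method's curve peaks where is a
  property of the drawn block moments, not of the algorithms: at strong
  signal both curves peak at the truth. This is consistent with the
  general finding that post hoc indices favor wrong K under weak or
  non-assortative mixing, and it is why the likelihood-based rule is the
  package's selector of record.
* Unnormalized spectral clustering is the most instance-sensitive method
  at the default signal. When the smallest community's contrast
  (within-mean minus between-mean relative to the noise sd) is weak, its
  rows scatter in the Laplacian embedding and Euclidean k-means spends
  clusters on the scatter; recovery NMI across ten instances ranged
  0.69–1.0 while the weighted SBM and correlation K-means recovered the
  truth on all ten.

The generator emulates block-constant Gaussian weights only. Real FC
matrices have heavier tails, spatially autocorrelated noise,
subject-level variability, and motion artifacts; passing these benchmarks
shows the machinery is correct and the selection protocol calibrated on
its own generative model, not that K chosen on a real cohort is "right".
Cohort-scale results (e.g. K around 11 for adult and 15 for infant
connectomes) require restricted neuroimaging data and are out of scope;
the pipeline runs unchanged on any user-supplied FC matrix in delimited
text.

## Numerical choices

* Convergence: relative objective change below `tol = 1e-6`, cap 200
  iterations. The objective is checked non-decreasing to 1e-6 in tests.
* Posterior variance guard: NIG scale floored at 1e-12; block-count
  sufficient statistics floored at 0 against floating-point drift.
* MAP labels break responsibility ties toward the smaller community
  index; majority-vote ties in consensus do the same.
* All stochastic stages take explicit integer seeds and restore the
  caller's RNG state; ensembles derive restart seeds as `base_seed + r`.
* Problem sizes in the tests and acceptance runs: grid K = 2..8, 100
  restarts per K, 500 bootstrap replicates, 10 master seeds — the
  reduced-budget configuration at which the whole benchmark runs in
  about a minute; the reference budgets (1000 restarts, 2000 bootstraps,
  K up to 20) are plain parameter changes.

## Known limitations

* The Gaussian edge model is dense: no sparse/presence component, no
  degree correction, no mixed membership.
* VEM's valid-solution rate decays with K (e.g. from 100/100 at K = 2–4
  to a handful at K = 8 on the benchmark); far above the true K the
  pools thin out and transitions become unevaluable, which the selection
  reports rather than hides.
* The Hungarian consensus aligns solutions at a fixed K only; consensus
  across different K values is out of scope.
* The correlation-metric k-means objective is only guaranteed
  non-increasing because of the explicit safeguard; the arithmetic-mean
  centroid is a surrogate under that metric.
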