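---
title: "Density-aware spectral clustering: model, heuristics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-aware spectral clustering: model, heuristics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speclust)
```

## The model

`speclust` clusters samples of one or more continuous feature-by-sample
matrices (typically log2 expression) by spectral decomposition of a fused
similarity graph. The pipeline is: per-view kernel, graph combination,
kNN sparsification, row normalisation, graph diffusion, normalised
Laplacian, automatic choice of the cluster number K, and Gaussian-mixture
clustering of the unit-row eigenvector embedding. Every stage is exported
so the pipeline can be taken apart; `spectral_cluster()` composes them.

### The adaptive density-aware kernel

Similarity between samples $i$ and $j$ is
$$A_{ij}=\exp\!\left(\frac{-d^2(s_i,s_j)}{\sigma_i\sigma_j\,(\mathrm{CNN}_{ij}+1)}\right),$$
with $d$ the Euclidean distance on the columns as given (no internal
centring or scaling — standardisation is deliberately the caller's
decision, since omic matrices are usually already normalised and
log-transformed). Two devices make the kernel self-tuning:

* **local scale** $\sigma_i$: the distance from $s_i$ to its $P$-th
  nearest neighbour. Dense regions get narrow bandwidths, sparse regions
  wide ones, so no global bandwidth needs tuning.
* **common nearest neighbours** $\mathrm{CNN}_{ij}$: the overlap of the
  two samples' $S$-nearest-neighbour sets. A shared dense neighbourhood
  multiplies the bandwidth by up to $S+1$, amplifying within-cluster
  similarity. With $\mathrm{CNN}=0$ the kernel equals the Zelnik-Manor
  self-tuning kernel exactly (available as `kernel = "zm"`).

Self is excluded from all neighbour sets: including it would only add a
constant to every $\sigma$ index and every CNN count, and "common
neighbours of a pair" naturally refers to other points. Neighbour ties
are broken by ascending sample index so results are reproducible.
Duplicated samples would give $\sigma_i = 0$; we then fall back to the
smallest strictly positive neighbour distance, and to 1 if all distances
vanish, keeping the kernel finite on degenerate input.

Defaults $P=3$, $S=7$ favour local structure; larger values emphasise
global structure. Both are plain integers in units of "neighbours".

### Integration and diffusion

Per-view similarity graphs over a common sample set are summed with equal
weights (views judged too noisy or structurally unrelated should be
excluded upstream; no weights are learned). Views are aligned by sample
id and any mismatch in the sample sets is a hard error raised before any
numeric work. The combined graph is then

1. sparsified: each row keeps its $Z$ strongest off-diagonal entries
   plus the diagonal (ties to the lower index). Retaining the diagonal
   guarantees positive row sums, so the next step is always defined, and
   composes with the $+I$ term of the diffusion;
2. row-normalised to a transition matrix;
3. diffused: $Q_1 = A$, $Q_t = A Q_{t-1} A^\top + I$, returning
   $Q_{\text{iters}}$. This recursion is the efficient equivalent of
   diffusion on the tensor-product graph: affinity flows along paths that
   the neighbourhood structure supports, which reinforces cluster
   structure shared between views and damps view-specific noise.

Defaults $Z=10$ and $\text{iters}=5$; diffusion performance is flat in a
broad range around them. The recursion is applied literally with
$A^\top$ even though the row-normalised $A$ is asymmetric, and no
re-symmetrisation happens between iterations; the final $A^*$ is
symmetrised once, as $(A^*+A^{*\top})/2$, because the downstream
eigendecomposition assumes a symmetric operator. Whether to symmetrise
at the end is a genuine design freedom; a single final symmetrisation is
the choice made here and changes nothing for symmetric inputs.

### Spectral clustering

With $D$ the diagonal of row sums of $A^*$, the normalised Laplacian is
$L = D^{-1/2} A^* D^{-1/2}$; its eigenvalues lie in $[-1, 1]$ and for a
graph of $k$ well-separated blocks the leading $k$ eigenvalues crowd near
1. The leading $k^*$ eigenvectors (descending eigenvalues) are stacked
as columns and every row is renormalised to unit length; rows that are
exactly zero — possible only on degenerate graphs — are mapped to the
first basis vector rather than NaN. Eigenvector signs are fixed by
making the largest-magnitude component positive, which makes the dip
statistics and the mixture initialisation reproducible (the dip is
reflection-invariant, so this is purely a determinism device).

The embedding is clustered with a Gaussian mixture model via `mclust`:
full covariance with a conjugate prior for regularisation and mclust's
deterministic model-based hierarchical initialisation. If the
full-covariance fit degenerates (frequent when clusters collapse to
near-points on the unit sphere), diagonal and spherical models are tried,
then k-means with 10 restarts. A deterministic initialisation was chosen
over random restarts so that a fixed seed gives byte-identical labels.

## Choosing the number of clusters

**Eigengap.** $k^* = \arg\max_{n=2..maxK} (\lambda_n - \lambda_{n+1})$,
ties to the smaller $n$. Reliable for Gaussian-like clusters, where the
spectrum has a clean elbow.

**Multimodality gap.** Informative eigenvectors are multimodal — they
take distinct values on distinct clusters — while eigenvectors past the
cluster structure are unimodal. Multimodality is measured by Hartigan's
dip statistic $z_j$ for eigenvector $j$; the differences
$d_j = z_{j+1} - z_j$ locate the transition. Rather than taking the raw
arg-min of $d$, which is vulnerable to shallow local minima early in the
series, the search keeps the deepest drop seen so far and walks forward:
a later drop replaces the stored one only if it is at least $f$-fold more
negative, and the walk gives up $c_{\max}$ positions past the stored
drop. Defaults $c_{\max}=7$, $f=2$. The first difference is always
skipped because the leading eigenvector is near-constant, making the
first drop uninformative. The chosen drop position $j$ means eigenvectors
$1..j$ are informative, so $K = j$. We compute $maxK+1$ dip statistics so
that $K = maxK$ remains selectable. If no difference is negative the
series carries no structure and K defaults to 2 with a warning.

The counter resets whenever the stored drop is replaced (it counts
positions ahead of the *stored* drop); the alternative global counter
would end the search prematurely after a replacement.

**Kernel tuning.** On non-convex shapes a fixed $P$ can fail: the dip
path can therefore rebuild the graph for $P = 1..10$ and keep the kernel
whose dip series contains the most negative difference (sharpest
multimodal-to-unimodal transition), ties to the smaller $P$. Only $P$ is
tuned; $S$ stays fixed. Tuning applies to the dip method only — the
eigengap path always uses the fixed kernel — and diffusion ahead of the
dip analysis is on by default with a flag to disable
(`dip_diffuse = FALSE`).

### The dip statistic

The dip of a sample is the smallest sup-norm distance between its
empirical CDF and any unimodal CDF (convex, then concave, with an atom
permitted at the mode). It lies in $(0, 0.25]$, is invariant under affine
maps, and equals $1/(2n)$ for a perfectly regular sample and $0.25$ for
two balanced point masses. The atom-at-the-mode case matters here more
than in typical applications: eigenvectors of a sparsified graph contain
many exact zeros, and without the atom the statistic would overshoot its
theoretical bound on such data. The implementation (in C++) iteratively
fits the greatest convex minorant and least concave majorant of the ecdf
on a shrinking modal interval, committing the largest deviation outside
the interval; at the modal boundary the pre-/post-jump ecdf corner is
used so the mode's atom is not charged. The test suite checks it to
$10^{-9}$ against an independent brute-force oracle that minimises the
deviation by linear programming over explicit piecewise-linear unimodal
candidates, one LP per candidate mode.

## FASP for large N

Spectral clustering costs $O(N^3)$; k-means is linear. For large N,
`fasp = TRUE` first compresses the samples to $m$ centroids (k-means,
10 restarts, joint across views so each centroid represents the same
samples in every view), runs the whole pipeline on the $m \times m$
centroid graph, and propagates centroid labels back to samples. Default
$m = 900$, chosen as a size at which the spectral stage is inexpensive
while typical cell-type structure is heavily oversampled. Centroids are
unweighted in the kernel: occupancy weighting is a plausible variant but
keeps the kernel's neighbour counts comparable between centroids, and on
blob-structured data the unweighted version already reproduces the full
pipeline's partition. Rare empty-cluster starts are re-seeded.

## Simulated benchmarks

The generators produce the regimes the method is designed around; they
are first-class, tested code, and each regime ships as a preset
(`cluster_preset()`):

* `blobs5` — 5 isotropic Gaussian clusters of 50 points in 2-D, centres
  on a circle with neighbouring centres 12 sd apart: the clean separated
  case both K heuristics must solve.
* `blobs10`, `blobs20` — 10 and 20 clusters of 50 points with centres on
  a regular simplex 8 sd apart in 10 and 20 dimensions: many moderately
  overlapping blobs, the single-cell-like regime.
* `multiview3` — two views, 300 shared samples in 3 balanced clusters,
  500 features per view; each view has its own random unit-variance
  centres plus independent Gaussian noise of sd 5.5. The noise level is
  calibrated to sit just past the single-view detection threshold: one
  view alone often misses K = 3 while the fused graph, which averages
  independent noise, recovers it. That contrast is the property the
  integration step exists to demonstrate, and the test suite verifies
  both halves of it.
* `spirals` — two interleaved Archimedean spiral arms (1.5 turns,
  noiseless): non-convex structure where the untuned kernel fails and
  kernel tuning yields a perfect partition.
* `worms` — two concentric curved bands (radii 3 and 3.8, jitter sd
  0.08) with a 2:1 density ratio: the bands pass close enough that the
  scale-only kernel bridges them, while the common-neighbour term keeps
  them apart — the regime exhibiting the density-aware kernel's
  advantage.

What passing these benchmarks shows — and what it does not: the
generators produce isotropic Gaussian or noiseless geometric structure
with balanced cluster sizes and no batch effects, dropouts, heavy tails
or feature correlation. Success here validates the algorithmic claims
(K recovery, integration, tuning, compression), not performance on any
particular real dataset; real omic matrices should be log-transformed
and variance-filtered (`cv_filter()`) before clustering, and results
inspected through the fit's diagnostics.

Problem sizes in the routine test run are kept small (tens to hundreds
of samples per fit, 25 seeds per regime, one large-N FASP run at
N = 5000) — large enough to pin the qualitative regimes down, small
enough that the whole suite runs in minutes on a laptop.

## Numerical choices and limitations

* Eigengap ties break toward smaller K (prefer the simpler model);
  kernel-tuning ties toward smaller P.
* `max_k` defaults to 10 and is configurable; candidate counts above
  `max_k` are never examined.
* Row sums after sparsification are provably positive, so the
  stochastic normalisation cannot divide by zero; diffusion checks for
  non-finite intermediates.
* The symmetry check before eigendecomposition uses a $10^{-10}$
  tolerance; eigen-pairs come from LAPACK's symmetric solver.
* Zero-mean features in `cv_filter()` get infinite coefficient of
  variation (kept, with a warning) rather than NaN.
* NMI is normalised by the arithmetic mean of the two entropies; other
  normalisations exist, and the output labels the variant.
* Missing values anywhere in an input matrix are an error naming the
  offending feature and sample; imputation is out of scope.
* Views must share their full sample set: partial overlap (missing
  samples in some views) is not supported.
* Binary data (for example somatic mutation matrices) are outside the
  kernel's domain, which assumes continuous values.
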