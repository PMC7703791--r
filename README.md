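# speclust

Density-aware spectral clustering for single- and multi-view omic data.

## The problem

Unsupervised clustering of continuous feature-by-sample matrices — bulk
multi-omic patient profiles or single-cell RNA-seq transcriptomes — faces
three recurring difficulties: similarity graphs must adapt to local scale
and density, several data views over the same samples must be integrated
into one structure while view-specific noise is suppressed, and the number
of clusters K has to be chosen automatically, including for non-convex
cluster shapes where Gaussian heuristics fail. `speclust` addresses all
three with a spectral clustering pipeline for analysts working with
expression-like data (log2-transformed, features in rows, samples in
columns).

## Method

**Similarity.** For samples $s_i, s_j$ with Euclidean distance $d(s_i,
s_j)$, the similarity kernel is

$$A_{ij} = \exp\!\left(\frac{-d^2(s_i,s_j)}{\sigma_i\,\sigma_j\,
(\mathrm{CNN}(s_i,s_j)+1)}\right)$$

where $\sigma_i$ is the distance from $s_i$ to its $P$-th nearest
neighbour (self-tuning local scale, default $P=3$) and
$\mathrm{CNN}(s_i,s_j)$ is the number of shared members of the two
samples' $S$-nearest-neighbour sets (default $S=7$). Shared dense
neighbourhoods widen the bandwidth and so strengthen within-cluster
similarity; with no shared neighbours the kernel reduces to the
Zelnik-Manor self-tuning kernel, which is also available for comparison.

**Integration and diffusion.** Per-view graphs are summed (views must
share their sample set), sparsified to each row's $Z=10$ strongest
neighbours, row-normalised, and smoothed by graph diffusion
$Q_1 = A$, $Q_t = A\,Q_{t-1}A^{\top} + I$ for $t = 2..5$ — an efficient
equivalent of tensor-product-graph integration that reinforces structure
shared across views.

**Clustering.** From the normalised Laplacian
$L = D^{-1/2} A^{*} D^{-1/2}$ the leading $k^*$ eigenvectors are stacked,
rows are renormalised to unit length, and samples are clustered with a
Gaussian mixture model.

**Choosing K.** Two heuristics: the classical *eigengap*
($k^* = \arg\max_{n\ge 2}(\lambda_n - \lambda_{n+1})$), and the
*multimodality gap* — Hartigan's dip statistic is computed for successive
eigenvectors, whose consecutive differences locate the last substantial
drop from multimodal (informative) to unimodal (uninformative)
eigenvectors. The dip path can additionally tune $P$ by maximising the
multimodality gap, which is what makes non-convex shapes such as
interleaved spirals clusterable. The dip statistic itself is implemented
in compiled code and verified against a brute-force linear-programming
oracle in the test suite.

**Large N.** `fasp = TRUE` compresses samples to $m$ k-means centroids
(default 900), runs the spectral pipeline on centroids only (spectral
clustering is cubic in N, k-means linear), and propagates labels back.

## Worked example

```r
library(speclust)
sim <- cluster_preset("blobs5", seed = 42)   # 5 Gaussian clusters, 2-D
fit <- spectral_cluster(sim, method = "dip")
summary(fit)
ari(fit$labels, sim$labels)
```

```
Density-aware spectral clustering
  samples: 250 
  K = 5 selected by dip
  cluster sizes: 50, 50, 50, 50, 50 

Selection diagnostics:
  k          drop        dip
  1 -0.0004072539 0.09268813
  ...
  5 -0.0761106552 0.09505596
  6  0.0049410677 0.01894531
  ...

ARI vs truth: 1
```

The `dip` column is the dip statistic of eigenvector $k$: eigenvectors
1–5 are strongly multimodal (≈ 0.09) because they separate clusters,
eigenvector 6 collapses to near-unimodal (0.019), and `drop` shows the
resulting large negative difference at position 5 — hence K = 5. With
`method = "eigengap"` the same data give K = 5 from the spectrum of the
Laplacian, and the clustering recovers the generating labels exactly
(adjusted Rand index 1).

A shell front-end wraps the same functions:

```sh
Rscript inst/scripts/spectrum-clust simulate --preset blobs5 --seed 4 --out demo/
Rscript inst/scripts/spectrum-clust run --input demo/view1.tsv --method eigengap --out demo/res
Rscript inst/scripts/spectrum-clust eval --labels demo/res_labels.tsv --truth demo/truth.tsv
# NMI 1.000000 / ARI 1.000000
```

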