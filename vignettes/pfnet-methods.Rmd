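---
title: "Planar filtered co-expression networks and their multiscale decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planar filtered co-expression networks and their multiscale decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`pfnet` infers a sparse gene co-expression network by *planar filtering*:
gene pairs are ranked by co-expression similarity and greedily embedded on
a topological sphere, accepting a pair only if the graph stays planar.
The resulting planar filtered network (PFN) retains at most
$3(|V| - 2)$ edges (the Euler bound for simple planar graphs) and keeps,
for each gene, its strongest partners while preserving the maximum
spanning tree of the similarity structure.  The network is then decomposed
into a multiscale cluster hierarchy, per-scale hub genes, and
cluster-trait associations.

This vignette explains the model and the numerical choices; the README
shows a worked example.

# Similarity and filtering

Pairwise similarity can be Pearson correlation, a plug-in mutual
information estimate (equal-frequency discretization into
$\lceil\sqrt{M}\rceil$ bins for $M$ samples), or Euclidean distance mapped
to $s = 1/(1+d)$.  Only the *ranking* of pairs feeds the embedding, so any
strictly decreasing transform of a distance is equivalent; $1/(1+d)$ is
used for boundedness.

Pairs are filtered at FDR $< 0.05$ before ranking.  For correlations the
route is analytic: a two-sided p-value from Fisher's Z-transformation,
$z = \operatorname{atanh}(r)\sqrt{n-3}$, followed by Benjamini–Hochberg
adjustment.  For mutual information and Euclidean similarity, which have
no convenient null, a global permutation FDR is used: each gene's samples
are permuted independently, and the FDR of an observed similarity $s$ is
the ratio of the mean permuted count of similarities $\ge s$ to the
observed count $\ge s$.

Retained pairs are sorted by descending $|s|$ (the sign is kept as an edge
attribute; ranking by signed similarity is available via
`rank_by = "signed"`), with ties broken lexicographically by node
identifiers so that reruns are bit-identical.

# Planar embedding

`is_planar()` implements the left-right planarity criterion in C++,
linear in the graph size per test.  `build_pfn()` walks the ranked list,
testing each pair against the current graph.  Three exact shortcuts keep
the construction fast without changing any decision: an edge joining two
components is always planar (a bridge); an edge inside a component that
already has $3(n_c - 2)$ edges is never planar (the component is a maximal
planar graph); otherwise the left-right test runs on that component only.

Because a subgraph of a planar graph is planar and the embedded graph only
grows, a pair that fails against the *current* graph can never be accepted
later.  This makes rejections permanent and justifies the batched
screening phase: when the sliding-window acceptance rate (window of 1000
tested pairs) drops below 10%, blocks of `batch_size` (default 1000 per
worker) candidates are pre-tested independently against the frozen graph,
and only survivors proceed to serial embedding in rank order.  Screening
decisions do not depend on evaluation order, so a parallel schedule and
the sequential fallback give identical output — the test suite asserts
edge-for-edge equality with brute-force serial embedding.

Construction stops at the first of: list exhausted; edge count reaching
`saturation` (default 0.95) of the Euler bound; or cumulative rejections
reaching 20 per node.  Pairs rejected during screening count against that
budget (they are genuine rejections of the serial order).  The fired
condition is recorded on the returned graph.

# Multiscale clustering

Compactness of a cluster $V_l$ is
$$\nu_l(\alpha) = \frac{\overline{SPD}}{\log(|V_l|)^\alpha},$$
the mean within-cluster shortest-path distance normalized by the
small-world scaling of path lengths with size; $\alpha$ is the resolution
parameter and $\log$ is natural (diameters of these networks grow like
$\ln|V|$).  Edge lengths are $1 - |s|$ by default (`"inverse"` available
for unbounded similarities); paths use Dijkstra since lengths are
nonnegative, with Bellman–Ford behind a flag.

One divisive step (`k_split`) partitions a cluster by k-medoids (PAM with
its deterministic BUILD initialisation) on the shortest-path distance
matrix, then corrects boundary nodes: a node adjacent to two or more
clusters is reassigned to the cluster maximizing its summed local path
index $LPI = A^2 + \epsilon A^3$ ($\epsilon = 0.01$), iterating
asynchronous sweeps to a fixed point.  The LPI diagonal is zeroed so a
node's own closed walks do not bias the comparison.  The number of
clusters is chosen by Newman modularity $Q$ on the unweighted network,
searching $k = 2, 3, \dots$ until no $k$ within `dk = 10` of the best
improves $Q$; a best $Q \le 0$ means no meaningful split.  Label groups
that the boundary correction disconnects are separated into connected
components, so every cluster in the hierarchy induces a connected
subgraph.

A child cluster's *characteristic resolution* $\alpha^c_l$ is the largest
grid value, not exceeding the parent's $\alpha^c$, at which the child is
strictly more compact than the parent at the same $\alpha$.  Because
$\nu_l(\alpha)/\nu_o(\alpha)$ is increasing in $\alpha$ for a smaller
child, the admissible set is a lower interval of the grid, so "the largest
admissible value" and "the value at which compactness first holds" bound
the same interval; the maximum is reported, and the full admissible set is
returned for inspection.  The default grid is geometric, 50 points over
$[0.02, 10]$ (observed characteristic ranges on real co-expression
networks span roughly 0.03–7); the root's $\alpha^c$ is the grid maximum.
A split is accepted iff at least one child has a characteristic
resolution (strictly better compactness; ties reject).

Significance of an accepted child is assessed against a random planar
null: a random maximal planar network of the parent's size grown by
triangle-face node insertions (a T2 move: a new node is connected to the
three corners of a uniformly chosen face), carrying the parent's permuted
edge weights (resampled with replacement when the triangulation has more
edges than the parent).  `n_rand = 100` connected subsets of the child's
size are drawn by snowball sampling; an arbitrary node subset of a
sparse graph is almost surely disconnected and would have infinite
pairwise distances, so the sampler grows each subset from a random seed
node through the neighbourhood frontier.  The p-value uses the
add-one estimator $p = (1 + \#\{\nu' \le \nu_l\})/(1 + n_{rand})$, which
cannot return 0 at finite Monte-Carlo size.  Recursion continues into
children with $p \le 0.05$ and at least 4 nodes; clusters of size 2–3 are
kept as leaves but never scored (for $|V| \le e$ the log-normalization is
degenerate).

All children of an accepted split enter the hierarchy, so children always
partition their parent and the leaves partition the roots.
`partition_at_alpha()` realises the hierarchy as one flat partition per
scale by assigning each node to its deepest significant cluster with
$\alpha^c \ge \alpha$.

# Hub analysis

Within-cluster connectivity $c^w(v_i, \alpha)$ sums the similarity
magnitudes of $v_i$'s edges to co-members under the partition at
$\alpha$.  The scale set $\Phi$ comprises grid values whose partition
contains at least one significant cluster.  Scales are grouped by
k-medoids on Euclidean distances between the $C^w$ columns; the number of
groups is chosen by combining four internal validity indices — average
silhouette width, permutation-normalized Hubert Gamma (100 relabelings),
Dunn's index, and a separation index — through the summed log of
normalized ranks, $\mathrm{score}(k) = \sum_m \log(\mathrm{rank}(k,m) /
(|\Phi|-1))$, minimized with smallest-$k$ tie-break.  The literature
attaches several definitions to "separation index"; here it is the mean
between-cluster distance over the mean within-cluster distance, which
measures average separation where Dunn measures worst-case separation.

Per scale, each cluster's nodes are scored against `n_s = 100` random
planar networks of the cluster's size (T2 topology, resampled cluster
weights): $p_i(\alpha)$ is the add-one estimate of the chance that a
random node is at least as connected.  Evidence is combined within a
scale group $A_l$ as $S_i = \sum_{\alpha \in A_l} -\log_{10} p_i(\alpha)$
(the printed inverse-chi-square form, not the classical $-2\ln p$
variant).  The null for $S_i$ shuffles the node-by-scale p-value matrix
over both dimensions `N_s = 100` times and pools all resulting null
statistics; pooling is essential — with per-node nulls alone the smallest
achievable p-value, $1/(N_s+1)$, could never clear a Bonferroni
correction for the network size.  Hubs are nodes with Bonferroni-corrected
$p < 0.05$ per scale group; *multiscale hubs* are the intersection across
groups.

# Cluster-trait association

Each cluster is summarized by its module eigengene — the first principal
component of the standardized cluster submatrix, sign-fixed to correlate
positively with the cluster's mean expression.  Numeric traits get
Pearson correlation with Fisher-Z p-values; survival gets a two-group
logrank test on the median split of the eigengene (samples exactly at the
median go to the low group, deterministically).  P-values are BH-adjusted
across clusters within each trait.  A multivariate Cox regression would
slot in where the logrank test is computed; it is a standard model and
deliberately out of scope here.  A generic Fisher-exact enrichment
utility (`cluster_signature_enrichment`) supports user-supplied gene
sets; no curated database ships with the package.

# Synthetic data

`generate_expression()` simulates a latent-factor model: gene $g$ of
module $m$ is $x_g = \lambda f_m + \sigma \varepsilon$ with
$\sigma = \sqrt{1-\lambda^2}$ by default, so genes have unit variance and
the expected within-module correlation is exactly $\lambda^2$ — a closed
form the tests exploit.  Two-level designs add a shared super-module
factor; hub genes get inflated loadings.  Survival times are exponential
with log-hazard linear in a latent factor, with independent exponential
censoring calibrated to the requested censored fraction.

The factor model was chosen over network-diffusion simulation precisely
for these closed-form checks; it emulates blocky co-expression with
Gaussian noise and does *not* emulate heavy-tailed expression, outlier
samples, batch structure, or directed regulatory logic, so passing tests
certify the pipeline's behaviour on well-specified module structure, not
robustness to real-data artefacts.

The canonical validation conditions, chosen once: four modules of 25
genes at loading 0.8 with 200 samples for module recovery and hub
recovery (one planted hub per module, loading multiplier 1.2); and a
two-level design of 2 super-modules x 2 sub-modules of 20 genes at
loadings 0.7/0.6 with 300 samples.  Monte-Carlo sizes follow the method
defaults (`n_rand`, `n_s`, `N_s` of 100); recovery is assessed over 20
seeds (5 for the two-level design), sizes at which the whole suite runs
in minutes on one core.

# Known limitations and degenerate inputs

* **Intermediate hierarchy levels require connectivity separation.**  The
  modularity-guided split goes directly to the strongest partition; on
  nested designs that is the finest level.  A coarse grouping is
  recovered as a hierarchy level only when it corresponds to connected
  components of the PFN — which early termination often produces, since
  cross-group edges rank last.  With three or more sub-modules per
  super-module the saturation cap can fire before every sub-module links
  to a sibling, fragmenting the coarse level; the canonical two-level
  fixture uses two sub-modules per super-module for this reason.
* Ranking by $|r|$ treats strong negative co-expression as evidence of
  interaction; use `rank_by = "signed"` to drop anti-correlated pairs to
  the bottom.
* Zero-variance genes are excluded from correlation networks with a
  warning; constant traits yield `NA` associations.
* p-value estimators use add-one pseudo-counts throughout, so reported
  Monte-Carlo p-values are conservative at their resolution limit.
* The T2 ensemble is the stated null model for these networks; it is not
  a uniform sample over all maximal planar graphs (exact uniform sampling
  is not attempted).
* Determinism: every stochastic stage takes a seed, and nested stages
  derive child seeds from it; the same master seed reproduces every
  table byte for byte.
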