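---
title: "Link Entropy: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link Entropy: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkEntropy)
```

## The problem

An edge's *strength* (how embedded it is in a cluster) and its
*significance* (how much global connectivity depends on it) are nearly
opposite notions: strong intra-community edges are redundant, while weak
ties between communities are exactly the edges whose targeted removal
disintegrates a network. `linkEntropy` quantifies this significance per
edge and evaluates indices by simulated targeted attack.

## The model

### Membership factorization

An undirected, unweighted graph on $n$ nodes is represented by its
adjacency matrix $\mathbf A$ with $a_{ii} = 1$: the unit diagonal treats
each node as connected to itself, which keeps every row nonzero and lets
the factorization assign a membership to isolated or peripheral nodes. We
model $a_{ij}$ as the inner product of latent community memberships,
$\hat a_{ij} = \sum_k x_{ik} x_{jk}$, and fit the $n \times K$ nonnegative
matrix $\mathbf X$ by minimizing the squared loss
$\|\mathbf A - \mathbf X \mathbf X^\top\|_F^2$ with the canonical
symmetric-NMF multiplicative update

$$x_{ik} \leftarrow x_{ik}\,
  \frac{(\mathbf A \mathbf X)_{ik}}{(\mathbf X \mathbf X^\top \mathbf X)_{ik}},$$

followed by row normalization, so each row remains a probability
distribution over the $K$ communities after every iteration. The update is
a rescaled gradient-descent step; the row normalization that the model
requires is a projection on top of it, so the loss is monitored rather than
guaranteed monotone — in practice it plateaus within tens of iterations on
the graph sizes this package targets. Normalization is applied *before*
the convergence check of each iteration, so the check always sees the
constrained iterate.

Numerical choices:

* initialization: entries i.i.d. uniform on $(0.01, 1)$, then
  row-normalized — bounded away from zero because zeros are fixed points of
  multiplicative updates;
* denominator guard $10^{-12}$; convergence when the relative loss change
  drops below $10^{-9}$; iteration cap 2000;
* `factorizeAdjacency()` is bit-reproducible from its seed and leaves the
  global RNG untouched.

The update only finds local optima and the optimum reached depends on the
initialization, so `scoreLE()` defaults to `bestOfRestarts()` with 20
seeded restarts, keeping the lowest loss (ties by lowest seed). Single-init
mode (`nRestarts = 1`) is retained deliberately: the variability study in
`thresholdDistribution()` is *about* that initialization dependence.

### Entropy, divergence, and the edge score

Logarithms with which entropies are computed use base $K$, so both terms
below live on $[0, 1]$ whatever $K$ is and scores are comparable across
$K$. Because $\log 0$ is undefined, membership entries below $10^{-7}$ are
raised to $10^{-7}$ and the added mass is subtracted from the row's largest
entry (`clampZeros()`); the rule compensates "the other component" when
$K = 2$, and for $K > 2$ we generalize it to subtract from the largest
entry, which perturbs the distribution least in relative terms.

Two complementary signals identify an inter-community edge $e_{ij}$:

1. an endpoint is an *overlapping node* — its membership row has high
   Shannon entropy $H$;
2. the endpoints belong cleanly to *different* communities — both
   entropies are near zero, but the Jensen–Shannon divergence between the
   rows is near one. JSD rather than Kullback–Leibler because the score
   must be symmetric in the endpoints and the mixture baseline
   $m = (p+q)/2$ is shared.

The Link Entropy averages the two aspects:

$$LE(e_{ij}) = \frac12\left[\frac{H(\mathbf X_i) + H(\mathbf X_j)}{2}
  + JSD(\mathbf X_i, \mathbf X_j)\right] \in [0, 1].$$

The closed form is pinned down by its limiting cases: identical
near-uniform endpoints give $\frac12[1 + 0] = 0.5$; opposite near-pure
endpoints give $\frac12[0 + 1] = 0.5$; identical pure endpoints give 0.

### Why K = 2 by default

Targeted edge attack seeks the smallest edge set whose removal splits the
network as severely as possible. Splitting into *two* large parts is both
the maximum damage per removed edge and the smallest boundary to cut, so
$K = 2$ is the right objective for ranking attack edges even in networks
with many real communities; larger $K$ spreads the membership signal over
boundaries that are individually cheaper to ignore. `k` stays exposed for
sensitivity analysis (with base-$K$ logs keeping scores comparable).

## The benchmark indices

Edge betweenness (sum over unordered pairs of shortest-path fractions;
computed via igraph and cross-checked in the test suite against an
exhaustive simple-path enumerator), degree product $(k_x k_y)^\theta$ with
$\theta = 1$ (only rank matters), bridgeness $\sqrt{S_x S_y}/S_e$ from an
exact R-level Bron–Kerbosch maximal-clique enumeration (R-level so that the
configurable wall-clock timeout can actually interrupt the exponential
search; there is no heuristic fallback because that would silently change
the index), diffusion importance (links leaving the partner's closed
neighborhood — "nearest neighborhood" is read as the closed neighborhood,
consistent with the epidemic motivation: a link back into $N(x) \cup \{x\}$
reaches no new territory, and the edge $e_{xy}$ itself is excluded for the
same reason), topological overlap (denominator 0 defined as score 0, the
"no common friends" reading for isolated-edge endpoints), and ERW-Kpath
(simulated edge-self-avoiding random walks, default length $k = 20$ and
$\rho = 50|E|$ walks; the walk count is not prescribed by the sources that
define the index, so it is a package default chosen to make the
Monte-Carlo error small relative to score gaps on desk-scale graphs —
estimates converge as $1/\sqrt{\rho}$).

## Percolation protocol

Edges are removed one at a time in descending score order, with scores
computed **once on the intact graph** (the static protocol: no
recomputation, no synergy between removals). After each removal we record
$f$ (fraction removed), $R_{GC}$ (largest-component fraction of the
*original* $N$, isolated nodes still counted) and the normalized
susceptibility $\tilde S = \sum_s n_s s^2 / N$ over all components except
one largest — with co-largest ties, exactly one copy of the maximal size is
excluded and the remaining ties are included, the standard census
convention. The threshold $f^*$ is the smallest $f$ attaining the
$\tilde S$ peak; an identically-zero $\tilde S$ means no disintegration was
observed and $f^* = 1$ is returned with a warning.

Equal scores are common (degree product and bridgeness produce large tie
groups), and a lexicographic tie order would bias the curves, so ties are
shuffled with a recorded `tieSeed`; with an all-constant score table the
attack reduces exactly to seeded random removal. Every removal is recorded
for $|E| \le 5000$; above that the trace is thinned to a 200-point grid,
which preserves curve shape at the sizes this package addresses.

## Synthetic generators and what the tests show

`generatePlantedPartition(nPerBlock, pIn, pOut, seed)` draws a two-block
graph with independent within-block ($p_{in}$) and cross-block ($p_{out}$)
edges and keeps the planted inter-block edges as ground truth. The default
study conditions used in the evaluation tests — 40 nodes per block,
$p_{in} = 0.3$, $p_{out} = 0.02$, 20 seeds — give dense, clearly separated
communities joined by a thin (~32-edge) boundary: the regime the LE score
is designed for, at a size where the full pipeline runs in seconds.
`generateBarbell(cliqueSize)` is the canonical bridge benchmark: two
cliques, one cut edge.

These generators emulate community structure and bridges only. They do not
produce heavy-tailed degree sequences, degree assortativity, clustering
gradients or core–periphery structure, so passing tests on them shows that
the pipeline recovers *planted* community boundaries — not that LE wins on
any real network. On real networks with weak community structure the
benchmark comparison can reverse (global indices like betweenness then have
the advantage); the comparison harness exists precisely to measure that
per network.

The replication study (`thresholdDistribution()`) reruns the single-init
pipeline with consecutive seeds and histograms the thresholds in bins of
width 0.1 centered on 0, 0.1, ..., 1 (the bar at 0.2 counts thresholds in
$[0.15, 0.25)$).

## Degenerate inputs and edge cases

* $K = 1$: every row normalizes to $[1]$; allowed in the factorizer,
  rejected in `scoreLE()` (no information);
* $K > n$: error;
* regular graphs: degree assortativity is 0/0 — returned as `NaN` with a
  warning rather than silently as 0;
* clustering $C$ is the mean *local* clustering coefficient with
  degree-<2 nodes contributing 0 (this, not global transitivity, matches
  the standard reference values, e.g. 0.5706 for the karate club);
* self-loops in input files are dropped (the model adds its own unit
  diagonal) and duplicate edges collapsed, with messages;
* directed input is rejected unless explicitly symmetrized
  (`symmetrize = TRUE`), because silently symmetrizing changes the data;
* node labels are strings; matrix rows follow sorted label order (numeric
  order when all labels are integer strings) for reproducibility.

## Worked example

```{r example}
g   <- fixtureFig2()
tab <- scoreLE(g, k = 2, nRestarts = 20, seed = 1)
sc  <- edgeScores(tab)
sc[order(-sc$score), ]
```

The three triangle-joining edges and the edges touching the straddling
nodes 4 and 5 rank on top; triangle-interior edges fall to the clamping
floor (both LE terms vanish for identical pure memberships — their exact
tail ordering below ~1e-6 is numerical noise, and equivalent edges such as
(5,7)/(5,8) tie to within optimizer tolerance).

```{r percolate}
tr <- percolate(g, tab, tieSeed = 1)
tr
plot(tr)
```

## Known limitations

* The dense NMF is $O(n^2 K)$ per iteration and the percolation trace
  recomputes components per removal: desk-scale by design (thousands of
  nodes, not millions).
* LE inherits NMF's initialization dependence; restarts mitigate but do
  not remove it. `thresholdDistribution()` quantifies the residual spread.
* Weighted and directed networks are out of scope; inputs are reduced to
  undirected, unweighted simple graphs or rejected.
* Bridgeness is exponential-time exact by construction; on networks where
  it times out the index should be skipped, as its definition (maximum
  cliques) admits no cheap faithful approximation.
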