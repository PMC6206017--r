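---
title: "Phylogenetic signal from metabolic network topology: models and methods"
author: "metnetphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic signal from metabolic network topology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the package addresses

A species' metabolism can be summarized as a directed network over its
metabolites, and the *shape* of that network — which metabolites are hubs,
how tightly neighborhoods are knit, how traffic concentrates on bridging
compounds — carries an imprint of the species' evolutionary history.
`metnetphylo` implements a pipeline that extracts that imprint: it turns a
per-species set of biochemical reactions into a directed substrate–product
graph, measures nine local topological properties per metabolite, aligns
those measurements across species into feature vectors over a shared
metabolite character set, and clusters species by the Euclidean geometry
of those vectors. The resulting UPGMA dendrograms can be scored against an
independent reference phylogeny (e.g. one built from plastid gene
alignments) with the cophenetic correlation coefficient (CPCC), and the
robustness of each clade can be quantified by character-resampling
bootstrap.

```{r, eval = FALSE}
library(metnetphylo)
cfg <- synth_config(seed = 1)           # 17-taxon synthetic study
sim <- evolve_repertoires(cfg)
dir <- tempfile(); write_synth_dataset(sim, cfg, dir)
files <- setNames(file.path(dir, paste0(names(sim$reaction_sets),
                                        ".reactions.tsv")),
                  names(sim$reaction_sets))
report <- run_pipeline(run_config(files,
  reference = file.path(dir, "true_tree.nwk"), seed = 1))
report$cpcc
```

# From reactions to networks

A reaction file (canonical dialect: `id TAB substrates TAB products TAB
direction`, sides `;`-separated, direction `LR`/`RL`/`BOTH`) passes
through a fixed normalization order: transcode to UTF-8, drop
byte-identical duplicate lines, standardize names through the synonym
map, strip leading stoichiometric coefficients (an integer, decimal,
simple fraction, or the symbolic count `n`, followed by whitespace).
Records that become identical in (substrates, products, direction) —
sides compared as sets — collapse to one. Name comparison is exact and
case-sensitive: biochemical nomenclature is case-significant, and folding
case would silently merge distinct compounds. The built-in synonym map
carries the single standardization `NADP(H) -> NADPH`; anything further
is the curator's responsibility via a two-column synonym file.

`build_network()` links every substrate of a reaction to every product,
following the arrow; reversible reactions contribute both orientations as
two separate directed links. The graph is simple and binary: repeated
edges collapse, and a metabolite appearing on both sides of one reaction
produces no self-loop by default. Self-loops would inflate degrees and
clustering without conveying cross-metabolite structure, which is why the
substrate–product literature conventionally drops them; a
`keep_self_loops` flag exists for sensitivity analysis. Metabolites whose
only participation is such a self-pair are still counted as (possibly
isolated) nodes, so the metabolite count N always equals the number of
distinct compounds in the reaction file. Nodes are ordered
lexicographically so the adjacency layout is reproducible across runs and
platforms.

# The nine local metrics

For the adjacency matrix $A = (a_{ij})$, $a_{ij} = 1$ iff there is an
edge $i \to j$:

* **degree, in-degree, out-degree** — $k_i^{in} = \sum_j a_{ji}$,
  $k_i^{out} = \sum_j a_{ij}$, $k_i = k_i^{in} + k_i^{out}$. The network
  mean degree equals $E/N$ and also the means of either directed degree.
* **local clustering** $C_i = e_i / (k_i(k_i-1))$, where the neighborhood
  of $i$ is the union of in- and out-neighbors and $e_i$ counts *ordered*
  neighbor pairs joined by an arc. This directed-literal convention is
  the default; an undirected-projection variant is available behind
  `undirected = TRUE` for sensitivity analysis. With the total degree in
  the denominator, a fully bidirectional triangle scores $C_i = 1/6$
  rather than 1 — the convention is deliberate and is what the package's
  tests pin down.
* **HITS hub and authority scores** — the mutual-reinforcement fixed
  point $A(v_j) = \sum_{i \to j} H(v_i)$, $H(v_i) = \sum_{i \to j}
  A(v_j)$, iterated from the all-ones start with Euclidean
  renormalization each sweep (tolerance $10^{-8}$, cap 1000 sweeps). The
  limits are the principal eigenvectors of $AA^\top$ and $A^\top A$.
* **betweenness** — the fraction of directed geodesics between ordered
  pairs passing through the node, normalized by $(N-1)(N-2)$ so values
  lie in $[0,1]$. Computed via the standard Brandes algorithm (igraph).
* **eigencentrality** — the principal eigenpair of the *symmetrized*
  adjacency ($a_{ij} \lor a_{ji}$). Substrate–product digraphs contain
  large acyclic regions whose directed spectral radius is zero, leaving
  the directed eigenproblem degenerate; symmetrization guarantees a
  non-negative Perron vector. The power iteration runs on $S + I$ to
  avoid two-cycling on bipartite components.
* **local efficiency** — the efficiency (mean reciprocal directed
  geodesic distance, zero for unreachable pairs) of the subgraph induced
  by the node's neighbors: a proxy for how well the neighborhood
  communicates if the node is removed. Nodes with fewer than two distinct
  neighbors score zero.

Distances follow a deliberate convention throughout: an unreachable pair
contributes distance **zero**, and the average path length
$L = \sum_{i \ne j} D(v_i,v_j) / (N(N-1))$ keeps those zeros in the
denominator. This shrinks $L$ on fragmented graphs relative to the
largest-component convention, but it makes $L$ well-defined on every
network without choosing a component, and reciprocal-distance efficiency
uses the matching rule ($1/D := 0$ when unreachable).

Degree-distribution exponents $\gamma_{in}, \gamma_{out}$ are fitted to
the nonzero degree samples by discrete maximum likelihood with
$x_{\min} = 1$ (zeta-function normalization, numerically minimized).
Samples with fewer than 10 nonzero values, or degenerate all-equal
samples, are flagged not estimable rather than guessed. The exponents are
reported as global descriptors only; they do not enter the feature
pipeline.

# Feature vectors, character sets, distances

Two canonical character sets are derived from a panel of networks: the
**common set** (intersection of metabolite lists — characters every taxon
possesses) and the **full set** (union — characters a taxon may lack).
The feature vector of taxon $P$ for one metric is
$\phi_P = [\mu_1, \ldots, \mu_m]$ over the ordered character set; a
character absent from a taxon's network takes value **0** in every
metric, which is exactly the value any connectivity-derived measure
assigns a node with no edges. Consequently the full-set matrix restricted
to common-set columns reproduces the common-set matrix — a property the
test suite enforces.

Features are *not* z-scored: the metrics are already on comparable,
bounded or norm-constrained scales within a metric type, and the
between-taxon contrasts of raw values are the signal of interest. PCA is
applied as a rotation: by default all `taxa - 1` components are kept, so
pairwise Euclidean distances of the scores equal those of the raw
centered vectors and the projection is purely a deterministic
re-expression (signs fixed by making each axis's largest-magnitude
loading positive). A reduced component count is available
(`pca_components`) since low-dimensional projections are useful for
visualization; with it, distances are computed in the truncated space.

UPGMA then agglomerates the taxa: inter-cluster distance is the
unweighted arithmetic mean of member-pair distances, each leaf sits at
half the merge distance below the joining node, and the cophenetic
distance of two leaves is the distance at which their clusters merged.
Taxa are sorted lexicographically before clustering so tie-breaking is
deterministic. CPCC between two distance structures is the Pearson
correlation of strictly-upper-triangle entries after aligning taxa by
label. Two CPCC variants are reported against a reference: the default
correlates the *dendrogram's cophenetic matrix* with the reference
matrix (it scores the clustering structure), and a `raw` variant
correlates the underlying feature distance matrix directly; the two
answer slightly different questions and both appear in the pipeline
report.

# Character bootstrap

`support_analysis()` resamples characters: for each ensemble size $m$ it
draws (by default without replacement — the resampled trait sets are
*combinations* of distinct metabolites; a `replace = TRUE` flag gives the
classical bootstrap) 100 random subsets, rebuilds the UPGMA tree per
subset, and scores every clade of the reference tree by the percentage of
replicate trees containing its exact leaf set. Support is clade
(rooted) presence, not unrooted bipartition presence, because every tree
involved is a rooted dendrogram. One master seed spawns an independent
child seed per (size, replicate) cell through a single `sample.int()`
draw, so any cell can be reproduced in isolation and the whole analysis
is bit-exact under a fixed seed.

# The synthetic study generator

Because the curated reaction exports and the reference plastid-gene
distance matrix of a real plant panel cannot be bundled with the package,
the generator in `synth_config()` / `simulate_universe()` /
`evolve_repertoires()` produces a fully synthetic stand-in with a known
ground truth, and every end-to-end claim in the test suite is made
against that truth.

The generator has two stages. First a **universe** of candidate reactions
is simulated: each reaction draws 1–3 substrates and 1–3 products from a
metabolite pool, with the probability of reusing a metabolite
proportional to $(1 + \text{usage})^{\beta}$. The preferential-reuse
exponent $\beta$ (`hub_bias`, default 1) produces the heavy-tailed
metabolite connectivity that real metabolic networks show; about 10% of
reactions are reversible. Second, a repertoire **evolves along a known
tree**: a root repertoire is drawn from the universe, and each branch
adds Poisson(gain rate × length) reactions from the lineage's complement
and removes Poisson(loss rate × length) uniformly (never emptying a
repertoire). Leaves inherit their path's final repertoire and are written
as canonical reaction TSVs.

Default conditions emulate the shape of a real multi-clade plant study:
17 taxa on an ultrametric tree (`example_study_tree()`) with one
early-diverging alga-like lineage, moss-like and lycophyte-like
lineages, and a 14-taxon angiosperm-like radiation split 7/7 into
monocot-like and dicot-like clades; pool of 400 metabolites, universe of
2500 reactions, root repertoire 500, gain rate 60 and loss rate 5 events
per unit branch. Two sizing rules matter and were fixed at design time:

* the **universe must comfortably exceed any achievable repertoire**
  (here roughly 3× the deepest lineage's expected repertoire). If the
  universe saturates, independent lineages are forced to gain largely the
  same reactions and between-clade signal collapses — an artifact of a
  finite reaction space, not a property of the inference. Real reaction
  databases hold a small fraction of chemically possible reactions, so
  the non-saturating regime is also the realistic one.
* the generating tree is **ultrametric**, so repertoires diverge
  clock-like — the regime in which UPGMA's implicit equal-rates
  assumption is met and recovery statements are meaningful.

The per-taxon networks this yields (~350–380 metabolites, mean degree
~8.6) are an order of magnitude smaller than curated plant networks
(thousands of metabolites); the sizes keep the full test suite and the
acceptance run in the minutes range on one CPU while leaving hundreds of
characters per feature vector.

What the generator does *not* emulate: compound chemistry, pathway
organization, compartments, reaction reversibility biology, and
correlated gain/loss (each event is independent). Passing the synthetic
suite therefore demonstrates that the pipeline's machinery — parsing,
graph construction, metric computation, feature alignment, clustering,
support — is correct and that topological feature vectors recover
tree-structured signal when it exists; it does not by itself certify
biological conclusions about any real panel.

Two regimes are used in validation. Under the **default study
conditions** (losses on, short shallow branches) the recovered
dendrograms reproduce the major clades in every run and correlate with
the generating tree at CPCC ≈ 0.94–0.99, while the shallowest splits are
recovered only imperfectly — feature-space distances compress deep
structure (Euclidean distance over per-metabolite metrics grows roughly
as the square root of the repertoire difference), so sister-pair
resolution is noise-limited exactly as it is on real data. Under a
**strong-signal regime** (no losses, internal branches several times
longer than tip branches, so gains are effectively clade-disjoint) the
true topology is recovered exactly, and per-clade bootstrap support rises
monotonically with ensemble size to 100 — the behavior the package's
acceptance tests pin down.

# Numerical choices and degenerate inputs

* HITS and the eigencentrality power iteration stop at a $10^{-8}$ /
  $10^{-10}$ max-change tolerance with generous iteration caps; a cap hit
  raises a warning and returns the last iterate rather than failing.
* Edgeless networks make HITS and eigencentrality undefined (error), as
  does a single-node network for path lengths, and fewer than 3 nodes for
  betweenness.
* An empty common set across networks is a warning, not an error — valid
  but unusable downstream, and the caller decides.
* Zero variance among pairwise distances makes the CPCC undefined
  (error), as does a taxon mismatch between the two matrices.
* The power-law fit is bounded in $(1, 20]$; an optimum pushed to the
  upper bound indicates a degenerate sample and is reported as `NA`.
* All RNG flows through one master seed: child seeds are spawned with a
  single `sample.int()` call, RNG state is saved and restored around
  every seeded block, and generated datasets are byte-identical across
  runs with the same configuration.

# Known limitations

* UPGMA assumes clock-like divergence; on strongly rate-heterogeneous
  data, neighbor-joining-style methods would be more appropriate — they
  are out of scope here, where the dendrogram *is* the method under
  study.
* Clade support is computed over UPGMA replicate trees directly.
  Mapping continuous topological characters into a maximum-likelihood
  tree engine for bootstrapping would require an encoding of continuous
  traits as discrete states that is neither standard nor
  self-consistent; the clade-frequency-over-replicates definition used
  here is self-contained and exactly reproducible.
* The directed-literal clustering and symmetrized eigencentrality
  conventions are choices among defensible alternatives; the variant
  flags exist precisely so their impact can be measured on a given
  dataset.
* Stoichiometry, enzyme assignments and flux are ignored by design: the
  substrate–product graph is a minimalist abstraction, and metrics on it
  should be read as such.
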