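# metnetphylo

Phylogenetic signal from the topology of metabolic networks.

A species' metabolism can be written as a directed **substrate–product
network**: every substrate metabolite of a reaction is linked to every
product metabolite, respecting the reaction arrow, with reversible
reactions contributing both orientations. `metnetphylo` asks how much
evolutionary information that graph's *shape* carries. It computes nine
local topological measures per metabolite — degree, in-degree,
out-degree, local clustering coefficient, Kleinberg HITS hub and
authority scores, local efficiency, betweenness and eigencentrality —
and treats them as metabolic characters: for each taxon *P* a feature
vector φ_P = [μ₁, …, μ_m] over an ordered metabolite character set
(either the **common set**, the intersection of all taxa's metabolites,
or the **full set**, their union with absent characters scored 0).
Euclidean distances between feature vectors feed UPGMA hierarchical
clustering; the resulting dendrogram is compared with an independent
reference phylogeny through the **cophenetic correlation coefficient**
(CPCC, the Pearson correlation of the two pairwise-distance structures),
and the stability of each clade is quantified by **character-resampling
bootstrap** (resample m characters, rebuild the tree, count the
percentage of replicates containing the clade).

Because curated per-species reaction exports cannot ship with the
package, it includes a first-class synthetic-data module that evolves a
reaction repertoire along a known ultrametric tree (hub-biased reaction
universe, Poisson gain/loss events per branch), so the entire pipeline is
testable against a ground-truth phylogeny.

Intended users: researchers in molecular evolution and systems biology
who want to score network-topological characters against sequence-based
phylogenies, and methodologists who need a reproducible testbed for
topology-based phylogenetic inference.

## Worked example

Simulate a 17-taxon study (five clades: one alga-like outgroup,
moss-like and lycophyte-like lineages, and a 7+7 monocot/dicot-like
radiation), then run the full pipeline against the generating tree:

```r
library(metnetphylo)

cfg <- synth_config(seed = 1)            # default study conditions
sim <- evolve_repertoires(cfg)
dir <- tempfile(); write_synth_dataset(sim, cfg, dir)
files <- setNames(file.path(dir, paste0(names(sim$reaction_sets),
                                        ".reactions.tsv")),
                  names(sim$reaction_sets))

report <- run_pipeline(run_config(files,
  metrics = c("hub", "degree", "clustering"),
  reference = file.path(dir, "true_tree.nwk"), seed = 1))
print(report)
#> Pipeline run over 17 taxa; common character set (m = 339 )
#> CPCC against reference:
#>       metric cpcc_cophenetic cpcc_raw
#> 1        hub           0.975    0.951
#> 2     degree           0.972    0.942
#> 3 clustering           0.808    0.791
```

Connectivity-derived metrics (hub score, degree) correlate strongly with
the generating phylogeny, while local clustering — a neighborhood
property only weakly coupled to repertoire divergence — trails behind;
the same ordering the method shows on real data. One network's global
profile:

```r
net <- build_network(parse_reaction_file(files[["t01"]], taxon_id = "t01"))
net
#> Metabolic network for taxon 't01': N = 356 metabolites, E = 3277 directed links
str(global_metrics(net))
#> $ mean_degree      : num 9.21
#> $ L                : num 2.45
#> $ global_efficiency: num 0.334
#> $ gamma_in         : num 1.4
#> $ gamma_out        : num 1.41
```

`mean_degree` is E/N; `L` is the average directed shortest-path length
with unreachable pairs contributing zero; `gamma_in`/`gamma_out` are
discrete maximum-likelihood power-law exponents of the degree
distributions. Bootstrap support for the clades of a reference tree:

```r
nets <- lapply(names(files), function(tx)
  build_network(parse_reaction_file(files[[tx]], taxon_id = tx)))
tabs <- lapply(nets, node_metrics)
fm <- assemble_features(tabs, "hub", full_set(nets))  # taxa x m matrix
sup <- support_analysis(fm, sim$tree, sizes = c(50, 100, 200, 300),
                        replicates = 100, seed = 7)
```

Support of the major clades rises with the number of resampled
characters and saturates at 100 well below the full character set.

A thin command-line front end wrapping these functions is installed at
`system.file("scripts/metnet", package = "metnetphylo")`, with
subcommands `parse`, `build`, `metrics`, `features`, `tree`, `cpcc`,
`support`, `synth` and `run`.

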