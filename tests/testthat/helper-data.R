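# Lazily-built synthetic datasets shared across test files (built once
# per test run; generation is deterministic so sharing does not couple
# tests).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 17-taxon study emulation under the generator's default conditions
study17 <- function() {
  fixture("study17", function() {
    cfg <- synth_config(seed = 1L)
    sim <- evolve_repertoires(cfg)
    nets <- lapply(sim$reaction_sets, build_network)
    tabs <- lapply(nets, node_metrics)
    list(cfg = cfg, sim = sim, nets = nets, tabs = tabs,
         cs = common_set(nets), fs = full_set(nets))
  })
}

# 8-taxon balanced tree in the strong-signal regime: no losses, long
# internal branches, so gains are effectively clade-disjoint and the
# topology is decisively recoverable
strong8_tree <- paste0("(((A:0.5,B:0.5):2,(C:0.5,D:0.5):2):1,",
                       "((E:0.5,F:0.5):2,(G:0.5,H:0.5):2):1);")

strong8 <- function() {
  fixture("strong8", function() {
    cfg <- synth_config(tree = strong8_tree, loss_rate = 0, seed = 1L)
    sim <- evolve_repertoires(cfg)
    nets <- lapply(sim$reaction_sets, build_network)
    tabs <- lapply(nets, node_metrics)
    list(cfg = cfg, sim = sim, nets = nets, tabs = tabs,
         fs = full_set(nets))
  })
}

clade_key <- function(taxa) paste(sort(taxa), collapse = "|")
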