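#' Configuration for the synthetic reaction-repertoire generator
#'
#' The generator evolves a repertoire of reactions along a known tree so
#' the whole pipeline can be validated against a ground-truth phylogeny:
#' a universe of candidate reactions is simulated with hub-biased
#' metabolite reuse (heavy-tailed connectivity, as in real metabolic
#' networks), a root repertoire is drawn from it, and reactions are
#' gained and lost along each branch as Poisson events.
#'
#' @param pool_size Number of distinct metabolites in the pool.
#' @param universe_size Number of reactions in the universe.
#' @param hub_bias Preferential-attachment exponent for metabolite
#'   reuse; 0 gives uniform usage, values >= 1 give heavy-tailed reuse.
#' @param tree Tree with branch lengths: an [ape::phylo] object or a
#'   Newick string.
#' @param gain_rate,loss_rate Expected reaction gains / losses per unit
#'   branch length.
#' @param root_size Repertoire size at the root.
#' @param reversible_frac Fraction of universe reactions made
#'   reversible.
#' @param seed Master seed; all randomness derives from it.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(pool_size = 400L, universe_size = 2500L,
                         hub_bias = 1, tree = example_study_tree(),
                         gain_rate = 60, loss_rate = 5,
                         root_size = 500L, reversible_frac = 0.1,
                         seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop_input("tree must be phylo or Newick")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop_input("tree must have positive branch lengths")
  if (pool_size < 6L) stop_input("metabolite pool too small for reactions")
  if (universe_size < 1L || root_size < 1L || root_size > universe_size)
    stop_input("need 1 <= root_size <= universe_size")
  if (gain_rate < 0 || loss_rate < 0) stop_input("rates must be >= 0")
  if (hub_bias < 0) stop_input("hub_bias must be >= 0")
  structure(list(pool_size = as.integer(pool_size),
                 universe_size = as.integer(universe_size),
                 hub_bias = hub_bias, tree = tree,
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 root_size = as.integer(root_size),
                 reversible_frac = reversible_frac,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' A 17-leaf study-design tree
#'
#' Synthetic stand-in tree whose shape mirrors the sampling design of a
#' multi-clade plant panel: one early-diverging alga-like lineage, one
#' moss-like and one lycophyte-like lineage, and an angiosperm-like
#' radiation split into a 7-leaf monocot-like and a 7-leaf dicot-like
#' clade. The tree is ultrametric (all leaves at depth 4), so gain and
#' loss events accumulate clock-like; branch lengths are in arbitrary
#' evolutionary time units.
#'
#' @return An [ape::phylo] tree with leaves `t01`..`t17`.
#' @export
example_study_tree <- function() {
  ape::read.tree(text = paste0(
    "(t01:4,(t02:3.2,(t03:2.8,(((t04:0.8,(t05:0.5,t06:0.5):0.3):0.4,",
    "(t07:0.9,(t08:0.6,(t09:0.3,t10:0.3):0.3):0.3):0.3):0.6,",
    "((t11:0.8,(t12:0.5,t13:0.5):0.3):0.5,",
    "(t14:1,(t15:0.6,(t16:0.3,t17:0.3):0.3):0.4):0.3):0.5):1):0.4):0.8);"))
}

#' Simulate a universe of candidate reactions
#'
#' Each reaction draws 1-3 substrates and 1-3 products from the
#' metabolite pool without overlap between its two sides; the chance of
#' picking a metabolite grows with its prior usage as
#' `(1 + usage)^hub_bias`, so repeatedly-used metabolites become hubs
#' and the resulting substrate-product network has a heavy-tailed degree
#' distribution. About `reversible_frac` of reactions are reversible,
#' the rest left-to-right.
#'
#' @param cfg A [synth_config()].
#' @return A [reaction_set()] (taxon id `"universe"`).
#' @export
simulate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  pool <- sprintf("M%04d", seq_len(cfg$pool_size))
  with_seed(cfg$seed, {
    usage <- rep(0, cfg$pool_size)
    recs <- vector("list", cfg$universe_size)
    for (r in seq_len(cfg$universe_size)) {
      ns <- sample(1:3, 1)
      np <- sample(1:3, 1)
      w <- (1 + usage)^cfg$hub_bias
      subs <- sample.int(cfg$pool_size, ns, prob = w)
      w2 <- w
      w2[subs] <- 0
      prods <- sample.int(cfg$pool_size, np, prob = w2)
      usage[c(subs, prods)] <- usage[c(subs, prods)] + 1
      dir <- if (stats::runif(1) < cfg$reversible_frac) "BOTH" else "LR"
      recs[[r]] <- reaction_record(sprintf("U%05d", r), pool[subs],
                                   pool[prods], dir)
    }
    reaction_set("universe", recs)
  })
}

#' Evolve reaction repertoires along the tree
#'
#' Samples a root repertoire from the universe, then walks every branch
#' accumulating Poisson(gain_rate x length) reaction gains (drawn
#' uniformly from the reactions the lineage lacks) and
#' Poisson(loss_rate x length) uniform losses; losses never empty a
#' repertoire (floored at one reaction, with a warning). Each leaf
#' inherits the repertoire at the end of its path.
#'
#' @param cfg A [synth_config()].
#' @param universe Optional pre-built universe [reaction_set()]
#'   (defaults to [simulate_universe()] on `cfg`).
#' @return List with `reaction_sets` (named by leaf), `tree` (the
#'   generating [ape::phylo]), and `universe`.
#' @export
evolve_repertoires <- function(cfg, universe = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  tree <- cfg$tree
  if (length(tree$tip.label) < 2L) stop_input("tree needs >= 2 leaves")
  universe <- universe %||% simulate_universe(cfg)
  nu <- universe$R
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # independent child seeds: one for the root draw, one per edge
  seeds <- spawn_seeds(cfg$seed + 1L, 1L + nrow(tree$edge))
  rep_at <- vector("list", ntip + tree$Nnode)
  rep_at[[root]] <- sort(with_seed(seeds[1],
                                   sample.int(nu, cfg$root_size)))
  # preorder: parents are assigned before their children in tree$edge
  # after reordering
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_len <- tree$edge.length[match(paste(edges[, 1], edges[, 2]),
                                     paste(tree$edge[, 1], tree$edge[, 2]))]
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]
    child <- edges[e, 2]
    len <- edge_len[e]
    rep_at[[child]] <- with_seed(seeds[1L + e], {
      cur <- rep_at[[parent]]
      n_gain <- stats::rpois(1, cfg$gain_rate * len)
      comp <- setdiff(seq_len(nu), cur)
      if (n_gain > 0 && length(comp) > 0)
        cur <- c(cur, sample(comp, min(n_gain, length(comp))))
      n_loss <- stats::rpois(1, cfg$loss_rate * len)
      if (n_loss >= length(cur)) {
        warning("losses would empty a repertoire; floored at 1 reaction")
        n_loss <- length(cur) - 1L
      }
      if (n_loss > 0) cur <- setdiff(cur, sample(cur, n_loss))
      sort(cur)
    })
  }
  sets <- lapply(seq_len(ntip), function(i)
    reaction_set(tree$tip.label[i], universe$records[rep_at[[i]]]))
  names(sets) <- tree$tip.label
  list(reaction_sets = sets, tree = tree, universe = universe)
}

#' Write a synthetic dataset to disk
#'
#' Writes one canonical reaction TSV per leaf, the generating tree as
#' Newick, and a JSON echo of the configuration.
#'
#' @param sim An [evolve_repertoires()] result.
#' @param cfg The [synth_config()] used.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synth_dataset <- function(sim, cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$reaction_sets), function(tx) {
    p <- file.path(out_dir, paste0(tx, ".reactions.tsv"))
    write_reaction_file(sim$reaction_sets[[tx]], p)
    p
  }, character(1))
  tree_path <- file.path(out_dir, "true_tree.nwk")
  ape::write.tree(sim$tree, file = tree_path)
  cfg_path <- file.path(out_dir, "config.json")
  cfg_echo <- cfg[setdiff(names(cfg), "tree")]
  cfg_echo$tree_newick <- ape::write.tree(cfg$tree)
  jsonlite::write_json(cfg_echo, cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tree = tree_path, config = cfg_path))
}
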