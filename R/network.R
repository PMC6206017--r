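#' Build the directed substrate-product network of a taxon
#'
#' Every metabolite appearing in any reaction becomes a node; for each
#' left-to-right reaction an edge runs from every substrate to every
#' product, right-to-left reactions give the reverse orientation, and
#' reversible reactions contribute both orientations as two separate
#' directed links. Repeated edges collapse to one; a metabolite occurring
#' on both sides of a reaction yields no self-loop by default (such
#' metabolites are still listed as nodes, possibly isolated). Nodes are
#' ordered lexicographically for a deterministic adjacency layout.
#'
#' @param reactions A [reaction_set()].
#' @param keep_self_loops Keep self-loops arising from a metabolite on
#'   both sides of one reaction (default drops them; intended for
#'   sensitivity analysis only).
#' @return An object of class `"metabolic_network"`: a list with
#'   `taxon_id`, `nodes` (sorted metabolite names), `graph` (an
#'   [igraph::igraph] directed graph), `N` (node count) and `E`
#'   (edge count).
#' @examples
#' rs <- reaction_set("toy", list(
#'   reaction_record("R1", c("A", "B"), "C", "LR")))
#' net <- build_network(rs)
#' net$N  # 3
#' net$E  # 2
#' @export
build_network <- function(reactions, keep_self_loops = FALSE) {
  stopifnot(inherits(reactions, "reaction_set"))
  if (reactions$R == 0L) stop_input("empty reaction set")
  nodes <- sort(unique(unlist(lapply(reactions$records, function(r)
    c(r$substrates, r$products)))))
  edges <- lapply(reactions$records, function(r) {
    s <- r$substrates; p <- r$products
    fw <- cbind(rep(s, each = length(p)), rep(p, length(s)))
    switch(r$direction,
           LR = fw,
           RL = fw[, 2:1, drop = FALSE],
           BOTH = rbind(fw, fw[, 2:1, drop = FALSE]))
  })
  em <- do.call(rbind, edges)
  if (!keep_self_loops) em <- em[em[, 1] != em[, 2], , drop = FALSE]
  em <- unique(em)
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  structure(
    list(taxon_id = reactions$taxon_id, nodes = nodes, graph = g,
         N = length(nodes), E = nrow(em)),
    class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network for taxon '", x$taxon_id, "': N = ", x$N,
      " metabolites, E = ", x$E, " directed links\n", sep = "")
  invisible(x)
}

# Sparse binary adjacency in node order (dgCMatrix).
adjacency <- function(net) {
  igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
}

#' Per-taxon and per-clade network size summary
#'
#' Tabulates the number of metabolites N and reactions R per taxon, and
#' their arithmetic means per clade.
#'
#' @param networks List of [build_network()] results.
#' @param reaction_sets List of the matching [reaction_set()] objects.
#' @param clade_map Named character vector mapping taxon id to clade.
#' @return List with `per_taxon` (data frame: taxon, clade, N, R) and
#'   `per_clade` (data frame: clade, mean_N, mean_R, n_taxa).
#' @export
network_summary <- function(networks, reaction_sets, clade_map) {
  tax_n <- vapply(networks, function(x) x$taxon_id, character(1))
  tax_r <- vapply(reaction_sets, function(x) x$taxon_id, character(1))
  if (!setequal(tax_n, tax_r))
    stop_input("networks and reaction sets cover different taxa")
  missing <- setdiff(tax_n, names(clade_map))
  if (length(missing))
    stop_input("taxa missing from clade map: ",
               paste(missing, collapse = ", "))
  per_taxon <- data.frame(
    taxon = tax_n,
    clade = unname(clade_map[tax_n]),
    N = vapply(networks, function(x) x$N, integer(1)),
    R = vapply(reaction_sets, function(x) x$R, integer(1))[
      match(tax_n, tax_r)],
    stringsAsFactors = FALSE)
  per_clade <- do.call(rbind, lapply(split(per_taxon, per_taxon$clade),
    function(d) data.frame(clade = d$clade[1], mean_N = mean(d$N),
                           mean_R = mean(d$R), n_taxa = nrow(d),
                           stringsAsFactors = FALSE)))
  rownames(per_clade) <- NULL
  list(per_taxon = per_taxon, per_clade = per_clade)
}

#' Write a network as edge-list and node-list TSVs
#'
#' @param net A `metabolic_network`.
#' @param out_prefix Path prefix; writes `<prefix>.edges.tsv`
#'   (source, target) and `<prefix>.nodes.tsv`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_network <- function(net, out_prefix) {
  el <- igraph::as_edgelist(net$graph)
  epath <- paste0(out_prefix, ".edges.tsv")
  npath <- paste0(out_prefix, ".nodes.tsv")
  utils::write.table(data.frame(source = el[, 1], target = el[, 2]),
                     epath, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(net$nodes, npath)
  invisible(c(edges = epath, nodes = npath))
}
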