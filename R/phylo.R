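#' Pairwise Euclidean distance matrix between taxa
#'
#' @param x A [assemble_features()] result, a PCA `scores` matrix, or any
#'   numeric matrix with taxa as rownames.
#' @return Object of class `"distance_matrix"`: list with `taxa` and the
#'   symmetric zero-diagonal matrix `values`.
#' @export
euclidean_distances <- function(x) {
  m <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (any(!is.finite(m))) stop_input("non-finite feature values")
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  distance_matrix(d)
}

#' @rdname euclidean_distances
#' @param values Square symmetric numeric matrix with zero diagonal and
#'   taxa as dimnames.
#' @export
distance_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop_input("distance matrix must be square")
  if (is.null(rownames(values)))
    stop_input("distance matrix needs taxon labels as dimnames")
  if (max(abs(values - t(values))) > 1e-12)
    stop_input("distance matrix is not symmetric")
  if (any(!is.finite(values)) || any(values < 0))
    stop_input("distances must be finite and non-negative")
  diag(values) <- 0
  colnames(values) <- rownames(values)
  structure(list(taxa = rownames(values), values = values),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Distance matrix over", length(x$taxa), "taxa\n")
  invisible(x)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Unweighted pair-group agglomeration with arithmetic-mean linkage: the
#' closest pair of clusters is merged repeatedly, inter-cluster distance
#' being the mean of all member-pair distances. The cophenetic distance
#' between two leaves is the distance at which their clusters merge, so
#' each leaf sits at height merge-distance / 2 below the joining node
#' and the tree is ultrametric. Taxa are processed in lexicographic
#' order, which makes tie-breaking deterministic.
#'
#' @param dm A [distance_matrix()] (or square matrix coercible to one).
#' @return Object of class `"dendrogram_upgma"`: list with the underlying
#'   [stats::hclust] tree, `taxa`, and the [ape::phylo] conversion
#'   (`phy`) whose patristic distances equal cophenetic distances.
#' @export
upgma <- function(dm) {
  if (!inherits(dm, "distance_matrix")) dm <- distance_matrix(dm)
  ord <- order(dm$taxa)
  v <- dm$values[ord, ord]
  hc <- stats::hclust(stats::as.dist(v), method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, taxa = sort(dm$taxa), phy = phy),
            class = "dendrogram_upgma")
}

#' @export
print.dendrogram_upgma <- function(x, ...) {
  cat("UPGMA dendrogram over", length(x$taxa), "taxa; height",
      format(max(x$hclust$height) / 2, digits = 4), "\n")
  invisible(x)
}

#' Cophenetic distance matrix of a tree
#'
#' For a UPGMA dendrogram, entry (P, Q) is the merge distance of the
#' lowest cluster containing both leaves; for a general `phylo` tree the
#' patristic distance is returned.
#'
#' @param tree A [upgma()] result or an [ape::phylo] tree.
#' @return A [distance_matrix()].
#' @export
cophenetic_matrix <- function(tree) {
  v <- if (inherits(tree, "dendrogram_upgma")) {
    as.matrix(stats::cophenetic(tree$hclust))
  } else if (inherits(tree, "phylo")) {
    ape::cophenetic.phylo(tree)
  } else stop_input("tree must be a dendrogram_upgma or phylo object")
  v <- v[order(rownames(v)), order(rownames(v))]
  distance_matrix(v)
}

#' Cophenetic correlation coefficient between two distance structures
#'
#' Pearson correlation of the strictly-upper-triangle entries of two
#' distance matrices after aligning taxa by label (order-independent).
#' Values lie in `[-1, 1]`; 1 means the two clustering structures agree
#' perfectly up to an affine rescaling.
#'
#' @param d1,d2 [distance_matrix()] objects (or coercible matrices) over
#'   the same taxa.
#' @return Numeric scalar.
#' @export
cpcc <- function(d1, d2) {
  if (!inherits(d1, "distance_matrix")) d1 <- distance_matrix(d1)
  if (!inherits(d2, "distance_matrix")) d2 <- distance_matrix(d2)
  if (!setequal(d1$taxa, d2$taxa))
    stop_input("distance matrices cover different taxa")
  if (length(d1$taxa) < 3L) stop_input("CPCC needs at least 3 taxa")
  m2 <- d2$values[d1$taxa, d1$taxa]
  ut <- upper.tri(d1$values)
  x <- d1$values[ut]
  y <- m2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_input("zero variance among pairwise distances: CPCC undefined")
  stats::cor(x, y)
}

#' Read a reference phylogeny
#'
#' Accepts either a Newick tree file or a PHYLIP-style square distance
#' matrix (first line the taxon count, then one labeled row per taxon).
#' Labels can be renamed to the pipeline's taxon ids through a mapping.
#'
#' @param path Input file.
#' @param label_map Optional named character vector, file labels as
#'   names, taxon ids as values. Labels absent from the map raise an
#'   error when a map is supplied.
#' @return A [distance_matrix()] (PHYLIP input) or an [ape::phylo] tree
#'   (Newick input).
#' @export
read_reference <- function(path, label_map = NULL) {
  if (!file.exists(path)) stop_input("cannot read reference: ", path)
  first <- trimws(readLines(path, n = 1L, warn = FALSE))
  remap <- function(labels) {
    if (is.null(label_map)) return(labels)
    unknown <- setdiff(labels, names(label_map))
    if (length(unknown))
      stop_input("labels missing from mapping: ",
                 paste(unknown, collapse = ", "))
    unname(label_map[labels])
  }
  if (startsWith(first, "(")) {
    phy <- ape::read.tree(path)
    phy$tip.label <- remap(phy$tip.label)
    return(phy)
  }
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop_input("not a Newick or PHYLIP distance file: ", path)
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  labels <- remap(vapply(rows, `[[`, character(1), 1))
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(vals) <- list(labels, labels)
  distance_matrix(vals)
}

#' Write a PHYLIP-style square distance matrix
#'
#' @param dm A [distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  lines <- c(length(dm$taxa),
             vapply(dm$taxa, function(tx)
               paste(tx, paste(format(dm$values[tx, ], digits = 10,
                                      trim = TRUE), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a dendrogram as Newick
#'
#' Branch lengths follow the dendrogram convention: the path from a leaf
#' to an ancestor is half the cophenetic distance, so leaf-to-leaf
#' patristic distances reproduce the cophenetic matrix.
#'
#' @param tree A [upgma()] result or [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "dendrogram_upgma")) tree$phy else tree
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Clades (leaf-label sets) of a rooted tree
#'
#' @param tree A [upgma()] result or rooted [ape::phylo] tree.
#' @param include_root Include the all-taxa clade.
#' @return Named list of sorted character vectors, one per internal node
#'   (singletons excluded); names are `|`-joined sorted leaf labels.
#' @export
clade_sets <- function(tree, include_root = TRUE) {
  phy <- if (inherits(tree, "dendrogram_upgma")) tree$phy else tree
  if (!inherits(phy, "phylo")) stop_input("not a tree")
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  clades <- lapply(pp, function(idx) sort(labs[idx]))
  if (!include_root)
    clades <- Filter(function(cl) length(cl) < length(labs), clades)
  names(clades) <- vapply(clades, paste, character(1), collapse = "|")
  clades[!duplicated(names(clades))]
}

#' Rooted clade-set difference between two trees
#'
#' Size of the symmetric difference of the two trees' clade sets
#' (singleton leaves ignored) — a rooted analogue of the
#' Robinson-Foulds distance. Zero iff the rooted topologies agree.
#'
#' @param t1,t2 Trees accepted by [clade_sets()], over the same leaves.
#' @return Integer count.
#' @export
clade_difference <- function(t1, t2) {
  c1 <- names(clade_sets(t1))
  c2 <- names(clade_sets(t2))
  length(setdiff(c1, c2)) + length(setdiff(c2, c1))
}
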