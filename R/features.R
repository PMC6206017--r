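#' Metabolite character sets
#'
#' The common set is the intersection of the metabolite (node) sets of
#' all networks — characters every taxon possesses; the full set is their
#' union, in which a taxon may lack characters (those take metric value
#' zero in its feature vector). Characters are kept sorted.
#'
#' @param networks List of [build_network()] results (common: at least 2;
#'   full: at least 1).
#' @return Object of class `"metabolite_set"`: list with `kind`,
#'   `characters` (sorted) and size `m`.
#' @export
common_set <- function(networks) {
  if (length(networks) < 2L) stop_input("need at least 2 networks")
  chars <- sort(Reduce(intersect, lapply(networks, function(x) x$nodes)))
  if (length(chars) == 0L)
    warning("common metabolite set is empty; downstream features unusable")
  metabolite_set("common", chars)
}

#' @rdname common_set
#' @export
full_set <- function(networks) {
  if (length(networks) < 1L) stop_input("need at least 1 network")
  chars <- sort(Reduce(union, lapply(networks, function(x) x$nodes)))
  metabolite_set("full", chars)
}

#' @rdname common_set
#' @param kind One of `"common"`, `"full"`, `"custom"`.
#' @param characters Character vector of metabolite names.
#' @export
metabolite_set <- function(kind = c("common", "full", "custom"), characters) {
  kind <- match.arg(kind)
  characters <- sort(unique(as.character(characters)))
  structure(list(kind = kind, characters = characters,
                 m = length(characters)),
            class = "metabolite_set")
}

#' @export
print.metabolite_set <- function(x, ...) {
  cat(x$kind, "metabolite set: m =", x$m, "characters\n")
  invisible(x)
}

#' Reactions shared by every taxon
#'
#' A reaction is shared when a record with identical substrates, products
#' (compared as sets) and direction occurs in every reaction set.
#'
#' @param reaction_sets List of at least 2 [reaction_set()] objects.
#' @return A [reaction_set()] (taxon id `"common"`) holding the shared
#'   records, drawn from the first input set.
#' @export
common_reactions <- function(reaction_sets) {
  if (length(reaction_sets) < 2L) stop_input("need at least 2 reaction sets")
  keysets <- lapply(reaction_sets, function(rs)
    vapply(rs$records, record_key, character(1)))
  shared <- Reduce(intersect, keysets)
  reaction_set("common", reaction_sets[[1]]$records[keysets[[1]] %in% shared])
}

#' Assemble aligned per-taxon feature vectors for one metric
#'
#' Row P of the result is the feature vector of taxon P: the chosen
#' metric's value for each character metabolite in P's network, in
#' character order. A character absent from a taxon's network takes the
#' value 0 — the value every connectivity-derived metric assigns an
#' absent node.
#'
#' @param metric_tables Named list (by taxon) of [node_metrics()] tables,
#'   or a list whose elements carry a `"taxon_id"` attribute.
#' @param metric One of [metric_names()].
#' @param characters A [metabolite_set()].
#' @return Object of class `"feature_matrix"`: list with `metric`,
#'   `taxa`, `characters` and the taxa x m numeric matrix `values`.
#' @export
assemble_features <- function(metric_tables, metric, characters) {
  if (!metric %in% metric_names())
    stop_input("unknown metric '", metric, "'; see metric_names()")
  stopifnot(inherits(characters, "metabolite_set"))
  if (is.null(names(metric_tables)))
    names(metric_tables) <- vapply(metric_tables, attr, character(1),
                                   "taxon_id")
  taxa <- names(metric_tables)
  vals <- matrix(0, nrow = length(taxa), ncol = characters$m,
                 dimnames = list(taxa, characters$characters))
  for (tx in taxa) {
    tab <- metric_tables[[tx]]
    hit <- intersect(characters$characters, rownames(tab))
    vals[tx, hit] <- tab[hit, metric]
  }
  structure(list(metric = metric, taxa = taxa, characters = characters,
                 values = vals),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix [", x$metric, "]: ", length(x$taxa), " taxa x ",
      x$characters$m, " characters (", x$characters$kind, " set)\n",
      sep = "")
  invisible(x)
}

#' Principal component projection of a feature matrix
#'
#' Column-centers the feature matrix and projects it onto the leading
#' principal axes. At full rank the projection is an orthogonal change of
#' basis, so pairwise Euclidean distances of the scores equal those of
#' the raw centered rows. Signs follow a deterministic convention: in
#' each axis the loading of largest magnitude is positive.
#'
#' @param fm A [assemble_features()] result, or a plain numeric matrix
#'   with taxa as rownames.
#' @param n_components Number of components, at most
#'   `min(taxa - 1, m)`.
#' @return List with `scores` (taxa x n_components), `explained`
#'   (variance shares) and `n_components`.
#' @export
pca_project <- function(fm, n_components = NULL) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (any(!is.finite(x))) stop_input("feature matrix has non-finite entries")
  max_rank <- min(nrow(x) - 1L, ncol(x))
  n_components <- n_components %||% max_rank
  if (n_components < 1L || n_components > max_rank)
    stop_input("n_components must be in 1..", max_rank)
  if (all(apply(x, 2, stats::var) < .Machine$double.eps))
    stop_input("constant feature matrix: PCA undefined")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  scores <- scale(x, center = pc$center, scale = FALSE) %*% rot
  ev <- pc$sdev^2
  list(scores = scores,
       explained = (ev / sum(ev))[seq_len(n_components)],
       n_components = n_components)
}
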