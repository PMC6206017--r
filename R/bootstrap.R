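#' Sample a metabolite character subset
#'
#' Draws `m` distinct characters uniformly (without replacement by
#' default) from a character set; the result is sorted and fully
#' determined by the seed.
#'
#' @param full A [metabolite_set()].
#' @param m Subset size, `1 <= m <= full$m`.
#' @param seed Integer RNG seed.
#' @param replace Sample with replacement (classical bootstrap variant);
#'   the result may then contain fewer than `m` distinct characters and
#'   duplicated columns are kept by [support_analysis()].
#' @return A `"custom"` [metabolite_set()] (without replacement) or a
#'   character vector with possible duplicates (with replacement).
#' @export
sample_characters <- function(full, m, seed, replace = FALSE) {
  stopifnot(inherits(full, "metabolite_set"))
  if (m < 1L || m > full$m)
    stop_input("m must be between 1 and ", full$m)
  picked <- with_seed(seed,
                      sample(full$characters, m, replace = replace))
  if (replace) return(picked)
  metabolite_set("custom", picked)
}

#' Character-resampling bootstrap support of reference clades
#'
#' For each ensemble size `m` in `sizes`, draws `replicates` random
#' character subsets of the feature matrix, rebuilds a UPGMA tree from
#' Euclidean distances per subset, and scores every clade of the
#' reference tree by the percentage of replicate trees in which its
#' exact leaf set appears as a cluster. The root clade (all taxa) is
#' therefore always at 100; singleton leaves are not reported. One
#' master seed spawns an independent child seed per (size, replicate)
#' cell, so the whole analysis is reproducible bit-exactly.
#'
#' @param fm A [assemble_features()] result (typically over the full
#'   metabolite set).
#' @param reference Reference tree ([upgma()] result or rooted
#'   [ape::phylo]); its leaves must all be taxa of `fm`.
#' @param sizes Integer vector of ensemble character counts.
#' @param replicates Replicate trees per size.
#' @param seed Master seed.
#' @param replace Resample characters with replacement.
#' @return Object of class `"support_report"`: list with `support`
#'   (data frame: clade, size (number of leaves), m, support in
#'   percent), `clades` (the reference leaf sets), `replicates`, `seed`.
#' @export
support_analysis <- function(fm, reference, sizes, replicates = 100L,
                             seed = 1L, replace = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(sizes) == 0L) stop_input("empty ensemble size list")
  if (replicates < 1L) stop_input("need at least 1 replicate")
  if (any(sizes < 1L) || any(sizes > fm$characters$m))
    stop_input("sizes must lie in 1..", fm$characters$m)
  ref_clades <- clade_sets(reference)
  ref_leaves <- unique(unlist(ref_clades))
  if (!all(ref_leaves %in% fm$taxa))
    stop_input("reference leaves not all present in the feature matrix")
  vals <- fm$values[ref_leaves, , drop = FALSE]

  cells <- expand.grid(rep = seq_len(replicates), m = sizes)
  cells$seed <- spawn_seeds(seed, nrow(cells))
  hits <- matrix(0L, nrow = length(ref_clades), ncol = length(sizes),
                 dimnames = list(names(ref_clades), as.character(sizes)))
  for (i in seq_len(nrow(cells))) {
    cols <- with_seed(cells$seed[i],
                      sample(ncol(vals), cells$m[i], replace = replace))
    tr <- upgma(euclidean_distances(vals[, cols, drop = FALSE]))
    found <- names(clade_sets(tr))
    mi <- as.character(cells$m[i])
    present <- rownames(hits) %in% found
    hits[present, mi] <- hits[present, mi] + 1L
  }
  support <- data.frame(
    clade = rep(rownames(hits), times = length(sizes)),
    size = rep(lengths(ref_clades), times = length(sizes)),
    m = rep(sizes, each = length(ref_clades)),
    support = 100 * as.vector(hits) / replicates,
    stringsAsFactors = FALSE)
  rownames(support) <- NULL
  structure(list(support = support, clades = ref_clades,
                 replicates = replicates, seed = seed),
            class = "support_report")
}

#' @export
print.support_report <- function(x, ...) {
  cat("Bootstrap support over", length(x$clades), "reference clades,",
      x$replicates, "replicates per ensemble size\n")
  invisible(x)
}
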