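#' End-to-end pipeline configuration
#'
#' Validates and normalizes a run configuration for [run_pipeline()]:
#' which reaction files to load, which metrics and character set to use,
#' optional PCA dimensionality, an optional reference phylogeny for
#' CPCC, and an optional bootstrap grid.
#'
#' @param reaction_files Named character vector: taxon id -> reaction
#'   file path (canonical TSV dialect).
#' @param metrics Metric names (subset of [metric_names()]).
#' @param character_set `"common"` or `"full"`.
#' @param pca_components `NULL` for full-rank scores (distance-identical
#'   to the raw centered vectors) or an integer.
#' @param reference Optional path to a Newick tree or PHYLIP distance
#'   matrix, or an object accepted by [cpcc()]/[clade_sets()].
#' @param label_map Optional label mapping for the reference file.
#' @param bootstrap_sizes Optional integer vector of ensemble sizes;
#'   enables the support analysis (full-set features, hub metric by
#'   default via `bootstrap_metric`).
#' @param bootstrap_metric Metric used for the support analysis.
#' @param replicates Bootstrap replicates per size.
#' @param seed Master seed.
#' @param out_dir Optional output directory for artifacts.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(reaction_files, metrics = metric_names(),
                       character_set = c("common", "full"),
                       pca_components = NULL, reference = NULL,
                       label_map = NULL, bootstrap_sizes = NULL,
                       bootstrap_metric = "hub", replicates = 100L,
                       seed = 1L, out_dir = NULL) {
  character_set <- match.arg(character_set)
  if (is.null(names(reaction_files)) || any(!nzchar(names(reaction_files))))
    stop_input("reaction_files must be named by taxon id")
  missing <- reaction_files[!file.exists(reaction_files)]
  if (length(missing))
    stop_input("reaction files not found: ", paste(missing, collapse = ", "))
  bad <- setdiff(metrics, metric_names())
  if (length(bad))
    stop_input("unknown metrics: ", paste(bad, collapse = ", "))
  if (is.character(reference) && !file.exists(reference))
    stop_input("reference file not found: ", reference)
  if (!bootstrap_metric %in% metric_names())
    stop_input("unknown bootstrap metric: ", bootstrap_metric)
  structure(list(reaction_files = reaction_files, metrics = metrics,
                 character_set = character_set,
                 pca_components = pca_components, reference = reference,
                 label_map = label_map, bootstrap_sizes = bootstrap_sizes,
                 bootstrap_metric = bootstrap_metric,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full topology-to-phylogeny pipeline
#'
#' Parses the reaction files, builds the substrate-product networks,
#' computes the per-metabolite metrics, assembles the feature matrices
#' over the chosen character set, derives Euclidean distance matrices
#' (from full-rank or reduced PCA scores), fits UPGMA dendrograms, and —
#' when a reference phylogeny is given — reports per-metric CPCC values
#' (dendrogram-cophenetic by default, plus the raw-distance variant) and
#' optional bootstrap clade support. When `out_dir` is set, trees,
#' matrices and a machine-readable JSON report are written there.
#'
#' @param cfg A [run_config()].
#' @return Object of class `"run_report"`: list with `summary`
#'   (set sizes and per-taxon N/R), `trees` (per metric), `cpcc`
#'   (data frame per metric: cophenetic and raw variants; `NULL` if no
#'   reference), `support` (or `NULL`), `config` echo.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  message("parsing ", length(cfg$reaction_files), " reaction files")
  rsets <- lapply(names(cfg$reaction_files), function(tx)
    parse_reaction_file(cfg$reaction_files[[tx]], dialect = "tsv",
                        taxon_id = tx))
  names(rsets) <- names(cfg$reaction_files)
  message("building networks")
  nets <- lapply(rsets, build_network)
  chars <- if (cfg$character_set == "common") common_set(nets)
           else full_set(nets)
  summary <- list(
    n_taxa = length(nets),
    character_set = cfg$character_set,
    m = chars$m,
    common_m = common_set(nets)$m,
    full_m = full_set(nets)$m,
    common_reactions = common_reactions(rsets)$R,
    per_taxon = data.frame(
      taxon = names(nets),
      N = vapply(nets, function(x) x$N, integer(1)),
      R = vapply(rsets, function(x) x$R, integer(1)),
      stringsAsFactors = FALSE))
  message("computing node metrics")
  tables <- lapply(nets, node_metrics)

  reference <- cfg$reference
  if (is.character(reference))
    reference <- read_reference(reference, cfg$label_map)
  ref_dm <- NULL
  if (inherits(reference, "distance_matrix")) ref_dm <- reference
  if (inherits(reference, "phylo")) ref_dm <- cophenetic_matrix(reference)

  trees <- list()
  fms <- list()
  cpcc_rows <- list()
  for (metric in cfg$metrics) {
    fm <- assemble_features(tables, metric, chars)
    fms[[metric]] <- fm
    proj <- pca_project(fm, cfg$pca_components)
    dm <- euclidean_distances(proj$scores)
    tr <- upgma(dm)
    trees[[metric]] <- tr
    if (!is.null(ref_dm)) {
      cpcc_rows[[metric]] <- data.frame(
        metric = metric,
        cpcc_cophenetic = cpcc(cophenetic_matrix(tr), ref_dm),
        cpcc_raw = cpcc(dm, ref_dm),
        stringsAsFactors = FALSE)
    }
  }
  cpcc_tab <- if (length(cpcc_rows)) {
    out <- do.call(rbind, cpcc_rows)
    rownames(out) <- NULL
    out
  } else {
    if (!is.null(cfg$reference))
      message("reference not usable for CPCC; stage skipped")
    NULL
  }

  support <- NULL
  if (!is.null(cfg$bootstrap_sizes)) {
    if (inherits(reference, "phylo") ||
        inherits(reference, "dendrogram_upgma")) {
      ref_tree <- reference
    } else {
      # no reference tree: support the tree inferred from the full data
      ref_tree <- trees[[cfg$bootstrap_metric]]
    }
    message("bootstrap support analysis (", cfg$bootstrap_metric, ")")
    boot_fm <- fms[[cfg$bootstrap_metric]] %||%
      assemble_features(tables, cfg$bootstrap_metric, chars)
    support <- support_analysis(boot_fm, ref_tree,
                                sizes = cfg$bootstrap_sizes,
                                replicates = cfg$replicates,
                                seed = cfg$seed)
  }

  report <- structure(
    list(summary = summary, trees = trees, cpcc = cpcc_tab,
         support = support, config = cfg),
    class = "run_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run over", x$summary$n_taxa, "taxa;",
      x$summary$character_set, "character set (m =", x$summary$m, ")\n")
  if (!is.null(x$cpcc)) {
    cat("CPCC against reference:\n")
    print(x$cpcc, digits = 3)
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (metric in names(report$trees))
    write_newick(report$trees[[metric]],
                 file.path(out_dir, paste0(metric, ".tree.nwk")))
  if (!is.null(report$support))
    utils::write.table(report$support$support,
                       file.path(out_dir, "support.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  js <- list(
    summary = report$summary[setdiff(names(report$summary), "per_taxon")],
    per_taxon = report$summary$per_taxon,
    cpcc = report$cpcc,
    seed = report$config$seed)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  invisible(out_dir)
}
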