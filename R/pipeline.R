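#' Run the full co-evolution detection pipeline
#'
#' Fit the gain/loss model, map expected events, build the
#' parametric-bootstrap null, test all candidate pairs, build and summarize
#' the co-evolution network, and write every artifact into a
#' self-describing run directory (config + seed suffice to reproduce it).
#'
#' @param tree A `coevo_tree`, or a path to a Newick file.
#' @param pattern A `phyletic_pattern`, or a path to a phyletic TSV.
#' @param out_dir Run directory (created if missing). `NULL` skips all
#'   file output and returns results in memory only.
#' @param seed Integer seed controlling the bootstrap null (mandatory).
#' @param fdr FDR level in (0, 1); default 0.01.
#' @param exch_threshold Exchangeability threshold; default 5 events.
#' @param bins Null bin lower edges (first edge = threshold).
#' @param null_per_bin Bootstrap coefficients per bin.
#' @param K Rate categories for the model fit.
#' @param two_sided Two-sided correlation test?
#' @param model Optional pre-fitted `gainloss_model` (skips fitting).
#' @param max_null_batches Simulation budget for the null.
#' @return List with `model`, `mapped`, `null`, `result`, `network`,
#'   `summary`, `clustering` and `out_dir`.
#' @export
run_pipeline <- function(tree, pattern, out_dir = NULL, seed,
                         fdr = 0.01, exch_threshold = 5,
                         bins = c(5, 7.5, 10, 15, 20, 30, 50),
                         null_per_bin = 2000L, K = 1L, two_sided = FALSE,
                         model = NULL, max_null_batches = 200L) {
  if (missing(seed)) stop("an explicit seed is required")
  if (!(fdr > 0 && fdr < 1)) stop("fdr must lie strictly between 0 and 1")
  if (bins[1] != exch_threshold) {
    bins <- c(exch_threshold, bins[bins > exch_threshold])
  }
  if (is.character(tree)) tree <- read_newick(file = tree)
  if (is.character(pattern)) pattern <- read_phyletic_pattern(pattern, tree)
  else pattern <- phyletic_pattern(unclass(pattern), tree)

  if (is.null(model)) model <- fit_model(pattern, tree, K = K)
  mapped <- map_events(pattern, tree, model)
  null <- build_null(tree, model, edges = bins, per_bin = null_per_bin,
                     seed = seed, max_batches = max_null_batches)
  result <- coevo_test(mapped, null, fdr = fdr,
                       threshold = exch_threshold, two_sided = two_sided)
  net <- coevo_network(result)
  summ <- network_summary(net)
  clust <- transitivity_cluster(net)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    model_to_json(model, file.path(out_dir, "model.json"))
    write_events(mapped, tree, file.path(out_dir, "events.tsv"),
                 file.path(out_dir, "exchangeability.tsv"))
    write_null(null, file.path(out_dir, "null.json"))
    write_coevo_result(result, file.path(out_dir, "results.tsv"))
    sig <- result[result$significant, c("gene_a", "gene_b"), drop = FALSE]
    utils::write.table(sig, file.path(out_dir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_clustering(clust, file.path(out_dir, "clusters.tsv"))
    run_meta <- list(
      seed = seed, fdr = fdr, exch_threshold = exch_threshold,
      bins = bins, null_per_bin = null_per_bin, K = K,
      two_sided = two_sided,
      n_genes = nrow(pattern), n_leaves = ncol(pattern),
      n_genes_tested = length(attr(result, "genes_tested")),
      n_candidate_pairs = attr(result, "n_pairs"),
      bh_critical = attr(result, "critical"),
      n_significant = sum(result$significant),
      network = summ[c("n_nodes", "n_edges", "average_degree",
                       "median_degree", "fraction_connected",
                       "clustering_coefficient")],
      n_clusters = clust$n_clusters,
      n_singletons = clust$n_singletons
    )
    jsonlite::write_json(run_meta, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(model = model, mapped = mapped, null = null, result = result,
       network = net, summary = summ, clustering = clust,
       out_dir = out_dir)
}
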