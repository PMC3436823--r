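#' Overlap between the co-evolution network and an external network
#'
#' Quantifies how strongly co-evolving pairs are enriched for membership in
#' an external relation (genomic proximity, gene fusion, co-expression,
#' protein-protein interaction, shared metabolic pathway, ...):
#' * `frequency` — external edges over all `choose(m, 2)` possible pairs;
#' * `conditional_frequency` — the share of co-evolution edges that are
#'   also external edges;
#' * `enrichment` — their ratio, an estimate of
#'   `Pr(edge in X | edge co-evolves) / Pr(edge in X)`;
#' * a Fisher exact P-value on the corresponding 2x2 pair table.
#'
#' The conditional frequency conditions on the co-evolution network, so the
#' statistic is directional: `overlap(C, X)` differs from `overlap(X, C)`.
#'
#' @param coevo Canonical edge data frame of co-evolution edges.
#' @param external Canonical edge data frame of the external network.
#' @param universe Character vector of all gene ids under study.
#' @return List with `universe_pairs`, `n_external`, `n_coevo`,
#'   `n_overlap`, `frequency`, `conditional_frequency` (`NA` when there are
#'   no co-evolution edges), `enrichment` and `p_value` (two-sided Fisher).
#' @export
network_overlap <- function(coevo, external, universe) {
  U <- length(universe) * (length(universe) - 1) / 2
  keyify <- function(df) paste(df$gene_a, df$gene_b, sep = "\r")
  coevo <- coevo[coevo$gene_a %in% universe & coevo$gene_b %in% universe, ,
                 drop = FALSE]
  external <- external[external$gene_a %in% universe &
                         external$gene_b %in% universe, , drop = FALSE]
  X <- nrow(external)
  C <- nrow(coevo)
  XC <- sum(keyify(coevo) %in% keyify(external))
  freq <- X / U
  cond <- if (C > 0) XC / C else NA_real_
  enr <- if (C > 0 && freq > 0) cond / freq else NA_real_
  p <- fisher_exact(XC, C - XC, X - XC, U - X - C + XC)
  list(universe_pairs = U, n_external = X, n_coevo = C, n_overlap = XC,
       frequency = freq, conditional_frequency = cond,
       enrichment = enr, p_value = p)
}

#' Enrichment ratio
#'
#' @param conditional_frequency Share of co-evolution edges in the external
#'   network.
#' @param frequency Baseline share of external edges among all pairs.
#' @return `conditional_frequency / frequency`.
#' @export
enrichment_ratio <- function(conditional_frequency, frequency) {
  conditional_frequency / frequency
}

#' Keep only functionally informative edges
#'
#' An edge is functionally informative when both endpoints carry the same
#' functional-category annotation. Edges with an unannotated endpoint are
#' dropped and tallied.
#'
#' @param edges Canonical edge data frame.
#' @param annotation Named character vector gene id -> category (see
#'   [read_annotation()]).
#' @return The filtered edge data frame, with attributes `n_unlabeled`
#'   (edges dropped for a missing annotation) and `n_mismatched` (edges
#'   dropped for differing categories).
#' @export
informative_filter <- function(edges, annotation) {
  ca <- annotation[edges$gene_a]
  cb <- annotation[edges$gene_b]
  unlabeled <- is.na(ca) | is.na(cb)
  same <- !unlabeled & ca == cb
  out <- edges[same, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unlabeled") <- sum(unlabeled)
  attr(out, "n_mismatched") <- sum(!unlabeled & !same)
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test by the probability-mass rule: the P-value sums
#' the probabilities of all tables with the observed margins that are no
#' more probable than the observed one. A zero margin gives P = 1.
#'
#' @param a,b,c,d The four cell counts (row-wise), or `a` may be a 2x2
#'   matrix.
#' @return P-value in `(0, 1]`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Compare the co-evolution network against external networks
#'
#' Produces one overlap row per external network, optionally repeated with
#' the functionally-informative edge filter applied to both sides.
#'
#' @param coevo Canonical edge data frame of co-evolution edges.
#' @param externals Named list of canonical edge data frames.
#' @param universe All gene ids.
#' @param annotation Optional named annotation vector; when given, a second
#'   set of rows is computed on informative edges only.
#' @return Data frame with columns `network`, `informative`, `frequency`,
#'   `conditional_frequency`, `enrichment`, `p_value`, `n_external`,
#'   `n_coevo`, `n_overlap`.
#' @export
compare_networks <- function(coevo, externals, universe, annotation = NULL) {
  one <- function(name, ext, coevo_edges, informative) {
    ov <- network_overlap(coevo_edges, ext, universe)
    data.frame(network = name, informative = informative,
               frequency = ov$frequency,
               conditional_frequency = ov$conditional_frequency,
               enrichment = ov$enrichment, p_value = ov$p_value,
               n_external = ov$n_external, n_coevo = ov$n_coevo,
               n_overlap = ov$n_overlap, stringsAsFactors = FALSE)
  }
  rows <- lapply(names(externals), function(nm) {
    one(nm, externals[[nm]], coevo, FALSE)
  })
  if (!is.null(annotation)) {
    coevo_inf <- informative_filter(coevo, annotation)
    rows <- c(rows, lapply(names(externals), function(nm) {
      one(nm, externals[[nm]], coevo_inf, TRUE)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
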