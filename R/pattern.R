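#' Construct a phyletic pattern
#'
#' A phyletic pattern (phylogenetic profile) records the presence (1) or
#' absence (0) of each gene family in each genome. Rows are gene families,
#' columns genomes; column order must match the tree leaf order for all
#' downstream computation.
#'
#' @param mat Numeric or integer matrix of 0/1 values with unique rownames
#'   (gene ids) and colnames (genome ids).
#' @param tree Optional `coevo_tree`; when given, columns are reordered to
#'   the tree's leaf order and the genome set is validated against the leaf
#'   label set.
#' @return A `phyletic_pattern`: the 0/1 integer matrix with attribute
#'   `constant` (logical per gene: present in no genome or in all genomes —
#'   such genes carry no gain/loss signal and cannot yield finite
#'   correlations).
#' @export
phyletic_pattern <- function(mat, tree = NULL) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("pattern matrix needs gene rownames and genome colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate genome ids")
  bad <- which(!(mat == 0 | mat == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-binary cell at gene '", rownames(mat)[bad[1, 1]],
         "', genome '", colnames(mat)[bad[1, 2]], "': ",
         mat[bad[1, , drop = FALSE]])
  }
  storage.mode(mat) <- "integer"
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "coevo_tree"))
    extra <- setdiff(colnames(mat), tree$tip_labels)
    missing <- setdiff(tree$tip_labels, colnames(mat))
    if (length(extra) || length(missing)) {
      stop("genome set does not match tree leaves; only in table: {",
           paste(extra, collapse = ", "), "}; only in tree: {",
           paste(missing, collapse = ", "), "}")
    }
    mat <- mat[, tree$tip_labels, drop = FALSE]
  }
  rs <- rowSums(mat)
  structure(mat,
            constant = rs == 0L | rs == ncol(mat),
            class = c("phyletic_pattern", "matrix", "array"))
}

#' Read a phyletic pattern from a tab-separated table
#'
#' The file must have a header row of genome ids and a first column of gene
#' ids; every cell must be literally `0` or `1` — no imputation is
#' performed.
#'
#' @param path Path to the TSV file.
#' @param tree Optional `coevo_tree` used to validate the genome set and
#'   reorder columns to leaf order.
#' @return A `phyletic_pattern`.
#' @export
read_phyletic_pattern <- function(path, tree = NULL) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("pattern table needs a gene-id column plus genomes")
  genes <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  ok <- cells == "0" | cells == "1"
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("non-binary cell '", cells[bad[1], bad[2]], "' at gene '",
         genes[bad[1]], "', genome '", colnames(cells)[bad[2]], "'")
  }
  mat <- matrix(as.integer(cells), nrow = nrow(cells),
                dimnames = list(genes, colnames(cells)))
  phyletic_pattern(mat, tree)
}

#' Write a phyletic pattern as a tab-separated table
#'
#' @param pattern A `phyletic_pattern` (or plain 0/1 matrix with dimnames).
#' @param path Output path.
#' @param gene_col Name of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_phyletic_pattern <- function(pattern, path, gene_col = "gene") {
  df <- data.frame(gene = rownames(pattern),
                   unclass(pattern)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Canonicalize an edge list
#'
#' Orders each pair lexicographically, drops self-loops (with a warning) and
#' collapses duplicate pairs, keeping the maximal score when one is present.
#'
#' @param df Data frame whose first two columns are gene ids; an optional
#'   third numeric column is a score.
#' @return A data frame with columns `gene_a`, `gene_b` (sorted within and
#'   across rows) and, when present, `score`.
#' @export
canonical_edges <- function(df) {
  if (nrow(df) == 0) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
    if (ncol(df) >= 3) out$score <- numeric(0)
    return(out)
  }
  a <- as.character(df[[1]])
  b <- as.character(df[[2]])
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop row(s) dropped")
    a <- a[!self]; b <- b[!self]
    df <- df[!self, , drop = FALSE]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- data.frame(gene_a = lo, gene_b = hi, stringsAsFactors = FALSE)
  if (ncol(df) >= 3) out$score <- as.numeric(df[[3]])
  key <- paste(out$gene_a, out$gene_b, sep = "\r")
  if (ncol(df) >= 3) {
    o <- order(key, -out$score)
    out <- out[o, , drop = FALSE]
    key <- key[o]
  }
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an external gene-pair edge list
#'
#' Reads a two- or three-column TSV (`gene_a`, `gene_b`[, `score`]), keeps
#' edges whose endpoints both belong to `universe`, applies a score
#' threshold when a score column is present (the high-confidence convention
#' of interaction databases such as STRING is a score of at least 700), and
#' canonicalizes pairs.
#'
#' @param path Path to the TSV file (header optional; detected by a
#'   non-numeric third field or non-gene first field is not attempted —
#'   pass `header` explicitly if needed).
#' @param universe Character vector of gene ids; edges outside it are
#'   dropped. `NULL` keeps everything.
#' @param score_threshold Minimum score to retain an edge (ignored when
#'   there is no score column).
#' @param header Does the file have a header row?
#' @return Canonical edge data frame (see [canonical_edges()]).
#' @export
read_edge_list <- function(path, universe = NULL, score_threshold = 700,
                           header = FALSE) {
  df <- tryCatch(
    utils::read.delim(path, header = header, stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(df) || nrow(df) == 0) {
    return(canonical_edges(data.frame(a = character(0), b = character(0))))
  }
  out <- canonical_edges(df)
  if (!is.null(out$score) && !is.null(score_threshold)) {
    out <- out[out$score >= score_threshold, , drop = FALSE]
  }
  if (!is.null(universe)) {
    out <- out[out$gene_a %in% universe & out$gene_b %in% universe, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a gene-to-functional-category annotation table
#'
#' @param path Two-column TSV: gene id, category label. One label per gene;
#'   genes absent from the table are treated as unannotated.
#' @param header Does the file have a header row?
#' @return Named character vector mapping gene id to category.
#' @export
read_annotation <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("annotation table needs two columns")
  if (anyDuplicated(df[[1]])) stop("multiple labels for gene(s): ",
                                   paste(unique(df[[1]][duplicated(df[[1]])]),
                                         collapse = ", "))
  stats::setNames(df[[2]], df[[1]])
}
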