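#' Read a rooted species tree from Newick
#'
#' Parses a Newick string or file into the indexed tree structure used by all
#' downstream gain/loss computations. The tree must have at least three
#' leaves with unique, non-empty labels and branch lengths on every non-root
#' edge (in substitutions per site or any proportional unit; the model's
#' branch-scale parameter absorbs the unit). Polytomies, including an
#' unrooted basal trifurcation, are resolved into bifurcations by inserting
#' zero-length branches; a zero-length branch receives zero expected events
#' under the model, so inference is unaffected by the arbitrary resolution.
#'
#' Every non-root node receives a stable branch index in 1..(2n-2), assigned
#' by preorder traversal from the root with children visited in Newick file
#' order, so that a given Newick string always yields the same event-vector
#' layout.
#'
#' @param text Newick string (used if `file` is `NULL`).
#' @param file Path to a Newick file.
#' @return An object of class `coevo_tree`: a list with elements `phylo`
#'   (the resolved [ape::read.tree()] object), `n_tips`, `n_nodes`, `root`,
#'   `parent` (integer vector indexed by node id, `NA` at the root),
#'   `children` (list of child ids in file order), `brlen` (branch length of
#'   the edge above each node, `NA` at the root), `branch_index` (integer
#'   vector, `NA` at the root), `preorder` (node ids, root first), and
#'   `tip_labels`.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("provide either `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL
  )
  if (is.null(phy)) stop("Newick parse failure: ", substr(text, 1, 60))
  as_coevo_tree(phy)
}

# Light syntactic scan so that malformed input is reported with the position
# of the offending character rather than an opaque parser error.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick format error: unbalanced ')' at character position ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick format error: ", depth, " unclosed '(' at end of string ",
         "(position ", length(chars), ")")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick format error: missing terminating ';' at character position ",
         nchar(text))
  }
  invisible(TRUE)
}

#' Convert an ape phylo object to the indexed tree structure
#'
#' Resolves polytomies (zero-length branches), validates the tree and builds
#' the deterministic branch indexing. See [read_newick()] for details.
#'
#' @param phy An [ape::read.tree()] `phylo` object.
#' @return A `coevo_tree`.
#' @export
as_coevo_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a phylo object")
  if (length(phy$tip.label) < 3L) stop("tree must have at least 3 leaves")
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(phy$tip.label))) stop("empty leaf label")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    phy <- ape::multi2di(phy, random = FALSE)
  }
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("branch lengths required on all non-root edges")
  }
  if (any(phy$edge.length < 0)) stop("negative branch length")
  if (all(phy$edge.length == 0)) stop("at least one branch length must be > 0")
  phy <- stats::reorder(phy, "cladewise")

  n <- length(phy$tip.label)
  n_nodes <- n + phy$Nnode
  root <- n + 1L
  parent <- rep(NA_integer_, n_nodes)
  brlen <- rep(NA_real_, n_nodes)
  branch_index <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  brlen[phy$edge[, 2]] <- phy$edge.length
  # cladewise edge order is a preorder with children in file order: the i-th
  # edge's child node gets branch index i
  branch_index[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    children[[p]] <- c(children[[p]], phy$edge[i, 2])
  }
  stopifnot(nrow(phy$edge) == 2L * n - 2L)
  structure(
    list(
      phylo = phy,
      n_tips = n,
      n_nodes = n_nodes,
      root = root,
      parent = parent,
      children = children,
      brlen = brlen,
      branch_index = branch_index,
      preorder = c(root, phy$edge[, 2]),
      tip_labels = phy$tip.label
    ),
    class = "coevo_tree"
  )
}

#' Number of branches of an indexed tree
#'
#' @param tree A `coevo_tree`.
#' @return Integer, `2 * n_tips - 2`.
#' @export
n_branches <- function(tree) {
  stopifnot(inherits(tree, "coevo_tree"))
  2L * tree$n_tips - 2L
}

#' Serialize an indexed tree back to Newick
#'
#' @param tree A `coevo_tree`.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "coevo_tree"))
  txt <- ape::write.tree(tree$phylo, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @export
print.coevo_tree <- function(x, ...) {
  cat("coevo_tree:", x$n_tips, "leaves,", n_branches(x), "indexed branches\n")
  invisible(x)
}

#' Branch lengths ordered by branch index
#'
#' @param tree A `coevo_tree`.
#' @return Numeric vector of length `2n - 2`; element `i` is the length of
#'   the branch with index `i`.
#' @export
branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "coevo_tree"))
  out <- numeric(n_branches(tree))
  nr <- which(!is.na(tree$branch_index))
  out[tree$branch_index[nr]] <- tree$brlen[nr]
  out
}
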