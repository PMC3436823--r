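#' Pearson correlation between two event vectors
#'
#' The co-evolution statistic: the product-moment correlation between two
#' `4n - 4` dimensional vectors of per-branch expected gains and losses.
#' A constant vector has no defined correlation; `NA` is returned (never a
#' silent 0).
#'
#' @param v1,v2 Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
pearson_events <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("event vectors differ in length")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}

#' Genes passing the exchangeability filter and their candidate pairs
#'
#' Only gene families whose exchangeability strictly exceeds `threshold`
#' (default 5 events, balancing loss of true pairs against multiple-testing
#' burden) are tested; all unordered pairs of passing genes are candidates,
#' so `m` passing genes yield `choose(m, 2)` pairs.
#'
#' @param exch Named numeric vector of exchangeabilities.
#' @param threshold Strict lower bound (pairs require both genes above it).
#' @return List with `genes` (ids passing), `n_pairs` (exact count as a
#'   double) and `pairs` — a 2-column matrix of id pairs, canonical order —
#'   unless `count_only = TRUE`.
#' @param count_only If `TRUE`, do not materialize the pair matrix (useful
#'   when only the count is needed).
#' @export
candidate_pairs <- function(exch, threshold = 5, count_only = FALSE) {
  pass <- names(exch)[exch > threshold]
  m <- length(pass)
  n_pairs <- m * (m - 1) / 2
  if (count_only) return(list(genes = pass, n_pairs = n_pairs, pairs = NULL))
  if (m < 2) {
    return(list(genes = pass, n_pairs = 0,
                pairs = matrix(character(0), 0, 2)))
  }
  idx <- utils::combn(m, 2)
  list(genes = pass, n_pairs = n_pairs,
       pairs = cbind(pass[idx[1, ]], pass[idx[2, ]]))
}

#' Assign a minimal exchangeability to its null bin
#'
#' Bins partition `[threshold, Inf)`; the first edge is the exchangeability
#' threshold itself. A value on a bin edge goes to the lower bin.
#'
#' @param min_exch Numeric vector of pairwise minimal exchangeabilities.
#' @param edges Increasing vector of bin lower edges (first = threshold).
#' @return Integer bin ids (1-based); values below the first edge get `NA`.
#' @export
assign_bin <- function(min_exch, edges) {
  # left-open intervals (e_i, e_{i+1}]: a value sitting exactly on a bin
  # edge goes to the lower bin, and the threshold itself is excluded
  b <- findInterval(min_exch, edges, left.open = TRUE)
  b[b == 0L] <- NA_integer_
  b
}

#' Build the exchangeability-binned parametric-bootstrap null
#'
#' Repeatedly simulates pairs of independently evolving gene families under
#' the fitted model, maps their event vectors by stochastic mapping exactly
#' as for the observed data, and records each pair's Pearson correlation in
#' the bin of its minimal exchangeability. Simulation continues in batches
#' until every bin holds at least `per_bin` coefficients or `max_batches`
#' is exhausted; bins still short are flagged (their shortfall reported),
#' since some exchangeability ranges may be unreachable under a given model
#' and tree.
#'
#' @param tree `coevo_tree`.
#' @param model Fitted `gainloss_model`.
#' @param edges Bin lower edges over minimal exchangeability; the first
#'   edge is the exchangeability threshold.
#' @param per_bin Target number of null coefficients per bin.
#' @param seed Integer seed (mandatory: the null must be reproducible).
#' @param batch Genes simulated per batch (must be even; paired up 2 at a
#'   time).
#' @param max_batches Simulation budget.
#' @return Object of class `coevo_null`: list with `edges`, `bins` (list of
#'   sorted correlation vectors), `counts`, `short` (logical per bin),
#'   `seed`, `model`.
#' @export
build_null <- function(tree, model, edges = c(5, 7.5, 10, 15, 20, 30, 50),
                       per_bin = 10000L, seed, batch = 2000L,
                       max_batches = 200L) {
  if (missing(seed)) stop("an explicit seed is required for the null")
  set.seed(seed)
  nbin <- length(edges)
  bins <- vector("list", nbin)
  for (i in seq_len(nbin)) bins[[i]] <- numeric(0)
  batch <- as.integer(batch)
  if (batch %% 2L != 0L) batch <- batch + 1L
  for (b in seq_len(max_batches)) {
    sim <- simulate_genes(tree, model, batch)
    mapped <- map_events(sim$pattern, tree, model)
    i1 <- seq(1L, batch, by = 2L)
    i2 <- i1 + 1L
    e1 <- mapped$exchangeability[i1]
    e2 <- mapped$exchangeability[i2]
    min_exch <- pmin(e1, e2)
    keep <- e1 > edges[1] & e2 > edges[1]
    if (any(keep)) {
      v1 <- mapped$events[i1[keep], , drop = FALSE]
      v2 <- mapped$events[i2[keep], , drop = FALSE]
      r <- row_pearson(v1, v2)
      bid <- assign_bin(min_exch[keep], edges)
      ok <- !is.na(r) & !is.na(bid)
      for (i in which(ok)) {
        bins[[bid[i]]] <- c(bins[[bid[i]]], r[i])
      }
    }
    if (all(lengths(bins) >= per_bin)) break
  }
  counts <- lengths(bins)
  structure(
    list(edges = edges,
         bins = lapply(bins, sort),
         counts = counts,
         short = counts < per_bin,
         per_bin = per_bin,
         seed = seed,
         model = list(gain = model$gain, loss = model$loss,
                      rho = model$rho, K = model$K,
                      alpha_gain = model$alpha_gain,
                      alpha_loss = model$alpha_loss)),
    class = "coevo_null"
  )
}

# Row-wise Pearson correlation between two matrices of event vectors.
row_pearson <- function(v1, v2) {
  m1 <- v1 - rowMeans(v1)
  m2 <- v2 - rowMeans(v2)
  s1 <- sqrt(rowSums(m1^2))
  s2 <- sqrt(rowSums(m2^2))
  num <- rowSums(m1 * m2)
  out <- ifelse(s1 > 0 & s2 > 0, num / (s1 * s2), NA_real_)
  pmin(1, pmax(-1, out))
}

#' @export
print.coevo_null <- function(x, ...) {
  cat("coevo_null:", length(x$edges), "bins over minimal exchangeability\n")
  for (i in seq_along(x$edges)) {
    hi <- if (i < length(x$edges)) x$edges[i + 1] else Inf
    cat(sprintf("  bin %d [%g, %g): %d samples%s\n", i, x$edges[i], hi,
                x$counts[i], if (x$short[i]) "  (short)" else ""))
  }
  invisible(x)
}

#' Empirical one-sided P-value against a null sample
#'
#' Add-one empirical tail probability `P = (#{null >= r} + 1) / (N + 1)`
#' for the one-sided test of positive co-evolution; with `two_sided =
#' TRUE`, `|null| >= |r|` is counted instead. The add-one rule means `P`
#' is never 0, which finite-sample FDR control requires.
#'
#' @param r Observed correlation(s).
#' @param null Numeric vector of null correlations (need not be sorted).
#' @param two_sided Count both tails?
#' @return P-value(s) in `(0, 1]`.
#' @export
empirical_pvalue <- function(r, null, two_sided = FALSE) {
  if (length(null) == 0) {
    stop("empty null bin: build_null() with a larger budget or wider bins")
  }
  if (two_sided) {
    null <- abs(null)
    r <- abs(r)
  }
  s <- sort(null)
  N <- length(s)
  ge <- N - findInterval(r, s, left.open = TRUE)
  (ge + 1) / (N + 1)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Finds the largest `k` with `p_(k) <= k q / m`, rejects all P-values at
#' or below the critical value `k q / m`, and returns monotone q-values
#' (cumulative-minimum adjusted).
#'
#' @param p P-values in `(0, 1]`.
#' @param q FDR level.
#' @return List with `critical` (the step-up critical value, 0 when nothing
#'   is rejected), `reject` (logical), `qvalue` and `k` (number rejected).
#' @export
bh_fdr <- function(p, q = 0.01) {
  m <- length(p)
  if (m == 0) {
    return(list(critical = 0, reject = logical(0), qvalue = numeric(0),
                k = 0L))
  }
  o <- order(p)
  ps <- p[o]
  ok <- ps <= seq_len(m) * q / m
  k <- if (any(ok)) max(which(ok)) else 0L
  critical <- bh_critical_value(k, m, q)
  qs <- rev(cummin(rev(ps * m / seq_len(m))))
  qs <- pmin(qs, 1)
  qvalue <- numeric(m)
  qvalue[o] <- qs
  list(critical = critical, reject = p <= critical & k > 0L,
       qvalue = qvalue, k = k)
}

#' Benjamini-Hochberg critical value
#'
#' @param k Rank of the largest rejected P-value.
#' @param m Number of tests.
#' @param q FDR level.
#' @return `k * q / m` (0 when `k` is 0).
#' @export
bh_critical_value <- function(k, m, q) {
  if (k <= 0) return(0)
  k * q / m
}

#' Test all candidate pairs for co-evolution
#'
#' Ties the statistical pipeline together: filters genes by
#' exchangeability, computes the Pearson correlation of every candidate
#' pair's event vectors, looks up each pair's empirical P-value in the null
#' bin of its minimal exchangeability, and applies Benjamini-Hochberg FDR
#' control.
#'
#' @param mapped Result of [map_events()] on the observed pattern.
#' @param null A `coevo_null` built under the same fitted model.
#' @param fdr FDR level (default 0.01).
#' @param threshold Exchangeability threshold; defaults to the null's first
#'   bin edge.
#' @param two_sided Use a two-sided test (default one-sided, positive
#'   co-evolution).
#' @return Object of class `coevo_result`: a data frame with columns
#'   `gene_a`, `gene_b`, `r`, `min_exch`, `bin`, `pvalue`, `qvalue`,
#'   `significant`, plus attributes `critical`, `fdr`, `threshold`,
#'   `genes_tested`, `n_pairs`, `genes_all`.
#' @export
coevo_test <- function(mapped, null, fdr = 0.01, threshold = NULL,
                       two_sided = FALSE) {
  stopifnot(inherits(null, "coevo_null"))
  if (is.null(threshold)) threshold <- null$edges[1]
  cand <- candidate_pairs(mapped$exchangeability, threshold)
  if (cand$n_pairs == 0) {
    res <- data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), min_exch = numeric(0),
                      bin = integer(0), pvalue = numeric(0),
                      qvalue = numeric(0), significant = logical(0))
    attr(res, "critical") <- 0
  } else {
    ia <- match(cand$pairs[, 1], rownames(mapped$events))
    ib <- match(cand$pairs[, 2], rownames(mapped$events))
    r <- row_pearson(mapped$events[ia, , drop = FALSE],
                     mapped$events[ib, , drop = FALSE])
    min_exch <- pmin(mapped$exchangeability[ia], mapped$exchangeability[ib])
    bin <- assign_bin(min_exch, null$edges)
    pvalue <- rep(NA_real_, length(r))
    for (b in unique(bin[!is.na(bin)])) {
      if (null$counts[b] == 0) next
      sel <- !is.na(bin) & bin == b & !is.na(r)
      pvalue[sel] <- empirical_pvalue(r[sel], null$bins[[b]],
                                      two_sided = two_sided)
    }
    testable <- !is.na(pvalue)
    bh <- bh_fdr(pvalue[testable], q = fdr)
    significant <- rep(FALSE, length(r))
    qvalue <- rep(NA_real_, length(r))
    significant[testable] <- bh$reject
    qvalue[testable] <- bh$qvalue
    lo <- pmin(cand$pairs[, 1], cand$pairs[, 2])
    hi <- pmax(cand$pairs[, 1], cand$pairs[, 2])
    res <- data.frame(gene_a = lo, gene_b = hi, r = r,
                      min_exch = unname(min_exch), bin = bin,
                      pvalue = pvalue, qvalue = qvalue,
                      significant = significant,
                      stringsAsFactors = FALSE)
    attr(res, "critical") <- bh$critical
  }
  attr(res, "fdr") <- fdr
  attr(res, "threshold") <- threshold
  attr(res, "genes_tested") <- cand$genes
  attr(res, "n_pairs") <- cand$n_pairs
  attr(res, "genes_all") <- names(mapped$exchangeability)
  class(res) <- c("coevo_result", "data.frame")
  res
}

#' Write co-evolution test results as TSV
#'
#' @param result A `coevo_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coevo_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a null table
#'
#' The null is stored as a JSON document holding the bin edges, the seed,
#' the generating model parameters and every stored coefficient, so a run
#' can be reproduced or reused exactly.
#'
#' @param null A `coevo_null`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null <- function(null, path) {
  doc <- list(edges = null$edges, per_bin = null$per_bin, seed = null$seed,
              model = null$model, counts = null$counts,
              bins = null$bins)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_null
#' @export
read_null <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  bins <- doc$bins
  if (!is.list(bins)) bins <- lapply(seq_len(nrow(bins)), function(i) bins[i, ])
  bins <- lapply(bins, as.numeric)
  structure(
    list(edges = as.numeric(doc$edges), bins = bins,
         counts = as.integer(doc$counts),
         short = as.integer(doc$counts) < doc$per_bin,
         per_bin = doc$per_bin, seed = doc$seed, model = doc$model),
    class = "coevo_null"
  )
}
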