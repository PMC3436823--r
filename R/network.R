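#' Build the co-evolution network
#'
#' Vertices are all analyzed gene families (including isolates — families
#' with no significant partner); undirected edges connect significantly
#' co-evolving pairs.
#'
#' @param edges Two-column matrix/data frame of gene-id pairs (e.g. the
#'   significant rows of a [coevo_test()] result), or a `coevo_result`
#'   (its significant pairs are used).
#' @param genes Character vector of all gene ids (the vertex set). For a
#'   `coevo_result` input this defaults to all analyzed genes.
#' @return An [igraph::graph] object.
#' @export
coevo_network <- function(edges, genes = NULL) {
  if (inherits(edges, "coevo_result")) {
    if (is.null(genes)) genes <- attr(edges, "genes_all")
    edges <- as.matrix(edges[edges$significant, c("gene_a", "gene_b")])
  }
  edges <- as.matrix(edges)
  if (is.null(genes)) genes <- sort(unique(as.vector(edges)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  g <- igraph::simplify(g)
  g
}

#' Degree summary of a network
#'
#' The average is `2E / N` over ALL vertices, isolates included — the
#' convention under which a network of 4,593 families and 8,710 edges has
#' average degree 3.793.
#'
#' @param net An igraph object.
#' @return List with `average`, `median`, `fraction_connected` (share of
#'   vertices with degree > 0), `n_connected`, `histogram` (named table of
#'   degree counts) and `degrees`.
#' @export
degree_summary <- function(net) {
  d <- igraph::degree(net)
  if (length(d) == 0) {
    return(list(average = 0, median = 0, fraction_connected = 0,
                n_connected = 0L, histogram = table(integer(0)),
                degrees = d))
  }
  list(average = mean(d),
       median = stats::median(d),
       fraction_connected = mean(d > 0),
       n_connected = sum(d > 0),
       histogram = table(d),
       degrees = d)
}

#' Watts-Strogatz clustering coefficient
#'
#' Mean over vertices of the local transitivity (realized / possible edges
#' among a vertex's neighbours). Vertices of degree < 2 contribute 0.
#' Whether isolates (degree 0) enter the average is a convention that
#' changes the statistic; by default they are excluded.
#'
#' @param net An igraph object.
#' @param include_isolates Include degree-0 vertices in the average?
#' @return Scalar in `[0, 1]` (0 for an empty network).
#' @export
clustering_coefficient <- function(net, include_isolates = FALSE) {
  d <- igraph::degree(net)
  keep <- if (include_isolates) rep(TRUE, length(d)) else d > 0
  if (!any(keep)) return(0)
  lt <- igraph::transitivity(net, type = "local",
                             vids = igraph::V(net)[keep])
  lt[is.nan(lt) | is.na(lt)] <- 0 # degree < 2: no neighbour pair to close
  mean(lt)
}

#' Log-log linear fit of the degree distribution
#'
#' Ordinary least squares of `log10(count)` on `log10(degree)` over
#' degrees >= 1 with at least one vertex; a high R-squared is the classic
#' (if rough) signature of a scale-free degree distribution.
#'
#' @param degrees Integer vector of vertex degrees, or a named histogram
#'   table as returned by [degree_summary()].
#' @return List with `slope`, `intercept`, `r_squared`, `n_points` and
#'   `unreliable` (fewer than 3 distinct degrees).
#' @export
powerlaw_loglog_fit <- function(degrees) {
  h <- degree_histogram(degrees)
  h <- h[h$degree >= 1 & h$count >= 1, , drop = FALSE]
  if (nrow(h) < 2) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n_points = nrow(h),
                unreliable = TRUE))
  }
  fit <- stats::lm(log10(count) ~ log10(degree), data = h)
  y <- log10(h$count)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::resid(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n_points = nrow(h),
       unreliable = nrow(h) < 3)
}

degree_histogram <- function(degrees) {
  if (is.table(degrees)) {
    data.frame(degree = as.integer(names(degrees)),
               count = as.integer(degrees))
  } else {
    tb <- table(degrees)
    data.frame(degree = as.integer(names(tb)), count = as.integer(tb))
  }
}

#' Chi-square goodness of fit of the degree distribution to a Poisson law
#'
#' Tests the degree histogram against `Poisson(mean degree)`. Adjacent
#' degree classes are pooled from the left until each pooled class has
#' expected count >= 5 (the remainder joins the last class), and one degree
#' of freedom is charged for the estimated mean.
#'
#' @param degrees Integer vector of degrees, or a degree histogram table.
#' @return List with `p_value`, `statistic`, `df`, `n_bins` and
#'   `unreliable` (fewer than 2 pooled classes, in which case the test is
#'   undefined and `p_value` is `NA`).
#' @export
poisson_gof <- function(degrees) {
  h <- degree_histogram(degrees)
  N <- sum(h$count)
  lambda <- sum(h$degree * h$count) / N
  kmax <- max(h$degree)
  obs <- integer(kmax + 1L)
  obs[h$degree + 1L] <- h$count
  expd <- N * stats::dpois(0:kmax, lambda)
  expd[kmax + 1L] <- expd[kmax + 1L] +
    N * stats::ppois(kmax, lambda, lower.tail = FALSE)
  # pool classes left-to-right until each expected count reaches 5
  po <- numeric(0); pe <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expd[i]
    if (ce >= 5) {
      po <- c(po, co); pe <- c(pe, ce)
      co <- 0; ce <- 0
    }
  }
  if (ce > 0 || co > 0) {
    if (length(pe) > 0) {
      po[length(po)] <- po[length(po)] + co
      pe[length(pe)] <- pe[length(pe)] + ce
    } else {
      po <- co; pe <- ce
    }
  }
  if (length(po) < 2) {
    return(list(p_value = NA_real_, statistic = NA_real_, df = NA_integer_,
                n_bins = length(po), unreliable = TRUE))
  }
  stat <- sum((po - pe)^2 / pe)
  df <- max(1L, length(po) - 2L) # one df lost to the estimated mean
  list(p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df, n_bins = length(po),
       unreliable = length(po) < 3)
}

# Cluster-editing cost of a partition: edges between clusters (deletions)
# plus non-edges within clusters (insertions). `adj` is a logical adjacency
# matrix; `membership` an integer vector.
editing_cost <- function(adj, membership) {
  n <- nrow(adj)
  cost <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- membership[i] == membership[j]
      if (adj[i, j] && !same) cost <- cost + 1
      if (!adj[i, j] && same) cost <- cost + 1
    }
  }
  cost
}

#' Partition a network by greedy cluster editing
#'
#' Heuristic for the cluster-editing (transitivity clustering) objective:
#' minimize the number of edge deletions plus insertions needed to turn the
#' graph into disjoint cliques. Each connected component is processed
#' separately: clusters are grown greedily from the highest-degree
#' unassigned vertex, adding the candidate with the best edge surplus while
#' it is connected to at least half the cluster (merge-preferring
#' tie-break), followed by a single pass of node moves that accepts any
#' strict cost reduction. Vertices are always scanned in lexicographic
#' order, so the result is deterministic. Isolates become singletons.
#'
#' @param net An igraph object with named vertices.
#' @return Object of class `coevo_clustering`: list with `membership`
#'   (named integer vector, cluster ids 1..C), `sizes`, `n_clusters`,
#'   `n_singletons` and `cost` (total editing cost of the partition).
#' @export
transitivity_cluster <- function(net) {
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(net)))
  membership <- stats::setNames(rep(NA_integer_, length(nm)), nm)
  comp <- igraph::components(net)
  next_id <- 1L
  total_cost <- 0
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    vnames <- sort(nm[vids])
    k <- length(vnames)
    if (k == 1) {
      membership[vnames] <- next_id
      next_id <- next_id + 1L
      next
    }
    sub <- igraph::induced_subgraph(net, nm[vids])
    adj <- as.matrix(igraph::as_adjacency_matrix(sub)) > 0
    adj <- adj[vnames, vnames]
    deg <- rowSums(adj)
    local <- rep(NA_integer_, k)
    cl_count <- 0L
    unassigned <- rep(TRUE, k)
    while (any(unassigned)) {
      cand <- which(unassigned)
      seed <- cand[order(-deg[cand], vnames[cand])][1]
      cl_count <- cl_count + 1L
      cluster <- seed
      local[seed] <- cl_count
      unassigned[seed] <- FALSE
      repeat {
        cand <- which(unassigned)
        if (length(cand) == 0) break
        e <- if (length(cluster) == 1) adj[cand, cluster]
             else rowSums(adj[cand, cluster, drop = FALSE])
        surplus <- 2 * e - length(cluster) # edges minus non-edges
        best <- cand[surplus >= 0 & e > 0]
        if (length(best) == 0) break
        bs <- surplus[match(best, cand)]
        pick <- best[order(-bs, vnames[best])][1]
        cluster <- c(cluster, pick)
        local[pick] <- cl_count
        unassigned[pick] <- FALSE
      }
    }
    # single-pass node-move refinement in lexicographic order
    for (i in seq_len(k)) {
      cur <- local[i]
      in_cur <- which(local == cur & seq_len(k) != i)
      e_cur <- sum(adj[i, in_cur])
      delta_leave <- e_cur - (length(in_cur) - e_cur)
      targets <- unique(local[which(adj[i, ])])
      targets <- setdiff(targets, cur)
      best_delta <- 0
      best_target <- NA_integer_
      for (tcl in targets) {
        in_t <- which(local == tcl)
        e_t <- sum(adj[i, in_t])
        delta <- delta_leave + (length(in_t) - 2 * e_t)
        if (delta < best_delta) {
          best_delta <- delta
          best_target <- tcl
        }
      }
      # moving out to a fresh singleton
      if (length(in_cur) > 0 && delta_leave < best_delta) {
        best_delta <- delta_leave
        best_target <- 0L
      }
      if (!is.na(best_target) && best_delta < 0) {
        if (best_target == 0L) {
          cl_count <- cl_count + 1L
          local[i] <- cl_count
        } else {
          local[i] <- best_target
        }
      }
    }
    membership[vnames] <- next_id + match(local, unique(local)) - 1L
    next_id <- next_id + length(unique(local))
    total_cost <- total_cost + editing_cost(adj, local)
  }
  sizes <- table(membership)
  structure(
    list(membership = membership,
         sizes = as.integer(sizes),
         n_clusters = length(sizes),
         n_singletons = sum(sizes == 1L),
         cost = total_cost),
    class = "coevo_clustering"
  )
}

#' @export
print.coevo_clustering <- function(x, ...) {
  cat("coevo_clustering:", x$n_clusters, "clusters (",
      x$n_singletons, "singletons ), editing cost", x$cost, "\n")
  invisible(x)
}

#' All network summary statistics in one call
#'
#' @param net An igraph object.
#' @return List combining [degree_summary()], [clustering_coefficient()],
#'   [powerlaw_loglog_fit()] and [poisson_gof()].
#' @export
network_summary <- function(net) {
  ds <- degree_summary(net)
  list(n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net),
       average_degree = ds$average,
       median_degree = ds$median,
       fraction_connected = ds$fraction_connected,
       n_connected = ds$n_connected,
       clustering_coefficient = clustering_coefficient(net),
       powerlaw = powerlaw_loglog_fit(ds$degrees),
       poisson = poisson_gof(ds$degrees))
}

#' Write a clustering as TSV
#'
#' @param clustering A `coevo_clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(clustering, path) {
  m <- clustering$membership
  sz <- table(m)
  df <- data.frame(cluster = unname(m), gene = names(m),
                   cluster_size = as.integer(sz[as.character(m)]))
  df <- df[order(df$cluster, df$gene), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
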