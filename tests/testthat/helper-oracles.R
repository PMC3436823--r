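# Shared fixtures and independent oracles used across the suite.

quartet_tree <- function() {
  read_newick("((A:1,B:1):1,(C:1,D:1):1);")
}

random_tree <- function(n, seed, min_len = 0.05, max_len = 0.8) {
  set.seed(seed)
  phy <- ape::rtree(n, br = function(k) stats::runif(k, min_len, max_len))
  as_coevo_tree(phy)
}

random_pattern <- function(tree, n_genes, seed, p = 0.5) {
  set.seed(seed)
  mat <- matrix(stats::rbinom(n_genes * tree$n_tips, 1, p), n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                tree$tip_labels))
  phyletic_pattern(mat, tree)
}

# Brute-force likelihood by exhaustive enumeration of internal-node states
# (feasible for <= 6 leaves). Mixture over categories handled by averaging.
brute_loglik <- function(row, tree, model) {
  internals <- (tree$n_tips + 1L):tree$n_nodes
  per_cat <- vapply(seq_len(model$K), function(k) {
    g <- model$gain * model$categories$gain_mult[k]
    l <- model$loss * model$categories$loss_mult[k]
    pi <- stationary_freq(g, l)
    combos <- as.matrix(expand.grid(rep(list(0:1), length(internals))))
    tot <- 0
    for (ci in seq_len(nrow(combos))) {
      st <- integer(tree$n_nodes)
      st[seq_len(tree$n_tips)] <- row
      st[internals] <- combos[ci, ]
      p <- pi[st[tree$root] + 1]
      for (v in tree$preorder) {
        if (v == tree$root) next
        P <- transition_probability(g, l, model$rho * tree$brlen[v])
        p <- p * P[st[tree$parent[v]] + 1, st[v] + 1]
      }
      tot <- tot + p
    }
    tot
  }, numeric(1))
  log(mean(per_cat))
}

# All set partitions of n elements as membership vectors (restricted
# growth strings); Bell(7) = 877 so exhaustive search is cheap.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (k in seq_len(maxid + 1L)) {
      rec(c(prefix, k), max(maxid, k))
    }
  }
  rec(integer(0), 0L)
  out
}

# Minimum cluster-editing cost by exhaustive partition search.
optimal_editing_cost <- function(adj) {
  n <- nrow(adj)
  best <- Inf
  for (mb in all_partitions(n)) {
    cost <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        same <- mb[i] == mb[j]
        if (adj[i, j] && !same) cost <- cost + 1
        if (!adj[i, j] && same) cost <- cost + 1
      }
    }
    if (cost < best) best <- cost
  }
  best
}

# Two-sided Fisher P-value by direct hypergeometric enumeration over all
# tables with the observed margins (probability-mass rule).
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  amin <- max(0L, c1 - (n - r1))
  amax <- min(r1, c1)
  probs <- stats::dhyper(amin:amax, c1, n - c1, r1)
  pobs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Direct Benjamini-Hochberg step-up enumeration.
bh_enum <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  if (k == 0) return(integer(0))
  which(p <= ps[k])
}
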