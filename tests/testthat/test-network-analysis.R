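triangle_graph <- function() {
  coevo_network(cbind(c("a", "a", "b"), c("b", "c", "c")))
}

test_that("degree summary counts isolates in the average", {
  net <- triangle_graph()
  ds <- degree_summary(net)
  expect_equal(ds$average, 2)
  expect_equal(ds$median, 2)
  expect_equal(ds$fraction_connected, 1)

  # isolates pull the average down but stay in the denominator
  net5 <- coevo_network(cbind(c("a", "a", "b"), c("b", "c", "c")),
                        genes = c("a", "b", "c", "d", "e"))
  ds5 <- degree_summary(net5)
  expect_equal(ds5$average, 2 * 3 / 5)
  expect_equal(ds5$fraction_connected, 3 / 5)
  expect_equal(ds5$n_connected, 3L)

  empty <- coevo_network(matrix(character(0), 0, 2), genes = character(0))
  expect_equal(degree_summary(empty)$average, 0)
})

test_that("handshake lemma holds on random graphs", {
  set.seed(151)
  for (i in 1:5) {
    g <- igraph::sample_gnp(30, 0.15)
    igraph::V(g)$name <- sprintf("v%02d", 1:30)
    expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  }
})

test_that("clustering coefficient follows the local-transitivity convention", {
  expect_equal(clustering_coefficient(triangle_graph()), 1)
  star <- coevo_network(cbind(rep("hub", 4), paste0("leaf", 1:4)))
  expect_equal(clustering_coefficient(star), 0)
  # triangle plus one pendant: (1 + 1 + 1/3 + 0) / 4
  tp <- coevo_network(cbind(c("a", "a", "b", "a"), c("b", "c", "c", "d")))
  expect_equal(clustering_coefficient(tp), (1 + 1 + 1 / 3 + 0) / 4,
               tolerance = 1e-12)
  # isolates excluded by default, included on request
  tp5 <- coevo_network(cbind(c("a", "a", "b", "a"), c("b", "c", "c", "d")),
                       genes = c("a", "b", "c", "d", "z"))
  expect_equal(clustering_coefficient(tp5), (1 + 1 + 1 / 3 + 0) / 4,
               tolerance = 1e-12)
  expect_equal(clustering_coefficient(tp5, include_isolates = TRUE),
               (1 + 1 + 1 / 3 + 0) / 5, tolerance = 1e-12)
})

test_that("log-log regression recognizes exact power laws and flat histograms", {
  k <- 1:10
  counts <- round(1000 * k^(-2))
  h <- as.table(stats::setNames(counts, k))
  fit <- powerlaw_loglog_fit(h)
  expect_gt(fit$r_squared, 0.999)
  expect_lt(abs(fit$slope - (-2)), 0.05)

  flat <- as.table(stats::setNames(rep(50, 8), 1:8))
  expect_lt(abs(powerlaw_loglog_fit(flat)$slope), 1e-10)

  tiny <- as.table(stats::setNames(c(5, 3), 1:2))
  expect_true(powerlaw_loglog_fit(tiny)$unreliable)
})

test_that("scale-free degree sequences fit the log-log line better than Poisson ones", {
  set.seed(152)
  pa <- igraph::sample_pa(2000, m = 2, directed = FALSE)
  er <- igraph::sample_gnp(2000, 4 / 1999)
  r2_pa <- powerlaw_loglog_fit(igraph::degree(pa))$r_squared
  r2_er <- powerlaw_loglog_fit(igraph::degree(er))$r_squared
  expect_gt(r2_pa, r2_er)
})

test_that("Poisson goodness of fit is calibrated and rejects gross misfits", {
  set.seed(153)
  rejections <- 0L
  for (i in 1:120) {
    d <- stats::rpois(2000, 3)
    p <- poisson_gof(d)$p_value
    if (!is.na(p) && p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / 120, 0.005)
  expect_lt(rejections / 120, 0.125)

  extreme <- as.table(stats::setNames(c(900, 100), c(0, 50)))
  expect_lt(poisson_gof(extreme)$p_value, 1e-10)

  # too few classes to test
  expect_true(poisson_gof(rep(1L, 10))$unreliable)
})

test_that("cluster editing recovers disjoint cliques at zero cost", {
  two_tri <- coevo_network(cbind(c("a", "a", "b", "x", "x", "y"),
                                 c("b", "c", "c", "y", "z", "z")))
  cl <- transitivity_cluster(two_tri)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(sort(cl$sizes), c(3L, 3L))
  expect_equal(cl$cost, 0)
  expect_equal(cl$membership[["a"]], cl$membership[["b"]])
  expect_false(cl$membership[["a"]] == cl$membership[["x"]])

  set.seed(161)
  sizes <- c(4, 3, 5, 1, 1)
  edges <- NULL
  off <- 0
  for (s in sizes) {
    if (s > 1) {
      ids <- sprintf("n%02d", off + 1:s)
      idx <- utils::combn(s, 2)
      edges <- rbind(edges, cbind(ids[idx[1, ]], ids[idx[2, ]]))
    }
    off <- off + s
  }
  net <- coevo_network(edges, genes = sprintf("n%02d", 1:sum(sizes)))
  cl <- transitivity_cluster(net)
  expect_equal(cl$cost, 0)
  expect_equal(sort(cl$sizes), sort(sizes))
  expect_equal(cl$n_singletons, 2L)
})

test_that("a three-node path merges into one cluster at editing cost one", {
  path <- coevo_network(cbind(c("a", "b"), c("b", "c")))
  cl <- transitivity_cluster(path)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$cost, 1)
})

test_that("heuristic editing cost is within one of the exhaustive optimum", {
  set.seed(162)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    adj <- matrix(FALSE, n, n)
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        adj[a, b] <- adj[b, a] <- stats::runif(1) < 0.45
      }
    }
    ids <- sprintf("v%d", seq_len(n))
    dimnames(adj) <- list(ids, ids)
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    edges <- cbind(ids[idx[, 1]], ids[idx[, 2]])
    net <- coevo_network(edges, genes = ids)
    cl <- transitivity_cluster(net)
    expect_lte(cl$cost, optimal_editing_cost(adj) + 1)
    # membership really is a partition
    expect_equal(sum(cl$sizes), n)
  }
})

test_that("clustering output serializes with sizes", {
  net <- coevo_network(cbind(c("a", "a", "b"), c("b", "c", "c")),
                       genes = c("a", "b", "c", "d"))
  cl <- transitivity_cluster(net)
  tmp <- tempfile(fileext = ".tsv")
  write_clustering(cl, tmp)
  df <- utils::read.delim(tmp)
  expect_equal(nrow(df), 4L)
  expect_equal(sort(unique(df$cluster_size)), c(1L, 3L))
})
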