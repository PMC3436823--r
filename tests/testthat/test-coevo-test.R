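test_that("pearson correlation handles identity, inversion and degeneracy", {
  v <- c(1, 0, 2, 1, 0, 3, 1, 1)
  expect_equal(pearson_events(v, v), 1)
  expect_equal(pearson_events(v, -v), -1)
  expect_equal(pearson_events(c(1, 0, 0, 1), c(1, 1, 0, 0)), 0)
  expect_true(is.na(pearson_events(v, rep(2, 8))))
  expect_error(pearson_events(v, v[-1]), "length")
})

test_that("candidate pairs use a strict exchangeability threshold", {
  exch <- c(a = 6, b = 5, c = 7, d = 10, e = 4.9)
  cand <- candidate_pairs(exch, 5)
  expect_setequal(cand$genes, c("a", "c", "d")) # exactly 5 is excluded
  expect_equal(cand$n_pairs, 3)
  expect_equal(nrow(cand$pairs), 3)

  cand4 <- candidate_pairs(c(a = 9, b = 9, c = 9, d = 9), 5)
  expect_equal(cand4$n_pairs, 6) # choose(4, 2)
  expect_equal(candidate_pairs(exch, 5, count_only = TRUE)$n_pairs, 3)
})

test_that("bin assignment sends edge ties to the lower bin", {
  edges <- c(5, 7.5, 10)
  expect_equal(assign_bin(c(5.1, 7.5, 7.6, 10, 11), edges),
               c(1L, 1L, 2L, 2L, 3L))
  expect_true(is.na(assign_bin(5, edges)))
  expect_true(is.na(assign_bin(4, edges)))
})

test_that("empirical P-values obey the add-one rule and never reach zero", {
  null <- seq(-0.999, 0.999, length.out = 999)
  expect_equal(empirical_pvalue(1, null), 1 / 1000)
  expect_equal(empirical_pvalue(-1, null), 1)
  set.seed(111)
  r <- stats::runif(50, -1, 1)
  p <- empirical_pvalue(r, null)
  manual <- vapply(r, function(x) (sum(null >= x) + 1) / 1000, numeric(1))
  expect_equal(p, manual)
  expect_true(all(p > 0 & p <= 1))
  expect_error(empirical_pvalue(0.5, numeric(0)), "build_null")
})

test_that("BH step-up matches direct enumeration and p.adjust", {
  p <- c(0.001, 0.02, 0.03, 0.5)
  res <- bh_fdr(p, 0.05)
  expect_equal(which(res$reject), bh_enum(p, 0.05))
  expect_equal(res$k, 3L)
  expect_equal(res$critical, 3 * 0.05 / 4)
  expect_equal(res$qvalue, stats::p.adjust(p, "BH"))

  expect_equal(bh_fdr(rep(1, 10), 0.05)$k, 0L)
  expect_equal(bh_fdr(numeric(0), 0.05)$k, 0L)

  set.seed(112)
  for (i in 1:10) {
    p <- stats::runif(60)^2
    q <- stats::runif(1, 0.01, 0.2)
    res <- bh_fdr(p, q)
    expect_equal(which(res$reject), bh_enum(p, q))
    expect_equal(res$qvalue, stats::p.adjust(p, "BH"))
  }
  # rejections monotone nondecreasing in q
  p <- stats::runif(100)^1.5
  ks <- vapply(c(0.01, 0.05, 0.1, 0.2), function(q) bh_fdr(p, q)$k,
               integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("the bootstrap null is reproducible, bounded and bin-disjoint", {
  tr <- random_tree(12, seed = 121)
  m <- gainloss_model(gain = 1, loss = 1, rho = 2)
  edges <- c(8.4, 8.8, 9.1)
  n1 <- build_null(tr, m, edges = edges, per_bin = 150, seed = 122,
                   batch = 300, max_batches = 30)
  n2 <- build_null(tr, m, edges = edges, per_bin = 150, seed = 122,
                   batch = 300, max_batches = 30)
  expect_identical(n1$bins, n2$bins)
  expect_true(all(unlist(n1$bins) >= -1 & unlist(n1$bins) <= 1))
  expect_false(any(n1$short))
  # unreachable bin is flagged, not fatal
  n3 <- build_null(tr, m, edges = c(8.4, 8.8, 1000), per_bin = 50,
                   seed = 123, batch = 200, max_batches = 3)
  expect_true(n3$short[3])
  expect_equal(n3$counts[3], 0L)
})

test_that("the null depends on exchangeability and is calibrated within bins", {
  # among-gene rate variability spreads exchangeability widely; the null
  # correlation distribution shifts materially across bins, which is what
  # makes binned rather than pooled nulls necessary
  tr <- random_tree(12, seed = 124)
  m <- gainloss_model(gain = 1, loss = 1, rho = 2, K = 4,
                      alpha_gain = 0.5, alpha_loss = 0.5)
  edges <- c(0.5, 3, 6, 9, 12)
  null <- build_null(tr, m, edges = edges, per_bin = 400,
                     seed = 125, batch = 1000, max_batches = 60)
  expect_false(any(null$short))
  med <- vapply(null$bins, stats::median, numeric(1))
  expect_gt(max(med) - min(med), 0.1)
  # confounder control: fresh independent pairs are uniform in EVERY bin
  sim <- simulate_genes(tr, m, 8000, seed = 126)
  mapped <- map_events(sim$pattern, tr, m)
  i1 <- seq(1L, 7999L, by = 2L)
  i2 <- i1 + 1L
  ex <- mapped$exchangeability
  keep <- ex[i1] > edges[1] & ex[i2] > edges[1]
  r <- coevonet:::row_pearson(mapped$events[i1[keep], , drop = FALSE],
                              mapped$events[i2[keep], , drop = FALSE])
  bins <- assign_bin(pmin(ex[i1], ex[i2])[keep], edges)
  for (b in seq_along(edges)) {
    sel <- which(bins == b & !is.na(r))
    if (length(sel) < 150) next
    p <- empirical_pvalue(r[sel], null$bins[[b]])
    ps <- sort(p)
    n <- length(ps)
    ks <- max(pmax(abs(ps - seq_len(n) / n),
                   abs(ps - (seq_len(n) - 1) / n)))
    expect_lt(ks, 1.63 / sqrt(n)) # 1% critical value of the KS statistic
  }
})

test_that("coevo_test flags exactly the BH rejections with bin-matched nulls", {
  tr <- random_tree(12, seed = 131)
  m <- gainloss_model(gain = 1, loss = 1, rho = 2)
  null <- build_null(tr, m, edges = c(8.4, 8.8, 9.1), per_bin = 300,
                     seed = 132, batch = 300, max_batches = 40)
  sim <- simulate_genes(tr, m, 40, seed = 133)
  cp <- simulate_coupled_pairs(tr, m, 0.95, 3, seed = 134)
  pat <- phyletic_pattern(rbind(unclass(sim$pattern),
                                unclass(cp$pattern_a),
                                unclass(cp$pattern_b)), tr)
  mapped <- map_events(pat, tr, m)
  res <- coevo_test(mapped, null, fdr = 0.05, threshold = 8.4)
  expect_s3_class(res, "coevo_result")
  expect_true(all(res$r >= -1 & res$r <= 1, na.rm = TRUE))
  expect_true(all(res$pvalue > 0 & res$pvalue <= 1, na.rm = TRUE))
  testable <- !is.na(res$pvalue)
  expect_equal(res$significant[testable],
               res$pvalue[testable] <= attr(res, "critical") &
                 attr(res, "critical") > 0)
  expect_equal(attr(res, "n_pairs"),
               choose(length(attr(res, "genes_tested")), 2))
  # each pair's bin matches its minimal exchangeability
  expect_equal(res$bin, assign_bin(res$min_exch, null$edges))
})

test_that("null tables serialize and reload exactly", {
  tr <- random_tree(10, seed = 141)
  m <- gainloss_model(gain = 1, loss = 1, rho = 2)
  null <- build_null(tr, m, edges = c(2, 6), per_bin = 50, seed = 142,
                     batch = 100, max_batches = 10)
  tmp <- tempfile(fileext = ".json")
  write_null(null, tmp)
  null2 <- read_null(tmp)
  expect_equal(null2$bins, null$bins, tolerance = 1e-12)
  expect_equal(null2$edges, null$edges)
  expect_equal(null2$seed, null$seed)
})
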