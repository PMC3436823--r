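test_that("transition matrix matches the matrix exponential and its limits", {
  expect_equal(transition_probability(1, 1, 0), diag(2),
               ignore_attr = TRUE)
  # long-branch limit: both rows reach the stationary distribution
  P <- transition_probability(1, 3, 500)
  expect_equal(unname(P), matrix(c(0.75, 0.25, 0.75, 0.25), 2,
                                 byrow = TRUE), tolerance = 1e-12)
  # closed form vs numerical exponential of the generator
  expect_equal(transition_probability(2, 1, 0.5)[1, 2],
               (2 / 3) * (1 - exp(-1.5)), tolerance = 1e-12)
  skip_if_not_installed("Matrix")
  set.seed(41)
  for (i in 1:25) {
    g <- stats::runif(1, 0.05, 5)
    l <- stats::runif(1, 0.05, 5)
    t <- stats::runif(1, 0, 3)
    Q <- matrix(c(-g, g, l, -l), 2, 2, byrow = TRUE)
    expect_equal(unname(transition_probability(g, l, t)),
                 unname(as.matrix(Matrix::expm(Q * t))),
                 tolerance = 1e-10)
  }
  expect_error(transition_probability(1, 1, -0.1), "negative")
})

test_that("Chapman-Kolmogorov and stationarity hold for random rates", {
  set.seed(42)
  for (i in 1:20) {
    g <- stats::runif(1, 0.05, 4)
    l <- stats::runif(1, 0.05, 4)
    t1 <- stats::runif(1, 0, 2)
    t2 <- stats::runif(1, 0, 2)
    expect_equal(transition_probability(g, l, t1) %*%
                   transition_probability(g, l, t2),
                 transition_probability(g, l, t1 + t2), tolerance = 1e-10)
    pi <- stationary_freq(g, l)
    expect_equal(as.vector(pi %*% transition_probability(g, l, t1)), pi,
                 tolerance = 1e-12)
  }
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    tr <- random_tree(n, seed = 1000 + i)
    model <- gainloss_model(gain = stats::runif(1, 0.2, 3),
                            loss = stats::runif(1, 0.2, 3),
                            rho = stats::runif(1, 0.3, 2),
                            K = sample(c(1L, 2L), 1),
                            alpha_gain = stats::runif(1, 0.3, 3),
                            alpha_loss = stats::runif(1, 0.3, 3))
    row <- stats::rbinom(n, 1, 0.5)
    pat <- phyletic_pattern(matrix(row, 1, n,
                                   dimnames = list("g", tr$tip_labels)), tr)
    ll <- log_likelihood(pat, tr, model)
    expect_equal(ll$per_gene[[1]], brute_loglik(row, tr, model),
                 tolerance = 1e-10)
  }
})

test_that("two-leaf-pair likelihood equals the direct sum over the root state", {
  tr <- read_newick("((A:1,B:1):0.5,C:0.5);") # smallest valid tree
  m <- gainloss_model(gain = 1, loss = 1, rho = 1)
  pat <- phyletic_pattern(matrix(c(1L, 1L, 1L), 1, 3,
                                 dimnames = list("g", tr$tip_labels)), tr)
  pi <- stationary_freq(1, 1)
  P1 <- transition_probability(1, 1, 1)
  P05 <- transition_probability(1, 1, 0.5)
  lik <- 0
  for (s_root in 0:1) {
    for (s_anc in 0:1) {
      lik <- lik + pi[s_root + 1] * P05[s_root + 1, 2] *
        P05[s_root + 1, s_anc + 1] * P1[s_anc + 1, 2]^2
    }
  }
  expect_equal(log_likelihood(pat, tr, m)$per_gene[[1]], log(lik),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to rescaling branch lengths into rho", {
  tr <- random_tree(8, seed = 5)
  pat <- random_pattern(tr, 20, seed = 6)
  m1 <- gainloss_model(gain = 1.2, loss = 0.8, rho = 1.4, K = 2)
  phy2 <- tr$phylo
  phy2$edge.length <- phy2$edge.length * 3
  tr2 <- as_coevo_tree(phy2)
  pat2 <- phyletic_pattern(unclass(pat), tr2)
  m2 <- gainloss_model(gain = 1.2, loss = 0.8, rho = 1.4 / 3, K = 2)
  expect_equal(log_likelihood(pat, tr, m1)$total,
               log_likelihood(pat2, tr2, m2)$total, tolerance = 1e-10)
})

test_that("rate-category mixture is coherent", {
  m <- gainloss_model(gain = 1, loss = 1, K = 4, alpha_gain = 0.7,
                      alpha_loss = 2)
  expect_equal(nrow(m$categories), 4L)
  expect_true(all(m$categories > 0))
  # median-based discretization: category means near 1
  expect_equal(mean(m$categories$gain_mult), 1, tolerance = 0.25)
  expect_equal(mean(m$categories$loss_mult), 1, tolerance = 0.1)

  tr <- random_tree(6, seed = 9)
  pat <- random_pattern(tr, 12, seed = 10)
  ll <- log_likelihood(pat, tr, m)
  expect_equal(rowSums(ll$cat_posterior), rep(1, 12), tolerance = 1e-12)
  expect_equal(ll$total, sum(ll$per_gene))
})

test_that("model JSON serialization round-trips", {
  m <- gainloss_model(gain = 0.6, loss = 1.4, rho = 2.5, K = 4,
                      alpha_gain = 0.9, alpha_loss = 1.8)
  m2 <- model_from_json(model_to_json(m))
  expect_equal(m2$gain, m$gain)
  expect_equal(m2$rho, m$rho)
  expect_equal(m2$categories, m$categories)
})

test_that("ML fit dominates a wrong model and is a likelihood fixed point", {
  tr <- random_tree(16, seed = 21)
  truth <- gainloss_model(gain = 0.8, loss = 1.2, rho = 1)
  sim <- simulate_genes(tr, truth, 250, seed = 22)
  fit <- fit_model(sim$pattern, tr, K = 1)
  expect_true(fit$converged)
  # reported logLik is reproducible from the returned parameters
  expect_equal(log_likelihood(sim$pattern, tr, fit)$total, fit$logLik,
               tolerance = 1e-9)
  # ML dominance over an arbitrary wrong model on the training data
  wrong <- gainloss_model(gain = 10, loss = 10, rho = 1)
  expect_gt(fit$logLik, log_likelihood(sim$pattern, tr, wrong)$total)
  # refitting from the optimum barely moves the likelihood
  refit <- fit_model(sim$pattern, tr, K = 1,
                     init = list(p = fit$gain / 2, alpha_gain = 1,
                                 alpha_loss = 1, rho = fit$rho))
  expect_lt(abs(refit$logLik - fit$logLik), 1e-3)
  # and the generating gain fraction is recovered reasonably
  expect_lt(abs(fit$gain / (fit$gain + fit$loss) - 0.4), 0.12)
})
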