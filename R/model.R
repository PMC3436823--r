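#' Two-state gain/loss model
#'
#' A stationary continuous-time Markov chain over gene presence (1) and
#' absence (0). Rate `gain` drives 0 -> 1 transitions and `loss` drives
#' 1 -> 0, both per unit of rescaled branch length. Among-family rate
#' variability is modelled by `K` equiprobable categories whose gain and
#' loss multipliers are the per-category medians of mean-1 gamma
#' distributions with shapes `alpha_gain` and `alpha_loss`, paired by
#' quantile. The `rho` factor rescales all input branch lengths from
#' substitutions-per-site units into gain/loss-event units. For
#' identifiability `gain + loss` is held at 2 during fitting, the overall
#' rate being absorbed by `rho`.
#'
#' @param gain Gain rate (> 0).
#' @param loss Loss rate (> 0).
#' @param rho Branch-length scaling factor (> 0).
#' @param K Number of rate categories (>= 1).
#' @param alpha_gain,alpha_loss Gamma shapes of the gain and loss rate
#'   multipliers (only relevant for `K > 1`).
#' @return An object of class `gainloss_model`.
#' @export
gainloss_model <- function(gain = 1, loss = 1, rho = 1, K = 1L,
                           alpha_gain = 1, alpha_loss = 1) {
  stopifnot(gain > 0, loss > 0, rho > 0, K >= 1,
            alpha_gain > 0, alpha_loss > 0)
  m <- list(gain = gain, loss = loss, rho = rho, K = as.integer(K),
            alpha_gain = alpha_gain, alpha_loss = alpha_loss)
  m$categories <- rate_categories(alpha_gain, alpha_loss, K)
  class(m) <- "gainloss_model"
  m
}

#' Discrete-gamma rate-category multipliers
#'
#' `K` equiprobable categories; category `k` carries the median of the
#' `k`-th quantile slice of a gamma(alpha, alpha) distribution (mean 1) for
#' each of the gain and loss axes, paired by quantile.
#'
#' @param alpha_gain,alpha_loss Gamma shape parameters.
#' @param K Number of categories.
#' @return Data frame with columns `gain_mult`, `loss_mult` (`K` rows).
#' @export
rate_categories <- function(alpha_gain, alpha_loss, K) {
  q <- (seq_len(K) - 0.5) / K
  data.frame(
    gain_mult = if (K == 1L) 1 else stats::qgamma(q, shape = alpha_gain,
                                                  rate = alpha_gain),
    loss_mult = if (K == 1L) 1 else stats::qgamma(q, shape = alpha_loss,
                                                  rate = alpha_loss)
  )
}

#' @export
print.gainloss_model <- function(x, ...) {
  cat("gainloss_model: gain =", signif(x$gain, 4),
      " loss =", signif(x$loss, 4),
      " rho =", signif(x$rho, 4), "\n")
  cat("  stationary presence pi1 =", signif(x$gain / (x$gain + x$loss), 4),
      "\n")
  cat("  K =", x$K, "categories; alpha_gain =", signif(x$alpha_gain, 4),
      " alpha_loss =", signif(x$alpha_loss, 4), "\n")
  if (!is.null(x$logLik)) cat("  logLik =", x$logLik, "\n")
  invisible(x)
}

#' Stationary presence/absence frequencies
#'
#' @param gain,loss Rates of the two-state chain.
#' @return Numeric vector `c(pi0, pi1)` with `pi1 = gain / (gain + loss)`.
#' @export
stationary_freq <- function(gain, loss) {
  r <- gain + loss
  c(loss / r, gain / r)
}

#' Transition probability matrix of the two-state chain
#'
#' Closed form for the chain with generator `Q = [[-g, g], [l, -l]]`:
#' `P01(t) = pi1 (1 - e^(-(g+l) t))`, `P11(t) = pi1 + pi0 e^(-(g+l) t)`,
#' and symmetrically for the absence row.
#'
#' @param gain,loss Rates (> 0).
#' @param t Effective elapsed length (>= 0), already rescaled by `rho`.
#' @return Row-stochastic 2x2 matrix; rows/cols ordered (absent, present).
#' @export
transition_probability <- function(gain, loss, t) {
  if (t < 0) stop("negative elapsed time")
  r <- gain + loss
  pi1 <- gain / r
  pi0 <- loss / r
  e <- exp(-r * t)
  matrix(c(pi0 + pi1 * e, pi1 * (1 - e),
           pi0 * (1 - e), pi1 + pi0 * e),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# Felsenstein pruning over all genes at once for one rate category.
# `pat` is the G x n 0/1 matrix with columns in tree leaf order. Returns
# per-gene log-likelihood, and optionally the per-node partial-likelihood
# matrices (normalized per gene; used by the stochastic mapping passes).
prune_category <- function(pat, tree, gain, loss, rho, keep_partials = FALSE) {
  G <- nrow(pat)
  n <- tree$n_tips
  partials <- vector("list", tree$n_nodes)
  logscale <- numeric(G)
  pmats <- vector("list", tree$n_nodes)
  for (v in rev(tree$preorder)) {
    if (v <= n) {
      partials[[v]] <- cbind(1 - pat[, v], pat[, v])
    } else {
      L <- matrix(1, G, 2)
      for (ch in tree$children[[v]]) {
        P <- transition_probability(gain, loss, rho * tree$brlen[ch])
        pmats[[ch]] <- P
        L <- L * (partials[[ch]] %*% t(P))
      }
      mx <- pmax(L[, 1], L[, 2])
      zero <- mx == 0
      if (any(zero)) mx[zero] <- 1 # log-likelihood becomes -Inf via log(0) at root
      logscale <- logscale + log(mx)
      partials[[v]] <- L / mx
    }
  }
  pi <- stationary_freq(gain, loss)
  rootlik <- partials[[tree$root]] %*% pi
  ll <- log(rootlik[, 1]) + logscale
  if (!keep_partials) return(list(loglik = ll))
  list(loglik = ll, partials = partials, pmats = pmats, pi = pi)
}

#' Log-likelihood of a phyletic pattern under a gain/loss model
#'
#' Computes, per gene family, the mixture likelihood over the model's rate
#' categories (equal prior weight `1/K`; pruning algorithm with branch
#' lengths `rho * t`; root prior = the stationary frequencies of each
#' category's chain), in log space with per-node scaling.
#'
#' @param pattern `phyletic_pattern` with columns in tree leaf order.
#' @param tree `coevo_tree`.
#' @param model `gainloss_model`.
#' @return List with `per_gene` (log-likelihoods), `total`,
#'   `cat_posterior` (G x K matrix of per-gene posterior category weights)
#'   and `per_gene_category` (G x K matrix of per-category log-likelihoods).
#' @export
log_likelihood <- function(pattern, tree, model) {
  stopifnot(inherits(tree, "coevo_tree"))
  pat <- unclass(pattern)
  if (ncol(pat) != tree$n_tips ||
      !identical(colnames(pat), tree$tip_labels)) {
    stop("pattern columns must match tree leaf order; ",
         "construct with phyletic_pattern(mat, tree)")
  }
  K <- model$K
  llk <- matrix(NA_real_, nrow(pat), K)
  for (k in seq_len(K)) {
    g <- model$gain * model$categories$gain_mult[k]
    l <- model$loss * model$categories$loss_mult[k]
    llk[, k] <- prune_category(pat, tree, g, l, model$rho)$loglik
  }
  mx <- apply(llk, 1, max)
  w <- exp(llk - mx)
  per_gene <- mx + log(rowMeans(w))
  list(per_gene = per_gene,
       total = sum(per_gene),
       cat_posterior = w / rowSums(w),
       per_gene_category = llk)
}

#' Fit the gain/loss model by maximum likelihood
#'
#' Maximizes the total log-likelihood over the stationary presence
#' frequency `gain/(gain+loss)` (with `gain + loss` fixed at 2 for
#' identifiability), the gamma shapes of the rate-multiplier distributions
#' (when `K > 1`) and the branch-scale `rho`, by cyclic one-dimensional
#' bounded search ([stats::optimize()] on each coordinate, `alpha` and
#' `rho` on the log scale) until the log-likelihood improves by less than
#' `tol` over a full cycle. Deterministic for a given configuration.
#'
#' @param pattern `phyletic_pattern`.
#' @param tree `coevo_tree`.
#' @param K Number of rate categories.
#' @param init Named list of starting values (`p` = gain fraction,
#'   `alpha_gain`, `alpha_loss`, `rho`).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_cycles Maximum number of coordinate cycles.
#' @return A fitted `gainloss_model` with extra fields `logLik`,
#'   `converged` and `cycles`.
#' @export
fit_model <- function(pattern, tree, K = 4L,
                      init = list(p = 0.5, alpha_gain = 1,
                                  alpha_loss = 1, rho = 1),
                      tol = 1e-4, max_cycles = 30L) {
  pat <- unclass(pattern)
  nonconst <- sum(!attr(pattern, "constant"))
  if (nonconst < 2) {
    warning("fewer than 2 non-constant genes; fit will be weakly informed")
  }
  par <- list(p = init$p, ag = init$alpha_gain, al = init$alpha_loss,
              rho = init$rho)
  obj <- function(par) {
    m <- gainloss_model(gain = 2 * par$p, loss = 2 * (1 - par$p),
                        rho = par$rho, K = K,
                        alpha_gain = par$ag, alpha_loss = par$al)
    log_likelihood(pattern, tree, m)$total
  }
  ll <- obj(par)
  ll_start <- ll
  converged <- FALSE
  cycles <- 0L
  coords <- if (K > 1L) c("p", "rho", "ag", "al") else c("p", "rho")
  for (cyc in seq_len(max_cycles)) {
    ll_prev <- ll
    for (cn in coords) {
      f <- function(x) {
        p2 <- par
        p2[[cn]] <- if (cn %in% c("rho", "ag", "al")) exp(x) else x
        obj(p2)
      }
      bounds <- switch(cn,
                       p = c(0.01, 0.99),
                       rho = log(c(1e-3, 1e3)),
                       ag = log(c(0.05, 100)),
                       al = log(c(0.05, 100)))
      opt <- stats::optimize(f, interval = bounds, maximum = TRUE,
                             tol = 1e-4)
      if (opt$objective > ll) {
        ll <- opt$objective
        par[[cn]] <- if (cn %in% c("rho", "ag", "al")) exp(opt$maximum)
                     else opt$maximum
      }
    }
    cycles <- cyc
    if (ll - ll_prev < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("optimizer did not converge in ", max_cycles,
            " cycles; returning best-found parameters")
  }
  stopifnot(ll >= ll_start)
  m <- gainloss_model(gain = 2 * par$p, loss = 2 * (1 - par$p),
                      rho = par$rho, K = K,
                      alpha_gain = par$ag, alpha_loss = par$al)
  m$logLik <- ll
  m$converged <- converged
  m$cycles <- cycles
  m
}

#' Serialize a model to JSON
#'
#' @param model `gainloss_model`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly when writing to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(g = model$gain, l = model$loss, rho = model$rho,
              K = model$K, alpha_gain = model$alpha_gain,
              alpha_loss = model$alpha_loss, constraint = "g+l=2")
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Deserialize a model from JSON
#'
#' @param path File path or JSON string.
#' @return `gainloss_model`.
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  gainloss_model(gain = doc$g, loss = doc$l, rho = doc$rho, K = doc$K,
                 alpha_gain = doc$alpha_gain, alpha_loss = doc$alpha_loss)
}
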