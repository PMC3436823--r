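#' Conditional expected event counts on a single branch
#'
#' For the two-state chain with rates `gain`, `loss` and elapsed length
#' `t`, computes the expected number of 0->1 (gain) and 1->0 (loss)
#' transitions conditional on each of the four (parent state, child state)
#' endpoint combinations. The two-state chain has eigenvalues 0 and
#' `-(gain+loss)`, so the defining integrals
#' `E[N01 | a,b] = g / P_ab(t) * int_0^t P_a0(s) P_1b(t-s) ds`
#' are evaluated in closed form — no sampling or truncation is involved.
#'
#' @param gain,loss Rates (> 0).
#' @param t Effective branch length (>= 0).
#' @return List of 2x2 matrices `gains`, `losses` (rows: parent state 0/1;
#'   columns: child state 0/1) and `P`, the transition matrix.
#' @export
conditional_event_counts <- function(gain, loss, t) {
  P <- transition_probability(gain, loss, t)
  gains <- matrix(0, 2, 2, dimnames = dimnames(P))
  losses <- matrix(0, 2, 2, dimnames = dimnames(P))
  if (t == 0) return(list(gains = gains, losses = losses, P = P))
  r <- gain + loss
  pi1 <- gain / r
  pi0 <- loss / r
  E <- exp(-r * t)
  Ie <- -expm1(-r * t) / r # int_0^t e^{-rs} ds
  pi <- c(pi0, pi1)
  for (a in 0:1) {
    for (b in 0:1) {
      # gains: integrand P_a0(s) * P_1b(t-s)
      da0 <- as.numeric(a == 0)
      d1b <- as.numeric(b == 1)
      Ig <- pi0 * pi[b + 1] * t +
        (pi0 * (d1b - pi[b + 1]) + (da0 - pi0) * pi[b + 1]) * Ie +
        (da0 - pi0) * (d1b - pi[b + 1]) * t * E
      # losses: integrand P_a1(s) * P_0b(t-s)
      da1 <- as.numeric(a == 1)
      d0b <- as.numeric(b == 0)
      Il <- pi1 * pi[b + 1] * t +
        (pi1 * (d0b - pi[b + 1]) + (da1 - pi1) * pi[b + 1]) * Ie +
        (da1 - pi1) * (d0b - pi[b + 1]) * t * E
      if (P[a + 1, b + 1] > 0) {
        gains[a + 1, b + 1] <- gain * Ig / P[a + 1, b + 1]
        losses[a + 1, b + 1] <- loss * Il / P[a + 1, b + 1]
      }
    }
  }
  list(gains = gains, losses = losses, P = P)
}

#' Map posterior expected gain and loss events onto every branch
#'
#' The core of the event-based co-evolution screen: for each gene family
#' and each branch, the posterior expected numbers of gains (0->1) and
#' losses (1->0) given the leaf pattern and the fitted model. Endpoint
#' posteriors come from inside (pruning) and outside passes; per-branch
#' conditional counts are analytic ([conditional_event_counts()]); rate
#' categories are averaged with each gene's posterior category weights.
#'
#' The result for gene `i` is a vector of length `4n - 4`: entry `j`
#' (`j <= 2n-2`) is the expected number of gains on the branch with index
#' `j`, entry `(2n-2) + j` the expected number of losses on that branch.
#' Genes absent from every leaf carry no mappable events and get an all-zero
#' vector, flagged in `degenerate`.
#'
#' @param pattern `phyletic_pattern` (columns in tree leaf order).
#' @param tree `coevo_tree`.
#' @param model Fitted `gainloss_model`.
#' @param zero_degenerate Zero out the vectors of all-absent genes (the
#'   default; such genes carry no inferable events). Set to `FALSE` to keep
#'   their raw posterior expectations, e.g. when checking the law of total
#'   expectation against unconditional event counts.
#' @return List with `events` (G x (4n-4) matrix, gene ids as rownames),
#'   `exchangeability` (named vector: per gene, (total expected gains +
#'   total expected losses) / 2), `degenerate` (logical flag per gene) and
#'   `loglik` (the [log_likelihood()] result reused for the category
#'   posteriors).
#' @export
map_events <- function(pattern, tree, model, zero_degenerate = TRUE) {
  stopifnot(inherits(tree, "coevo_tree"))
  pat <- unclass(pattern)
  if (!identical(colnames(pat), tree$tip_labels)) {
    stop("pattern columns must match tree leaf order")
  }
  G <- nrow(pat)
  n <- tree$n_tips
  nb <- n_branches(tree)
  ll <- log_likelihood(pattern, tree, model)
  w <- ll$cat_posterior
  events <- matrix(0, G, 2L * nb,
                   dimnames = list(rownames(pat), NULL))
  for (k in seq_len(model$K)) {
    g <- model$gain * model$categories$gain_mult[k]
    l <- model$loss * model$categories$loss_mult[k]
    pr <- prune_category(pat, tree, g, l, model$rho, keep_partials = TRUE)
    # outside pass: A[[v]][gene, a] is proportional to the likelihood of all
    # data outside v's subtree with v's PARENT in state a (sibling subtrees
    # folded in), normalized per gene for numerical stability
    A <- vector("list", tree$n_nodes)
    down <- vector("list", tree$n_nodes)
    down[[tree$root]] <- matrix(pr$pi, G, 2, byrow = TRUE)
    S <- vector("list", tree$n_nodes) # S[[w]][gene, a] = sum_b P_ab In_w(b)
    for (u in tree$preorder) {
      kids <- tree$children[[u]]
      if (length(kids) == 0) next
      for (ch in kids) {
        S[[ch]] <- pr$partials[[ch]] %*% t(pr$pmats[[ch]])
      }
      for (ch in kids) {
        Av <- down[[u]]
        for (sib in kids) {
          if (sib != ch) Av <- Av * S[[sib]]
        }
        rs <- Av[, 1] + Av[, 2]
        rs[rs == 0] <- 1
        A[[ch]] <- Av / rs
        down[[ch]] <- A[[ch]] %*% pr$pmats[[ch]]
      }
    }
    for (v in tree$preorder) {
      if (v == tree$root) next
      bi <- tree$branch_index[v]
      cec <- conditional_event_counts(g, l, model$rho * tree$brlen[v])
      P <- cec$P
      In <- pr$partials[[v]]
      Av <- A[[v]]
      gsum <- numeric(G); lsum <- numeric(G); denom <- numeric(G)
      for (a in 1:2) {
        for (b in 1:2) {
          wab <- Av[, a] * P[a, b] * In[, b]
          denom <- denom + wab
          gsum <- gsum + wab * cec$gains[a, b]
          lsum <- lsum + wab * cec$losses[a, b]
        }
      }
      ok <- denom > 0
      gk <- ifelse(ok, gsum / denom, 0)
      lk <- ifelse(ok, lsum / denom, 0)
      events[, bi] <- events[, bi] + w[, k] * gk
      events[, nb + bi] <- events[, nb + bi] + w[, k] * lk
    }
  }
  degenerate <- rowSums(pat) == 0L
  if (zero_degenerate) events[degenerate, ] <- 0
  exch <- rowSums(events) / 2
  names(exch) <- rownames(pat)
  list(events = events, exchangeability = exch,
       degenerate = stats::setNames(degenerate, rownames(pat)),
       loglik = ll)
}

#' Exchangeability of an event vector
#'
#' The average of the total posterior expected gains and total expected
#' losses across the tree: a scalar measure of how much gain/loss signal a
#' gene family carries. Families with low exchangeability can show extreme
#' correlations by chance and are excluded from testing by a threshold.
#'
#' @param v Event vector of length `4n - 4` (gains then losses), or a
#'   matrix of such rows.
#' @return Nonnegative scalar (or vector for a matrix input).
#' @export
exchangeability <- function(v) {
  if (is.matrix(v)) return(rowSums(v) / 2)
  sum(v) / 2
}

#' Write mapped events and per-gene summaries as TSV
#'
#' @param mapped Result of [map_events()].
#' @param tree The `coevo_tree` used for mapping.
#' @param events_path Long-format per-branch table (gene, branch,
#'   expected_gains, expected_losses).
#' @param summary_path Per-gene table (gene, exchangeability, degenerate).
#' @return `events_path`, invisibly.
#' @export
write_events <- function(mapped, tree, events_path, summary_path = NULL) {
  nb <- ncol(mapped$events) / 2L
  genes <- rownames(mapped$events)
  long <- data.frame(
    gene = rep(genes, each = nb),
    branch = rep(seq_len(nb), times = length(genes)),
    expected_gains = as.vector(t(mapped$events[, seq_len(nb), drop = FALSE])),
    expected_losses = as.vector(t(mapped$events[, nb + seq_len(nb),
                                                drop = FALSE])),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, events_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.table(
      data.frame(gene = genes,
                 exchangeability = unname(mapped$exchangeability),
                 degenerate = unname(mapped$degenerate)),
      summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(events_path)
}
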