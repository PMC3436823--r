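# Evolve a vector of parent states along one branch by exact Gillespie
# simulation (exponential waiting times), returning end states and the true
# gain/loss counts. `gain`/`loss` are per-gene rate vectors (category rates
# already folded in), `t` the effective branch length.
sim_branch <- function(state, t, gain, loss) {
  G <- length(state)
  gains <- integer(G)
  losses <- integer(G)
  if (t > 0) {
    elapsed <- numeric(G)
    active <- seq_len(G)
    while (length(active)) {
      rate <- ifelse(state[active] == 0L, gain[active], loss[active])
      wait <- stats::rexp(length(active), rate)
      elapsed[active] <- elapsed[active] + wait
      flip <- active[elapsed[active] < t]
      if (length(flip)) {
        was0 <- state[flip] == 0L
        gains[flip] <- gains[flip] + as.integer(was0)
        losses[flip] <- losses[flip] + as.integer(!was0)
        state[flip] <- 1L - state[flip]
      }
      active <- flip
    }
  }
  list(state = state, gains = gains, losses = losses)
}

#' Simulate gene families evolving on the tree
#'
#' Each gene draws a rate category uniformly, a root state from that
#' category's stationary distribution, and then evolves down every branch by
#' exact event-level simulation (exponential waiting times), so the true
#' latent gain and loss counts per branch are returned along with the leaf
#' pattern. This is the parametric-bootstrap engine behind the null
#' distribution and the ground-truth generator for validation studies.
#'
#' Reproducibility: results depend only on the R random-number state; call
#' `set.seed()` (or use the `seed` argument) before simulating.
#'
#' @param tree `coevo_tree`.
#' @param model `gainloss_model`.
#' @param n_genes Number of independent gene families to simulate.
#' @param gene_ids Optional character vector of ids (default `sim0001`...).
#' @param seed Optional integer seed applied via `set.seed()`.
#' @return List with `pattern` (a `phyletic_pattern`, genes x leaves),
#'   `events` (G x (4n-4) matrix of TRUE simulated counts, gains then
#'   losses, in branch-index order), `category` (per-gene category index)
#'   and `node_states` (G x n_nodes matrix of realized states).
#' @export
simulate_genes <- function(tree, model, n_genes, gene_ids = NULL,
                           seed = NULL) {
  stopifnot(inherits(tree, "coevo_tree"), inherits(model, "gainloss_model"))
  if (!is.null(seed)) set.seed(seed)
  G <- as.integer(n_genes)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("sim%04d", seq_len(G))
  }
  nb <- n_branches(tree)
  cat_idx <- sample.int(model$K, G, replace = TRUE)
  gk <- model$gain * model$categories$gain_mult[cat_idx]
  lk <- model$loss * model$categories$loss_mult[cat_idx]
  pi1 <- gk / (gk + lk)
  states <- matrix(NA_integer_, G, tree$n_nodes)
  states[, tree$root] <- as.integer(stats::runif(G) < pi1)
  events <- matrix(0, G, 2L * nb, dimnames = list(gene_ids, NULL))
  for (v in tree$preorder) {
    if (v == tree$root) next
    res <- sim_branch(states[, tree$parent[v]], model$rho * tree$brlen[v],
                      gk, lk)
    states[, v] <- res$state
    bi <- tree$branch_index[v]
    events[, bi] <- res$gains
    events[, nb + bi] <- res$losses
  }
  mat <- states[, seq_len(tree$n_tips), drop = FALSE]
  dimnames(mat) <- list(gene_ids, tree$tip_labels)
  list(pattern = phyletic_pattern(mat, tree),
       events = events,
       category = cat_idx,
       node_states = states)
}

#' Simulate a pair of gene families with coupled histories
#'
#' Gene A evolves as in [simulate_genes()]. Gene B copies A's root state
#' with probability `rho_c` and, independently on each branch with
#' probability `rho_c`, re-uses A's realized segment on that branch (the
#' same event sequence, hence the same end state and gain/loss counts);
#' otherwise it evolves independently from its own entering state.
#' `rho_c = 0` reduces exactly to two
#' independent simulations; `rho_c = 1` yields identical histories. For
#' intermediate `rho_c`, B's state path may jump where a copied segment
#' begins; the device exists purely to plant correlated histories. This
#' coupling is a validation device for power studies — the null
#' distribution only ever uses independent pairs.
#'
#' @param tree `coevo_tree`.
#' @param model `gainloss_model`.
#' @param rho_c Per-branch coupling probability in `[0, 1]`.
#' @param n_pairs Number of pairs.
#' @param seed Optional integer seed.
#' @return List with `pattern_a`, `pattern_b` (each a `phyletic_pattern`
#'   of `n_pairs` rows), `events_a`, `events_b` (true simulated counts).
#' @export
simulate_coupled_pairs <- function(tree, model, rho_c, n_pairs = 1L,
                                   seed = NULL) {
  if (rho_c < 0 || rho_c > 1) stop("rho_c must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  G <- as.integer(n_pairs)
  nb <- n_branches(tree)
  ids <- sprintf("pair%04d", seq_len(G))
  a <- simulate_genes(tree, model, G, gene_ids = paste0(ids, "_a"))
  # gene B: own rate category, root copied with prob rho_c
  cat_b <- sample.int(model$K, G, replace = TRUE)
  gk <- model$gain * model$categories$gain_mult[cat_b]
  lk <- model$loss * model$categories$loss_mult[cat_b]
  pi1 <- gk / (gk + lk)
  states <- matrix(NA_integer_, G, tree$n_nodes)
  root_coupled <- stats::runif(G) < rho_c
  states[, tree$root] <- ifelse(root_coupled,
                                a$node_states[, tree$root],
                                as.integer(stats::runif(G) < pi1))
  events <- matrix(0, G, 2L * nb, dimnames = list(paste0(ids, "_b"), NULL))
  for (v in tree$preorder) {
    if (v == tree$root) next
    bi <- tree$branch_index[v]
    entering <- states[, tree$parent[v]]
    coupled <- stats::runif(G) < rho_c
    out_state <- integer(G)
    gains <- numeric(G); losses <- numeric(G)
    if (any(coupled)) {
      gains[coupled] <- a$events[coupled, bi]
      losses[coupled] <- a$events[coupled, nb + bi]
      out_state[coupled] <- a$node_states[coupled, v]
    }
    if (any(!coupled)) {
      idx <- which(!coupled)
      res <- sim_branch(entering[idx], model$rho * tree$brlen[v],
                        gk[idx], lk[idx])
      out_state[idx] <- res$state
      gains[idx] <- res$gains
      losses[idx] <- res$losses
    }
    states[, v] <- out_state
    events[, bi] <- gains
    events[, nb + bi] <- losses
  }
  mat_b <- states[, seq_len(tree$n_tips), drop = FALSE]
  dimnames(mat_b) <- list(paste0(ids, "_b"), tree$tip_labels)
  list(pattern_a = a$pattern,
       pattern_b = phyletic_pattern(mat_b, tree),
       events_a = a$events,
       events_b = events,
       category_a = a$category,
       category_b = cat_b)
}
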