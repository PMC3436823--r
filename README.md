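# coevonet

Detecting co-evolving gene families from phylogenetic profiles of gene
gain and loss.

## The problem

Prokaryotic gene content is fluid: families are acquired by horizontal
transfer and lost by reductive evolution. When two gene families depend on
one another — subunits of a complex, steps of a pathway, parts of a
secretion system — their gains and losses tend to happen on the same
branches of the species tree. A genes × genomes 0/1 presence/absence
matrix (the *phyletic pattern*) together with a rooted species phylogeny
therefore carries a co-evolution signal that `coevonet` extracts and turns
into a network of significantly co-evolving family pairs, for people
studying microbial genome evolution, pathway modularity, or function
prediction for uncharacterized families.

## The method

1. **Gain/loss model.** Presence of a family evolves as a stationary
   two-state continuous-time Markov chain with gain rate *g* (0 → 1) and
   loss rate *l* (1 → 0), stationary presence frequency
   π₁ = *g*/(*g*+*l*). Among-family rate variability is a mixture of *K*
   equiprobable categories with gamma-distributed (mean 1) gain and loss
   multipliers, and a branch-scale factor ρ converts the tree's
   substitutions-per-site lengths into gain/loss-event units. Parameters
   are estimated by maximum likelihood (Felsenstein pruning, with
   *g* + *l* = 2 fixed for identifiability so ρ carries the overall rate).
2. **Stochastic mapping.** For every family and every one of the 2*n* − 2
   branches, the posterior expected numbers of gains and losses given the
   leaf states are computed analytically from the two-state chain's
   closed-form endpoint-conditioned integrals — no sampling. Each family
   becomes a vector of length 4*n* − 4 (expected gains per branch, then
   expected losses per branch), summarized by its *exchangeability*:
   (total expected gains + total expected losses)/2.
3. **Pair test.** Families with exchangeability above a threshold (default
   5 events) are paired; each pair's Pearson correlation *r* between event
   vectors is compared against a parametric-bootstrap null — independent
   family pairs simulated under the fitted model, mapped identically, and
   binned by minimal exchangeability, because the null distribution of
   *r* depends strongly on it. One-sided empirical P-values
   (#{null ≥ r} + 1)/(N + 1) are corrected by Benjamini–Hochberg FDR
   (default 0.01).
4. **Network.** Significant pairs form an undirected network: degree
   statistics, Watts–Strogatz clustering coefficient, Poisson
   goodness-of-fit and log–log degree regression, plus a deterministic
   greedy cluster-editing partition into putative functional modules, and
   overlap/enrichment comparison (Fisher exact test) against external
   networks such as genomic proximity, gene fusion, co-expression, PPI or
   shared metabolic pathways.

## Worked example

Simulate a 16-genome study with 40 independent families plus 5 planted
co-evolving pairs (per-branch coupling 0.95), then run the full pipeline:

```r
library(coevonet)

set.seed(7)
tree  <- as_coevo_tree(ape::rtree(16, br = function(k) runif(k, 0.1, 0.7)))
truth <- gainloss_model(gain = 0.8, loss = 1.2, rho = 1)
background <- simulate_genes(tree, truth, 40, seed = 8)
partners   <- simulate_coupled_pairs(tree, truth, rho_c = 0.95,
                                     n_pairs = 5, seed = 9)
pattern <- phyletic_pattern(rbind(unclass(background$pattern),
                                  unclass(partners$pattern_a),
                                  unclass(partners$pattern_b)), tree)

run <- run_pipeline(tree, pattern, out_dir = NULL, seed = 10,
                    fdr = 0.05, exch_threshold = 5, bins = c(5, 7),
                    null_per_bin = 20000, K = 1)
print(run$model)
res <- run$result
head(res[order(res$pvalue), ])
```

which prints

```
gainloss_model: gain = 0.7775  loss = 1.223  rho = 0.8042
  stationary presence pi1 = 0.3887
  K = 1 categories; alpha_gain = 1  alpha_loss = 1
  logLik = -519.8947

        gene_a     gene_b     r min_exch   pvalue  qvalue significant
394 pair0002_a pair0002_b 1.000     5.72 4.32e-05 0.00585        TRUE
399 pair0003_a pair0003_b 1.000     5.80 4.32e-05 0.00585        TRUE
403 pair0004_a pair0004_b 1.000     5.37 4.32e-05 0.00585        TRUE
207    sim0014    sim0033 0.697     5.82 4.11e-03 0.41698       FALSE
239    sim0018    sim0025 0.678     5.64 5.26e-03 0.42722       FALSE
22     sim0001    sim0040 0.649     5.06 7.83e-03 0.52964       FALSE
```

The fitted model recovers the generating gain fraction (0.39 vs the true
0.4) and branch scale. Of the 406 candidate pairs, exactly three planted
pairs are significant (r = 1, P at the add-one floor 1/(20000 + 1),
q ≈ 0.006); the other two planted pairs fell below the exchangeability
threshold of five expected events — families that barely move carry too
little signal to test, which is what the filter is for. The strongest
background pair (r = 0.70) stays two orders of magnitude away in P-value.
`run$summary` and `run$clustering` then report the network side: 3 edges
over 50 families (average degree 0.12, 12% of families co-evolving) and a
cluster-editing partition with the three pairs as two-member clusters.

A thin command-line front end over the same functions is installed at
`inst/cli/coevonet.R` with subcommands `run`, `fit`, `map`, `simulate`,
`test`, `network`, `compare`.

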