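---
title: "Detecting co-evolving gene families from gain/loss histories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting co-evolving gene families from gain/loss histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevonet)
```

# Overview

`coevonet` infers pairs of gene families whose gain and loss events
co-occur on the branches of a species tree more strongly than expected for
independently evolving families. The pipeline has four stages — model
fitting, stochastic mapping, a binned parametric-bootstrap pair test, and
network analysis — each exposed as ordinary functions and wired together
by `run_pipeline()`. This vignette describes the model, the estimators,
the numerical choices and the limitations, and states what the simulation
studies shipped in the test suite do and do not establish.

# The gain/loss model

Presence of a gene family in a genome is a binary character evolving along
a rooted, bifurcating species tree under a stationary two-state
continuous-time Markov chain with generator

$$Q = \begin{pmatrix} -g & g \\ l & -l \end{pmatrix},$$

where $g$ is the gain rate (absent to present, e.g. by horizontal
transfer) and $l$ the loss rate. The stationary frequencies are
$\pi_1 = g/(g+l)$ for presence and $\pi_0 = 1 - \pi_1$; the root state is
drawn from them (stationarity means no separate root parameters). The
transition probabilities are closed-form, e.g.
$P_{01}(t) = \pi_1(1 - e^{-(g+l)t})$, and `transition_probability()` is
checked against the numerical matrix exponential in the test suite.

**Rate variability.** Families differ enormously in volatility, so the
model mixes $K$ equiprobable rate categories. Category $k$ multiplies
$(g, l)$ by the medians of the $k$-th quantile slices of two mean-one
gamma distributions with shapes `alpha_gain` and `alpha_loss`, paired by
quantile (category $k$ is fast, or slow, on both axes). Pairing keeps the
parameter count at two shapes; a factorial combination would square the
number of categories for little benefit at the data sizes involved. The
default for fitting real data is $K = 4$; several shipped simulation
studies use $K = 1$ where rate variability is not the property under
test.

**Branch scale.** Input branch lengths are in substitutions per site, not
gain/loss events, so a scale factor $\rho$ multiplies every branch length.
The likelihood only identifies the products $g\rho t$ and $l\rho t$;
`fit_model()` therefore fixes $g + l = 2$ and lets $\rho$ absorb the
overall rate. Reported rates are in events per unit of rescaled branch
length.

**Estimation.** Per-family likelihoods are computed by Felsenstein
pruning, vectorized across families, in log space with per-node rescaling
(partial likelihoods are divided by their row maximum and the logs
accumulated), so thousands of families on hundreds of leaves pose no
underflow problem. The mixture likelihood averages the $K$ per-category
likelihoods with equal prior weight. Optimization is cyclic bounded
one-dimensional search (`stats::optimize`) over the gain fraction
$g/(g+l) \in [0.01, 0.99]$, $\log \rho \in [\log 10^{-3}, \log 10^{3}]$
and, for $K > 1$, $\log \alpha \in [\log 0.05, \log 100]$, iterated until
the log-likelihood gains less than $10^{-4}$ per cycle. The fit is
deterministic given its configuration; the parameter-recovery study in
the acceptance suite (64 leaves, 500 families) recovers the generating
gain fraction within $\pm 0.1$ and $\rho$ within a factor of 1.5.

**Degenerate input.** A family absent from every genome has likelihood
$\pi_0^{\,n}$-like terms but no mappable events: it is flagged
`degenerate` and receives an all-zero event vector. Families present in
every genome are retained — they are handled naturally by the
exchangeability filter, since a family that never moves has expected
event totals near zero. No ascertainment-bias correction for
unobservable all-absent families is applied; with presence frequencies
and data sizes typical of phyletic matrices the correction is small
relative to the stochastic error of the pair test, and it is recorded
here as a limitation.

# Stochastic mapping of expected events

For each family and branch, the quantity of interest is the posterior
expected number of gains and of losses given the leaf pattern. Endpoint
posteriors $\Pr(\text{parent}=a, \text{child}=b \mid \text{data})$ come
from an inside (pruning) and outside pass, both vectorized over families
and rescaled per node. Conditional on endpoints, the expected transition
counts of a two-state chain are exact integrals of products of transition
probabilities; because the chain's eigenvalues are $0$ and $-(g+l)$,

$$E[N_{0\to1} \mid a, b, t] \;=\; \frac{g}{P_{ab}(t)} \int_0^t
P_{a0}(s)\, P_{1b}(t-s)\, ds$$

evaluates in closed form (`conditional_event_counts()`). No sampling is
involved anywhere in the mapping, matching the decision to correlate
*expected* counts rather than sampled histories; the test suite verifies
the closed form against endpoint-conditioned Monte-Carlo trajectory
simulation, and the whole mapping against rejection-sampled whole-tree
histories on an 8-leaf tree (within three Monte-Carlo standard errors).

Rate categories are averaged with each family's *posterior* category
weights, not the uniform prior — a fast family's mapping should be
dominated by the fast categories its data support. The alternative
(best-category mapping) discards uncertainty and was not adopted.

Each family yields a vector of length $4n-4$: entries $1..2n-2$ hold
expected gains per branch (branches indexed by a deterministic preorder
traversal with children in Newick file order), entries $2n-1..4n-4$ the
expected losses. Zero-length branches — including those created when a
polytomy is resolved — receive exactly zero expected events, which is why
the arbitrary polytomy resolution cannot affect inference.

# Exchangeability and the pair test

The **exchangeability** of a family is the average of its total expected
gains and total expected losses. Families below the threshold (default 5
events) are excluded from testing: a family that hardly moves produces a
nearly rank-one event vector whose correlation with anything is
uninformative and occasionally extreme. The threshold trades lost true
pairs against multiple-testing burden; 5 events is the package default
and the comparison is strict (`> 5`).

Candidate pairs are all unordered pairs of passing families. The test
statistic is the Pearson correlation of the two event vectors. The
correlation of two constant vectors is undefined and reported as `NA`,
never silently zero.

**The null.** Correlations between independent families are not centred
at zero: both vectors share the branch-length profile of the tree (long
branches expect many events for everyone), and the strength of that
confounding depends on how much signal the families carry. The null is
therefore built by parametric bootstrap — simulate independent family
pairs under the fitted model, map them *identically* to the observed
data, and bin each pair's correlation by its minimal exchangeability. A
pair's P-value is the add-one tail probability
$(\#\{r_{\text{null}} \ge r\} + 1)/(N+1)$ within its bin; it can never be
zero, which finite-sample FDR control requires. Default bin edges are
$\{5, 7.5, 10, 15, 20, 30, 50\}$ (configurable; geometric-ish growth
mirrors how the null tightens with signal). Bins that the model and tree
cannot reach are flagged with their shortfall rather than treated as
errors. Because observed and null pairs are drawn through the same
binning, P-values of independent pairs are uniform within every bin by
construction — the suite checks this per bin and overall
(Kolmogorov–Smirnov distance below 0.05 on 2,000 pairs), and checks that
the empirical size at nominal 0.05 falls inside the binomial 99%
interval.

One detail deserves honesty: in the regimes our simulations can reach
(tens of leaves), the *location* of the null rises with exchangeability —
high-signal independent pairs correlate strongly through branch lengths,
while low-signal pairs are shrunk toward flatter vectors. Claims about
which bins have the heaviest upper tail are therefore regime-dependent,
and the shipped tests assert only what the method requires: the null
distribution differs materially across bins (so pooling would be wrong)
and is calibrated within each bin.

**Sidedness.** The screen is one-sided for positive correlation: negative
correlation of gain/loss profiles ("anti-co-evolution") is a different
and rarer hypothesis, and folding it in would halve power for the
intended question. `two_sided = TRUE` is available for exploration.

**FDR.** Benjamini–Hochberg step-up at level $q$ (default 0.01):
the critical value is $k q / m$ for the largest $k$ with
$p_{(k)} \le k q/m$; monotone q-values come from the cumulative minimum.
Note the interaction between the add-one floor and BH: with $N$ null
samples per bin the smallest attainable P-value is $1/(N+1)$, so a run
with $m$ candidate pairs can only reject anything if
$1/(N+1) \le k q/m$ for some feasible $k$. Null sizes must be chosen
with the number of tests in mind; this is why the original methodology
needed millions of bootstrap simulations and why `scripts/acceptance.R`
uses 60,000 samples per bin for ~3,000 candidate pairs.

# The simulator and the coupling device

`simulate_genes()` draws the root state from the stationary distribution
and evolves each branch by exact Gillespie simulation (exponential
waiting times), so the *true* latent gain and loss counts per branch are
available — this is both the bootstrap engine and the ground-truth
generator. Identical seeds give bit-identical output.

`simulate_coupled_pairs()` plants correlated pairs for power studies:
family B copies family A's root state with probability $\rho_c$ and, on
each branch independently with probability $\rho_c$, re-uses A's realized
segment on that branch (same events, same end state); otherwise it
evolves freely from its own entering state. $\rho_c = 0$ is exactly
independence, $\rho_c = 1$ exact identity, and re-copying a whole segment
means the two histories re-synchronize at every coupled branch (an
earlier design that replayed only A's flip *count* from B's own entering
state could anti-align the histories permanently after a single
uncoupled branch). For intermediate $\rho_c$, B's state path may jump at
the start of a copied segment; the device is a validation artifact — the
null never uses it — so this bookkeeping quirk buys exact
reduction-to-independence and exact identity at the endpoints of the
$\rho_c$ range. Power at $\rho_c = 0.9$ exceeds power at $0.5$, which
exceeds the nominal size, in the shipped calibration study.

**What the generator emulates, and what it does not.** It reproduces the
modelled world: stationary two-state dynamics, among-family rate
variability, branch-scale effects. It does not emulate copy-number
expansion and contraction of gene families (presence/absence only),
correlated rate variation among co-functional families beyond the
explicit coupling device, horizontal transfer *between* the sampled
lineages (events arrive from outside the tree), annotation error in real
phyletic matrices, or tree-estimation error. Passing tests therefore
demonstrate internal correctness and calibration under the model, not
robustness to model misspecification on real data.

# Network analysis

Significant pairs form an undirected network over *all* analyzed
families; isolates count. The average degree is $2E/N$ over all nodes.
The Watts–Strogatz clustering coefficient is the mean local transitivity;
vertices of degree $< 2$ contribute zero, and whether isolates enter the
average is a flag (`include_isolates`, default `FALSE`) because the
convention changes the statistic and published values rarely state it.
The degree distribution is summarized by a chi-square goodness-of-fit
test against a Poisson law with the observed mean (classes pooled so each
expected count is at least 5, one degree of freedom charged for the
mean) and by an ordinary least-squares fit of log10 count on log10
degree, whose $R^2$ is the usual rough scale-free diagnostic — it is
reported as a descriptive statistic, not a formal power-law test.

**Clustering.** Modules are extracted by cluster editing: minimize edge
deletions plus insertions turning the network into disjoint cliques. The
exact problem is NP-hard; the package uses a deterministic greedy
heuristic — per connected component, grow clusters from the
highest-degree unassigned vertex, adding the candidate with the best edge
surplus while it is adjacent to at least half the cluster
(merge-preferring tie-break), then a single lexicographic pass of
strict-improvement node moves. On graphs whose components are cliques it
returns the components at cost zero, and on all graphs with up to seven
vertices it lands within one edit of the exhaustive-search optimum in the
shipped property test. The objective, not any particular published
heuristic's output, is the claim being reproduced.

**Comparison with external networks.** For an external edge set $X$ over
the same families: frequency $|X|/\binom{m}{2}$, conditional frequency
$|X \cap C|/|C|$ over the co-evolution edges $C$, enrichment = their
ratio, and a two-sided Fisher exact P-value (probability-mass rule, via
`stats::fisher.test`, validated against direct hypergeometric
enumeration). The conditional frequency conditions on $C$, so the
statistic is deliberately asymmetric. With an annotation map,
`informative_filter()` keeps edges whose endpoints share a functional
category; edges with an unannotated endpoint are dropped and tallied, and
the filtered edge count becomes the conditioning denominator.

# Numerical choices, in one place

* Pruning and outside passes rescale per node, per family; log-space
  totals throughout.
* $(1 - e^{-rt})/r$ uses `expm1`; $t = 0$ branches short-circuit to zero
  conditional counts and an identity transition matrix.
* Branch indexing is the cladewise (preorder, file-order children) edge
  order of the parsed tree, making event-vector layouts reproducible
  across runs and platforms.
* Polytomies and unrooted basal trifurcations are resolved
  deterministically with zero-length branches; under a stationary
  reversible chain neither the resolution nor the root placement changes
  the likelihood.
* Ties at a bin edge go to the lower bin; the exchangeability threshold
  itself is excluded (strict `>`).
* Cluster editing breaks ties toward merging and orders vertices
  lexicographically; the result is deterministic.
* All simulation entry points take explicit seeds; `build_null()`
  refuses to run without one.

# Validation scales

The shipped studies run on one CPU in well under an hour in total:
pruning vs exhaustive enumeration on 200 random trees of up to 6 leaves
(tolerance $10^{-10}$); mapping vs rejection-sampled trajectories on an
8-leaf tree (30,000+ accepted histories); calibration on 2,000
independent 16-leaf pairs against a 2,000-per-bin null; parameter
recovery on 64 leaves × 500 families; and an end-to-end 24-genome study
with 25 planted pairs and a 60,000-per-bin null in the acceptance
script. These sizes were chosen to make Monte-Carlo error small relative
to the tolerances being asserted while staying convenient to re-run.

# Limitations

* Presence/absence only: co-evolution expressed through correlated
  family-size expansion and contraction is invisible.
* The pair test conditions on one fitted model; model misspecification
  (e.g. non-stationarity, branch-heterogeneous rates) propagates into
  the null.
* No explicit joint model of interacting pairs — the test detects
  deviation from independence, it does not estimate interaction
  parameters.
* No ascertainment correction for all-absent families.
* The cluster-editing heuristic is not exact; only its objective is
  principled.
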