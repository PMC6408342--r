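---
title: "Correlation-informed null models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-informed null models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(corrnull)
```

This vignette is the package's own account of the statistics it implements:
the model, the randomization machinery, the tunable parameters and their
defaults, the synthetic generators used to validate everything, and the
places where a genuine design choice had to be made.

## 1. The null-model family

A binary incidence matrix `A` (n × m) records a relation between two sets:
species across sites, consumers against resources. The fixed-fixed (swap)
null model randomizes `A` while preserving every row and column total
exactly: two existing links `i←j` and `l←m` are drawn uniformly and
replaced by `i←m` and `l←j` whenever neither target cell is already
occupied. Iterating this checkerboard swap yields an ensemble of matrices
sharing all marginal totals with the data, and any metric's departure from
that ensemble is summarized as

\[ z = \frac{k - \langle k^* \rangle}{\sigma_{k^*}} , \]

with the sample (n−1) standard deviation and the conventional two-sided 5%
threshold |z| ≥ 1.96 (`z_significance_threshold()`). When the ensemble
metric is constant the z-score is undefined and reported as `NA` rather
than ±Inf.

The correlation-informed variant weights the same chain. Given a
correlation matrix `V` over the columns, each row of `A` is fitted with

\[ \mathrm{logit}(p_{ij}) = \alpha_i + b_{ij}, \qquad
   b_i \sim \mathcal N(0, \sigma_i^2 V), \]

and a proposed swap is accepted with the product of the probabilities of
the two links it would create, `p_im · p_lj` (interactions treated as
independent). Probabilities are estimated once, from the observed matrix,
before any randomization: every swap is informed relative to the data, not
the current chain state. The misinformed control permutes `V`'s row and
column identities symmetrically — afresh for every replicate — re-estimates
the probabilities, and randomizes with those; it answers whether merely
*having* structure (rather than the *right* structure) changes conclusions.

Two details of the acceptance rule deserve note. First, the product rule
uses only the links being created, not those destroyed, so the informed
chain is not a Metropolis sampler of any explicitly stated target
distribution; the package exposes a `rule = "metropolis"` variant (ratio of
created over destroyed products) for comparison, but the product rule is
the default and is what all shipped analyses use. Second, because
acceptance depends on the estimated probabilities, informed chains move
more slowly than uninformed ones; consequences for budgeting are in section 4.

### Food webs

For a directed food web (square matrix, `W[i, j] = 1` meaning consumer `i`
eats resource `j` — the direction convention everything else inherits),
plain marginal preservation is not enough: it would let reciprocal pairs
and self-loops appear or vanish. The food-web chain therefore swaps within
link classes. Single (unreciprocated) links swap with single links, with
proposals rejected if they would create a self-loop or the reciprocal of an
existing link; double (reciprocal) links swap as atomic unordered pairs
with other double links, the informed acceptance being the product of all
four created directed-link probabilities; cannibal self-loops never move
(on a fixed node set, any move would change the cannibal distribution).
This preserves each species' prey and predator counts and the
single/double/cannibal decomposition exactly — so three-node results are
never artefacts of two-node structure.

## 2. Estimating the link probabilities

With one binary observation per random-effect level, the marginal
likelihood of the row model has no closed form. The package uses a Laplace
approximation: for trial values of `(alpha, log sigma)` an inner Newton
iteration (with step halving) finds the posterior mode of `b`; the
marginal log-likelihood is approximated as the joint log-density at the
mode minus half the log-determinant of `I + sigma^2 W^{1/2} V W^{1/2}`
(`W` the Bernoulli weights at the mode); an outer quasi-Newton search
(`nlminb`) optimizes `(alpha, log sigma)`. Numerical choices, each of
which matters in practice:

* **Separation guard.** A weak Gaussian penalty on the intercept
  (sd 10) keeps rows with extreme fill from driving `alpha` to infinity.
* **Sigma search.** `log sigma` is bounded in `[log 1e-4, log 20]`. The
  lower boundary is compared against the exact `sigma = 0` profile
  (penalized intercept-only logistic); whichever is better is reported,
  with `sigma = 0` and flag `"boundary"` when the profile wins. Tiny-row
  likelihoods are often maximized on ridges; the tie-break is always
  toward the simpler `sigma = 0` fit.
* **Degenerate rows.** All-0 or all-1 rows carry no information about
  `sigma`; they return the Laplace-smoothed uniform probability
  `(s + 1) / (m + 2)` with flag `"degenerate"`, so every cell still has a
  defined weight.
* **Clipping.** Fitted probabilities are clipped to `[1e-6, 1 - 1e-6]`,
  keeping every swap acceptance strictly positive (the informed chain
  remains irreducible on the fixed-constraint class).
* **Failure mode.** If the outer optimization errors, the row falls back
  to the `sigma = 0` fit with flag `"fallback"` rather than aborting a
  whole matrix estimation.

`tidy()` on a probability matrix exposes `alpha_i`, `sigma_i`, the
convergence flag and the approximate log-likelihood per row; `glance()`
summarizes them.

The fit was validated two ways: against exact Gauss–Hermite integration on
rows short enough to integrate (m ≤ 3; agreement in fitted probabilities to
10⁻², and exact agreement on the `sigma = 0` ridge), and by parameter
recovery on data simulated from the model itself (section 5). For rows of length
2–3 the likelihood frequently does not identify `sigma` at all (flat ridges
or boundary divergence); comparisons there are restricted to identifiable
configurations, and `sigma > 0` behaviour is exercised by the long-row
recovery study instead.

## 3. Correlation structures

All builders return a symmetric PSD matrix with unit diagonal, labelled,
and carrying provenance:

* `constant_correlation()` — all ones; the uninformative reference.
* `group_correlation(groups, eta)` — `1 - eta` within a group, 0 between.
* `exponential_correlation(traits, eta)` — off-diagonal
  `v_ij = (1 - eta) · exp(-d_ij / d_max)`, with `d_ij` the Euclidean
  distance between trait/coordinate vectors and `d_max` the largest
  pairwise distance. Normalizing by `d_max` makes the decay scale-free;
  this precise form (decay ∝ distance over maximum distance) is the
  package's adopted reading of the exponential family, recorded in the
  provenance so downstream reports state it.
* `phylogenetic_correlation(tree)` — the Brownian variance–covariance of a
  rooted, branch-length tree (shared root-to-MRCA branch length),
  standardized to a correlation matrix `C_ij / sqrt(C_ii C_jj)`. Only the
  correlation shape matters: any overall scale is absorbed by `sigma_i`.

The nugget `eta` (default **0.01** everywhere one is accepted) keeps
coincident elements from being perfectly correlated. Perfect correlation
still arises by construction (constant, group structures), so before any
fit `regularize_correlation()` clips negative eigenvalues at zero, adds
`1e-8` to the diagonal and rescales back to unit diagonal. Genuine
indefiniteness (smallest eigenvalue below −1e-6) is treated as an input
error, never repaired silently. `permute_correlation()` applies one
uniform symmetric permutation — it preserves the spectrum and the entry
multiset, which the tests assert.

## 4. Randomization budgets and mixing

The chain stops after **2L accepted swaps** (L = number of 1s), the
standard expected-swap recommendation applied to actual accepted swaps,
with a safety cap of **100L trials** and a warning when the cap is hit.
Three facts shape how the package uses budgets:

* The *uninformed* chain, counting rejected proposals as steps, has a
  symmetric transition kernel, hence a uniform stationary distribution
  over the fixed-constraint class. On a 4×4, 6-link matrix the test suite
  enumerates the class by brute force and verifies uniform occupancy over
  10⁵ steps (chi-square on a thinned trajectory — thinning because
  successive Markov-chain states are autocorrelated, which inflates the
  raw chi-square statistic regardless of uniformity).
* The *informed* chain accepts at roughly
  `(valid fraction) × (mean p)²` per trial — and double-link swaps at
  `~density⁴` — so at realistic connectance it needs far more trials per
  accepted swap than the uninformed chain. Analyses that compare models
  should let every chain *complete* its accepted-swap target; otherwise
  "the informed ensemble stays closer to the data" is confounded with
  "the informed chain moved less". Benchmarks in this package therefore
  pass an explicit budget override (same 2L target, larger trial cap)
  through the same `swap_budget()` mechanism users have.
* A constant (all-ones) `V` gives within-row-constant probabilities, so
  informed acceptance still varies with row fill. The informed and
  uninformed chains then share the same uniform stationary law but differ
  in transient speed — exact equivalence is a statement about the mixed
  randomization distribution. The equivalence test runs both models to a
  matched 150L accepted swaps (deep enough for the slow double-link
  sub-chain) and finds NODF and all 13 motif-class distributions
  indistinguishable at n = 200, alpha = 0.01.

Ensembles derive per-replicate seeds deterministically from one master
seed; identical inputs and seed give byte-identical ensembles, which the
suite asserts. The swap kernels are compiled (Rcpp) but draw exclusively
from R's RNG, so `set.seed()` semantics are ordinary.

## 5. Synthetic data: what it emulates and what it does not

`simulate_tree_and_traits()` grows a pure-birth (rate 1) phylogeny and one
Brownian trait (unit variance per unit branch length).
`synthetic_foodweb()` draws consumer diets from the row model's own
generative direction: `b_i ~ N(0, beta² V_phylo)` over resources, an
intercept solved numerically so each row's expected density matches the
target given its drawn effects, links Bernoulli. `beta = 0` removes all
structure (an Erdős–Rényi-style control at matched density).
`synthetic_assemblage()` builds sites-by-species matrices with a geometric
site-richness gradient (ratio `gamma`) and species sampled per site with
exponentially rank-decaying weights (`strength = 0` = uniform regime), plus
site coordinates and log-normal areas for spatial/area correlation
structures; the geometric gradient is deliberate, because fixed-fixed
nestedness tests are sensitive to exactly that marginal heterogeneity.

Generating from the model's own equation is the strongest self-consistency
check available — recovery is exact in expectation — but it is a
simplification of real data in ways worth keeping in mind: consumer diets
are conditionally independent given the phylogeny (no trophic hierarchy,
no body-size ordering, no niche-model contiguity), assemblages have no
true spatial process behind their coordinates, and all structure lives in
one random effect. Passing benchmarks therefore demonstrates internal
coherence of estimation + randomization + scoring, not that any particular
empirical system satisfies the model.

**Benchmark study conditions** (fixed once, used by the acceptance suite):
6 replicate worlds per condition, 24-species webs at connectance 0.25,
effect strength `beta = 2` against the `beta = 0` control, ensembles of 60
per model, budget 2L accepted with a 1000L trial cap. Connectance sits at
the denser end of the empirical food-web range; it was chosen with the
acceptance-rate arithmetic of section 4 so that informed and misinformed chains
genuinely complete their swap targets. Under these conditions the
informed model (true phylogeny) attains mean |z| ≈ 0.95 over motif classes
versus ≈ 1.12 (uninformed) and ≈ 1.16 (misinformed); at `beta = 0` all
three agree to within 0.01. The mixed-model recovery study uses rows of
length 400 in 20 groups of 20 — about one effective random-effect draw per
group, so `sigma` has ~20 degrees of freedom; with only two groups no
estimator could meet the stated tolerances — and recovers `alpha = -1`
within ±0.3 and `sigma = 1.5` within ±0.4 (medians over 50 seeds).

## 6. Metrics

`motif_census()` classifies all C(n,3) induced three-node subdigraphs into
the 13 connected triad isomorphism classes via a precomputed canonical-code
table (minimum 6-bit code over the 6 vertex permutations — exhaustive
isomorphism, just tabulated once). Self-loops are excluded from
classification (the triad catalogue is defined on simple digraphs) but
still constrain the randomization. The five motifs with standard food-web
names map, under the rows-eat-columns convention, to: food chain `021C`,
exploitative competition `021U` (two consumers, one resource), apparent
competition `021D` (one consumer, two resources), omnivory `030T`,
three-species loop `030C`. The census is verified against igraph's
independent triad census on random digraphs.

`nodf()` is NODF on the 0–100 scale, computed by vegan's calculator with
the matrix packed by decreasing marginal totals — the convention that makes
the score independent of input row/column order (pairs with equal
marginals contribute 0). It is cross-checked against a direct
implementation of the published formula. `overlap_fraction()` reports the
share of observed links a replicate retains, and ensembles carry their
mean overlap in `tidy()`/`glance()` and persisted manifests, so analyses
can control for how far each model strays from the data.

## 7. Known limitations

* One correlation matrix per analysis: no joint row-and-column
  information, no multiple simultaneous random effects.
* The product acceptance rule's stationary distribution is not
  characterized analytically (only its constant-`V` and uninformed limits
  are); the Metropolis variant is provided for sensitivity checks.
* Binary data only; quantitative interaction strengths are out of scope.
* Probabilistic (marginal-preserving-in-expectation) null models and the
  fill algorithm are not implemented.
* Phylogenetic correlation assumes plain Brownian covariance — no Pagel's
  lambda or Ornstein–Uhlenbeck transformations.
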