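---
title: "Models and methods behind morphoclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind morphoclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(morphoclock)
```

## The question the package addresses

Discrete morphological characters are routinely combined with molecular
sequences in divergence-time analyses — through node calibrations, tip
dating, or the fossilized birth–death process. Whether that is justified
depends on whether morphology carries *time structure* that is concordant
with the molecular signal on the same phylogeny. morphoclock implements a
complete desk-scale version of that concordance analysis: maximum-likelihood
branch lengths per data type on a fixed rooted topology, a likelihood-ratio
test of branch-length proportionality, Bayesian relaxed-clock dating under
three fossil-calibration strategies, stepping-stone model comparison of
linked versus unlinked clocks, and summary statistics (through-origin
regression, HPD coverage, relative HPD widths, node-to-tip distance
contrasts) — all exercisable end to end on synthetic data with known truth.

## Substitution models and the likelihood engine

Both data types are scored with Felsenstein pruning over compressed site
patterns, with a discrete-gamma rate mixture (default five categories whose
rates are the *means* of equal-probability bins — not the medians; the
choice shifts log-likelihoods slightly and is therefore stated).

* **Molecular data** use GTR+Γ: five free exchangeabilities (GT is the
  reference), three free stationary frequencies, gamma shape α. The rate
  matrix is scaled to mean rate 1 at stationarity, so branch lengths are
  expected substitutions per site. `-` and `?` are treated as missing;
  IUPAC ambiguity codes spread partial likelihood over their state sets.
* **Morphological data** use Mk+Γ with equal state frequencies. The state
  space of each character defaults to its *observed* state count (minimum
  2), the usual convention for mixed-state matrices; a global `k` can be
  forced. Because morphologists score only variable characters, the
  likelihood can be conditioned on variability: each character's
  log-likelihood becomes `log L − log(1 − P_invariant)`, with
  `P_invariant` computed by pruning one-hot constant patterns. For
  characters with missing entries the correction uses fully observed
  constant patterns (standard Mkv practice); the alternative of
  marginalizing the observed missingness pattern would couple the
  correction to each character's missingness and is not what the common
  implementations condition on.

The pruning kernel is a small C++ routine (spectral form of the reversible
rate matrix, per-pattern rescaling); an exhaustive enumeration oracle over
internal-state assignments verifies it to 1e-10 in the tests, and an
independent likelihood implementation (phangorn) cross-checks GTR+Γ.

## ML branch lengths and the proportionality test

Branch lengths are fitted on the unrooted view of the topology (2n−3 free
lengths; reversible models cannot identify the root), by coordinate-wise
Brent search per branch interleaved with model-parameter updates
(quasi-Newton on log/additive-log-ratio transforms), until the
log-likelihood gains less than `tolerance` (default 1e-6) in a round.
Branch lengths are bounded in [0, 10].

Two partitions can be fitted **unlinked** (independent length sets) or
**linked**: one shared length set with a free proportionality coefficient
for the second partition (the first is fixed at 1 for identifiability, so
lengths are reported on the molecular scale). The proportionality LRT is
`2Δl = 2(l_unlinked − l_linked)` against χ² with df = 2n−3, the value
implied by the parameter accounting of the analysis this package mirrors;
boundary effects from zero-length branches are ignored. Because coordinate
ascent at loose tolerances can leave the unlinked optimum slightly below
the linked one, `proportionality_test()` warm-starts the unlinked fit at
the linked solution, which restores the nesting inequality structurally.

## Fossil calibration strategies

All calibrations are hard-bounded uniforms built from fossil minima
(in Ma):

* **C1** (diffuse): `U(t_L, 2 t_M − t_L)`, the mean pinned at the original
  calibration mean — agnosticism between the bounds.
* **C2** (narrow): `U(t_L, t_L + t_L/10)` — the fossil minimum taken as a
  close approximation of the clade age.
* **Cr**: the root's C1 calibration only — a poor fossil record baseline.

Minima are rounded to the nearest Ma *first*, halves away from zero, and
the upper bound is computed from the rounded minimum and rounded the same
way. That convention is the only one consistent with tabulated bounds such
as 125.9 → U(126, 139) and 235 → U(235, 259); round-to-even would give 258.
Two published C2 cells (a root bound printed as 354 where the rule gives
154, and one printed as 282 where the rule gives 292) are inconsistent with
the rule that generates every other cell; the package reproduces the rule,
not those two cells, and the test suite pins both facts. Nesting is
validated when a topology is available: a descendant's minimum may not
exceed an ancestor's maximum.

## Bayesian dating under the IGR relaxed clock

Node ages (units of 100 Myr; tips at 0) are sampled on the fixed rooted
binary topology by Metropolis-within-Gibbs, one proposal per generation:

* non-root internal ages — independence uniform proposals on the interval
  allowed by the parent and children (symmetric, always order-valid);
* root age, branch rates, and the clock hyperparameters — multiplicative
  proposals with the log-scale Jacobian in the acceptance ratio.

Each branch carries an independent Gamma rate with mean `m` and variance
`v` (shape m²/v, rate m/v), read directly from the clock model this
implements; the variant with duration-scaled variance is deliberately not
the default. `m` has a lognormal hyperprior and `v` an exponential one; the
defaults mirror a mean rate of about 0.0023 changes per character per
100 Myr. The likelihood sees branch length = rate × duration. With two
partitions the clock can be **linked** (one rate set and one (m, v) shared)
or **unlinked** (independent per partition); substitution models are always
per-partition. The tree prior on non-root ages conditional on the root is
i.i.d. uniform subject to the order constraints (the default), or the
closed-form-normalized conditional birth–death kernel (used for the
prior-correlation experiment); calibrations act as hard truncations, with
violations encoded as −∞.

Prior-only runs (`partitions = NULL`) sample the *effective* time prior
after truncation — the chain never computes a likelihood, so prior-only
marginals can be checked against analytic forms (the tests do this with
Kolmogorov–Smirnov distances on 2- and 3-tip cases).

Chains: one move per generation, sampling every `interval`, 10% burn-in
per chain, pooling across chains (≥2 for convergence checks; the
between-run relative range of posterior mean ages is reported). HPD
intervals are the shortest contiguous window holding 95% of sorted pooled
samples; ESS uses the initial-positive-autocorrelation truncation. A move
class with zero acceptances raises a warning (step-size failure).

## Stepping-stone marginal likelihoods

Powers follow `β_k = ((K−k)/K)^(1/0.4)` with K = 50 by default,
concentrating steps near the prior. At each step a tempered chain
(likelihood raised to β) is warm-started from the previous step; the log
marginal is the sum of `log mean exp[(β_{k−1} − β_k) ℓ]` over steps,
computed with a stabilized log-sum-exp. A conjugate gamma–Poisson toy with
an exact power-posterior sampler and a closed-form marginal verifies the
estimator to 0.1; the error decreases monotonically across per-step
budgets in the tests. The Bayes factor is reported as the difference of
log marginals (linked − unlinked; negative favors unlinked clocks).

## The synthetic-data generator

The generator produces the study conditions the pipeline assumes, and its
defaults are fixed once: 20 tips, root age 3 (300 Myr), Yule trees
(λ = 1); molecular partition of 1000 GTR+Γ sites at IGR mean rate 0.10
changes/site/100 Myr (variance 0.002); morphological partition of 200
binary Mk+Γ characters at mean rate 0.05 (variance 0.005 — a higher
relative spread, as morphology shows); latent rate correlation ρ = 0.6;
variable-only ascertainment; 25% / 20% missing cells, inside the 12–48%
range of the empirical supermatrices this emulates. Tip counts of 44 and
character counts are raised to empirical scale in individual experiments
where that matters (and said so there).

Design choices worth stating:

* **Discordance knob**: the correlation is applied to latent standard
  normals and mapped through each partition's gamma inverse CDF (Gaussian
  copula). Marginals are therefore exact at every ρ; the rate-scale
  correlation differs slightly from ρ. ρ = 1 with equal gamma shapes gives
  exactly proportional branch lengths — the null of the proportionality
  LRT, which is how the LRT calibration experiment generates its data.
* **Ascertainment by rejection**: invariant (and optionally
  parsimony-uninformative singleton) characters are discarded and
  re-simulated, so the variable-only-corrected likelihood is exactly the
  data-generating law and the correction is testable as a likelihood.
* **Yule trees** use the conditioned-process representation — non-root
  speciation ages i.i.d. truncated-exponential given the root age, each
  event splitting a uniformly chosen extant lineage — so the root age is
  exact rather than rescaled; the birth–death option delegates to
  `ape::rphylo` and rescales. The age law is verified by KS against the
  truncated-exponential CDF.
* **Missing data** are injected completely at random (with a guard that no
  taxon is fully erased); structured missingness of real supermatrices is
  not modeled.

What passing tests on these data do *not* show: real morphological
characters are correlated, selected for diagnosticity, and not exchangeable
across states; real missingness is blockwise; real molecular data are
partitioned by gene. Synthetic recovery is a correctness check of the
machinery, not evidence about any empirical dataset.

## Node depth classes and the averaging effect

The node-to-tip distance of a node is the mean, over its descendant tips,
of the summed branch lengths on the node-to-tip paths. Averaging over many
paths suppresses independent per-branch rate noise, which is why node ages
can agree across data types even when individual branch lengths do not.
Internal nodes are classed as *terminal* (both children tips), *deep* (the
root plus nodes subtending ≥ 50% of tips — the threshold is configurable;
no operational rule exists in the literature beyond excluding the root, so
50% is this package's choice), and *intermediate* (the rest).

A known limitation, measured honestly by the acceptance suite: with the
50% rule the deep class holds only the root and one to three near-root
nodes, whose node-to-tip distances are compressed into a narrow range, so
its within-tree correlation is range-restricted and regularly falls below
the terminal class on synthetic discordant-rate data. The averaging
mechanism itself — terminal nodes (two paths) correlating worse than
intermediate ones (many paths) — holds in every seeded replicate, as does
the headline contrast r(node-to-tip) > r(branch lengths).

## Numerical choices and degenerate inputs

* Pruning rescales per-pattern partials when they drop below 1e-200,
  accumulating log scale factors; category mixing uses log-sum-exp.
* All-zero branch lengths make `P_invariant = 1`; the variable-only
  correction then raises a degenerate-input error rather than returning
  −∞.
* Branch-length optimization visits branches in postorder; proposals that
  do not improve the current likelihood are discarded, making each round
  monotone.
* The LRT statistic is clamped at 0 if coordinate ascent leaves it within
  0.01 of zero from below; a larger violation raises an optimization
  failure.
* Calibration-infeasible MCMC starts are repaired by pulling calibrated
  nodes into their bounds and re-stacking ancestor ages; an infeasible
  joint configuration errors out before sampling.
* One master seed drives everything; per-chain and per-stage streams are
  derived sub-seeds kept below 2³¹.

## Problem sizes used by the tests and the acceptance script

The checked experiments run at desk scale, chosen so the full suite stays
within a coffee break: likelihood oracles on ≤5 taxa; LRT calibration on
200 replicates of 5 taxa × (150 sites + 50 characters) with single-category
models and parameters held at truth; HPD coverage on 20 replicates of
8 taxa × (250 sites + 80 characters) with 2 × 12,000-generation chains;
calibration-strategy precision on one 10-taxon dataset × three strategies;
the class contrast on 20 trees of 44 taxa. The acceptance script repeats
the same computations from scratch at (sometimes slightly reduced)
replicate counts and records every number it prints.
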