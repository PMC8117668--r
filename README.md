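# morphoclock

Do discrete morphological characters carry the same *time structure* as
molecular sequences on a shared phylogeny? That question decides whether
morphology can be trusted in node-dating, tip-dating and fossilized
birth–death analyses, where fossil placements and the branch durations
connecting them to the extant tree rest on morphological evidence alone.
morphoclock implements the full concordance analysis as a tested R
package plus a numbered analysis workflow:

* **Likelihood engine** — Felsenstein-pruning log-likelihoods under
  Mk+Γ (equal frequencies, per-character state counts, optional
  variable-only ascertainment correction `log L − log(1 − P_invariant)`)
  and GTR+Γ, with ML branch-length optimization on a fixed topology and a
  likelihood-ratio test of branch-length *proportionality* between
  partitions: `2Δl = 2(l_unlinked − l_linked)` against χ²(2n−3).
* **Calibration builder** — fossil minima to hard uniform node priors
  under three strategies: `Cr` root-only, `C1` diffuse
  `U(t_L, 2t_M − t_L)`, `C2` narrow `U(t_L, t_L + t_L/10)`.
* **Bayesian dating** — Metropolis-within-Gibbs on node ages under an
  independent-gamma-rates relaxed clock (per-branch rate ~ Gamma(mean m,
  variance v); lognormal/exponential hyperpriors), linked or unlinked
  clocks across partitions, prior-only sampling of the effective time
  prior, 95% HPD summaries, and stepping-stone marginal likelihoods
  (`β_k = ((K−k)/K)^{1/0.4}`, K = 50) with Bayes factors.
* **Concordance statistics** — regression through the origin
  (slope = Σxy/Σx², uncentered R²), HPD coverage, mean relative HPD width
  `100·(hi−lo)/mean`, and the node-to-tip distance contrast (per-node mean
  path length to descendant tips) with terminal/intermediate/deep node
  classes.
* **Synthetic-data generator** — time trees with per-branch gamma rates
  whose latent log-rates correlate across partitions at a tunable ρ
  (Gaussian copula, exact marginals), variable-only ascertainment by
  rejection, autapomorphy stripping, and missing data — so every stage is
  testable against known truth.

## Worked example

```r
library(morphoclock)

# a partially discordant paired dataset with known truth (rho = 0.6)
ds <- simulate_dataset(sim_config(n = 12, s_mol = 500, m_morph = 120, seed = 7))

# ML branch lengths per partition + proportionality LRT
pt <- proportionality_test(ds$cm_mol, ds$cm_morph, ds$time_tree$phy,
                           gtr_model(alpha = 1),
                           mk_model(alpha = 1, ascertainment = "variable_only"),
                           tolerance = 1e-3)
pt$lrt
#> Proportionality LRT: 2*dl = 57.91, df = 21, p = 2.64e-05

ctr <- branch_vs_nodepath_contrast(
  map_to_rooted(pt$fit_unlinked$fits[[1]]$tree, ds$time_tree$phy),
  map_to_rooted(pt$fit_unlinked$fits[[2]]$tree, ds$time_tree$phy))
round(c(branch = ctr$r_branch, nodepath = ctr$r_nodepath), 3)
#>   branch nodepath
#>    0.814    0.938
```

The LRT rejects branch-length proportionality decisively (the partitions
really do evolve under discordant rates), yet the node-to-tip distance
correlation (0.94) exceeds the branch-length correlation (0.81): averaging
path lengths over many descendant tips recovers the shared time structure.
That contrast is the package's headline diagnostic. Dating the same data:

```r
cal <- build_strategy(morphoclock:::synthetic_calibration_table(ds$time_tree),
                      "C1")
post <- run_mcmc(ds$time_tree$phy,
                 list(list(cm = ds$cm_mol, model = gtr_model(alpha = 1))),
                 cal, hyper = clock_hyper(meanlog = log(0.1), sdlog = 1,
                                          v_mean = 0.05),
                 cfg = mcmc_config(runs = 2, iterations = 10000, interval = 20))
head(post$summary, 3)
#>   node  mean hpd_lo hpd_hi rel_width_pct   ess
#> 1   13 3.070  2.704  3.689         32.07 42.15
#> 2   14 2.096  1.735  2.365         30.06 16.54
#> 3   15 1.733  1.492  2.018         30.34 22.49
```

Ages are in units of 100 Myr (node 13 is the root, truth 3.0 = 300 Ma);
`rel_width_pct` is the relative 95% HPD width used to compare dating
precision across calibration strategies and data types.

The `analysis/` directory holds the same workflow as numbered drivers
(`01_simulate.R` … `05_concordance.R`), each writing its tables under
`results/`.

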