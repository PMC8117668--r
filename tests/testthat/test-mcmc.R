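test_that("HPD intervals behave on degenerate, uniform, and normal samples", {
  expect_equal(hpd_interval(rep(3, 200)), c(3, 3))
  g <- seq_len(1000)
  h <- hpd_interval(g)
  expect_equal(h[2] - h[1], 949)   # shortest 95% window of a uniform grid
  set.seed(9)
  z <- stats::rnorm(1e5)
  hz <- hpd_interval(z)
  expect_lt(abs(hz[1] + 1.96), 0.05)
  expect_lt(abs(hz[2] - 1.96), 0.05)
  expect_error(hpd_interval(1:10), "at least")
})

test_that("retained-sample bookkeeping follows runs/iterations/interval/burn-in", {
  expect_equal(mcmc_retained_samples(4, 5e6, 200, 0.1), 9e4)
  expect_equal(mcmc_retained_samples(6, 1e7, 200, 0.1), 2.7e5)
  expect_error(mcmc_retained_samples(2, 1001, 10), "divisible")
})

test_that("prior-only sampling reproduces analytic uniform-prior means", {
  phy <- parse_tree("(A:1,B:1);")
  cs <- build_strategy(data.frame(node = 3, t_L = 100, t_M = 150), "C1")
  res <- run_mcmc(phy, NULL, cs,
                  cfg = mcmc_config(runs = 2, iterations = 20000,
                                    interval = 10, seed = 5))
  mc_se <- stats::sd(res$samples$age_3) / sqrt(ess(res$samples$age_3))
  expect_lt(abs(res$summary$mean - 1.5), 3 * mc_se + 0.01)

  phy3 <- parse_tree("((A:1,B:1):1,C:2);")
  cs3 <- build_strategy(data.frame(node = 4, t_L = 100, t_M = 150), "C1")
  res3 <- run_mcmc(phy3, NULL, cs3,
                   cfg = mcmc_config(runs = 2, iterations = 40000,
                                     interval = 10, seed = 6))
  expect_lt(abs(res3$summary$mean[res3$summary$node == 4] - 1.5), 0.03)
  # internal age ~ U(0, root): mean = E[root]/2
  expect_lt(abs(res3$summary$mean[res3$summary$node == 5] - 0.75), 0.03)
})

test_that("a lone calibrated node reproduces its truncated marginal prior", {
  # 3-tip tree, root U(100, 200) Ma, no other calibration: the internal
  # age marginal is Uniform(0, t_root) mixed over the root, with CDF
  # F(x) = P(U < x / t_root) for t_root ~ U(1, 2)
  phy3 <- parse_tree("((A:1,B:1):1,C:2);")
  cs3 <- build_strategy(data.frame(node = 4, t_L = 100, t_M = 150), "C1")
  res3 <- run_mcmc(phy3, NULL, cs3,
                   cfg = mcmc_config(runs = 2, iterations = 100000,
                                     interval = 10, seed = 17))
  x <- res3$samples$age_5
  marg_cdf <- function(q) {
    vapply(q, function(qq)
      stats::integrate(function(t) pmin(qq / t, 1), 1, 2)$value, numeric(1))
  }
  ks <- suppressWarnings(stats::ks.test(x, marg_cdf))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("every retained sample satisfies order constraints and bounds", {
  cfg <- sim_config(n = 6, s_mol = 100, m_morph = 40, seed = 3)
  ds <- simulate_dataset(cfg)
  tt <- ds$time_tree
  tab <- morphoclock:::synthetic_calibration_table(tt, 0.85, 1.15, max_nodes = 2)
  cs <- build_strategy(tab, "C1")
  parts <- list(list(cm = ds$cm_mol, model = gtr_model(alpha = 1)),
                list(cm = ds$cm_morph,
                     model = mk_model(alpha = 1, ascertainment = "variable_only")))
  res <- run_mcmc(tt$phy, parts, cs, clock = "unlinked",
                  hyper = clock_hyper(meanlog = log(0.1), sdlog = 1, v_mean = 0.05),
                  cfg = mcmc_config(runs = 2, iterations = 4000, interval = 20,
                                    seed = 4))
  edge <- tt$phy$edge
  ntip <- length(tt$phy$tip.label)
  age_of <- function(v) if (v <= ntip) 0 else res$samples[[paste0("age_", v)]]
  for (e in seq_len(nrow(edge)))
    expect_true(all(age_of(edge[e, 1]) > age_of(edge[e, 2])))
  for (nm in names(cs$calibrations)) {
    a <- res$samples[[paste0("age_", nm)]]
    expect_true(all(a >= cs$calibrations[[nm]]$t_L / 100 - 1e-12))
    expect_true(all(a <= cs$calibrations[[nm]]$t_U / 100 + 1e-12))
  }
  expect_true(all(res$summary$ess > 0))
  expect_true(all(res$summary$rel_width_pct >= 0))
})

test_that("posterior means track true ages with informative calibrations", {
  cfg <- sim_config(n = 8, s_mol = 250, m_morph = 80, rho = 1,
                    root_age = 3, seed = 41)
  ds <- simulate_dataset(cfg)
  tt <- ds$time_tree
  tab <- morphoclock:::synthetic_calibration_table(tt, 0.85, 1.15, max_nodes = 3)
  cs <- build_strategy(tab, "C1")
  parts <- list(list(cm = ds$cm_mol, model = gtr_model(alpha = 1)),
                list(cm = ds$cm_morph,
                     model = mk_model(alpha = 1, ascertainment = "variable_only")))
  res <- run_mcmc(tt$phy, parts, cs, clock = "unlinked",
                  hyper = clock_hyper(meanlog = log(0.1), sdlog = 1, v_mean = 0.05),
                  cfg = mcmc_config(runs = 2, iterations = 16000, interval = 20,
                                    seed = 42))
  truth <- tt$ages[res$summary$node]
  reg <- regression_through_origin(truth, res$summary$mean)
  expect_gt(reg$slope, 0.85)
  expect_lt(reg$slope, 1.15)
})
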