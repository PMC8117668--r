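test_that("time trees have the configured structure and are reproducible", {
  cfg <- sim_config(n = 5, seed = 2)
  tt <- simulate_time_tree(cfg)
  expect_equal(tt$phy$Nnode, 4)
  expect_equal(tt$ages[6], cfg$root_age)
  expect_true(all(branch_durations(tt) > 0))
  tt2 <- simulate_time_tree(cfg)
  expect_equal(tt, tt2)

  ttb <- simulate_time_tree(sim_config(n = 7, process = "birth_death",
                                       lambda = 1.5, mu = 0.5, seed = 3))
  expect_equal(ttb$ages[8], 3)
  expect_equal(length(ttb$phy$tip.label), 7)
})

test_that("Yule node ages follow the truncated-exponential density", {
  cfg <- sim_config(n = 120, lambda = 1, root_age = 3, seed = 9)
  tt <- simulate_time_tree(cfg)
  ntip <- 120
  ages <- tt$ages[(ntip + 2):(2 * ntip - 1)]   # non-root internal ages
  trunc_exp_cdf <- function(q) (1 - exp(-cfg$lambda * q)) /
    (1 - exp(-cfg$lambda * cfg$root_age))
  ks <- suppressWarnings(stats::ks.test(ages, trunc_exp_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("branch rates keep exact gamma marginals at every correlation", {
  cfg <- sim_config(n = 100, seed = 4)
  tt <- simulate_time_tree(cfg)
  igr <- list(m = 0.1, v = 0.004)

  r1 <- simulate_branch_rates(tt, igr, igr, rho = 1, seed = 5)
  expect_equal(r1$mol, r1$morph)   # comonotone, identical marginals

  # proportional branch lengths when shapes match
  igr_b <- list(m = 0.05, v = 0.001)
  r1b <- simulate_branch_rates(tt, igr, igr_b, rho = 1, seed = 5)
  expect_equal(r1b$morph, 0.5 * r1b$mol, tolerance = 1e-12)

  set.seed(6)
  big <- simulate_time_tree(sim_config(n = 5000, seed = 6))
  r0 <- simulate_branch_rates(big, igr, igr, rho = 0, seed = 7)
  expect_lt(abs(stats::cor(r0$mol, r0$morph)), 0.03)
  n_e <- length(r0$mol)
  expect_lt(abs(mean(r0$mol) - igr$m), 3 * sqrt(igr$v / n_e))
  expect_lt(abs(stats::var(r0$mol) - igr$v), 3 * stats::sd((r0$mol - igr$m)^2) / sqrt(n_e))
})

test_that("alignments respect zero-length trees and stationarity", {
  phy <- parse_tree("((A:0,B:0):0,C:0);")
  cm <- simulate_alignment(phy, gtr_model(alpha = 1), 50, seed = 8)
  expect_true(all(apply(cm$x, 2, function(col) length(unique(col)) == 1)))

  # long star branches: tip states approach the stationary distribution
  star_txt <- paste0("(", paste0("t", 1:6, ":25", collapse = ","), ");")
  star <- ape::read.tree(text = star_txt)
  gm <- gtr_model(freq = c(0.4, 0.3, 0.2, 0.1), alpha = 1, ncat = 1)
  cms <- simulate_alignment(star, gm, 5000, seed = 9)
  freq <- table(factor(as.vector(cms$x), levels = c("a", "c", "g", "t"))) /
    length(cms$x)
  n_cells <- length(cms$x)
  for (i in 1:4)
    expect_lt(abs(freq[i] - gm$freq[i]),
              3 * sqrt(gm$freq[i] * (1 - gm$freq[i]) / n_cells) + 0.005)
})

test_that("the generating tree beats a length-doubled tree in likelihood", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- sim_config(n = 6, s_mol = 500, missing_mol = 0, seed = 400 + seed)
    ds <- simulate_dataset(cfg)
    l_true <- log_likelihood(ds$cm_mol, ds$tree_mol, cfg$gtr)
    wrong <- ds$tree_mol
    wrong$edge.length <- 2 * wrong$edge.length
    l_wrong <- log_likelihood(ds$cm_mol, wrong, cfg$gtr)
    if (l_true > l_wrong) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("ascertainment and autapomorphy filters shape the characters", {
  phy <- rand_binary_tree(8, seed = 12)
  phy$edge.length <- phy$edge.length / 4
  cm_v <- simulate_morphology(phy, M = 80, ascertainment = "variable_only",
                              seed = 13)
  expect_true(all(state_counts(cm_v) >= 2))

  cm_s <- simulate_morphology(phy, M = 80, ascertainment = "variable_only",
                              strip_autapomorphies = TRUE, seed = 14)
  singleton <- apply(cm_s$x, 2, function(col) {
    tab <- table(col)
    length(tab) == 2 && min(tab) == 1
  })
  expect_false(any(singleton))

  tiny <- phy
  tiny$edge.length <- rep(1e-8, nrow(phy$edge))
  expect_error(simulate_morphology(tiny, M = 50, seed = 15, max_tries = 5),
               "budget")
})

test_that("autapomorphy stripping shortens fitted terminal branches", {
  shorter <- 0
  n_rep <- 8
  for (seed in seq_len(n_rep)) {
    cfg <- sim_config(n = 6, seed = 700 + seed)
    ds <- simulate_dataset(cfg)
    tr <- ds$tree_morph
    cm_all <- simulate_morphology(tr, M = 120, ascertainment = "variable_only",
                                  seed = 800 + seed)
    cm_str <- simulate_morphology(tr, M = 120, ascertainment = "variable_only",
                                  strip_autapomorphies = TRUE, seed = 800 + seed)
    mk <- mk_model(k = 2, alpha = 1, ncat = 1, ascertainment = "variable_only")
    f_all <- optimize_branch_lengths(cm_all, tr, mk, tolerance = 1e-3,
                                     optimize_model = FALSE)
    f_str <- optimize_branch_lengths(cm_str, tr, mk, tolerance = 1e-3,
                                     optimize_model = FALSE)
    term_a <- f_all$tree$edge.length[f_all$tree$edge[, 2] <= 6]
    term_s <- f_str$tree$edge.length[f_str$tree$edge[, 2] <= 6]
    if (mean(term_s) < mean(term_a)) shorter <- shorter + 1
  }
  expect_gte(shorter, n_rep - 2)
})

test_that("missing injection hits its rate and never erases a taxon", {
  x <- matrix(sample(c("0", "1"), 100 * 100, replace = TRUE), 100, 100,
              dimnames = list(paste0("t", 1:100)))
  cm <- char_matrix(x, "standard")
  expect_identical(inject_missing(cm, 0, seed = 1)$x, cm$x)
  cm12 <- inject_missing(cm, 0.12, seed = 2)
  expect_lt(abs(missing_fraction(cm12) - 0.12), 0.01)

  heavy <- inject_missing(cm, 0.95, seed = 3)
  observed_per_row <- rowSums(matrix(!(heavy$x %in% heavy$missing),
                                     nrow(heavy$x)))
  expect_true(all(observed_per_row >= 1))
})

test_that("whole datasets are reproducible bit-for-bit from the config", {
  cfg <- sim_config(n = 6, s_mol = 80, m_morph = 30, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_equal(d1, d2)
  expect_equal(d1$tree_mol$edge.length,
               d1$rates$mol * branch_durations(d1$time_tree))
})
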