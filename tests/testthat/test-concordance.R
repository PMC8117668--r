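test_that("through-origin regression matches closed forms", {
  x <- c(1, 2, 3); y <- c(2, 6, 10)
  reg <- regression_through_origin(x, y)
  expect_equal(reg$slope, 44 / 14)   # sum(xy) / sum(x^2)

  reg2 <- regression_through_origin(x, 2 * x)
  expect_equal(reg2$slope, 2)
  expect_equal(reg2$r, 1)
  expect_equal(reg2$r_squared, 1)

  regc <- regression_through_origin(x, c(4, 4, 4))
  expect_equal(regc$r, 0)
  expect_equal(regc$p_value, 1)

  expect_error(regression_through_origin(c(0, 0, 0), y), "zero")
})

test_that("through-origin slope agrees with brute-force minimization", {
  set.seed(8)
  for (i in 1:6) {
    x <- stats::runif(10, 0.1, 3)
    y <- 1.7 * x + stats::rnorm(10, 0, 0.4)
    reg <- regression_through_origin(x, y)
    brute <- stats::optimize(function(b) sum((y - b * x)^2), c(-10, 10),
                             tol = 1e-12)$minimum
    expect_equal(reg$slope, brute, tolerance = 1e-6)
  }
})

test_that("coverage counts bound-inclusive and is permutation invariant", {
  iv <- data.frame(node = 1:4, hpd_lo = c(0, 0, 2, 5), hpd_hi = c(1, 1, 3, 6))
  est <- stats::setNames(c(0.5, 1.0, 4.0, 7.0), 1:4)  # 1.0 ties the bound
  expect_equal(coverage_fraction(est, iv), 50)
  perm <- sample(4)
  expect_equal(coverage_fraction(est[perm], iv), 50)
  expect_equal(coverage_fraction(stats::setNames(c(0.5, 0.5, 2.5, 5.5), 1:4), iv), 100)
  expect_equal(coverage_fraction(stats::setNames(c(9, 9, 9, 9), 1:4), iv), 0)
  expect_error(coverage_fraction(stats::setNames(1, "77"), iv), "mismatch")
})

test_that("mean relative HPD width follows its definition", {
  s <- data.frame(node = 1, mean = 100, hpd_lo = 80, hpd_hi = 120)
  expect_equal(mean_relative_hpd_width(s), 40)
  s0 <- data.frame(node = 1:2, mean = c(1, 2), hpd_lo = c(1, 2), hpd_hi = c(1, 2))
  expect_equal(mean_relative_hpd_width(s0), 0)
  expect_error(mean_relative_hpd_width(
    data.frame(node = 1, mean = 0, hpd_lo = 0, hpd_hi = 1)), "non-positive")
})

test_that("identical or proportional trees give perfect concordance", {
  phy <- rand_binary_tree(10, seed = 33)
  res <- branch_vs_nodepath_contrast(phy, phy)
  expect_equal(res$r_branch, 1)
  expect_equal(res$r_nodepath, 1)
  scaled <- phy
  scaled$edge.length <- 3.7 * phy$edge.length
  expect_equal(branch_vs_nodepath_contrast(phy, scaled)$r_nodepath, 1)
})

test_that("path averaging lifts the node-to-tip correlation above branch r", {
  # i.i.d. multiplicative branch noise: node-to-tip averaging cancels part
  # of it, so r_nodepath should beat r_branch in nearly every replicate
  wins <- 0
  for (seed in 1:20) {
    set.seed(1000 + seed)
    tt <- simulate_time_tree(sim_config(n = 24, seed = 1000 + seed))
    dur <- branch_durations(tt)
    noise_a <- exp(stats::rnorm(length(dur), 0, 0.7))
    noise_b <- exp(stats::rnorm(length(dur), 0, 0.7))
    ta <- tt$phy; ta$edge.length <- dur * noise_a
    tb <- tt$phy; tb$edge.length <- dur * noise_b
    res <- branch_vs_nodepath_contrast(ta, tb)
    if (res$r_nodepath > res$r_branch) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("concordance reports assemble regression, coverage and widths", {
  sx <- data.frame(node = 9:13, mean = c(3, 2, 1.5, 1, 0.5),
                   hpd_lo = c(2.5, 1.6, 1.2, 0.8, 0.3),
                   hpd_hi = c(3.5, 2.4, 1.8, 1.2, 0.7))
  sy <- sx
  sy$mean <- sx$mean * 0.95
  rep <- concordance_report(sx, sy, exclude_root = TRUE, root_node = 9)
  expect_equal(rep$regression$n, 4)
  expect_equal(rep$regression$slope, 0.95, tolerance = 1e-12)
  expect_equal(rep$coverage_y_in_x_pct, 100)
})
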