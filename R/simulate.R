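#' Simulation configuration
#'
#' Study conditions for paired molecular/morphological synthetic data:
#' a rooted time tree, per-branch rates drawn independently per branch
#' from partition-specific gamma distributions whose latent log-rates have
#' a tunable cross-partition correlation, sequence and character matrices
#' simulated on the resulting branch-length trees, variable-only
#' ascertainment for morphology, optional autapomorphy stripping, and
#' missing data injected completely at random at rates in the range seen
#' in empirical supermatrices (roughly 12-48%).
#'
#' @param n tip count (>= 3).
#' @param process `"yule"` or `"birth_death"`.
#' @param lambda,mu birth and death rates of the tree process.
#' @param root_age root age in internal units (100 Myr).
#' @param igr_mol,igr_morph per-partition IGR parameters `list(m =, v =)`
#'   (changes per character per 100 Myr).
#' @param rho cross-partition correlation of latent normal log-rates in
#'   `[-1, 1]` (1 = comonotone rates, 0 = independent).
#' @param s_mol molecular sites; `gtr` the generating [gtr_model()].
#' @param m_morph morphological characters; `k_morph` state count;
#'   `mk` the generating [mk_model()].
#' @param ascertainment `"variable_only"` (reject invariant characters) or
#'   `"none"`.
#' @param strip_autapomorphies also reject parsimony-uninformative
#'   singleton characters.
#' @param missing_mol,missing_morph missing-cell fractions in `[0, 1)`.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 20, process = c("yule", "birth_death"),
                       lambda = 1, mu = 0, root_age = 3,
                       igr_mol = list(m = 0.10, v = 0.002),
                       igr_morph = list(m = 0.05, v = 0.005),
                       rho = 0.6,
                       s_mol = 1000, gtr = gtr_model(alpha = 1),
                       m_morph = 200, k_morph = 2,
                       mk = mk_model(alpha = 1, ascertainment = "variable_only"),
                       ascertainment = c("variable_only", "none"),
                       strip_autapomorphies = FALSE,
                       missing_mol = 0.25, missing_morph = 0.20,
                       seed = 1) {
  process <- match.arg(process)
  ascertainment <- match.arg(ascertainment)
  stopifnot(n >= 3, s_mol >= 1, m_morph >= 1, rho >= -1, rho <= 1,
            missing_mol >= 0, missing_mol < 1,
            missing_morph >= 0, missing_morph < 1, root_age > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a rooted ultrametric time tree
#'
#' Yule trees use the conditioned-process representation: given the root
#' age and tip count, the non-root speciation ages are i.i.d. truncated
#' exponential (rate `lambda`, support (0, root_age)), each event
#' splitting a uniformly chosen extant lineage. Birth-death trees are
#' simulated with [ape::rphylo()] and rescaled to the configured root age.
#'
#' @param config a [sim_config()] (only the tree fields are used).
#' @return a [time_tree()].
#' @export
simulate_time_tree <- function(config) {
  set.seed(derive_seeds(config$seed, 6)[1])
  n <- config$n
  T0 <- config$root_age
  if (config$process == "yule") {
    la <- config$lambda
    # inverse-CDF draws from the truncated exponential age density
    u <- stats::runif(n - 2)
    x <- -log(1 - u * (1 - exp(-la * T0))) / la   # ages in (0, T0)
    ages_int <- c(T0, sort(x, decreasing = TRUE))
    ntip <- n
    nnode <- n - 1
    edge <- matrix(0L, 2 * n - 2, 2)
    ecount <- 0
    open_parent <- c(ntip + 1L, ntip + 1L)
    for (i in 2:nnode) {
      j <- sample.int(length(open_parent), 1)
      v <- ntip + i
      ecount <- ecount + 1
      edge[ecount, ] <- c(open_parent[j], v)
      open_parent <- c(open_parent[-j], v, v)
    }
    tips <- sample.int(ntip)  # random tip assignment
    for (j in seq_along(open_parent)) {
      ecount <- ecount + 1
      edge[ecount, ] <- c(open_parent[j], tips[j])
    }
    ages <- c(rep(0, ntip), ages_int)
    phy <- list(edge = edge, Nnode = nnode, tip.label = paste0("t", seq_len(ntip)),
                edge.length = ages[edge[, 1]] - ages[edge[, 2]])
    class(phy) <- "phylo"
    phy <- ape::reorder.phylo(phy, "postorder")
    return(as_time_tree(phy))
  }
  phy <- ape::rphylo(n, birth = config$lambda, death = config$mu)
  tt <- as_time_tree(phy)
  tt$ages <- tt$ages * (T0 / tt$ages[n + 1L])
  time_tree(tt$phy, tt$ages)
}

#' Simulate correlated per-branch rates for two partitions
#'
#' Per branch, a pair of standard normals with correlation `rho` is mapped
#' through the gamma inverse CDF of each partition (Gaussian copula), so
#' each partition's rates are exactly Gamma(mean m, variance v)
#' marginally while their dependence is tunable: `rho = 1` gives
#' comonotone rates, `rho = 0` independent ones.
#'
#' @param tt a [time_tree()].
#' @param igr_mol,igr_morph `list(m =, v =)` per partition.
#' @param rho latent-normal correlation in `[-1, 1]`.
#' @param seed RNG seed.
#' @return list with `mol` and `morph` rate vectors aligned with
#'   `tt$phy$edge` rows.
#' @export
simulate_branch_rates <- function(tt, igr_mol, igr_morph, rho, seed = 1) {
  stopifnot(rho >= -1, rho <= 1)
  set.seed(seed)
  ne <- nrow(tt$phy$edge)
  z1 <- stats::rnorm(ne)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(ne)
  to_rates <- function(z, p) {
    u <- stats::pnorm(z)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    stats::qgamma(u, shape = p$m^2 / p$v, rate = p$m / p$v)
  }
  list(mol = to_rates(z1, igr_mol), morph = to_rates(z2, igr_morph))
}

# Evolve one batch of characters down the tree. Returns an ntip x nchar
# matrix of 1-based state indices.
evolve_states <- function(phy, lengths, dec, cat_rates, nchar) {
  k <- dec$k
  ntip <- length(phy$tip.label)
  nall <- ntip + phy$Nnode
  root <- ntip + 1L
  cat_i <- sample.int(length(cat_rates), nchar, replace = TRUE)
  states <- matrix(0L, nall, nchar)
  states[root, ] <- sample.int(k, nchar, replace = TRUE, prob = dec$pi)
  for (e in rev(seq_len(nrow(phy$edge)))) {   # preorder
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    for (c_i in unique(cat_i)) {
      P <- transition_prob(dec, lengths[e] * cat_rates[c_i])
      for (s in seq_len(k)) {
        idx <- which(cat_i == c_i & states[par, ] == s)
        if (length(idx))
          states[ch, idx] <- sample.int(k, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
  }
  states[seq_len(ntip), , drop = FALSE]
}

#' Simulate a nucleotide alignment on a branch-length tree
#'
#' Root states drawn from the stationary frequencies; states evolved
#' edge-wise through GTR transition probabilities at per-site
#' gamma-scaled lengths.
#'
#' @param phy `phylo` with branch lengths (expected substitutions/site).
#' @param model a [gtr_model()].
#' @param S number of sites.
#' @param seed RNG seed.
#' @return a `char_matrix` of type `"dna"`.
#' @export
simulate_alignment <- function(phy, model, S, seed = 1) {
  set.seed(seed)
  phy <- ape::reorder.phylo(phy, "postorder")
  dec <- model_eigen(model)
  cr <- gamma_category_rates(model$alpha, model$ncat)
  st <- evolve_states(phy, phy$edge.length, dec, cr, S)
  x <- matrix(c("a", "c", "g", "t")[st], nrow(st), ncol(st))
  rownames(x) <- phy$tip.label
  char_matrix(x, "dna")
}

# Columns (of a 1-based state matrix) that are parsimony-uninformative
# singletons: variable, with exactly one taxon carrying a minority state.
is_singleton <- function(col) {
  tab <- table(col)
  length(tab) == 2 && min(tab) == 1
}

#' Simulate a morphological matrix on a branch-length tree
#'
#' Characters evolve under Mk+Gamma. With variable-only ascertainment,
#' invariant characters are rejected and re-simulated until `M` variable
#' characters accumulate — so the variable-only-corrected likelihood is
#' exactly the data-generating law. With `strip_autapomorphies`,
#' parsimony-uninformative singleton characters are also rejected,
#' emulating the truncation of terminal morphological branches seen when
#' autapomorphies go unsampled.
#'
#' @param phy `phylo` with branch lengths (expected changes/character).
#' @param model a [mk_model()] with fixed `k` (defaults to `k`).
#' @param M number of characters to return.
#' @param k state count.
#' @param ascertainment `"none"` or `"variable_only"`.
#' @param strip_autapomorphies reject singleton characters too.
#' @param seed RNG seed.
#' @param max_tries rejection budget (multiples of `M`).
#' @return a `char_matrix` of type `"standard"`.
#' @export
simulate_morphology <- function(phy, model = mk_model(k = 2), M, k = 2,
                                ascertainment = c("variable_only", "none"),
                                strip_autapomorphies = FALSE, seed = 1,
                                max_tries = 500) {
  ascertainment <- match.arg(ascertainment)
  set.seed(seed)
  phy <- ape::reorder.phylo(phy, "postorder")
  if (is.null(model$k)) model$k <- k
  dec <- model_eigen(model, k = model$k)
  cr <- gamma_category_rates(model$alpha, model$ncat)
  kept <- NULL
  tries <- 0
  while (is.null(kept) || ncol(kept) < M) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("rejection budget exceeded: rates too low to yield variable characters")
    st <- evolve_states(phy, phy$edge.length, dec, cr, M)
    ok <- apply(st, 2, function(col) length(unique(col)) > 1)
    if (ascertainment == "none") ok[] <- TRUE
    if (strip_autapomorphies)
      ok <- ok & !apply(st, 2, is_singleton)
    kept <- cbind(kept, st[, ok, drop = FALSE])
  }
  kept <- kept[, seq_len(M), drop = FALSE]
  x <- matrix(as.character(kept - 1L), nrow(kept), ncol(kept))
  rownames(x) <- phy$tip.label
  char_matrix(x, "standard")
}

#' Inject missing data completely at random
#'
#' Cells are set to `"?"` independently with probability `fraction`; a
#' guard restores one observed cell in any row that would otherwise be
#' fully erased.
#'
#' @param cm a `char_matrix`.
#' @param fraction missing fraction in `[0, 1)`.
#' @param seed RNG seed.
#' @return a `char_matrix` with attribute `realized_fraction`.
#' @export
inject_missing <- function(cm, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(cm)
  set.seed(seed)
  x <- cm$x
  hit <- matrix(stats::runif(length(x)) < fraction, nrow(x), ncol(x))
  x[hit] <- "?"
  for (i in seq_len(nrow(x))) {
    if (all(x[i, ] %in% cm$missing)) {
      j <- sample.int(ncol(x), 1)
      x[i, j] <- cm$x[i, j]
    }
  }
  out <- char_matrix(x, cm$type)
  attr(out, "realized_fraction") <- mean(x %in% out$missing)
  out
}

#' Simulate a paired molecular/morphological dataset with known truth
#'
#' Runs the full generative chain of [sim_config()]: time tree, correlated
#' branch rates, branch-length trees (length = rate x duration), sequence
#' and character matrices, ascertainment and missing data. All randomness
#' derives from the config's master seed.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_dataset`: `time_tree`, `rates`
#'   (`mol`, `morph`), `tree_mol`, `tree_morph` (branch-length trees),
#'   `cm_mol`, `cm_morph`, `config`.
#' @export
simulate_dataset <- function(config) {
  seeds <- derive_seeds(config$seed, 6)
  tt <- simulate_time_tree(config)
  rates <- simulate_branch_rates(tt, config$igr_mol, config$igr_morph,
                                 config$rho, seed = seeds[2])
  dur <- branch_durations(tt)
  tree_mol <- tt$phy; tree_mol$edge.length <- rates$mol * dur
  tree_morph <- tt$phy; tree_morph$edge.length <- rates$morph * dur
  cm_mol <- simulate_alignment(tree_mol, config$gtr, config$s_mol, seed = seeds[3])
  cm_morph <- simulate_morphology(tree_morph, config$mk, config$m_morph,
                                  k = config$k_morph,
                                  ascertainment = config$ascertainment,
                                  strip_autapomorphies = config$strip_autapomorphies,
                                  seed = seeds[4])
  if (config$missing_mol > 0)
    cm_mol <- inject_missing(cm_mol, config$missing_mol, seed = seeds[5])
  if (config$missing_morph > 0)
    cm_morph <- inject_missing(cm_morph, config$missing_morph, seed = seeds[6])
  structure(list(time_tree = tt, rates = rates, tree_mol = tree_mol,
                 tree_morph = tree_morph, cm_mol = cm_mol, cm_morph = cm_morph,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d tips, %d sites, %d characters (rho = %g)\n",
              x$config$n, ncol(x$cm_mol$x), ncol(x$cm_morph$x), x$config$rho))
  invisible(x)
}
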