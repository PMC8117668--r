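#' MCMC configuration
#'
#' @param runs number of independent chains (>= 2 for convergence checks;
#'   1 allowed for tempered stepping-stone chains).
#' @param iterations generations per chain; one proposal per generation.
#' @param interval sampling interval (iterations divisible by it).
#' @param burnin fraction of samples discarded per chain.
#' @param seed master seed; per-chain streams are derived from it.
#' @param steps proposal step sizes: multiplicative windows for the root
#'   age, branch rates and hyperparameters.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(runs = 2, iterations = 10000, interval = 10,
                        burnin = 0.1, seed = 1,
                        steps = list(root = 0.2, rate = 0.6, m = 0.4, v = 0.8)) {
  stopifnot(iterations %% interval == 0, burnin >= 0, burnin < 1, runs >= 1)
  structure(list(runs = runs, iterations = iterations, interval = interval,
                 burnin = burnin, seed = seed, steps = steps),
            class = "mcmc_config")
}

#' Clock-model hyperpriors
#'
#' Hyperpriors for the independent-gamma-rates clock: the mean rate gets a
#' lognormal prior, the variance an exponential prior. Defaults mirror a
#' rate of about 0.0023 changes per character per 100 Myr.
#'
#' @param meanlog,sdlog lognormal hyperprior on the IGR mean rate.
#' @param v_mean mean of the exponential hyperprior on the IGR variance.
#' @return list of class `clock_hyper`.
#' @export
clock_hyper <- function(meanlog = -6.0605, sdlog = 0.0519, v_mean = 0.039) {
  stopifnot(is.finite(meanlog), sdlog > 0, v_mean > 0)
  structure(list(meanlog = meanlog, sdlog = sdlog, v_mean = v_mean),
            class = "clock_hyper")
}

# Feasible initial ages: scale by the maximum edge-count depth below each
# node, then pull calibrated nodes into their bounds, and verify.
init_ages <- function(phy, calib_int, ntip) {
  root <- ntip + 1L
  nall <- ntip + phy$Nnode
  height <- integer(nall)
  for (e in seq_len(nrow(phy$edge))) {   # postorder
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    height[par] <- max(height[par], height[ch] + 1L)
  }
  root_cal <- calib_int[[as.character(root)]]
  t_root <- if (!is.null(root_cal)) mean(root_cal) else 1
  ages <- t_root * height / height[root]
  ages[seq_len(ntip)] <- 0
  for (nm in names(calib_int)) {
    v <- as.integer(nm)
    b <- calib_int[[nm]]
    ages[v] <- min(max(ages[v], b[1] + 0.02 * diff(b)), b[2] - 0.02 * diff(b))
  }
  # repair order violations root-down
  ord <- rev(unique(phy$edge[, 1]))  # preorder over internal nodes
  for (v in ord) {
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    for (c in ch[ch > ntip]) {
      if (ages[c] >= ages[v]) ages[c] <- 0.9 * ages[v]
    }
  }
  ages
}

#' Bayesian divergence-time MCMC under an IGR relaxed clock
#'
#' Metropolis-within-Gibbs sampler on a fixed rooted binary topology:
#' node ages (uniform proposals within the parent/children window), the
#' root age, per-branch rates, and the IGR mean/variance hyperparameters,
#' with hard uniform calibrations and a choice of tree prior. The branch
#' length seen by the likelihood is rate x duration. With
#' `partitions = NULL` the likelihood is constant and the chain samples
#' the effective time prior ("prior-only" mode). One proposal is made per
#' iteration; chains are pooled after per-chain burn-in.
#'
#' @param phy rooted binary topology (`phylo`).
#' @param partitions list of partitions, each `list(cm = , model = )`
#'   (a [char_matrix()] and a [mk_model()]/[gtr_model()]); `NULL` for
#'   prior-only sampling.
#' @param calibrations [build_strategy()] result; node names are node
#'   numbers of `phy`, bounds in Ma. The root must be calibrated.
#' @param clock `"linked"` (one rate set shared by all partitions) or
#'   `"unlinked"` (independent rate sets).
#' @param tree_prior a [make_tree_prior()].
#' @param hyper a [clock_hyper()] or list of one per clock.
#' @param cfg an [mcmc_config()].
#' @param beta power on the likelihood (stepping-stone tempering;
#'   default 1).
#' @param init_state optional warm-start state from a previous run.
#' @param time_unit Ma per internal unit (default 100).
#' @return list of class `dating_mcmc`: `samples` (data.frame, pooled,
#'   post burn-in, with run ids), `summary` (per-node posterior summary),
#'   `acceptance` (per move class), `state` (final state), plus
#'   convergence diagnostics.
#' @export
run_mcmc <- function(phy, partitions = NULL, calibrations,
                     clock = c("linked", "unlinked"),
                     tree_prior = make_tree_prior("uniform"),
                     hyper = clock_hyper(), cfg = mcmc_config(),
                     beta = 1, init_state = NULL, time_unit = 100) {
  clock <- match.arg(clock)
  phy <- ape::reorder.phylo(phy, "postorder")
  stopifnot(ape::is.rooted(phy), ape::is.binary(phy))
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  nint <- phy$Nnode
  edge <- phy$edge
  ne <- nrow(edge)
  parent_of <- integer(ntip + nint)
  parent_of[edge[, 2]] <- edge[, 1]
  edge_above <- integer(ntip + nint)        # edge row whose child is node
  edge_above[edge[, 2]] <- seq_len(ne)
  children_of <- split(edge[, 2], edge[, 1])

  if (!(as.character(root) %in% names(calibrations$calibrations)))
    stop("the root node must be calibrated")
  calib_int <- lapply(calibrations$calibrations,
                      function(cal) c(cal$t_L, cal$t_U) / time_unit)

  npart <- length(partitions)
  nclock <- if (clock == "linked" || npart <= 1) 1L else npart
  clock_of <- if (npart) (if (clock == "linked") rep(1L, npart) else seq_len(npart)) else integer(0)
  if (inherits(hyper, "clock_hyper")) hyper <- rep(list(hyper), nclock)
  stopifnot(length(hyper) == nclock)

  ll_funs <- lapply(partitions, function(p) make_loglik(p$cm, phy, p$model))
  part_models <- lapply(partitions, function(p) p$model)

  # ---- state ----
  if (is.null(init_state)) {
    ages <- init_ages(phy, calib_int, ntip)
    m <- vapply(hyper, function(h) exp(h$meanlog), numeric(1))
    v <- vapply(hyper, function(h) h$v_mean, numeric(1))
    rates <- lapply(seq_len(nclock), function(c) rep(m[c], ne))
    state <- list(ages = ages, rates = rates, m = m, v = v)
  } else state <- init_state

  tt_of <- function(ages) structure(list(phy = phy, ages = ages), class = "time_tree")
  lp_times_fun <- function(ages) log_prior_times(tt_of(ages), tree_prior,
                                                 calibrations, time_unit)
  durations <- function(ages) ages[edge[, 1]] - ages[edge[, 2]]
  part_ll <- function(p, ages, rates) {
    ll_funs[[p]](rates[[clock_of[p]]] * durations(ages), part_models[[p]])
  }

  lp_t <- lp_times_fun(state$ages)
  if (!is.finite(lp_t)) stop("initial state violates age constraints or calibrations")
  lp_r <- vapply(seq_len(nclock), function(c)
    igr_log_prior(state$rates[[c]], state$m[c], state$v[c]), numeric(1))
  lp_h <- vapply(seq_len(nclock), function(c)
    stats::dlnorm(state$m[c], hyper[[c]]$meanlog, hyper[[c]]$sdlog, log = TRUE) +
    stats::dexp(state$v[c], 1 / hyper[[c]]$v_mean, log = TRUE), numeric(1))
  ll <- if (npart) vapply(seq_len(npart), function(p)
    part_ll(p, state$ages, state$rates), numeric(1)) else numeric(0)

  move_types <- c("age", "root", "rate", "m", "v")
  wts <- c(if (nint > 1) 2 * (nint - 1) else 0, 2, ne * nclock, 2 * nclock, 2 * nclock)
  acc <- prop <- stats::setNames(numeric(5), move_types)
  nonroot_int <- setdiff((ntip + 1L):(ntip + nint), root)
  st <- cfg$steps

  all_samples <- list()
  run_means <- list()
  seeds <- derive_seeds(cfg$seed, cfg$runs)

  for (run in seq_len(cfg$runs)) {
    set.seed(seeds[run])
    nsamp <- cfg$iterations / cfg$interval
    keep_from <- floor(cfg$burnin * nsamp) + 1L
    rec <- matrix(NA_real_, nsamp, nint + 2 * nclock + 2)
    for (iter in seq_len(cfg$iterations)) {
      mv <- sample.int(5L, 1L, prob = wts)
      type <- move_types[mv]
      prop[type] <- prop[type] + 1
      if (type == "age") {
        j <- if (length(nonroot_int) == 1) nonroot_int else sample(nonroot_int, 1)
        lb <- max(state$ages[children_of[[as.character(j)]]])
        ub <- state$ages[parent_of[j]]
        new_ages <- state$ages
        new_ages[j] <- stats::runif(1, lb, ub)
        lp_t_new <- lp_times_fun(new_ages)
        if (is.finite(lp_t_new)) {
          ll_new <- if (npart) vapply(seq_len(npart), function(p)
            part_ll(p, new_ages, state$rates), numeric(1)) else numeric(0)
          lr <- beta * (sum(ll_new) - sum(ll)) + lp_t_new - lp_t
          if (log(stats::runif(1)) < lr) {
            state$ages <- new_ages; lp_t <- lp_t_new; ll <- ll_new
            acc[type] <- acc[type] + 1
          }
        }
      } else if (type == "root") {
        eps <- stats::runif(1, -st$root, st$root)
        new_ages <- state$ages
        new_ages[root] <- state$ages[root] * exp(eps)
        lp_t_new <- lp_times_fun(new_ages)
        if (is.finite(lp_t_new)) {
          ll_new <- if (npart) vapply(seq_len(npart), function(p)
            part_ll(p, new_ages, state$rates), numeric(1)) else numeric(0)
          lr <- beta * (sum(ll_new) - sum(ll)) + lp_t_new - lp_t + eps
          if (log(stats::runif(1)) < lr) {
            state$ages <- new_ages; lp_t <- lp_t_new; ll <- ll_new
            acc[type] <- acc[type] + 1
          }
        }
      } else if (type == "rate") {
        c_i <- sample.int(nclock, 1)
        e_i <- sample.int(ne, 1)
        eps <- stats::runif(1, -st$rate, st$rate)
        new_rates <- state$rates
        new_rates[[c_i]][e_i] <- new_rates[[c_i]][e_i] * exp(eps)
        lp_r_new <- igr_log_prior(new_rates[[c_i]], state$m[c_i], state$v[c_i])
        parts <- which(clock_of == c_i)
        ll_new <- ll
        if (length(parts))
          ll_new[parts] <- vapply(parts, function(p)
            part_ll(p, state$ages, new_rates), numeric(1))
        lr <- beta * (sum(ll_new) - sum(ll)) + lp_r_new - lp_r[c_i] + eps
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          state$rates <- new_rates; lp_r[c_i] <- lp_r_new; ll <- ll_new
          acc[type] <- acc[type] + 1
        }
      } else if (type == "m") {
        c_i <- sample.int(nclock, 1)
        eps <- stats::runif(1, -st$m, st$m)
        m_new <- state$m[c_i] * exp(eps)
        lp_r_new <- igr_log_prior(state$rates[[c_i]], m_new, state$v[c_i])
        lp_h_new <- stats::dlnorm(m_new, hyper[[c_i]]$meanlog, hyper[[c_i]]$sdlog, log = TRUE) +
          stats::dexp(state$v[c_i], 1 / hyper[[c_i]]$v_mean, log = TRUE)
        lr <- lp_r_new - lp_r[c_i] + lp_h_new - lp_h[c_i] + eps
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          state$m[c_i] <- m_new; lp_r[c_i] <- lp_r_new; lp_h[c_i] <- lp_h_new
          acc[type] <- acc[type] + 1
        }
      } else {
        c_i <- sample.int(nclock, 1)
        eps <- stats::runif(1, -st$v, st$v)
        v_new <- state$v[c_i] * exp(eps)
        lp_r_new <- igr_log_prior(state$rates[[c_i]], state$m[c_i], v_new)
        lp_h_new <- stats::dlnorm(state$m[c_i], hyper[[c_i]]$meanlog, hyper[[c_i]]$sdlog, log = TRUE) +
          stats::dexp(v_new, 1 / hyper[[c_i]]$v_mean, log = TRUE)
        lr <- lp_r_new - lp_r[c_i] + lp_h_new - lp_h[c_i] + eps
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          state$v[c_i] <- v_new; lp_r[c_i] <- lp_r_new; lp_h[c_i] <- lp_h_new
          acc[type] <- acc[type] + 1
        }
      }
      if (iter %% cfg$interval == 0) {
        rec[iter / cfg$interval, ] <- c(state$ages[(ntip + 1L):(ntip + nint)],
                                        state$m, state$v, sum(ll),
                                        lp_t + sum(lp_r) + sum(lp_h))
      }
    }
    kept <- rec[keep_from:nsamp, , drop = FALSE]
    df <- as.data.frame(kept)
    names(df) <- c(paste0("age_", (ntip + 1L):(ntip + nint)),
                   paste0("m_", seq_len(nclock)), paste0("v_", seq_len(nclock)),
                   "loglik", "logprior")
    df$run <- run
    all_samples[[run]] <- df
    run_means[[run]] <- colMeans(kept[, seq_len(nint), drop = FALSE])
  }

  samples <- do.call(rbind, all_samples)
  node_ids <- (ntip + 1L):(ntip + nint)
  summ <- summarize_posterior(samples, node_ids)
  conv <- if (cfg$runs >= 2) {
    rm <- do.call(rbind, run_means)
    max(apply(rm, 2, function(x) diff(range(x))) /
          pmax(apply(rm, 2, mean), 1e-12))
  } else NA_real_
  acc_rate <- ifelse(prop > 0, acc / prop, NA)
  dead <- names(acc_rate)[!is.na(acc_rate) & prop > 50 & acc_rate == 0]
  if (length(dead))
    warning("zero acceptance in move class(es): ", paste(dead, collapse = ", "))
  structure(list(samples = samples, summary = summ, acceptance = acc_rate,
                 proposals = prop, run_mean_rel_range = conv,
                 state = state, cfg = cfg, clock = clock, beta = beta,
                 node_ids = node_ids, time_unit = time_unit),
            class = "dating_mcmc")
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(level * N)` of the
#' sorted samples.
#'
#' @param samples numeric vector (at least `min_n` values).
#' @param level credibility level (default 0.95).
#' @param min_n minimum sample count (default 100).
#' @return numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, level = 0.95, min_n = 100) {
  n <- length(samples)
  if (n < min_n) stop("need at least ", min_n, " samples")
  s <- sort(samples)
  m <- ceiling(level * n)
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)
  c(s[i], s[i + m - 1])
}

#' Effective sample size
#'
#' Autocorrelation-time estimate: `N / (1 + 2 sum rho_k)` with the sum
#' truncated at the first non-positive autocorrelation.
#'
#' @param x numeric sample vector.
#' @return effective sample size (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  cut <- which(ac <= 0)[1]
  if (!is.na(cut)) ac <- ac[seq_len(cut - 1)]
  min(n, n / (1 + 2 * sum(ac)))
}

#' Posterior summary of node ages
#'
#' @param samples data.frame of pooled post-burn-in samples with columns
#'   `age_<node>`.
#' @param node_ids internal node numbers to summarize.
#' @param level HPD level.
#' @return data.frame: `node`, `mean`, `hpd_lo`, `hpd_hi`,
#'   `rel_width_pct` (= 100 * (hi - lo) / mean), `ess`.
#' @export
summarize_posterior <- function(samples, node_ids, level = 0.95) {
  out <- lapply(node_ids, function(v) {
    x <- samples[[paste0("age_", v)]]
    h <- hpd_interval(x, level, min_n = min(100, length(x)))
    data.frame(node = v, mean = mean(x), hpd_lo = h[1], hpd_hi = h[2],
               rel_width_pct = 100 * (h[2] - h[1]) / mean(x),
               ess = ess(x))
  })
  do.call(rbind, out)
}

#' @export
print.dating_mcmc <- function(x, ...) {
  cat(sprintf("dating_mcmc: %s clock, %d pooled samples, beta = %g\n",
              x$clock, nrow(x$samples), x$beta))
  print(x$summary, digits = 4)
  invisible(x)
}
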