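#' Tree prior on node ages
#'
#' Prior on non-root internal node ages conditional on the root age:
#' either i.i.d. uniform on (0, t_root) subject to the topology's
#' parent-older-than-child constraints (`"uniform"`, the default order
#' statistics prior), or the standard conditional birth-death node-age
#' kernel with birth rate `lambda`, death rate `mu`, and sampling fraction
#' `rho`.
#'
#' @param kind `"uniform"` or `"birth_death"`.
#' @param lambda,mu,rho birth-death parameters (birth_death only);
#'   `lambda > 0`, `0 <= mu < lambda`, `0 < rho <= 1`.
#' @return object of class `tree_prior`.
#' @export
make_tree_prior <- function(kind = c("uniform", "birth_death"),
                            lambda = 1, mu = 0, rho = 1) {
  kind <- match.arg(kind)
  if (kind == "birth_death")
    stopifnot(lambda > 0, mu >= 0, mu < lambda, rho > 0, rho <= 1)
  structure(list(kind = kind, lambda = lambda, mu = mu, rho = rho),
            class = "tree_prior")
}

# Probability that a lineage of age t leaves >= 1 sampled descendant.
bd_p0 <- function(t, lambda, mu, rho) {
  a <- lambda - mu
  rho * a / (rho * lambda + (lambda * (1 - rho) - mu) * exp(-a * t))
}

#' Conditional birth-death node-age density
#'
#' Density of a single (non-root) internal node age given the root age
#' under a birth-death process with incomplete sampling; normalized in
#' closed form so it integrates to 1 on (0, t_root).
#'
#' @param t node age(s).
#' @param t_root root age.
#' @param lambda,mu,rho process parameters.
#' @param log return log density.
#' @return density values (0 outside (0, t_root)).
#' @export
bd_age_density <- function(t, t_root, lambda, mu, rho = 1, log = FALSE) {
  if (abs(lambda - mu) < 1e-9) mu <- lambda - 1e-9  # numerical limit
  a <- lambda - mu
  p1 <- function(s) bd_p0(s, lambda, mu, rho)^2 * exp(-a * s) / rho
  v1 <- 1 - bd_p0(t_root, lambda, mu, rho) * exp(-a * t_root) / rho
  d <- ifelse(t > 0 & t < t_root, lambda * p1(t) / v1, 0)
  if (log) base::log(d) else d
}

#' Log prior density of node ages
#'
#' Sum of the tree-prior density on non-root internal ages conditional on
#' the root age and the log calibration densities (hard-bounded uniforms)
#' at every calibrated node. Returns `-Inf` if any order constraint or
#' calibration bound is violated.
#'
#' @param tt a [time_tree()] (ages in units of 100 Myr).
#' @param tree_prior a [make_tree_prior()].
#' @param calibrations a [build_strategy()] result whose node names are
#'   node numbers of `tt$phy`; bounds in Ma.
#' @param time_unit Ma per internal time unit (default 100).
#' @return log density (unnormalized for the uniform kind).
#' @export
log_prior_times <- function(tt, tree_prior, calibrations, time_unit = 100) {
  phy <- tt$phy
  ages <- tt$ages
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(dur <= 0) || ages[root] <= 0) return(-Inf)
  lp <- 0
  for (nm in names(calibrations$calibrations)) {
    cal <- calibrations$calibrations[[nm]]
    age <- ages[as.integer(nm)]
    lo <- cal$t_L / time_unit; hi <- cal$t_U / time_unit
    if (age < lo || age > hi) return(-Inf)
    lp <- lp - log(hi - lo)
  }
  nonroot <- setdiff((ntip + 1L):(ntip + phy$Nnode), root)
  if (length(nonroot)) {
    if (tree_prior$kind == "uniform") {
      lp <- lp - length(nonroot) * log(ages[root])
    } else {
      g <- bd_age_density(ages[nonroot], ages[root], tree_prior$lambda,
                          tree_prior$mu, tree_prior$rho, log = TRUE)
      if (any(!is.finite(g))) return(-Inf)
      lp <- lp + sum(g)
    }
  }
  lp
}

#' Log prior density of branch rates under the independent-gamma-rates clock
#'
#' Each branch rate is an independent Gamma draw with mean `m` and
#' variance `v` (shape `m^2/v`, rate `m/v`).
#'
#' @param rates positive branch rates.
#' @param m mean rate (changes per character per 100 Myr).
#' @param v rate variance.
#' @return log density; `-Inf` for any non-positive rate.
#' @export
igr_log_prior <- function(rates, m, v) {
  if (any(rates <= 0) || m <= 0 || v <= 0) return(-Inf)
  sum(stats::dgamma(rates, shape = m^2 / v, rate = m / v, log = TRUE))
}
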