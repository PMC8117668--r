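#' Linear regression through the origin
#'
#' Fits `y = slope * x` with `slope = sum(xy) / sum(x^2)` and reports the
#' uncentered coefficient of determination
#' `R^2 = 1 - sum((y - slope x)^2) / sum(y^2)` together with the ordinary
#' Pearson correlation `r` and its two-sided p-value (t transform). For
#' through-origin fits `R^2` and `r` can disagree (and `R^2` can be
#' negative); both are reported.
#'
#' @param x,y numeric vectors of equal length (>= 3); `x` not all zero.
#' @return list: `slope`, `r`, `r_squared`, `p_value`, `n`.
#' @export
regression_through_origin <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (all(x == 0)) stop("all x values are zero")
  slope <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- 0; p <- 1
  } else {
    r <- stats::cor(x, y)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(slope = slope, r = r, r_squared = r2, p_value = p, n = n)
}

#' Coverage of point estimates by credibility intervals
#'
#' Percentage of point estimates falling inside matched HPD intervals,
#' bounds inclusive.
#'
#' @param estimates named numeric vector of point estimates.
#' @param intervals data.frame with columns `node`, `hpd_lo`, `hpd_hi`
#'   (names/ids matched against `names(estimates)`).
#' @return percent in `[0, 100]`.
#' @export
coverage_fraction <- function(estimates, intervals) {
  idx <- match(names(estimates), as.character(intervals$node))
  if (anyNA(idx)) stop("node id mismatch between estimates and intervals")
  inside <- estimates >= intervals$hpd_lo[idx] & estimates <= intervals$hpd_hi[idx]
  100 * mean(inside)
}

#' Mean relative HPD width
#'
#' Mean over nodes of `100 * (hpd_hi - hpd_lo) / mean`, the relative
#' credibility-interval width used to compare dating precision across
#' calibration strategies and data types.
#'
#' @param summary a posterior summary (data.frame with `mean`, `hpd_lo`,
#'   `hpd_hi`), e.g. from [run_mcmc()].
#' @return percent (>= 0).
#' @export
mean_relative_hpd_width <- function(summary) {
  if (any(summary$mean <= 0)) stop("non-positive mean age")
  mean(100 * (summary$hpd_hi - summary$hpd_lo) / summary$mean)
}

#' Branch-length vs node-to-tip distance concordance contrast
#'
#' For two branch-length trees on one topology, computes the Pearson
#' correlation between the paired branch lengths and between the paired
#' node-to-tip distances of internal nodes, plus the node-to-tip
#' correlation within each node depth class. Averaging path lengths over
#' many descendant tips suppresses independent per-branch rate noise, so
#' the node-to-tip correlation typically exceeds the branch-length one —
#' least so for terminal nodes, which average only two branches.
#'
#' @param tree_a,tree_b `phylo` objects with branch lengths on the same
#'   rooted topology.
#' @param deep_fraction passed to [classify_node_depth()].
#' @return list: `r_branch`, `r_nodepath`, `r_by_class` (named vector,
#'   `NA` where a class has < 3 nodes), `classes`.
#' @export
branch_vs_nodepath_contrast <- function(tree_a, tree_b, deep_fraction = 0.5) {
  ev <- edge_vectors(tree_a, tree_b, unrooted = TRUE)
  r_branch <- stats::cor(ev$a, ev$b)
  da <- node_to_tip_distances(tree_a)
  db <- node_to_tip_distances(tree_b)
  # match internal nodes of a onto b through descendant tip sets
  keys_for <- function(phy) {
    ntip <- length(phy$tip.label)
    below <- vector("list", ntip + phy$Nnode)
    for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
    phy <- ape::reorder.phylo(phy, "postorder")
    for (e in seq_len(nrow(phy$edge)))
      below[[phy$edge[e, 1]]] <- c(below[[phy$edge[e, 1]]], below[[phy$edge[e, 2]]])
    vapply((ntip + 1L):(ntip + phy$Nnode),
           function(v) paste(sort(below[[v]]), collapse = "|"), character(1))
  }
  ntip_a <- length(tree_a$tip.label)
  ka <- keys_for(tree_a); kb <- keys_for(tree_b)
  ia <- (ntip_a + 1L):(ntip_a + tree_a$Nnode)
  ib <- (length(tree_b$tip.label) + 1L):(length(tree_b$tip.label) + tree_b$Nnode)
  m <- match(ka, kb)
  if (anyNA(m)) stop("tree topologies differ")
  xa <- da[ia]; xb <- db[ib[m]]
  r_nodepath <- stats::cor(xa, xb)
  cls <- classify_node_depth(tree_a, deep_fraction)
  r_by_class <- vapply(c("terminal", "intermediate", "deep"), function(cl) {
    sel <- cls$node[cls$class == cl]
    idx <- match(sel, ia)
    if (length(idx) < 3) return(NA_real_)
    stats::cor(xa[idx], xb[idx])
  }, numeric(1))
  list(r_branch = r_branch, r_nodepath = r_nodepath,
       r_by_class = r_by_class, classes = cls)
}

#' Concordance report for two sets of node-age estimates
#'
#' Cross-data comparison of posterior node ages: through-origin
#' regression, correlation, mutual HPD coverage and mean relative HPD
#' widths. The root can be excluded (its age is prior-driven when it
#' carries the only calibration).
#'
#' @param summary_x,summary_y posterior summaries ([run_mcmc()]) on the
#'   same topology (x = molecular by convention).
#' @param exclude_root drop the root node from the scatter.
#' @param root_node root node id (required if `exclude_root`).
#' @return list of class `concordance_report`.
#' @export
concordance_report <- function(summary_x, summary_y, exclude_root = TRUE,
                               root_node = NULL) {
  sx <- summary_x; sy <- summary_y
  if (exclude_root) {
    if (is.null(root_node)) root_node <- min(sx$node)
    sx <- sx[sx$node != root_node, , drop = FALSE]
    sy <- sy[sy$node != root_node, , drop = FALSE]
  }
  idx <- match(sx$node, sy$node)
  if (anyNA(idx)) stop("node sets differ")
  sy <- sy[idx, , drop = FALSE]
  reg <- regression_through_origin(sx$mean, sy$mean)
  cov_y_in_x <- coverage_fraction(stats::setNames(sy$mean, sy$node), sx)
  cov_x_in_y <- coverage_fraction(stats::setNames(sx$mean, sx$node), sy)
  structure(list(regression = reg,
                 coverage_y_in_x_pct = cov_y_in_x,
                 coverage_x_in_y_pct = cov_x_in_y,
                 mean_rel_width_x = mean_relative_hpd_width(sx),
                 mean_rel_width_y = mean_relative_hpd_width(sy),
                 scatter = data.frame(node = sx$node, x = sx$mean, y = sy$mean,
                                      x_lo = sx$hpd_lo, x_hi = sx$hpd_hi,
                                      y_lo = sy$hpd_lo, y_hi = sy$hpd_hi)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  r <- x$regression
  cat(sprintf("concordance: slope = %.3f, r = %.3f, R2 = %.3f (n = %d)\n",
              r$slope, r$r, r$r_squared, r$n))
  cat(sprintf("  coverage y-in-x %.1f%%, x-in-y %.1f%%; mean %%HPD width x %.1f, y %.1f\n",
              x$coverage_y_in_x_pct, x$coverage_x_in_y_pct,
              x$mean_rel_width_x, x$mean_rel_width_y))
  invisible(x)
}
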