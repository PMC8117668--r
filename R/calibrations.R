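#' Diffuse uniform calibration from a fossil minimum and a prior mean (C1)
#'
#' Builds a uniform node-age density U(t_L, t_U) whose mean equals the
#' original calibration mean: `t_U = 2 t_M - t_L`. The minimum is rounded
#' to the nearest Ma first (half up), then the maximum is computed and
#' rounded. This strategy expresses agnosticism about the true age between
#' the bounds.
#'
#' @param t_L fossil minimum age (Ma, > 0).
#' @param t_M prior mean age (Ma, > t_L).
#' @return list of class `calibration` with fields `t_L`, `t_U`, `t_M`,
#'   `density = "uniform"`.
#' @export
build_c1 <- function(t_L, t_M) {
  stopifnot(t_L > 0)
  if (t_M <= t_L) stop("mean must exceed the minimum bound")
  lo <- round_half_up(t_L)
  hi <- round_half_up(2 * t_M - lo)
  structure(list(t_L = lo, t_U = hi, t_M = t_M, density = "uniform"),
            class = "calibration")
}

#' Narrow uniform calibration from a fossil minimum (C2)
#'
#' Builds U(t_L, t_L + t_L/10): the upper bound exceeds the minimum by one
#' tenth of the minimum, expressing the prior belief that the fossil
#' minimum closely approximates the clade age. The minimum is rounded to
#' the nearest Ma (half up) before the width is computed.
#'
#' @param t_L fossil minimum age (Ma, > 0).
#' @return list of class `calibration`.
#' @export
build_c2 <- function(t_L) {
  if (t_L <= 0) stop("minimum bound must be positive")
  lo <- round_half_up(t_L)
  hi <- round_half_up(lo + lo / 10)
  structure(list(t_L = lo, t_U = hi, t_M = NA_real_, density = "uniform"),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("U(%g, %g) Ma\n", x$t_L, x$t_U))
  invisible(x)
}

#' Build a calibration set under a strategy
#'
#' Applies one of three calibration strategies to a fossil table:
#' * `Cr` — a single root calibration, with the C1 bounds for the root
#'   (no internal calibrations; the baseline for a poor fossil record);
#' * `C1` — diffuse uniforms [build_c1()] on every row;
#' * `C2` — narrow uniforms [build_c2()] on every row.
#'
#' The table needs columns `node` (node label/id, resolved downstream),
#' `t_L` (Ma) and, for C1/Cr, `t_M` (Ma; if absent it can be supplied as
#' the midpoint of known bounds). A row flagged `root = TRUE` (or with
#' `node` equal to `root_node`) must be present. Nesting consistency is
#' validated when a topology is supplied: a descendant's minimum may not
#' exceed an ancestor's maximum.
#'
#' @param table data.frame with columns `node`, `t_L`, optional `t_M`,
#'   optional logical `root`.
#' @param strategy `"Cr"`, `"C1"`, or `"C2"`.
#' @param root_node value of `node` identifying the root row (used when no
#'   `root` column is present; default: the row with the largest `t_L`).
#' @param phy optional rooted `phylo` with node identifiers matching
#'   `node`, used to validate calibration nesting.
#' @return list of class `calibration_set`: `strategy`, `calibrations`
#'   (named by node), `root_node`.
#' @export
build_strategy <- function(table, strategy = c("Cr", "C1", "C2"),
                           root_node = NULL, phy = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(table), all(c("node", "t_L") %in% names(table)))
  if (is.null(table$root)) {
    if (is.null(root_node)) root_node <- table$node[which.max(table$t_L)]
    table$root <- table$node == root_node
  }
  if (sum(table$root) != 1) stop("exactly one root row is required")
  root_node <- table$node[table$root]
  if (is.null(table$t_M)) table$t_M <- NA_real_
  rows <- if (strategy == "Cr") table[table$root, , drop = FALSE] else table
  cals <- lapply(seq_len(nrow(rows)), function(i) {
    if (strategy == "C2") build_c2(rows$t_L[i])
    else {
      tm <- rows$t_M[i]
      if (is.na(tm)) stop("t_M required for strategy ", strategy,
                          " (node ", rows$node[i], ")")
      build_c1(rows$t_L[i], tm)
    }
  })
  names(cals) <- as.character(rows$node)
  cs <- structure(list(strategy = strategy, calibrations = cals,
                       root_node = as.character(root_node)),
                  class = "calibration_set")
  if (!is.null(phy)) validate_calibration_nesting(cs, phy)
  cs
}

# Nesting check: for every calibrated node pair on one root-to-tip path,
# the descendant's lower bound must not exceed the ancestor's upper bound
# (otherwise the joint prior is empty).
validate_calibration_nesting <- function(cs, phy) {
  nodes <- suppressWarnings(as.integer(names(cs$calibrations)))
  if (anyNA(nodes)) return(invisible(cs))  # labels not numeric node ids
  missing <- nodes[nodes > length(phy$tip.label) + phy$Nnode | nodes < 1]
  if (length(missing)) stop("calibrated node not in topology: ",
                            paste(missing, collapse = ", "))
  anc <- lapply(nodes, function(v) {
    path <- integer(0)
    repeat {
      p <- phy$edge[phy$edge[, 2] == v, 1]
      if (!length(p)) break
      path <- c(path, p); v <- p
    }
    path
  })
  for (i in seq_along(nodes)) {
    up <- intersect(anc[[i]], nodes)
    for (a in up) {
      ca <- cs$calibrations[[as.character(a)]]
      cd <- cs$calibrations[[as.character(nodes[i])]]
      if (cd$t_L > ca$t_U)
        stop(sprintf("calibration nesting violated: node %d minimum %g exceeds ancestor %d maximum %g",
                     nodes[i], cd$t_L, a, ca$t_U))
    }
  }
  invisible(cs)
}

#' Read a calibration table
#'
#' Tab-separated input with columns `node`, `clade` (optional), `t_L`,
#' `t_M` (optional), `root` (optional logical).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_calibration_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("calibration_set [%s]: %d calibration(s), root node %s\n",
              x$strategy, length(x$calibrations), x$root_node))
  for (nm in names(x$calibrations)) {
    cal <- x$calibrations[[nm]]
    cat(sprintf("  node %-6s U(%g, %g)\n", nm, cal$t_L, cal$t_U))
  }
  invisible(x)
}

#' Export a calibration set as JSON
#' @param cs a `calibration_set`.
#' @param path output path.
#' @export
write_calibration_set <- function(cs, path) {
  obj <- list(strategy = cs$strategy, root_node = cs$root_node,
              calibrations = lapply(cs$calibrations, function(cal)
                list(t_L = cal$t_L, t_U = cal$t_U, density = cal$density)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}
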