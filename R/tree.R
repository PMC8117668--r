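#' Parse a Newick tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Trees used for
#' dating must be rooted and binary; polytomies are allowed read-only.
#'
#' @param text Newick string.
#' @param require_binary reject polytomies (needed for dating).
#' @return an [ape::phylo] object in postorder edge order.
#' @export
parse_tree <- function(text, require_binary = FALSE) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("invalid Newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("invalid Newick string")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (any(!nzchar(phy$tip.label))) stop("empty tip label")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch length")
  if (require_binary && !(ape::is.rooted(phy) && ape::is.binary(phy)))
    stop("tree contains polytomies or is unrooted; a rooted binary tree is required")
  ape::reorder.phylo(phy, "postorder")
}

#' Write a tree to a Newick string
#' @param phy an `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return Newick string.
#' @export
write_tree <- function(phy, digits = 12) {
  ape::write.tree(phy, digits = digits)
}

#' Time tree: a rooted binary topology with node ages
#'
#' Ages are measured back from the tips (all contemporaneous at age 0), in
#' units of 100 Myr internally; conversion from Ma is explicit at I/O
#' boundaries. Every parent must be strictly older than each child.
#'
#' @param phy rooted binary `phylo` topology.
#' @param ages numeric vector of node ages indexed by node number
#'   (1..Ntip + Nnode); tips must be 0.
#' @return an object of class `time_tree`.
#' @export
time_tree <- function(phy, ages) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  stopifnot(ape::is.rooted(phy), ape::is.binary(phy),
            length(ages) == ntip + phy$Nnode)
  if (any(abs(ages[seq_len(ntip)]) > 1e-12)) stop("tip ages must be 0")
  root <- ntip + 1L
  if (ages[root] <= 0) stop("root age must be positive")
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(dur <= 0)) stop("every parent must be strictly older than its children")
  structure(list(phy = phy, ages = ages), class = "time_tree")
}

#' Convert a chronogram (ultrametric phylo) to a time tree
#' @param phy ultrametric `phylo` with edge lengths in time units.
#' @return a `time_tree`.
#' @export
as_time_tree <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth) - depth
  ages[seq_len(length(phy$tip.label))] <- 0
  time_tree(phy, ages)
}

#' Branch durations of a time tree
#' @param tt a `time_tree`.
#' @return numeric vector aligned with `tt$phy$edge` rows.
#' @export
branch_durations <- function(tt) {
  tt$ages[tt$phy$edge[, 1]] - tt$ages[tt$phy$edge[, 2]]
}

#' Time tree to phylo with durations as branch lengths
#' @param tt a `time_tree`.
#' @return `phylo` whose edge lengths are branch durations.
#' @export
time_tree_phylo <- function(tt) {
  phy <- tt$phy
  phy$edge.length <- branch_durations(tt)
  phy
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("time_tree: %d tips, root age %.4g (x100 Myr)\n",
              length(x$phy$tip.label), x$ages[length(x$phy$tip.label) + 1L]))
  invisible(x)
}

# Postorder accumulation of (path-length sum to descendant tips, tip count)
# for every node.
node_path_stats <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  n_all <- length(phy$tip.label) + phy$Nnode
  S <- numeric(n_all)
  cnt <- integer(n_all)
  cnt[seq_len(length(phy$tip.label))] <- 1L
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    S[par] <- S[par] + S[ch] + cnt[ch] * phy$edge.length[e]
    cnt[par] <- cnt[par] + cnt[ch]
  }
  list(sum = S, tips = cnt)
}

#' Node-to-tip distances
#'
#' For each node, the sum of branch lengths over all paths from the node to
#' its descendant tips divided by the number of descendant tips. Tips map
#' to 0. This per-node average underlies the comparison of time structure
#' between data types: averaging over many paths smooths branch-specific
#' rate noise.
#'
#' @param phy `phylo` with branch lengths.
#' @return named numeric vector over all nodes (names = node numbers).
#' @export
node_to_tip_distances <- function(phy) {
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(phy$edge.length))) stop("non-finite branch length")
  st <- node_path_stats(phy)
  d <- st$sum / st$tips
  names(d) <- seq_along(d)
  d
}

#' Classify internal nodes by phylogenetic depth
#'
#' Internal nodes are partitioned into `terminal` (both children are tips:
#' the split of one lineage into two living taxa), `deep` (the root, plus
#' any node subtending at least `deep_fraction` of all tips), and
#' `intermediate` (the remainder). The root is always deep; the terminal
#' rule takes precedence over the tip-count rule for non-root nodes so the
#' classes partition the internal nodes.
#'
#' @param phy rooted `phylo`.
#' @param deep_fraction fraction of total tips in (0, 1] defining deep
#'   nodes (default 0.5).
#' @return data.frame with columns `node`, `class`, `n_tips`.
#' @export
classify_node_depth <- function(phy, deep_fraction = 0.5) {
  if (!(deep_fraction > 0 && deep_fraction <= 1))
    stop("deep_fraction must be in (0, 1]")
  stopifnot(ape::is.rooted(phy))
  ntip <- length(phy$tip.label)
  phy2 <- phy
  if (is.null(phy2$edge.length)) phy2$edge.length <- rep(1, nrow(phy2$edge))
  st <- node_path_stats(phy2)
  internal <- (ntip + 1L):(ntip + phy$Nnode)
  root <- ntip + 1L
  kids_are_tips <- vapply(internal, function(v) {
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    length(ch) >= 2 && all(ch <= ntip)
  }, logical(1))
  cls <- ifelse(internal == root, "deep",
         ifelse(kids_are_tips, "terminal",
         ifelse(st$tips[internal] >= deep_fraction * ntip, "deep",
                "intermediate")))
  data.frame(node = internal, class = cls, n_tips = st$tips[internal])
}

# Unroot when possible (ape cannot unroot a 2-tip tree).
unroot_safe <- function(phy) {
  if (length(phy$tip.label) > 2 && ape::is.rooted(phy)) ape::unroot(phy) else phy
}

# Split key for an edge. Canonical (bipartition) keys are invariant to
# root placement: the sorted tip labels of the side *not* containing the
# reference (alphabetically first) label. Non-canonical keys are the raw
# child-clade label sets, which distinguish the two root-adjacent edges
# of a rooted tree.
edge_split_keys <- function(phy, canonical = TRUE) {
  ntip <- length(phy$tip.label)
  ref <- sort(phy$tip.label)[1]
  n_all <- ntip + phy$Nnode
  below <- vector("list", n_all)
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  phy <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  vapply(seq_len(nrow(phy$edge)), function(e) {
    s <- below[[phy$edge[e, 2]]]
    if (canonical && ref %in% s) s <- setdiff(phy$tip.label, s)
    paste(sort(s), collapse = "|")
  }, character(1))
}

#' Map fitted unrooted branch lengths onto a rooted topology
#'
#' ML fits under reversible models live on the unrooted tree, where the
#' two root-adjacent branches are merged. This maps the fitted lengths
#' back onto the rooted topology for node-centric statistics
#' (node-to-tip distances, depth classes): every non-root edge takes its
#' fitted length, and the merged root edge is split equally between the
#' two root children (the split is not identifiable; only non-root
#' node-to-tip distances are unaffected by the convention).
#'
#' @param fitted unrooted `phylo` with fitted branch lengths.
#' @param rooted rooted `phylo` with the same (unrooted) topology.
#' @return the rooted topology with mapped branch lengths.
#' @export
map_to_rooted <- function(fitted, rooted) {
  kf <- edge_split_keys(fitted, canonical = TRUE)
  kr <- edge_split_keys(rooted, canonical = TRUE)
  m <- match(kr, kf)
  if (anyNA(m)) stop("tree topologies differ")
  out <- rooted
  out$edge.length <- fitted$edge.length[m]
  root <- length(rooted$tip.label) + 1L
  root_edges <- which(rooted$edge[, 1] == root)
  if (length(root_edges) == 2) {
    merged <- fitted$edge.length[m[root_edges[1]]]
    out$edge.length[root_edges] <- merged / 2
  }
  out
}

#' Paired branch-length vectors from two trees on one topology
#'
#' Aligns edges of two branch-length trees sharing a topology and returns
#' the paired length vectors. By default the comparison is on the unrooted
#' view (the two root-adjacent edges merged into one), matching the 2n-3
#' free branch-length parameters of an unrooted ML fit; `internal_only`
#' drops edges ending in tips.
#'
#' @param tree_a,tree_b `phylo` objects with identical topology and branch
#'   lengths.
#' @param internal_only drop terminal edges.
#' @param unrooted compare the unrooted view (default TRUE).
#' @return data.frame with columns `split`, `a`, `b`, `terminal`.
#' @export
edge_vectors <- function(tree_a, tree_b, internal_only = FALSE, unrooted = TRUE) {
  if (unrooted) {
    tree_a <- unroot_safe(tree_a)
    tree_b <- unroot_safe(tree_b)
  }
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees have different tip sets")
  ka <- edge_split_keys(tree_a, canonical = unrooted)
  kb <- edge_split_keys(tree_b, canonical = unrooted)
  if (!setequal(ka, kb)) stop("tree topologies differ")
  m <- match(ka, kb)
  ntip_a <- length(tree_a$tip.label)
  term <- tree_a$edge[, 2] <= ntip_a
  out <- data.frame(split = ka,
                    a = tree_a$edge.length,
                    b = tree_b$edge.length[m],
                    terminal = term,
                    stringsAsFactors = FALSE)
  if (internal_only) out <- out[!out$terminal, , drop = FALSE]
  rownames(out) <- NULL
  out
}
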