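# Independent oracles and small fixture builders used across tests.

# Exhaustive-enumeration log-likelihood for Mk: sums over every assignment
# of internal states and every gamma category, using the analytic Mk
# transition probability. Independent of the pruning engine.
enum_loglik_mk <- function(tipstates, phy, k, alpha, ncat, ascertain = FALSE) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nall <- ntip + phy$Nnode
  cr <- gamma_category_rates(alpha, ncat)
  pmat <- function(t) {
    p_same <- 1 / k + (k - 1) / k * exp(-k * t / (k - 1))
    p_diff <- 1 / k - 1 / k * exp(-k * t / (k - 1))
    m <- matrix(p_diff, k, k); diag(m) <- p_same; m
  }
  site_lik <- function(tips) {
    tot <- 0
    internal <- (ntip + 1):nall
    grid <- expand.grid(rep(list(1:k), length(internal)))
    for (c_i in seq_len(ncat)) {
      s <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nall)
        st[seq_len(ntip)] <- tips
        st[internal] <- as.integer(grid[g, ])
        pr <- 1 / k
        for (e in seq_len(nrow(phy$edge))) {
          P <- pmat(phy$edge.length[e] * cr[c_i])
          pr <- pr * P[st[phy$edge[e, 1]], st[phy$edge[e, 2]]]
        }
        s <- s + pr
      }
      tot <- tot + s / ncat
    }
    tot
  }
  liks <- apply(tipstates, 2, site_lik)
  if (ascertain) {
    pinv <- sum(sapply(1:k, function(s) site_lik(rep(s, ntip))))
    liks <- liks / (1 - pinv)
  }
  sum(log(liks))
}

# All-paths node-to-tip oracle: explicit path enumeration tip by tip.
enum_node_to_tip <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nall <- ntip + phy$Nnode
  parent <- integer(nall); elen <- numeric(nall)
  for (e in seq_len(nrow(phy$edge))) {
    parent[phy$edge[e, 2]] <- phy$edge[e, 1]
    elen[phy$edge[e, 2]] <- phy$edge.length[e]
  }
  out <- numeric(nall)
  for (v in seq_len(nall)) {
    tot <- 0; cnt <- 0
    for (tip in seq_len(ntip)) {
      path <- 0; u <- tip; found <- (u == v)
      while (!found && parent[u] != 0) {
        path <- path + elen[u]
        u <- parent[u]
        found <- (u == v)
      }
      if (found) { tot <- tot + path; cnt <- cnt + 1 }
    }
    out[v] <- tot / cnt
  }
  out
}

# Character matrix from an integer (1-based) state matrix with taxa names.
cm_from_states <- function(states, taxa) {
  x <- matrix(as.character(states - 1L), nrow(states), ncol(states))
  rownames(x) <- taxa
  char_matrix(x, "standard")
}

rand_binary_tree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.05, 0.8)
  ape::reorder.phylo(phy, "postorder")
}
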