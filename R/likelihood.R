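# Precompute everything that depends on the data but not on branch lengths
# or substitution parameters: site-pattern compression and per-tip partial
# likelihoods, grouped by Mk state count (nucleotide data forms one group).
partition_data <- function(cm, phy, model) {
  stopifnot(inherits(cm, "char_matrix"), inherits(model, "subst_model"))
  if (!setequal(rownames(cm$x), phy$tip.label))
    stop("matrix taxa do not match tree tips")
  x <- cm$x[phy$tip.label, , drop = FALSE]
  groups <- list()
  ntip <- length(phy$tip.label)
  if (model$kind == "GTR") {
    if (cm$type != "dna") stop("GTR model requires nucleotide data")
    cp <- compress_patterns(x)
    states <- c("a", "c", "g", "t")
    groups[[1]] <- list(k = 4L, weights = cp$weights,
                        tp = tip_partials_for(cp$pat, states, cm$missing, dna = TRUE),
                        const_tp = replicate(ntip, diag(4), simplify = FALSE))
  } else {
    kc <- state_counts(cm)
    kc <- pmax(kc, 2L)
    if (!is.null(model$k)) {
      if (any(kc > model$k))
        stop("character with more observed states than the forced Mk state count")
      kc[] <- model$k
    }
    # recode each column's observed states onto a canonical alphabet so
    # columns with the same state count share one pruning block (Mk is
    # exchangeable in its state labels)
    canon <- as.character(0:35)
    xr <- x
    for (j in seq_len(ncol(x))) {
      obs <- sort(unique(x[, j][!(x[, j] %in% cm$missing)]))
      if (length(obs))
        xr[, j] <- ifelse(x[, j] %in% cm$missing, x[, j],
                          canon[match(x[, j], obs)])
    }
    for (k in sort(unique(kc))) {
      cols <- which(kc == k)
      cp <- compress_patterns(xr[, cols, drop = FALSE])
      groups[[length(groups) + 1]] <-
        list(k = as.integer(k), weights = cp$weights,
             tp = tip_partials_for(cp$pat, canon[seq_len(k)], cm$missing),
             const_tp = replicate(ntip, diag(k), simplify = FALSE))
    }
  }
  list(groups = groups, ntip = length(phy$tip.label), nchar = ncol(cm$x))
}

# Probability that a character is invariant (all tips share one state),
# computed by pruning with one-hot constant patterns; used for the
# variable-only ascertainment correction.
invariant_prob <- function(const_tp, edge, lengths, dec, cat_rates) {
  lg <- prune_loglik_cpp(const_tp, edge, lengths, dec$A, dec$B,
                         dec$lambda, dec$pi, cat_rates)
  sum(exp(lg))
}

# Model-dependent context (gamma category rates, spectral decompositions)
# shared across likelihood evaluations at fixed model parameters.
model_context <- function(pd, model) {
  list(cat_rates = gamma_category_rates(model$alpha, model$ncat),
       decs = lapply(pd$groups, function(g) model_eigen(model, k = g$k)))
}

# Total log-likelihood for prepared data at given branch lengths.
partition_loglik <- function(pd, model, edge, lengths, ctx = NULL) {
  if (is.null(ctx)) ctx <- model_context(pd, model)
  total <- 0
  for (i in seq_along(pd$groups)) {
    g <- pd$groups[[i]]
    dec <- ctx$decs[[i]]
    sl <- prune_loglik_cpp(g$tp, edge, lengths, dec$A, dec$B,
                           dec$lambda, dec$pi, ctx$cat_rates)
    if (identical(model$ascertainment, "variable_only")) {
      p_inv <- invariant_prob(g$const_tp, edge, lengths, dec, ctx$cat_rates)
      if (p_inv >= 1 - 1e-12)
        stop("degenerate input: invariant probability is 1 (all branch lengths zero?)")
      sl <- sl - log1p(-p_inv)
    }
    total <- total + sum(g$weights * sl)
  }
  total
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a character matrix on a tree with branch
#' lengths under Mk+Gamma or GTR+Gamma. Site likelihoods use a
#' discrete-gamma mixture whose category rates are the means of
#' equal-probability bins; missing cells contribute partial likelihood 1
#' for every state. For the Mk model the per-character state space is the
#' observed state count (minimum 2) unless the model fixes a global `k`;
#' with `ascertainment = "variable_only"` each character's log-likelihood
#' is conditioned on the character being variable:
#' `log L - log(1 - P_invariant)`.
#'
#' @param cm a [char_matrix()].
#' @param tree `phylo` with branch lengths (expected changes per
#'   character).
#' @param model a [mk_model()] or [gtr_model()].
#' @return total log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(cm, tree, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  pd <- partition_data(cm, tree, model)
  l <- partition_loglik(pd, model, tree$edge, tree$edge.length)
  if (!is.finite(l)) stop("non-finite log-likelihood")
  l
}

# Closure evaluating the log-likelihood of `cm` on a fixed topology as a
# function of (lengths, model); data preprocessing is done once and the
# model-parameter context is cached between calls at identical parameters.
make_loglik <- function(cm, phy, model) {
  phy <- ape::reorder.phylo(phy, "postorder")
  pd <- partition_data(cm, phy, model)
  edge <- phy$edge
  cache_key <- NULL
  cache_ctx <- NULL
  function(lengths, model_now = model) {
    key <- list(model_now$alpha, model_now$ncat, model_now$rates,
                model_now$freq, model_now$k)
    if (!identical(key, cache_key)) {
      cache_ctx <<- model_context(pd, model_now)
      cache_key <<- key
    }
    partition_loglik(pd, model_now, edge, lengths, cache_ctx)
  }
}
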