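#' Discrete-gamma category rates (bin means)
#'
#' Rates for the equal-probability discretization of a Gamma(shape = alpha,
#' rate = alpha) distribution (mean 1). Each category rate is the *mean* of
#' its probability bin, computed from the incomplete-gamma identity
#' `x f_(a,b)(x) = (a/b) f_(a+1,b)(x)`, not the bin median.
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories (default 5).
#' @return numeric vector of `ncat` rates with mean 1.
#' @export
gamma_category_rates <- function(alpha, ncat = 5L) {
  stopifnot(alpha > 0, ncat >= 1)
  if (ncat == 1L) return(1)
  qb <- stats::qgamma((0:ncat) / ncat, shape = alpha, rate = alpha)
  r <- ncat * diff(stats::pgamma(qb, shape = alpha + 1, rate = alpha))
  r / mean(r) * 1  # guard tiny round-off; mean is 1 analytically
}

#' Mk substitution model for discrete morphological characters
#'
#' Markov k-states model: equal stationary frequencies, equal exchange
#' rates, scaled so the expected substitution rate at stationarity is 1.
#' State count may be fixed globally or resolved per character from the
#' observed states (the default; see [log_likelihood()]).
#'
#' @param k state count (`NULL` = per-character observed count, minimum 2).
#' @param alpha gamma shape for among-character rate heterogeneity.
#' @param ncat gamma category count.
#' @param ascertainment `"none"` or `"variable_only"` (condition on a
#'   character being variable, as morphological matrices only score
#'   variable characters).
#' @return an object of class `subst_model`.
#' @export
mk_model <- function(k = NULL, alpha = 1, ncat = 5L,
                     ascertainment = c("none", "variable_only")) {
  ascertainment <- match.arg(ascertainment)
  stopifnot(is.null(k) || k >= 2, alpha > 0)
  structure(list(kind = "Mk", k = k, alpha = alpha, ncat = as.integer(ncat),
                 ascertainment = ascertainment),
            class = "subst_model")
}

#' GTR substitution model for nucleotide data
#'
#' General time-reversible model with gamma rate heterogeneity. The rate
#' matrix is scaled to mean rate 1 at stationarity so branch lengths are in
#' expected substitutions per site.
#'
#' @param rates exchangeabilities in the order AC, AG, AT, CG, CT, GT
#'   (positive; the GT rate acts as reference).
#' @param freq stationary base frequencies (A, C, G, T), summing to 1.
#' @param alpha gamma shape; `ncat` category count.
#' @param ncat gamma category count.
#' @return an object of class `subst_model`.
#' @export
gtr_model <- function(rates = rep(1, 6), freq = rep(0.25, 4),
                      alpha = 1, ncat = 5L) {
  stopifnot(length(rates) == 6, all(rates > 0),
            length(freq) == 4, all(freq > 0),
            abs(sum(freq) - 1) < 1e-8, alpha > 0)
  structure(list(kind = "GTR", rates = rates, freq = freq / sum(freq),
                 alpha = alpha, ncat = as.integer(ncat),
                 ascertainment = "none"),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s+G%d model (alpha = %g", x$kind, x$ncat, x$alpha), sep = "")
  if (x$kind == "Mk") {
    cat(sprintf(", k = %s, ascertainment = %s)\n",
                if (is.null(x$k)) "per character" else x$k, x$ascertainment))
  } else {
    cat(")\n")
  }
  invisible(x)
}

# Normalized rate matrix for a model instance with a concrete state count.
rate_matrix <- function(model, k = NULL) {
  if (model$kind == "Mk") {
    stopifnot(!is.null(k) || !is.null(model$k))
    k <- if (is.null(k)) model$k else k
    Q <- matrix(1 / (k - 1), k, k)
    diag(Q) <- -1
    pi <- rep(1 / k, k)
  } else {
    r <- model$rates
    pi <- model$freq
    Q <- matrix(0, 4, 4)
    Q[1, 2] <- r[1]; Q[1, 3] <- r[2]; Q[1, 4] <- r[3]
    Q[2, 3] <- r[4]; Q[2, 4] <- r[5]; Q[3, 4] <- r[6]
    Q <- Q + t(Q)
    Q <- Q * rep(pi, each = 4)   # Q_ij = s_ij * pi_j
    diag(Q) <- -rowSums(Q)
    mu <- -sum(pi * diag(Q))
    Q <- Q / mu
  }
  list(Q = Q, pi = pi)
}

# Spectral decomposition of a reversible rate matrix via the symmetrized
# form B = D^(1/2) Q D^(-1/2): P(t) = A exp(L t) B with A = D^(-1/2) U,
# B = t(U) D^(1/2).
model_eigen <- function(model, k = NULL) {
  rm <- rate_matrix(model, k)
  sp <- sqrt(rm$pi)
  S <- rm$Q * outer(sp, 1 / sp)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / sp,           # diag(1/sp) %*% U
       B = t(e$vectors) * rep(sp, each = length(sp)),  # t(U) %*% diag(sp)
       lambda = e$values,
       pi = rm$pi,
       k = length(rm$pi))
}

# Transition probability matrix P(t) for a decomposed model.
transition_prob <- function(dec, t) {
  P <- dec$A %*% (exp(dec$lambda * t) * dec$B)
  P[P < 0] <- 0
  P
}
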