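# Update substitution-model parameters (gamma shape; GTR exchangeabilities
# and frequencies) by bounded quasi-Newton on transformed coordinates,
# holding branch lengths fixed.
update_model_params <- function(ll_fun, lengths, model) {
  if (model$kind == "Mk") {
    opt <- stats::optimize(function(la) {
      m <- model; m$alpha <- exp(la)
      -ll_fun(lengths, m)
    }, interval = log(c(0.02, 50)), tol = 1e-4)
    model$alpha <- exp(opt$minimum)
    return(model)
  }
  # GTR: 5 free exchangeabilities (GT fixed at 1), 3 free frequency
  # coordinates (additive log-ratio vs T), log alpha
  par0 <- c(log(model$rates[1:5] / model$rates[6]),
            log(model$freq[1:3] / model$freq[4]),
            log(model$alpha))
  obj <- function(p) {
    m <- model
    m$rates <- c(exp(p[1:5]), 1)
    f <- exp(c(p[6:8], 0)); m$freq <- f / sum(f)
    m$alpha <- exp(p[9])
    v <- try(-ll_fun(lengths, m), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  opt <- stats::nlminb(par0, obj, control = list(iter.max = 60, rel.tol = 1e-7))
  p <- opt$par
  model$rates <- c(exp(p[1:5]), 1)
  f <- exp(c(p[6:8], 0)); model$freq <- f / sum(f)
  model$alpha <- exp(p[9])
  model
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate-wise optimization: each branch length is optimized in turn by
#' bracketed univariate search (Brent), interleaved with substitution-model
#' parameter updates, until the log-likelihood improves by less than
#' `tolerance` over a full round. The fit is on the unrooted view of the
#' topology (2n-3 free branch lengths for reversible models).
#'
#' @param cm a [char_matrix()].
#' @param phy fixed topology (`phylo`; may be rooted, fitted unrooted).
#' @param model substitution model; its parameters are starting values.
#' @param tolerance convergence tolerance on the log-likelihood
#'   (default 1e-6).
#' @param max_rounds maximum optimization rounds (default 100).
#' @param b_max upper bound for any branch length (default 10).
#' @param optimize_model also optimize model parameters (default TRUE).
#' @param init initial branch lengths (scalar or vector).
#' @return list with `tree` (unrooted `phylo` with fitted lengths),
#'   `model`, `loglik`, `converged`, `rounds`.
#' @export
optimize_branch_lengths <- function(cm, phy, model, tolerance = 1e-6,
                                    max_rounds = 100, b_max = 10,
                                    optimize_model = TRUE, init = 0.1) {
  un <- ape::reorder.phylo(unroot_safe(phy), "postorder")
  ne <- nrow(un$edge)
  lengths <- rep_len(init, ne)
  ll_fun <- make_loglik(cm, un, model)
  l <- ll_fun(lengths, model)
  converged <- FALSE
  r <- 0
  while (r < max_rounds) {
    r <- r + 1
    for (e in seq_len(ne)) {
      opt <- stats::optimize(function(b) {
        lengths[e] <- b
        -ll_fun(lengths, model)
      }, interval = c(0, b_max), tol = max(1e-8, tolerance / 10))
      if (-opt$objective >= l - 1e-12) {
        lengths[e] <- opt$minimum
        l <- -opt$objective
      }
    }
    if (optimize_model) {
      model <- update_model_params(ll_fun, lengths, model)
      l <- ll_fun(lengths, model)
    }
    if (r > 1 && l - l_prev < tolerance) { converged <- TRUE; break }
    l_prev <- l
  }
  un$edge.length <- lengths
  list(tree = un, model = model, loglik = l, converged = converged, rounds = r)
}

#' Unlinked two-partition fit
#'
#' Independent branch-length optimizations for two partitions on the same
#' topology; the unrestricted model of the proportionality test.
#'
#' @param cm_a,cm_b the two character matrices (e.g. molecular and
#'   morphological).
#' @param phy shared fixed topology.
#' @param model_a,model_b substitution models per partition.
#' @param init_a,init_b initial branch lengths per partition (scalar or
#'   vector; a warm start from a linked fit guarantees the nesting
#'   inequality at loose tolerances).
#' @param ... passed to [optimize_branch_lengths()].
#' @return list of class `partitioned_fit` with per-partition fits and
#'   total `loglik`; `linked = FALSE`.
#' @export
fit_unlinked <- function(cm_a, cm_b, phy, model_a, model_b,
                         init_a = 0.1, init_b = 0.1, ...) {
  fa <- optimize_branch_lengths(cm_a, phy, model_a, init = init_a, ...)
  fb <- optimize_branch_lengths(cm_b, phy, model_b, init = init_b, ...)
  structure(list(linked = FALSE, fits = list(fa, fb),
                 loglik = fa$loglik + fb$loglik,
                 n_branches = nrow(fa$tree$edge)),
            class = "partitioned_fit")
}

#' Linked (proportional) two-partition fit
#'
#' Both partitions share one set of branch lengths up to a proportionality
#' coefficient: partition A (molecular by convention) uses lengths `b_e`
#' with its coefficient fixed at 1 for identifiability, partition B uses
#' `c * b_e` with `c > 0` estimated. Shared lengths, the coefficient, and
#' model parameters are optimized coordinate-wise.
#'
#' @inheritParams fit_unlinked
#' @param tolerance,max_rounds,b_max,optimize_model,init as in
#'   [optimize_branch_lengths()].
#' @return list of class `partitioned_fit` with the shared `tree`,
#'   coefficient `c_b`, models, total `loglik`; `linked = TRUE`.
#' @export
fit_linked <- function(cm_a, cm_b, phy, model_a, model_b, tolerance = 1e-6,
                       max_rounds = 100, b_max = 10, optimize_model = TRUE,
                       init = 0.1) {
  un <- ape::reorder.phylo(unroot_safe(phy), "postorder")
  ne <- nrow(un$edge)
  lengths <- rep_len(init, ne)
  c_b <- 1
  ll_a <- make_loglik(cm_a, un, model_a)
  ll_b <- make_loglik(cm_b, un, model_b)
  total <- function(len, cb, ma, mb) ll_a(len, ma) + ll_b(cb * len, mb)
  l <- total(lengths, c_b, model_a, model_b)
  converged <- FALSE
  r <- 0
  while (r < max_rounds) {
    r <- r + 1
    for (e in seq_len(ne)) {
      opt <- stats::optimize(function(b) {
        lengths[e] <- b
        -total(lengths, c_b, model_a, model_b)
      }, interval = c(0, b_max), tol = max(1e-8, tolerance / 10))
      if (-opt$objective >= l - 1e-12) {
        lengths[e] <- opt$minimum
        l <- -opt$objective
      }
    }
    optc <- stats::optimize(function(lc) -total(lengths, exp(lc), model_a, model_b),
                            interval = log(c(1e-4, 1e3)), tol = 1e-7)
    if (-optc$objective >= l - 1e-12) {
      c_b <- exp(optc$minimum)
      l <- -optc$objective
    }
    if (optimize_model) {
      model_a <- update_model_params(ll_a, lengths, model_a)
      model_b <- update_model_params(ll_b, c_b * lengths, model_b)
      l <- total(lengths, c_b, model_a, model_b)
    }
    if (r > 1 && l - l_prev < tolerance) { converged <- TRUE; break }
    l_prev <- l
  }
  un$edge.length <- lengths
  structure(list(linked = TRUE, tree = un, c_b = c_b,
                 models = list(model_a, model_b), loglik = l,
                 loglik_parts = c(ll_a(lengths, model_a),
                                  ll_b(c_b * lengths, model_b)),
                 n_branches = ne, converged = converged, rounds = r),
            class = "partitioned_fit")
}

#' Likelihood-ratio test of branch-length proportionality
#'
#' Compares the linked (shared branch lengths up to one proportionality
#' coefficient) and unlinked (independent branch lengths) fits of two
#' partitions on one topology: `2 * dl = 2 (l_unlinked - l_linked)`,
#' referred to a chi-squared distribution with `df = 2n - 3` (the extra
#' free branch lengths of the unlinked model, net of the shared set plus
#' one coefficient).
#'
#' @param fit_linked,fit_unlinked results of [fit_linked()] and
#'   [fit_unlinked()] on the same data and topology (or any objects with a
#'   `loglik` field).
#' @param df degrees of freedom; defaults to the unrooted branch count.
#' @return list of class `lrt_result`: `l_linked`, `l_unlinked`,
#'   `statistic`, `df`, `p_value`.
#' @export
proportionality_lrt <- function(fit_linked, fit_unlinked, df = NULL) {
  l0 <- fit_linked$loglik
  l1 <- fit_unlinked$loglik
  if (is.null(df)) df <- fit_linked$n_branches  # unrooted branch count 2n-3
  lrt_from_loglik(l0, l1, df)
}

#' Branch-length proportionality test (linked fit, warm-started unlinked
#' fit, LRT)
#'
#' Convenience wrapper running [fit_linked()] first and then
#' [fit_unlinked()] initialized at the linked optimum (partition B scaled
#' by the fitted coefficient), which enforces the nesting inequality
#' `l_unlinked >= l_linked` even at loose optimization tolerances.
#'
#' @inheritParams fit_linked
#' @return list: `fit_linked`, `fit_unlinked`, `lrt` (an `lrt_result`).
#' @export
proportionality_test <- function(cm_a, cm_b, phy, model_a, model_b,
                                 tolerance = 1e-4, ...) {
  fl <- fit_linked(cm_a, cm_b, phy, model_a, model_b,
                   tolerance = tolerance, ...)
  fu <- fit_unlinked(cm_a, cm_b, phy, fl$models[[1]], fl$models[[2]],
                     init_a = fl$tree$edge.length,
                     init_b = fl$c_b * fl$tree$edge.length,
                     tolerance = tolerance, ...)
  list(fit_linked = fl, fit_unlinked = fu, lrt = proportionality_lrt(fl, fu))
}

#' Likelihood-ratio statistic from two log-likelihoods
#'
#' @param l_linked,l_unlinked log-likelihoods of the nested (linked) and
#'   unrestricted (unlinked) models.
#' @param df degrees of freedom of the chi-squared reference.
#' @return list of class `lrt_result`.
#' @export
lrt_from_loglik <- function(l_linked, l_unlinked, df) {
  stat <- 2 * (l_unlinked - l_linked)
  if (stat < -1e-2)
    stop("unlinked log-likelihood below linked: optimization failure")
  stat <- max(stat, 0)
  structure(list(l_linked = l_linked, l_unlinked = l_unlinked,
                 statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Proportionality LRT: 2*dl = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
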