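#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Felsenstein pruning over compressed site patterns with a discrete-gamma
// rate mixture. Tips 1..ntip carry partial-likelihood matrices (k x npat);
// internal partials are accumulated in post-order with per-pattern
// rescaling. Transition probabilities use the spectral form
// P(t) = A diag(exp(lambda t)) B, precomputed in R from the (reversible)
// rate matrix. Returns the per-pattern log likelihood, already averaged
// over the equal-weight rate categories.
// [[Rcpp::export]]
NumericVector prune_loglik_cpp(List tip_partials,
                               IntegerMatrix edge,
                               NumericVector len,
                               NumericMatrix A,
                               NumericMatrix B,
                               NumericVector lam,
                               NumericVector pi,
                               NumericVector cat_rates) {
  const int k = A.nrow();
  const int ntip = tip_partials.size();
  const int nedge = edge.nrow();
  int nnode = 0;
  for (int e = 0; e < nedge; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  NumericMatrix tp0 = tip_partials[0];
  const int npat = tp0.ncol();
  const int ncat = cat_rates.size();
  const int root = edge(nedge - 1, 0);

  std::vector<double> patmax(npat, R_NegInf);
  NumericMatrix catlog(ncat, npat);
  std::vector<double> P(k * k);

  for (int c = 0; c < ncat; ++c) {
    std::vector< std::vector<double> > part(nnode + 1);
    std::vector< std::vector<double> > lsc(nnode + 1);
    for (int v = 1; v <= nnode; ++v) {
      part[v].assign((size_t)k * npat, 1.0);
      lsc[v].assign(npat, 0.0);
    }
    for (int t = 0; t < ntip; ++t) {
      NumericMatrix tp = tip_partials[t];
      std::vector<double>& pt = part[t + 1];
      for (int p = 0; p < npat; ++p)
        for (int s = 0; s < k; ++s)
          pt[(size_t)p * k + s] = tp(s, p);
    }
    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0), ch = edge(e, 1);
      const double bl = len[e] * cat_rates[c];
      for (int i = 0; i < k; ++i)
        for (int j = 0; j < k; ++j) {
          double s = 0.0;
          for (int m = 0; m < k; ++m)
            s += A(i, m) * std::exp(lam[m] * bl) * B(m, j);
          P[i * k + j] = (s > 0.0) ? s : 0.0;  // clamp round-off negatives
        }
      std::vector<double>& cp = part[ch];
      std::vector<double>& pp = part[par];
      std::vector<double>& cs = lsc[ch];
      std::vector<double>& ps = lsc[par];
      for (int p = 0; p < npat; ++p) {
        double mx = 0.0;
        for (int i = 0; i < k; ++i) {
          double s = 0.0;
          for (int j = 0; j < k; ++j)
            s += P[i * k + j] * cp[(size_t)p * k + j];
          const double val = pp[(size_t)p * k + i] * s;
          pp[(size_t)p * k + i] = val;
          if (val > mx) mx = val;
        }
        ps[p] += cs[p];
        if (mx > 0.0 && mx < 1e-200) {
          for (int i = 0; i < k; ++i) pp[(size_t)p * k + i] /= mx;
          ps[p] += std::log(mx);
        }
      }
    }
    for (int p = 0; p < npat; ++p) {
      double s = 0.0;
      for (int i = 0; i < k; ++i) s += pi[i] * part[root][(size_t)p * k + i];
      const double lg = (s > 0.0) ? std::log(s) + lsc[root][p] : R_NegInf;
      catlog(c, p) = lg;
      if (lg > patmax[p]) patmax[p] = lg;
    }
  }

  NumericVector out(npat);
  for (int p = 0; p < npat; ++p) {
    if (!R_finite(patmax[p])) { out[p] = R_NegInf; continue; }
    double s = 0.0;
    for (int c = 0; c < ncat; ++c) s += std::exp(catlog(c, p) - patmax[p]);
    out[p] = patmax[p] + std::log(s / ncat);
  }
  return out;
}
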