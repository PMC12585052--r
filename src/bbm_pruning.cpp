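#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-state F81 pruning kernels shared by the likelihood and the marginal
// ancestral-state pass.  State 0 = absent, 1 = present.  The rate matrix is
// normalized so one expected change per Myr at stationarity per unit rate
// multiplier: beta = 1 / (2 * pi0 * pi1), and
//   P_ij(t) = pi_j + (delta_ij - pi_j) * exp(-beta * r * t).

namespace {

inline void pmat(double pi1, double e, double P[4]) {
  const double pi0 = 1.0 - pi1;
  P[0] = pi0 + pi1 * e; // 0 -> 0
  P[1] = pi1 * (1.0 - e); // 0 -> 1
  P[2] = pi0 * (1.0 - e); // 1 -> 0
  P[3] = pi1 + pi0 * e; // 1 -> 1
}

} // namespace

// Total log-likelihood over all area characters, each averaged over the
// discrete-gamma rate categories with equal weights.
// edge: postorder two-column matrix (parent, child), 1-based ape numbering;
// elen: matching branch lengths; tips: ntip x narea 0/1 matrix;
// rates: k gamma-category multipliers.
// [[Rcpp::export]]
double bbm_loglik_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                      IntegerMatrix tips, double pi1, NumericVector rates) {
  const int nedge = edge.nrow();
  const int nnode = nedge + 1; // rooted binary tree
  const int narea = tips.ncol();
  const int k = rates.size();
  const double pi0 = 1.0 - pi1;
  const double beta = 1.0 / (2.0 * pi0 * pi1);
  const int root = edge(nedge - 1, 0) - 1;

  // transition matrices per (edge, category), shared across areas
  std::vector<double> P(static_cast<size_t>(nedge) * k * 4);
  for (int r = 0; r < nedge; ++r)
    for (int c = 0; c < k; ++c)
      pmat(pi1, std::exp(-beta * rates[c] * elen[r]), &P[(static_cast<size_t>(r) * k + c) * 4]);

  std::vector<double> L0(nnode), L1(nnode);
  const double logk = std::log(static_cast<double>(k));
  double total = 0.0;

  for (int a = 0; a < narea; ++a) {
    double maxll = R_NegInf;
    std::vector<double> ll(k);
    for (int c = 0; c < k; ++c) {
      for (int v = 0; v < nnode; ++v) { L0[v] = 1.0; L1[v] = 1.0; }
      for (int t = 0; t < ntip; ++t) {
        if (tips(t, a) == 1) L0[t] = 0.0; else L1[t] = 0.0;
      }
      // multiplicative scaling, folded into a log only near underflow
      double logscale = 0.0, scale = 1.0;
      bool dead = false;
      for (int r = 0; r < nedge; ++r) {
        const int p = edge(r, 0) - 1, ch = edge(r, 1) - 1;
        const double *Pm = &P[(static_cast<size_t>(r) * k + c) * 4];
        const double m0 = Pm[0] * L0[ch] + Pm[1] * L1[ch];
        const double m1 = Pm[2] * L0[ch] + Pm[3] * L1[ch];
        const double s = m0 + m1;
        if (s <= 0.0) { dead = true; break; }
        scale *= s;
        if (scale < 1e-280) { logscale += std::log(scale); scale = 1.0; }
        const double inv = 1.0 / s;
        L0[p] *= m0 * inv;
        L1[p] *= m1 * inv;
      }
      const double lik = pi0 * L0[root] + pi1 * L1[root];
      ll[c] = (!dead && lik > 0.0)
        ? std::log(lik) + logscale + std::log(scale) : R_NegInf;
      if (ll[c] > maxll) maxll = ll[c];
    }
    if (!R_finite(maxll)) return R_NegInf;
    double s = 0.0;
    for (int c = 0; c < k; ++c) s += std::exp(ll[c] - maxll);
    total += maxll + std::log(s) - logk;
  }
  return total;
}

// Marginal posterior P(present) for every node and area via an up-down
// (outside-inside) pass, mixing gamma categories by each category's data
// likelihood.  Returns an nnode x narea matrix; tip rows reproduce the
// observed states.
// [[Rcpp::export]]
NumericMatrix bbm_marginals_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                                IntegerMatrix tips, double pi1,
                                NumericVector rates) {
  const int nedge = edge.nrow();
  const int nnode = nedge + 1;
  const int narea = tips.ncol();
  const int k = rates.size();
  const double pi0 = 1.0 - pi1;
  const double beta = 1.0 / (2.0 * pi0 * pi1);
  const int root = edge(nedge - 1, 0) - 1;

  // per-node pendant branch index and sibling, for the up pass
  std::vector<int> kid1(nnode, -1), kid2(nnode, -1), pedge(nnode, -1);
  for (int r = 0; r < nedge; ++r) {
    const int p = edge(r, 0) - 1, ch = edge(r, 1) - 1;
    pedge[ch] = r;
    if (kid1[p] < 0) kid1[p] = ch; else kid2[p] = ch;
  }

  std::vector<double> P(static_cast<size_t>(nedge) * k * 4);
  for (int r = 0; r < nedge; ++r)
    for (int c = 0; c < k; ++c)
      pmat(pi1, std::exp(-beta * rates[c] * elen[r]), &P[(static_cast<size_t>(r) * k + c) * 4]);

  NumericMatrix out(nnode, narea);
  std::vector<double> D0(static_cast<size_t>(nnode) * k), D1(static_cast<size_t>(nnode) * k);
  std::vector<double> U0(nnode), U1(nnode);
  std::vector<double> marg(static_cast<size_t>(nnode) * k), ll(k);

  for (int a = 0; a < narea; ++a) {
    double maxll = R_NegInf;
    for (int c = 0; c < k; ++c) {
      double *d0 = &D0[static_cast<size_t>(c) * nnode];
      double *d1 = &D1[static_cast<size_t>(c) * nnode];
      for (int v = 0; v < nnode; ++v) { d0[v] = 1.0; d1[v] = 1.0; }
      for (int t = 0; t < ntip; ++t) {
        if (tips(t, a) == 1) d0[t] = 0.0; else d1[t] = 0.0;
      }
      double logscale = 0.0, scale = 1.0;
      bool dead = false;
      for (int r = 0; r < nedge; ++r) {
        const int p = edge(r, 0) - 1, ch = edge(r, 1) - 1;
        const double *Pm = &P[(static_cast<size_t>(r) * k + c) * 4];
        const double m0 = Pm[0] * d0[ch] + Pm[1] * d1[ch];
        const double m1 = Pm[2] * d0[ch] + Pm[3] * d1[ch];
        const double s = m0 + m1;
        if (s <= 0.0) { dead = true; break; } // data impossible in category
        scale *= s;
        if (scale < 1e-280) { logscale += std::log(scale); scale = 1.0; }
        const double inv = 1.0 / s;
        d0[p] *= m0 * inv;
        d1[p] *= m1 * inv;
      }
      const double lik = dead ? 0.0 : pi0 * d0[root] + pi1 * d1[root];
      if (dead || lik <= 0.0) {
        // zero posterior weight; park the category at an uninformative 0.5
        ll[c] = R_NegInf;
        double *mg0 = &marg[static_cast<size_t>(c) * nnode];
        for (int v = 0; v < nnode; ++v) mg0[v] = 0.5;
        continue;
      }
      ll[c] = std::log(lik) + logscale + std::log(scale);
      if (ll[c] > maxll) maxll = ll[c];

      // up pass (reverse postorder = parents before children)
      U0[root] = pi0; U1[root] = pi1;
      for (int r = nedge - 1; r >= 0; --r) {
        const int p = edge(r, 0) - 1, ch = edge(r, 1) - 1;
        const int sib = (kid1[p] == ch) ? kid2[p] : kid1[p];
        const double *Ps = &P[(static_cast<size_t>(pedge[sib]) * k + c) * 4];
        const double ms0 = Ps[0] * d0[sib] + Ps[1] * d1[sib];
        const double ms1 = Ps[2] * d0[sib] + Ps[3] * d1[sib];
        const double A0 = U0[p] * ms0, A1 = U1[p] * ms1;
        const double *Pc = &P[(static_cast<size_t>(r) * k + c) * 4];
        double u0 = Pc[0] * A0 + Pc[2] * A1;
        double u1 = Pc[1] * A0 + Pc[3] * A1;
        const double s = u0 + u1;
        if (s > 0.0) { u0 /= s; u1 /= s; }
        U0[ch] = u0; U1[ch] = u1;
      }
      double *mg = &marg[static_cast<size_t>(c) * nnode];
      for (int v = 0; v < nnode; ++v) {
        const double uu0 = (v == root) ? pi0 : U0[v];
        const double uu1 = (v == root) ? pi1 : U1[v];
        const double w0 = uu0 * d0[v], w1 = uu1 * d1[v];
        mg[v] = (w0 + w1 > 0.0) ? w1 / (w0 + w1) : 0.5;
      }
    }
    double wsum = 0.0;
    std::vector<double> w(k);
    for (int c = 0; c < k; ++c) {
      w[c] = R_finite(maxll) ? std::exp(ll[c] - maxll) : 1.0;
      wsum += w[c];
    }
    for (int v = 0; v < nnode; ++v) {
      double m = 0.0;
      for (int c = 0; c < k; ++c) m += w[c] * marg[static_cast<size_t>(c) * nnode + v];
      out(v, a) = m / wsum;
    }
  }
  return out;
}
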