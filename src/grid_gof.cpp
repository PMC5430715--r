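#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean per-order deviation between empirical type-ratio curves and the
// exact expected curves of the two-mode model, evaluated over the full
// 5-parameter grid. Output layout: p_sw varies fastest, then p_intra_e,
// p_trans_e, p_intra_l, p_trans_l (column-major over a G^5 array).
//
// emp:  (n_ord x 5) empirical ratios, columns intra, trans, obj->bg,
//       bg->obj, bg->bg.
// bbar: flip probability of each of the n_ord + 1 fixations.
// grid: candidate values shared by all five parameters.
// norm: 1 = L1 over the 5 components, 2 = L2.
//
// The three background-involving components do not depend on the five grid
// parameters, so their contribution per order is precomputed; only the
// putative intra-state probability s_i is propagated per combination. At
// the degenerate point p_intra_e = p_trans_e = 1 the early-mode stationary
// distribution is undefined and the symmetric limit 0.5 is used.
// [[Rcpp::export]]
NumericVector grid_mean_dev(NumericMatrix emp, NumericVector bbar,
                            NumericVector grid, int norm) {
  const int n_ord = emp.nrow();
  const int G = grid.size();
  if (bbar.size() != n_ord + 1)
    stop("bbar must have length n_ord + 1");
  std::vector<double> cc(n_ord), dconst(n_ord), e1(n_ord), e2(n_ord);
  for (int i = 0; i < n_ord; ++i) {
    const double bi = bbar[i], bn = bbar[i + 1];
    const double ci = 1.0 - bi, cn = 1.0 - bn;
    cc[i] = ci * cn;
    const double d3 = ci * bn - emp(i, 2);
    const double d4 = bi * cn - emp(i, 3);
    const double d5 = bi * bn - emp(i, 4);
    dconst[i] = (norm == 1)
      ? std::fabs(d3) + std::fabs(d4) + std::fabs(d5)
      : d3 * d3 + d4 * d4 + d5 * d5;
    e1[i] = emp(i, 0);
    e2[i] = emp(i, 1);
  }
  const R_xlen_t total = (R_xlen_t)G * G * G * G * G;
  NumericVector out(total);
  std::vector<double> s(n_ord);
  R_xlen_t idx = 0;
  for (int iTL = 0; iTL < G; ++iTL) {
    const double pTL = grid[iTL];
    for (int iIL = 0; iIL < G; ++iIL) {
      const double pIL = grid[iIL];
      for (int iTE = 0; iTE < G; ++iTE) {
        const double pTE = grid[iTE];
        for (int iIE = 0; iIE < G; ++iIE) {
          const double pIE = grid[iIE];
          const double den = 2.0 - pIE - pTE;
          const double pi_intra = (den > 0.0) ? (1.0 - pTE) / den : 0.5;
          for (int iSW = 0; iSW < G; ++iSW, ++idx) {
            const double pSW = grid[iSW];
            double ei = pi_intra, et = 1.0 - pi_intra, li = 0.0, lt = 0.0;
            s[0] = ei + li;
            for (int j = 1; j < n_ord; ++j) {
              const double nei = (1.0 - pSW) * (ei * pIE + et * (1.0 - pTE));
              const double net = (1.0 - pSW) * (et * pTE + ei * (1.0 - pIE));
              const double nli = li * pIL + lt * (1.0 - pTL) +
                pSW * (ei * pIL + et * (1.0 - pTL));
              const double nlt = lt * pTL + li * (1.0 - pIL) +
                pSW * (et * pTL + ei * (1.0 - pIL));
              ei = nei; et = net; li = nli; lt = nlt;
              s[j] = ei + li;
            }
            double acc = 0.0;
            for (int i = 0; i < n_ord; ++i) {
              const double d1 = s[i] * cc[i] - e1[i];
              const double d2 = (1.0 - s[i]) * cc[i] - e2[i];
              if (norm == 1) {
                acc += std::fabs(d1) + std::fabs(d2) + dconst[i];
              } else {
                acc += std::sqrt(d1 * d1 + d2 * d2 + dconst[i]);
              }
            }
            out[idx] = acc / n_ord;
          }
        }
      }
    }
  }
  return out;
}
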