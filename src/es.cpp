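#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Weighted KS enrichment scores for all samples and gene sets.
// stats: genes x samples statistic matrix; members: list of 1-based
// integer index vectors into the gene dimension; p: weight exponent.
// Genes are ranked by decreasing statistic with ties kept in gene order;
// the running sum gains |s|^p / sum_set |s|^p at member genes (uniform
// member weights if that sum is zero) and loses 1/(G - m) at non-members.
// The score is the running-sum value of maximal absolute deviation; among
// equal deviations the earliest rank position wins.  Matches the R
// reference walk exactly.
// [[Rcpp::export(name = ".es_matrix_cpp")]]
NumericMatrix es_matrix_cpp(NumericMatrix stats, List members, double p) {
  const int G = stats.nrow(), S = stats.ncol(), K = members.size();
  NumericMatrix out(S, K);
  std::vector<int> ord(G), ranks(G);
  std::vector<double> s(G);

  std::vector<std::vector<int>> midx(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector mk = members[k];
    midx[k].assign(mk.begin(), mk.end());
    for (size_t t = 0; t < midx[k].size(); ++t) midx[k][t] -= 1;
  }

  std::vector<int> pos;
  std::vector<double> w, cumw;
  for (int i = 0; i < S; ++i) {
    for (int g = 0; g < G; ++g) { s[g] = stats(g, i); ord[g] = g; }
    // decreasing by s, stable in gene order
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return s[a] > s[b]; });
    for (int r = 0; r < G; ++r) ranks[ord[r]] = r + 1;

    for (int k = 0; k < K; ++k) {
      const std::vector<int> &mk = midx[k];
      const int m = (int)mk.size();
      pos.resize(m); w.resize(m); cumw.resize(m);
      std::vector<int> order_m(m);
      for (int t = 0; t < m; ++t) { pos[t] = ranks[mk[t]]; order_m[t] = t; }
      std::sort(order_m.begin(), order_m.end(),
                [&](int a, int b) { return pos[a] < pos[b]; });
      double W = 0.0;
      std::vector<int> spos(m);
      for (int t = 0; t < m; ++t) {
        int src = order_m[t];
        spos[t] = pos[src];
        double wt = (p == 0.0) ? 1.0 : std::pow(std::fabs(s[mk[src]]), p);
        w[t] = wt;
        W += wt;
      }
      double cum = 0.0;
      const double miss = 1.0 / (double)(G - m);
      double best = 0.0; int best_pos = G + 1;
      for (int t = 0; t < m; ++t) {
        double wt = (W > 0.0) ? w[t] / W : 1.0 / (double)m;
        double gap = (double)(spos[t] - (t + 1)) * miss;
        double val_pre = cum - gap;          // just before the hit
        cum += wt;
        double val_hit = cum - gap;          // at the hit
        double a_pre = std::fabs(val_pre), a_hit = std::fabs(val_hit);
        double a_best = std::fabs(best);
        if (a_pre > a_best || (a_pre == a_best && spos[t] - 1 < best_pos)) {
          best = val_pre; best_pos = spos[t] - 1; a_best = a_pre;
        }
        if (a_hit > a_best || (a_hit == a_best && spos[t] < best_pos)) {
          best = val_hit; best_pos = spos[t];
        }
      }
      out(i, k) = best;
    }
  }
  return out;
}
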