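#include <Rcpp.h>
using namespace Rcpp;

// Connected components of supra-threshold pixels in a statistic map under
// 4-neighbour (rook) adjacency, with per-cluster sums of the statistic.
// sign = +1 labels pixels with t >= thr, sign = -1 pixels with t <= -thr.

// [[Rcpp::export]]
List label_clusters_cpp(NumericMatrix t, double thr, int sign) {
  int nr = t.nrow(), nc = t.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<double> sums;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = t(i, j) * sign;
      if (lab(i, j) != 0 || !(v >= thr)) continue;
      ++next;
      double s = 0.0;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        s += t(pi, pj);
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (lab(qi, qj) != 0) continue;
          if (t(qi, qj) * sign >= thr) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
      sums.push_back(s);
    }
  }
  return List::create(_["labels"] = lab, _["sums"] = wrap(sums));
}

// Extreme cluster sum (max of positive-cluster sums if sign = +1, min of
// negative-cluster sums if sign = -1); 0.0 when no cluster exists.

// [[Rcpp::export]]
double extreme_cluster_sum_cpp(NumericMatrix t, double thr, int sign) {
  List r = label_clusters_cpp(t, thr, sign);
  NumericVector s = r["sums"];
  if (s.size() == 0) return 0.0;
  double best = s[0];
  for (int i = 1; i < s.size(); ++i)
    if ((sign > 0 && s[i] > best) || (sign < 0 && s[i] < best)) best = s[i];
  return best;
}
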