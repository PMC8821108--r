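#include <Rcpp.h>
using namespace Rcpp;

// Count permutations of ry whose centered rank-product sum is at least
// as extreme (in absolute value) as `thresh`.  Used for the exact
// two-sided permutation p-value of the Spearman coefficient at small n:
// with the margins fixed, rs is an increasing affine function of
// S = sum(rx_i * ry_perm(i)), so comparing |S - center| suffices.
static void perm_rec(const std::vector<double>& rx,
                     const std::vector<double>& ry,
                     std::vector<bool>& used,
                     int pos, double partial, int n,
                     double center, double thresh, double eps,
                     double& count) {
  if (pos == n) {
    if (std::fabs(partial - center) >= thresh - eps) count += 1.0;
    return;
  }
  for (int j = 0; j < n; ++j) {
    if (used[j]) continue;
    used[j] = true;
    perm_rec(rx, ry, used, pos + 1, partial + rx[pos] * ry[j], n,
             center, thresh, eps, count);
    used[j] = false;
  }
}

// [[Rcpp::export]]
double spearman_perm_count(NumericVector rx, NumericVector ry,
                           double center, double thresh, double eps) {
  int n = rx.size();
  std::vector<double> vx(rx.begin(), rx.end());
  std::vector<double> vy(ry.begin(), ry.end());
  std::vector<bool> used(n, false);
  double count = 0.0;
  perm_rec(vx, vy, used, 0, 0.0, n, center, thresh, eps, count);
  return count;
}
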