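// Partitioning Around Medoids with a deterministic contract:
//  * BUILD: greedy initialization; ties in the gain criterion are broken by
//    a caller-supplied candidate order (derived from the seed in R).
//  * SWAP: all (medoid, candidate) swap deltas are evaluated per sweep in
//    O(n * (n-k)) using nearest / second-nearest medoid distances
//    (FastPAM1-style accumulation); the single best strictly improving swap
//    is applied per iteration, ties by candidate order then medoid order.
//  * Cost trace: total deviation after BUILD and after every accepted swap,
//    so callers can assert the non-increasing cost invariant.
#include <Rcpp.h>
using namespace Rcpp;

static void nearest_two(const NumericMatrix& D, const std::vector<int>& med,
                        std::vector<int>& n1, std::vector<double>& d1,
                        std::vector<double>& d2) {
  int n = D.nrow(), k = med.size();
  for (int j = 0; j < n; ++j) {
    double b1 = R_PosInf, b2 = R_PosInf; int w1 = -1;
    for (int m = 0; m < k; ++m) {
      double d = D(j, med[m]);
      if (d < b1) { b2 = b1; b1 = d; w1 = m; }
      else if (d < b2) { b2 = d; }
    }
    n1[j] = w1; d1[j] = b1; d2[j] = b2;
  }
}

// [[Rcpp::export(name = ".pam_cpp")]]
List pam_cpp(NumericMatrix D, int k, IntegerVector tie_order,
             int max_iter = 1000) {
  int n = D.nrow();
  if (D.ncol() != n) stop("distance matrix must be square");
  if (k < 1 || k > n) stop("k must lie in [1, n]");
  // rank of each point in the tie-break order (lower = preferred)
  std::vector<int> pref(n);
  for (int i = 0; i < n; ++i) pref[tie_order[i] - 1] = i;

  std::vector<bool> is_med(n, false);
  std::vector<int> med;
  med.reserve(k);

  // BUILD: first medoid minimizes total distance
  {
    double best = R_PosInf; int who = -1;
    for (int c = 0; c < n; ++c) {
      double s = 0;
      for (int j = 0; j < n; ++j) s += D(j, c);
      if (s < best - 1e-12 || (s < best + 1e-12 && (who < 0 || pref[c] < pref[who]))) {
        best = s; who = c;
      }
    }
    med.push_back(who); is_med[who] = true;
  }
  std::vector<double> dnear(n);
  for (int j = 0; j < n; ++j) dnear[j] = D(j, med[0]);

  std::vector<double> build_costs;
  {
    double c0 = 0; for (int j = 0; j < n; ++j) c0 += dnear[j];
    build_costs.push_back(c0);
  }
  while ((int)med.size() < k) {
    double best_gain = -1; int who = -1;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double g = 0;
      for (int j = 0; j < n; ++j) {
        double diff = dnear[j] - D(j, c);
        if (diff > 0) g += diff;
      }
      if (g > best_gain + 1e-12 ||
          (g > best_gain - 1e-12 && (who < 0 || pref[c] < pref[who]))) {
        best_gain = g; who = c;
      }
    }
    med.push_back(who); is_med[who] = true;
    for (int j = 0; j < n; ++j)
      if (D(j, who) < dnear[j]) dnear[j] = D(j, who);
    double cc = 0; for (int j = 0; j < n; ++j) cc += dnear[j];
    build_costs.push_back(cc);
  }

  // SWAP
  std::vector<int> n1(n); std::vector<double> d1(n), d2(n);
  std::vector<double> swap_costs;
  double total = 0;
  nearest_two(D, med, n1, d1, d2);
  for (int j = 0; j < n; ++j) total += d1[j];

  std::vector<double> delta(k);
  for (int iter = 0; iter < max_iter; ++iter) {
    double best_delta = -1e-12; int best_h = -1, best_m = -1;
    for (int h = 0; h < n; ++h) {
      if (is_med[h]) continue;
      double acc_all = 0;               // shared term over all medoids
      std::fill(delta.begin(), delta.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        double dhj = D(j, h);
        double shared = dhj < d1[j] ? dhj - d1[j] : 0.0;  // <= 0
        acc_all += shared;
        // correction for the removed medoid being j's nearest
        double repl = std::min(d2[j], dhj) - d1[j];
        delta[n1[j]] += repl - shared;
      }
      for (int m = 0; m < k; ++m) {
        double dd = acc_all + delta[m];
        bool better = dd < best_delta - 1e-12;
        bool tied = !better && dd < best_delta + 1e-12 && best_h >= 0;
        if (better ||
            (tied && (pref[h] < pref[best_h] ||
                      (pref[h] == pref[best_h] && med[m] < med[best_m])))) {
          best_delta = dd; best_h = h; best_m = m;
        }
      }
    }
    if (best_h < 0 || best_delta >= -1e-12) break;
    is_med[med[best_m]] = false;
    med[best_m] = best_h;
    is_med[best_h] = true;
    nearest_two(D, med, n1, d1, d2);
    total = 0; for (int j = 0; j < n; ++j) total += d1[j];
    swap_costs.push_back(total);
  }

  // assignment: nearest medoid, ties by the smaller medoid (point) index
  std::vector<int> med_sorted(med);
  std::sort(med_sorted.begin(), med_sorted.end());
  IntegerVector assign(n);
  double cost = 0;
  for (int j = 0; j < n; ++j) {
    double b = R_PosInf; int w = -1;
    for (size_t m = 0; m < med_sorted.size(); ++m) {
      double d = D(j, med_sorted[m]);
      if (d < b - 1e-15) { b = d; w = med_sorted[m]; }
    }
    assign[j] = w + 1;
    cost += b;
  }
  return List::create(
    _["medoids"] = IntegerVector(med_sorted.begin(), med_sorted.end()) + 1,
    _["assignment"] = assign,
    _["cost"] = cost,
    _["build_costs"] = NumericVector(build_costs.begin(), build_costs.end()),
    _["swap_costs"] = NumericVector(swap_costs.begin(), swap_costs.end()));
}
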