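#include <Rcpp.h>
using namespace Rcpp;

// Local similarity dynamic program. For each alignment offset d in [-D, D]
// we accumulate positive and negative chains over the aligned products
// x[i] * y[i + d], resetting at zero, and keep the largest chain overall.
// The score is normalized by the series length n so that identical
// unit-variance series give LS = 1.
static double ls_dp(const double* x, const double* y, int n, int D,
                    int* best_delay) {
  double best_pos = 0.0, best_neg = 0.0;
  int d_pos = 0, d_neg = 0;
  for (int d = -D; d <= D; ++d) {
    int lo = d < 0 ? -d : 0;
    int hi = d > 0 ? n - d : n;  // exclusive
    double P = 0.0, N = 0.0;
    for (int i = lo; i < hi; ++i) {
      double prod = x[i] * y[i + d];
      P += prod; if (P < 0.0) P = 0.0;
      N -= prod; if (N < 0.0) N = 0.0;
      if (P > best_pos) { best_pos = P; d_pos = d; }
      if (N > best_neg) { best_neg = N; d_neg = d; }
    }
  }
  if (best_pos >= best_neg) {
    *best_delay = d_pos;
    return best_pos / n;
  }
  *best_delay = d_neg;
  return -best_neg / n;
}

// [[Rcpp::export]]
List cpp_local_similarity(NumericVector x, NumericVector y, int D) {
  if (x.size() != y.size()) stop("series length mismatch");
  int delay = 0;
  double ls = ls_dp(x.begin(), y.begin(), x.size(), D, &delay);
  return List::create(_["ls"] = ls, _["delay"] = delay);
}

// Batch LSA with a shared set of time permutations. za: pA x n, zb: pB x n
// (series in rows). perms: n_perm x n of 1-based time indices; the second
// series of each pair is permuted. Returns observed LS, optimal delay and
// the count of permuted |LS| >= observed |LS| for every pair.
// [[Rcpp::export]]
List cpp_lsa_batch(NumericMatrix za, NumericMatrix zb, int D,
                   IntegerMatrix perms) {
  int pa = za.nrow(), pb = zb.nrow(), n = za.ncol();
  if (zb.ncol() != n) stop("time axes differ");
  int nperm = perms.nrow();
  if (nperm > 0 && perms.ncol() != n) stop("permutation length mismatch");

  NumericMatrix ls(pa, pb);
  IntegerMatrix delay(pa, pb);
  IntegerMatrix exceed(pa, pb);

  std::vector<double> xi(n), yj(n), yperm((size_t)std::max(1, nperm) * n);

  for (int j = 0; j < pb; ++j) {
    for (int t = 0; t < n; ++t) yj[t] = zb(j, t);
    for (int k = 0; k < nperm; ++k)
      for (int t = 0; t < n; ++t)
        yperm[(size_t)k * n + t] = yj[perms(k, t) - 1];
    for (int i = 0; i < pa; ++i) {
      for (int t = 0; t < n; ++t) xi[t] = za(i, t);
      int dopt = 0;
      double obs = ls_dp(xi.data(), yj.data(), n, D, &dopt);
      ls(i, j) = obs;
      delay(i, j) = dopt;
      double obs_abs = std::fabs(obs);
      int cnt = 0, dtmp = 0;
      for (int k = 0; k < nperm; ++k) {
        double lp = ls_dp(xi.data(), yperm.data() + (size_t)k * n, n, D,
                          &dtmp);
        if (std::fabs(lp) >= obs_abs - 1e-12) ++cnt;
      }
      exceed(i, j) = cnt;
    }
  }
  return List::create(_["ls"] = ls, _["delay"] = delay,
                      _["exceed"] = exceed);
}
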