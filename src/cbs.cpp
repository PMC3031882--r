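#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// Circular binary segmentation scan: for a probe sequence x[0..n-1], find
// the arc (i, j], 0 <= i < j <= n (excluding the full sequence), maximising
// the two-sample t statistic (pooled variance) between probes inside and
// outside the arc. Treating the sequence as a circle means complements of
// contiguous runs are covered automatically: arc (i, j] vs the rest is the
// same comparison as the wrapped arc (j, i]. Ties broken by smallest start
// index, then smallest width (guaranteed by scan order).
// For fixed arc width k the statistic is monotone in the squared mean
// contrast d^2 (within-arc sum of squares decomposes as
// SS_w = TSS - k(n-k)/n * d^2), so only the arcs with extreme window sums
// need their statistic evaluated: an O(n) sweep per width instead of a
// full t computation per arc.
static void max_arc(const std::vector<double> &cs,
                    const std::vector<double> &cs2, int n,
                    double &best, int &bi, int &bj) {
  best = -1.0;
  bi = 0;
  bj = 1;
  const double total = cs[n];
  const double tss0 = cs2[n] - total * total / n;
  const double tss = (tss0 < 0) ? 0 : tss0;
  // zero-variance guard scaled to the data's magnitude
  const double var_eps = 1e-12 * (cs2[n] / n + 1.0);
  for (int k = 1; k < n; ++k) {
    double smax = -1e300, smin = 1e300;
    int imax = 0, imin = 0;
    for (int i = 0; i + k <= n; ++i) {
      const double s = cs[i + k] - cs[i];
      if (s > smax) { smax = s; imax = i; }
      if (s < smin) { smin = s; imin = i; }
    }
    const double cands[2] = {smax, smin};
    const int candi[2] = {imax, imin};
    for (int c = 0; c < 2; ++c) {
      const double s_in = cands[c];
      const int i = candi[c];
      const double d = s_in / k - (total - s_in) / (n - k);
      double ss = tss - (double)k * (n - k) / n * d * d;
      if (ss < 0) ss = 0;
      const double sp2 = ss / (n - 2);
      double stat;
      if (sp2 <= var_eps) {
        stat = (std::fabs(d) > 1e-9) ? R_PosInf : 0.0;
      } else {
        stat = std::fabs(d) / std::sqrt(sp2 * (1.0 / k + 1.0 / (n - k)));
      }
      if (stat > best ||
          (stat == best && (i < bi || (i == bi && i + k < bj)))) {
        best = stat;
        bi = i;
        bj = i + k;
      }
    }
  }
}

static void cumsums(const NumericVector &x, std::vector<double> &cs,
                    std::vector<double> &cs2) {
  const int n = x.size();
  cs.assign(n + 1, 0.0);
  cs2.assign(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
}

//' Maximum arc t statistic of a probe sequence
//'
//' Exhaustive scan over all circular arcs of at least one probe, returning
//' the maximising arc and its pooled-variance t statistic. The arc is
//' reported as 0-based half-open bounds `(i, j]` into the sequence; on
//' zero-variance input with distinct means the statistic is `Inf`.
//'
//' @param x Numeric vector of (normalised) log2 ratios, length >= 3.
//' @return List with `stat`, `i`, `j`.
//' @export
// [[Rcpp::export]]
List cbs_max_arc(NumericVector x) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 probes");
  std::vector<double> cs, cs2;
  cumsums(x, cs, cs2);
  double best;
  int bi, bj;
  max_arc(cs, cs2, n, best, bi, bj);
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}

// Deterministic Fisher-Yates shuffle driven by a raw mt19937 stream (the
// modulo bias is irrelevant for a permutation null and keeps the stream
// identical across platforms, unlike std::shuffle).
static void shuffle_vec(std::vector<double> &v, std::mt19937 &rng) {
  for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
    const int j = static_cast<int>(rng() % static_cast<uint32_t>(i + 1));
    std::swap(v[i], v[j]);
  }
}

//' Permutation split test for one segmentation step
//'
//' Finds the maximising arc of `x` and evaluates its permutation p-value:
//' the fraction of label permutations whose own maximal arc statistic
//' reaches the observed one. The split is accepted when `p < alpha`.
//' Scanning stops early as soon as the accept/reject decision is forced
//' (the exceedance count either passes `alpha * n_perm` or can no longer
//' reach it), which leaves the decision identical to the full scan.
//'
//' @param x Numeric vector of log2 ratios (length >= 4).
//' @param n_perm Number of permutations (>= 100).
//' @param alpha Significance level in (0, 1).
//' @param seed Seed for the permutation stream (one stream per call).
//' @return List with `stat`, `i`, `j`, `significant`, `exceed`, `n_done`.
//' @export
// [[Rcpp::export]]
List cbs_split_test(NumericVector x, int n_perm, double alpha, int seed) {
  const int n = x.size();
  if (n < 4) stop("need at least 4 probes");
  if (n_perm < 100) stop("n_perm must be >= 100");
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)");
  std::vector<double> cs, cs2;
  cumsums(x, cs, cs2);
  double obs;
  int bi, bj;
  max_arc(cs, cs2, n, obs, bi, bj);

  // accept split iff exceed / n_perm < alpha  <=>  exceed <= thresh
  const int thresh = static_cast<int>(std::ceil(alpha * n_perm)) - 1;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<double> xp(x.begin(), x.end());
  int exceed = 0;
  int done = 0;
  bool significant = false;
  for (int t = 0; t < n_perm; ++t) {
    shuffle_vec(xp, rng);
    std::vector<double> pcs, pcs2;
    NumericVector tmp(xp.begin(), xp.end());
    cumsums(tmp, pcs, pcs2);
    double pb;
    int pi, pj;
    max_arc(pcs, pcs2, n, pb, pi, pj);
    if (pb >= obs) ++exceed;
    ++done;
    if (exceed > thresh) {  // p >= alpha is certain: reject split
      significant = false;
      break;
    }
    if (exceed + (n_perm - done) <= thresh) {  // p < alpha is certain
      significant = true;
      break;
    }
  }
  if (done == n_perm) significant = exceed <= thresh;
  return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                      _["significant"] = significant,
                      _["exceed"] = exceed, _["n_done"] = done);
}
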