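#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Lagged Pearson correlation between a rate and a speed series living on a
// common stride-spaced grid split into contiguous segments. At lag k
// (positive lag = rate follows speed) the pairs are (rate[i], speed[i-k])
// for i and i-k inside the same segment, so lagged pairs never mix across
// discontinuities. Lags with fewer than n_min pairs are NA.
//
// Surrogate nulls circularly rotate the rate series through the
// concatenated valid-bin sequence. The pairing pattern depends only on the
// segment layout, so the per-lag pair counts and all speed-side sums are
// shared across rotations; per rotation only the rate-side sums and the
// cross products need recomputing, each a contiguous dot product.

struct SegLayout {
  std::vector<int> a, b; // segment [a, b) index ranges
};

static SegLayout segment_runs(const IntegerVector& seg) {
  SegLayout s;
  int L = seg.size();
  int start = 0;
  for (int i = 1; i <= L; ++i) {
    if (i == L || seg[i] != seg[i - 1]) {
      s.a.push_back(start);
      s.b.push_back(i);
      start = i;
    }
  }
  return s;
}

// Per-lag pair count and speed-side sums (independent of rotation).
static void speed_side(const SegLayout& sl, const double* y, int max_k,
                       std::vector<int>& n, std::vector<double>& sy,
                       std::vector<double>& syy) {
  int nl = 2 * max_k + 1;
  n.assign(nl, 0); sy.assign(nl, 0.0); syy.assign(nl, 0.0);
  for (int k = -max_k; k <= max_k; ++k) {
    int idx = k + max_k;
    for (size_t s = 0; s < sl.a.size(); ++s) {
      int lo = sl.a[s] + std::max(0, k);
      int hi = sl.b[s] + std::min(0, k);
      for (int i = lo; i < hi; ++i) {
        double yv = y[i - k];
        sy[idx] += yv; syy[idx] += yv * yv; ++n[idx];
      }
    }
  }
}

static void rate_side(const SegLayout& sl, const double* x, const double* y,
                      const std::vector<double>& p1,
                      const std::vector<double>& p2, int max_k, int n_min,
                      const std::vector<int>& n, const std::vector<double>& sy,
                      const std::vector<double>& syy, double* r_out) {
  for (int k = -max_k; k <= max_k; ++k) {
    int idx = k + max_k;
    if (n[idx] < n_min) { r_out[idx] = NA_REAL; continue; }
    double sx = 0, sxx = 0, sxy = 0;
    for (size_t s = 0; s < sl.a.size(); ++s) {
      int lo = sl.a[s] + std::max(0, k);
      int hi = sl.b[s] + std::min(0, k);
      if (hi <= lo) continue;
      sx += p1[hi] - p1[lo];
      sxx += p2[hi] - p2[lo];
      const double* xv = x + lo;
      const double* yv = y + lo - k;
      double acc = 0;
      for (int i = 0; i < hi - lo; ++i) acc += xv[i] * yv[i];
      sxy += acc;
    }
    double m = n[idx];
    double vx = sxx - sx * sx / m, vy = syy[idx] - sy[idx] * sy[idx] / m;
    double cv = sxy - sx * sy[idx] / m;
    r_out[idx] = (vx <= 0 || vy <= 0) ? NA_REAL : cv / std::sqrt(vx * vy);
  }
}

// [[Rcpp::export]]
List ccg_lags_cpp(NumericVector rate, NumericVector speed,
                  IntegerVector seg, int max_k, int n_min) {
  int L = rate.size();
  if (L != speed.size() || L != seg.size())
    stop("rate, speed and seg must have equal length");
  SegLayout sl = segment_runs(seg);
  std::vector<int> n; std::vector<double> sy, syy;
  speed_side(sl, speed.begin(), max_k, n, sy, syy);
  std::vector<double> p1(L + 1, 0.0), p2(L + 1, 0.0);
  for (int i = 0; i < L; ++i) {
    p1[i + 1] = p1[i] + rate[i];
    p2[i + 1] = p2[i] + rate[i] * rate[i];
  }
  int nl = 2 * max_k + 1;
  NumericVector r(nl);
  rate_side(sl, rate.begin(), speed.begin(), p1, p2, max_k, n_min,
            n, sy, syy, r.begin());
  IntegerVector np(nl);
  std::copy(n.begin(), n.end(), np.begin());
  return List::create(_["r"] = r, _["n_pairs"] = np);
}

// Correlation-by-lag profiles for each circular shift of the rate series:
// returns an (2*max_k+1) x length(shifts) matrix.
// [[Rcpp::export]]
NumericMatrix ccg_shift_matrix_cpp(NumericVector rate, NumericVector speed,
                                   IntegerVector seg, int max_k, int n_min,
                                   IntegerVector shifts) {
  int L = rate.size();
  if (L != speed.size() || L != seg.size())
    stop("rate, speed and seg must have equal length");
  SegLayout sl = segment_runs(seg);
  std::vector<int> n; std::vector<double> sy, syy;
  speed_side(sl, speed.begin(), max_k, n, sy, syy);
  int nl = 2 * max_k + 1, S = shifts.size();
  NumericMatrix r(nl, S);
  std::vector<double> rot(L), p1(L + 1), p2(L + 1);
  for (int sidx = 0; sidx < S; ++sidx) {
    int s = ((shifts[sidx] % L) + L) % L; // rot[i] = rate[(i - s) mod L]
    if (s == 0) std::memcpy(rot.data(), rate.begin(), L * sizeof(double));
    else {
      std::memcpy(rot.data(), rate.begin() + (L - s), s * sizeof(double));
      std::memcpy(rot.data() + s, rate.begin(), (L - s) * sizeof(double));
    }
    p1[0] = 0; p2[0] = 0;
    for (int i = 0; i < L; ++i) {
      p1[i + 1] = p1[i] + rot[i];
      p2[i + 1] = p2[i] + rot[i] * rot[i];
    }
    rate_side(sl, rot.data(), speed.begin(), p1, p2, max_k, n_min,
              n, sy, syy, &r(0, sidx));
  }
  return r;
}
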