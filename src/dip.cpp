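#include <Rcpp.h>
using namespace Rcpp;

// Hartigan & Hartigan dip statistic of a numeric sample.
//
// The dip is the smallest sup-norm distance between the empirical CDF and
// any unimodal CDF. It is computed by iteratively fitting the greatest
// convex minorant (GCM) and least concave majorant (LCM) of the ecdf on a
// shrinking modal interval, accumulating the largest deviation committed
// outside that interval; the answer is half the largest deviation.
//
// Ties are folded into the ecdf corner counts, so duplicated values are
// handled exactly.

static std::vector<int> lower_hull(const std::vector<double>& x,
                                   const std::vector<double>& y,
                                   int lo, int hi) {
  std::vector<int> h;
  for (int i = lo; i <= hi; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      double cross = (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]);
      if (cross > 0) break;   // b strictly below chord a--i: keep
      h.pop_back();
    }
    h.push_back(i);
  }
  return h;
}

static std::vector<int> upper_hull(const std::vector<double>& x,
                                   const std::vector<double>& y,
                                   int lo, int hi) {
  std::vector<int> h;
  for (int i = lo; i <= hi; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      double cross = (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]);
      if (cross < 0) break;   // b strictly above chord a--i: keep
      h.pop_back();
    }
    h.push_back(i);
  }
  return h;
}

static double curve_at(const std::vector<double>& x, const std::vector<double>& y,
                       const std::vector<int>& hull, double xq) {
  int m = (int) hull.size();
  if (m == 1) return y[hull[0]];
  int k = 0;
  while (k < m - 2 && x[hull[k + 1]] < xq) ++k;
  double x0 = x[hull[k]], x1 = x[hull[k + 1]];
  double y0 = y[hull[k]], y1 = y[hull[k + 1]];
  if (x1 <= x0) return std::max(y0, y1);
  double t = (xq - x0) / (x1 - x0);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  return y0 + t * (y1 - y0);
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xs) {
  int n = xs.size();
  if (n < 2) return 0.0;
  std::vector<double> xv(xs.begin(), xs.end());
  std::sort(xv.begin(), xv.end());

  // unique values with ecdf corner counts:
  //   u[i] = #obs strictly below v[i],  l[i] = #obs at or below v[i]
  std::vector<double> v, u, l;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xv[j] == xv[i]) ++j;
    v.push_back(xv[i]);
    u.push_back((double) i);
    l.push_back((double) j);
    i = j;
  }
  int q = (int) v.size();
  if (q == 1) return 0.0;

  int low = 0, high = q - 1;
  double D = 0.0;
  for (int iter = 0; iter < q + 2; ++iter) {
    std::vector<int> gcm = lower_hull(v, u, low, high);
    std::vector<int> lcm = upper_hull(v, l, low, high);

    // greatest separation between the two hull curves, with the hull
    // vertices bracketing it
    double d = -1.0;
    int newlow = low, newhigh = high;
    for (size_t k = 0; k < gcm.size(); ++k) {
      int idx = gcm[k];
      double sep = curve_at(v, l, lcm, v[idx]) - u[idx];
      if (sep > d) {
        d = sep;
        newlow = idx;
        int kk = 0;
        while (kk < (int) lcm.size() - 1 && v[lcm[kk]] < v[idx]) ++kk;
        newhigh = lcm[kk];
        if (newhigh < idx) newhigh = idx;
      }
    }
    for (size_t k = 0; k < lcm.size(); ++k) {
      int idx = lcm[k];
      double sep = l[idx] - curve_at(v, u, gcm, v[idx]);
      if (sep > d) {
        d = sep;
        newhigh = idx;
        int kk = (int) gcm.size() - 1;
        while (kk > 0 && v[gcm[kk]] > v[idx]) --kk;
        newlow = gcm[kk];
        if (newlow > idx) newlow = idx;
      }
    }
    if (d <= D) break;

    // deviations committed outside the new modal interval; at the modal
    // boundary itself the pre-/post-jump ecdf corner is used, because a
    // unimodal CDF may carry an atom at its mode and absorb that jump
    double dl = 0.0, du = 0.0;
    for (int t = low; t <= newlow; ++t) {
      double ft = (t == newlow) ? u[t] : l[t];
      double dev = ft - curve_at(v, u, gcm, v[t]);
      if (dev > dl) dl = dev;
    }
    for (int t = newhigh; t <= high; ++t) {
      double ft = (t == newhigh) ? l[t] : u[t];
      double dev = curve_at(v, l, lcm, v[t]) - ft;
      if (dev > du) du = dev;
    }
    if (dl > D) D = dl;
    if (du > D) D = du;
    if (newlow == low && newhigh == high) break;
    low = newlow;
    high = newhigh;
  }
  return D / (2.0 * n);
}
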