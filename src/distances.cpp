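#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Fast deterministic generator for the bootstrap inner loops, seeded
// from R's RNG so that set.seed() fully determines the draws.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  inline uint64_t next_u64() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double next() { return (next_u64() >> 11) * 0x1.0p-53; }
  inline std::size_t index(std::size_t n) {
    std::size_t k = (std::size_t)(next() * n);
    return k >= n ? n - 1 : k;
  }
};

static SplitMix64 seeded_from_R() {
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  return SplitMix64((hi << 32) ^ lo ^ 0xD1B54A32D192ED03ULL);
}

// Two-sample Kolmogorov-Smirnov distance sup_x |F1(x) - F2(x)| for
// pre-sorted inputs; duplicate runs are consumed in full before the
// ECDF gap is evaluated.
static double ks_sorted(const std::vector<double>& x,
                        const std::vector<double>& y) {
  const std::size_t n = x.size(), m = y.size();
  std::size_t i = 0, j = 0;
  double d = 0.0;
  while (i < n || j < m) {
    double v;
    if (i >= n) v = y[j];
    else if (j >= m) v = x[i];
    else v = std::min(x[i], y[j]);
    while (i < n && x[i] == v) ++i;
    while (j < m && y[j] == v) ++j;
    double diff = std::fabs((double)i / n - (double)j / m);
    if (diff > d) d = diff;
  }
  return d;
}

// Energy distance 2 E|X-Y| - E|X-X'| - E|Y-Y'| with plain double-loop
// means over all ordered pairs (diagonal included, contributing zero).
static double energy_plain(const std::vector<double>& x,
                           const std::vector<double>& y) {
  const std::size_t n = x.size(), m = y.size();
  double axy = 0.0, axx = 0.0, ayy = 0.0;
  for (std::size_t i = 0; i < n; ++i)
    for (std::size_t j = 0; j < m; ++j)
      axy += std::fabs(x[i] - y[j]);
  axy /= (double)(n * m);
  for (std::size_t i = 0; i < n; ++i)
    for (std::size_t j = 0; j < n; ++j)
      axx += std::fabs(x[i] - x[j]);
  axx /= (double)(n * n);
  for (std::size_t i = 0; i < m; ++i)
    for (std::size_t j = 0; j < m; ++j)
      ayy += std::fabs(y[i] - y[j]);
  ayy /= (double)(m * m);
  return 2.0 * axy - axx - ayy;
}

static std::vector<double> to_sorted(const NumericVector& v) {
  std::vector<double> out(v.begin(), v.end());
  std::sort(out.begin(), out.end());
  return out;
}

// [[Rcpp::export(name = ".cpp_ks_stat")]]
double cpp_ks_stat(NumericVector x, NumericVector y) {
  std::vector<double> xs = to_sorted(x), ys = to_sorted(y);
  return ks_sorted(xs, ys);
}

// [[Rcpp::export(name = ".cpp_energy_stat")]]
double cpp_energy_stat(NumericVector x, NumericVector y) {
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  return energy_plain(xs, ys);
}

// Bootstrap draws of log(max(D, floor)) where D is the KS distance
// between independent same-size resamples of x and y.  Resamples are
// kept as multiset counts over the sorted originals; the merged support
// (with end-of-value-run boundaries) is precomputed once, so each draw
// costs O(n + m) with no sorting.
static NumericVector ks_boot(const std::vector<double>& xs,
                             const std::vector<double>& ys,
                             int M, double floor_) {
  const std::size_t n = xs.size(), m = ys.size();
  // merged walk: which sample each merged position comes from, and
  // whether a value run ends there (only then is the ECDF gap scored)
  std::vector<unsigned char> from_x, boundary;
  from_x.reserve(n + m); boundary.reserve(n + m);
  {
    std::size_t i = 0, j = 0;
    while (i < n || j < m) {
      double v;
      if (i >= n) v = ys[j];
      else if (j >= m) v = xs[i];
      else v = std::min(xs[i], ys[j]);
      while (i < n && xs[i] == v) { from_x.push_back(1); boundary.push_back(0); ++i; }
      while (j < m && ys[j] == v) { from_x.push_back(0); boundary.push_back(0); ++j; }
      boundary.back() = 1;
    }
  }
  std::vector<int> cx(n), cy(m);
  SplitMix64 rng = seeded_from_R();
  NumericVector out(M);
  const double lfloor = std::log(floor_);
  for (int r = 0; r < M; ++r) {
    std::fill(cx.begin(), cx.end(), 0);
    std::fill(cy.begin(), cy.end(), 0);
    for (std::size_t i = 0; i < n; ++i) ++cx[rng.index(n)];
    for (std::size_t j = 0; j < m; ++j) ++cy[rng.index(m)];
    long cumx = 0, cumy = 0;
    std::size_t ix = 0, iy = 0;
    double d = 0.0;
    for (std::size_t t = 0; t < from_x.size(); ++t) {
      if (from_x[t]) cumx += cx[ix++]; else cumy += cy[iy++];
      if (boundary[t]) {
        double diff = std::fabs((double)cumx / n - (double)cumy / m);
        if (diff > d) d = diff;
      }
    }
    out[r] = d > floor_ ? std::log(d) : lfloor;
  }
  return out;
}

static void resample_counts(const std::vector<double>& src,
                            std::vector<double>& dst,
                            std::vector<int>& cnt, SplitMix64& rng) {
  const std::size_t n = src.size();
  std::fill(cnt.begin(), cnt.end(), 0);
  for (std::size_t i = 0; i < n; ++i) ++cnt[rng.index(n)];
  dst.clear();
  for (std::size_t k = 0; k < n; ++k)
    for (int r = 0; r < cnt[k]; ++r) dst.push_back(src[k]);
}

// Bootstrap draws of log(max(D, floor)) for either distance.
// method: 0 = Kolmogorov-Smirnov (fast counts path), 1 = energy.
// [[Rcpp::export(name = ".cpp_dist_boot")]]
NumericVector cpp_dist_boot(NumericVector x, NumericVector y, int M,
                            double floor_, int method) {
  std::vector<double> xs = to_sorted(x), ys = to_sorted(y);
  if (method == 0) return ks_boot(xs, ys, M, floor_);
  std::vector<double> bx, by;
  bx.reserve(xs.size()); by.reserve(ys.size());
  std::vector<int> cx(xs.size()), cy(ys.size());
  SplitMix64 rng = seeded_from_R();
  NumericVector out(M);
  for (int r = 0; r < M; ++r) {
    resample_counts(xs, bx, cx, rng);
    resample_counts(ys, by, cy, rng);
    out[r] = std::log(std::max(energy_plain(bx, by), floor_));
  }
  return out;
}

// Bootstrap draws of the sample median (resample with replacement,
// same size).  Even-count median = midpoint of the central pair.
// [[Rcpp::export(name = ".cpp_boot_median")]]
NumericVector cpp_boot_median(NumericVector x, int M) {
  const std::size_t n = x.size();
  std::vector<double> buf(n);
  SplitMix64 rng = seeded_from_R();
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    for (std::size_t i = 0; i < n; ++i) buf[i] = x[rng.index(n)];
    std::size_t h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = 0.5 * (med + lo);
    }
    out[m] = med;
  }
  return out;
}
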