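// Grid-bucketed radius queries for planar cell coordinates.
// All distances are Euclidean, center-to-center, boundary inclusive (<= r).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline long long bin_key(int gx, int gy) {
  return (static_cast<long long>(gx) << 32) ^
         static_cast<long long>(static_cast<unsigned int>(gy));
}

// Hash grid with cell size = query radius, so every point within r of a
// query lies in the 3x3 block of bins around the query's bin.
struct Grid {
  double cell, x0, y0;
  const double *x, *y;
  int n;
  std::unordered_map<long long, std::vector<int> > bins;

  Grid(const NumericVector& xs, const NumericVector& ys, double cell_size)
      : cell(cell_size), x0(0.0), y0(0.0),
        x(xs.begin()), y(ys.begin()), n(xs.size()) {
    if (n > 0) {
      x0 = *std::min_element(x, x + n);
      y0 = *std::min_element(y, y + n);
    }
    for (int i = 0; i < n; ++i)
      bins[bin_key(gx(x[i]), gy(y[i]))].push_back(i);
  }
  inline int gx(double v) const { return (int)std::floor((v - x0) / cell); }
  inline int gy(double v) const { return (int)std::floor((v - y0) / cell); }

  // visit indices of stored points within r of (qx, qy)
  template <typename F>
  void visit(double qx, double qy, double r2, F& f) const {
    int cx = gx(qx), cy = gy(qy);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
            bins.find(bin_key(cx + dx, cy + dy));
        if (it == bins.end()) continue;
        const std::vector<int>& v = it->second;
        for (size_t k = 0; k < v.size(); ++k) {
          int j = v[k];
          double ddx = x[j] - qx, ddy = y[j] - qy;
          if (ddx * ddx + ddy * ddy <= r2) f(j);
        }
      }
    }
  }
};

struct Counter {
  double n;
  Counter() : n(0) {}
  void operator()(int) { ++n; }
};

} // namespace

// Unordered pairs between two disjoint point sets with distance <= r.
// [[Rcpp::export]]
double cpp_pair_count_between(NumericVector ax, NumericVector ay,
                              NumericVector bx, NumericVector by,
                              double r) {
  if (ax.size() == 0 || bx.size() == 0) return 0.0;
  double r2 = r * r;
  // index the larger set, sweep the smaller
  if (ax.size() > bx.size())
    return cpp_pair_count_between(bx, by, ax, ay, r);
  Grid g(bx, by, r);
  double total = 0.0;
  for (int i = 0; i < ax.size(); ++i) {
    Counter c;
    g.visit(ax[i], ay[i], r2, c);
    total += c.n;
  }
  return total;
}

// Distinct unordered pairs within one point set with distance <= r.
// A point never pairs with itself; coincident points do pair.
// [[Rcpp::export]]
double cpp_pair_count_within(NumericVector x, NumericVector y, double r) {
  int n = x.size();
  if (n < 2) return 0.0;
  double r2 = r * r;
  Grid g(x, y, r);
  double ordered = 0.0;
  for (int i = 0; i < n; ++i) {
    Counter c;
    g.visit(x[i], y[i], r2, c);
    ordered += c.n - 1.0; // drop self (index i is always within r of itself)
  }
  return ordered / 2.0;
}

namespace {
struct TypeTally {
  const IntegerVector& type;
  int skip;
  std::vector<double>& row;
  TypeTally(const IntegerVector& t, int s, std::vector<double>& r)
      : type(t), skip(s), row(r) {}
  void operator()(int j) {
    if (j != skip) row[type[j] - 1] += 1.0;
  }
};
} // namespace

// Per-seed neighbor counts by cell type. seed_idx are 0-based indices into
// (x, y); the seed cell itself is excluded from its own neighborhood.
// type codes are 1..n_types. Returns n_seed x n_types matrix of counts.
// [[Rcpp::export]]
NumericMatrix cpp_neighbor_type_counts(IntegerVector seed_idx,
                                       NumericVector x, NumericVector y,
                                       IntegerVector type, int n_types,
                                       double r) {
  int ns = seed_idx.size();
  NumericMatrix out(ns, n_types);
  if (ns == 0 || x.size() == 0) return out;
  double r2 = r * r;
  Grid g(x, y, r);
  std::vector<double> row(n_types);
  for (int s = 0; s < ns; ++s) {
    std::fill(row.begin(), row.end(), 0.0);
    int i = seed_idx[s];
    TypeTally tally(type, i, row);
    g.visit(x[i], y[i], r2, tally);
    for (int t = 0; t < n_types; ++t) out(s, t) = row[t];
  }
  return out;
}
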