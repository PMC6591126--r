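// Maximal information coefficient (MINE-style ApproxMaxMI).
//
// For every grid resolution (kx, ky) with kx * ky <= B(n) and kx, ky >= 2,
// one axis is equipartitioned by rank (ties never split) and the other is
// partitioned by a dynamic program maximising mutual information over
// candidate cut points between distinct values.  The characteristic value
// at (kx, ky) is I* / log2(min(kx, ky)); MIC is the maximum over the
// matrix and over both axis orientations.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

inline double xlog2x(double p) {
  return (p <= 0.0) ? 0.0 : p * std::log2(p);
}

// Rank-equipartition of a pre-sorted vector into (at most) q bins, never
// splitting runs of tied values.  Returns bin id per sorted position.
std::vector<int> equipartition_sorted(const std::vector<double>& v, int q) {
  const int n = static_cast<int>(v.size());
  std::vector<int> bin(n);
  double desired = static_cast<double>(n) / q;
  int i = 0, curr = 0, in_curr = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && v[j] == v[i]) ++j;   // tie block [i, j)
    const int S = j - i;
    if (in_curr != 0 && curr < q - 1 &&
        std::fabs(in_curr + S - desired) >= std::fabs(in_curr - desired)) {
      ++curr;
      in_curr = 0;
      desired = static_cast<double>(n - i) / (q - curr);
    }
    for (int t = i; t < j; ++t) bin[t] = curr;
    in_curr += S;
    i = j;
  }
  return bin;
}

// One DP orientation: the "row" axis is y equipartitioned into q bins; the
// "column" axis x is cut optimally into up to p_max contiguous groups of
// x-tie clumps.  Returns best[t] = max over partitions into <= t columns of
// H(P) - H(P,Q) (base-2), for t = 1..p_max; realised row entropy via *hq.
//
// ox:   indices of the points ordered by x (ties adjacent)
// row:  row-bin id per point (original index)
void optimize_axis(const std::vector<double>& x,
                   const std::vector<int>& ox,
                   const std::vector<int>& row,
                   int q, int p_max, int clump_cap,
                   std::vector<double>& best, double* hq_out) {
  const int n = static_cast<int>(ox.size());

  // clumps = maximal runs of equal x in x-order
  std::vector<int> clump_end;   // exclusive end index into ox
  {
    int i = 0;
    while (i < n) {
      int j = i + 1;
      while (j < n && x[ox[j]] == x[ox[i]]) ++j;
      clump_end.push_back(j);
      i = j;
    }
  }
  int k = static_cast<int>(clump_end.size());

  // superclump approximation for very large k (lossy; only for big n)
  if (clump_cap > 0 && k > clump_cap) {
    std::vector<int> merged;
    double desired = static_cast<double>(n) / clump_cap;
    double acc = 0.0;
    int prev = 0;
    for (int c = 0; c < k; ++c) {
      acc = clump_end[c] - prev;
      if (acc >= desired || c == k - 1) {
        merged.push_back(clump_end[c]);
        prev = clump_end[c];
      }
    }
    clump_end = merged;
    k = static_cast<int>(clump_end.size());
  }

  // cumulative row histograms at clump boundaries: cum[c][r], c = 0..k
  std::vector<std::vector<int> > cum(k + 1, std::vector<int>(q, 0));
  std::vector<int> cn(k + 1, 0);
  {
    int pos = 0;
    for (int c = 0; c < k; ++c) {
      cum[c + 1] = cum[c];
      for (; pos < clump_end[c]; ++pos) cum[c + 1][row[ox[pos]]]++;
      cn[c + 1] = clump_end[c];
    }
  }

  // realised row entropy H(Q) over all n points
  double hq = 0.0;
  for (int r = 0; r < q; ++r) hq -= xlog2x(static_cast<double>(cum[k][r]) / n);
  *hq_out = hq;

  // column contribution f(s, i) for clump range (s, i]
  const double dn = static_cast<double>(n);
  auto colf = [&](int s, int i) {
    const int np = cn[i] - cn[s];
    double v = -xlog2x(np / dn);
    for (int r = 0; r < q; ++r) v += xlog2x((cum[i][r] - cum[s][r]) / dn);
    return v;
  };

  const int tmax = std::min(p_max, k);
  // F[t][i]: best over partitions of first i clumps into exactly t columns
  std::vector<std::vector<double> > F(tmax + 1,
      std::vector<double>(k + 1, -std::numeric_limits<double>::infinity()));
  for (int i = 1; i <= k; ++i) F[1][i] = colf(0, i);
  for (int t = 2; t <= tmax; ++t)
    for (int i = t; i <= k; ++i)
      for (int s = t - 1; s < i; ++s) {
        const double cand = F[t - 1][s] + colf(s, i);
        if (cand > F[t][i]) F[t][i] = cand;
      }

  best.assign(p_max + 1, -std::numeric_limits<double>::infinity());
  double run = -std::numeric_limits<double>::infinity();
  for (int t = 1; t <= p_max; ++t) {
    if (t <= tmax && F[t][k] > run) run = F[t][k];
    best[t] = run;   // <= t columns
  }
}

struct MicResult {
  double mic;
  NumericMatrix M;
};

MicResult mic_engine(const std::vector<double>& x,
                     const std::vector<double>& y,
                     int B, int clump_factor) {
  const int n = static_cast<int>(x.size());
  const int kmax = B / 2;           // largest bin count on either axis
  NumericMatrix M(kmax + 1, kmax + 1);
  std::fill(M.begin(), M.end(), NA_REAL);

  // orderings by each axis
  std::vector<int> ox(n), oy(n);
  for (int i = 0; i < n; ++i) ox[i] = oy[i] = i;
  std::sort(ox.begin(), ox.end(), [&](int a, int b) { return x[a] < x[b]; });
  std::sort(oy.begin(), oy.end(), [&](int a, int b) { return y[a] < y[b]; });

  double mic = 0.0;
  for (int orient = 0; orient < 2; ++orient) {
    // orient 0: equipartition y into q rows, optimise x columns -> (p, q)
    // orient 1: swapped                                        -> (q, p)
    const std::vector<double>& rv = (orient == 0) ? y : x;
    const std::vector<int>& ro = (orient == 0) ? oy : ox;
    const std::vector<double>& cv = (orient == 0) ? x : y;
    const std::vector<int>& co = (orient == 0) ? ox : oy;

    std::vector<double> rsorted(n);
    for (int i = 0; i < n; ++i) rsorted[i] = rv[ro[i]];

    for (int q = 2; q <= kmax; ++q) {
      const int p_max = B / q;
      if (p_max < 2) break;
      std::vector<int> bin_sorted = equipartition_sorted(rsorted, q);
      std::vector<int> row(n);
      for (int i = 0; i < n; ++i) row[ro[i]] = bin_sorted[i];

      std::vector<double> best;
      double hq = 0.0;
      const int cap = (clump_factor > 0) ? clump_factor * p_max : 0;
      optimize_axis(cv, co, row, q, p_max, cap, best, &hq);

      for (int p = 2; p <= p_max; ++p) {
        if (!std::isfinite(best[p])) continue;
        double I = best[p] + hq;
        if (I < 0.0) I = 0.0;       // numeric guard
        const double val = I / std::log2(static_cast<double>(std::min(p, q)));
        const int a = (orient == 0) ? p : q;
        const int b = (orient == 0) ? q : p;
        if (!R_finite(M(a, b)) || val > M(a, b)) M(a, b) = val;
        if (val > mic) mic = val;
      }
    }
  }
  if (mic > 1.0) mic = 1.0;   // guard against tiny fp excess
  MicResult res;
  res.mic = mic;
  res.M = M;
  return res;
}

int grid_bound(int n, double b_exponent) {
  int B = static_cast<int>(std::floor(std::pow(static_cast<double>(n),
                                               b_exponent)));
  if (B < 4) B = 4;
  return B;
}

}  // namespace

// [[Rcpp::export]]
List mic_cpp(NumericVector x, NumericVector y, double b_exponent,
             int max_clumps_factor) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  const int B = grid_bound(n, b_exponent);
  MicResult r = mic_engine(xv, yv, B, max_clumps_factor);
  return List::create(_["mic"] = r.mic, _["matrix"] = r.M, _["B"] = B);
}

// All unordered column pairs of a matrix; returns a flat vector in
// combn-order (pair (i, j), i < j, j fastest ... actually i outer).
// [[Rcpp::export]]
NumericVector mic_pairs_cpp(NumericMatrix m, double b_exponent,
                            int max_clumps_factor) {
  const int n = m.nrow(), p = m.ncol();
  const int B = grid_bound(n, b_exponent);
  NumericVector out(p * (p - 1) / 2);
  std::vector<double> xi(n), xj(n);
  int idx = 0;
  for (int i = 0; i < p; ++i) {
    for (int k = 0; k < n; ++k) xi[k] = m(k, i);
    for (int j = i + 1; j < p; ++j) {
      for (int k = 0; k < n; ++k) xj[k] = m(k, j);
      out[idx++] = mic_engine(xi, xj, B, max_clumps_factor).mic;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Shared permutation null: n_perm MIC scores between independently permuted
// column pairs drawn from the table.  Permutations are supplied from R so
// that all randomness goes through R's RNG.
// [[Rcpp::export]]
NumericVector mic_null_cpp(NumericMatrix m, IntegerMatrix cols,
                           IntegerMatrix perms, double b_exponent,
                           int max_clumps_factor) {
  const int n = m.nrow();
  const int n_perm = cols.nrow();
  const int B = grid_bound(n, b_exponent);
  NumericVector out(n_perm);
  std::vector<double> xv(n), yv(n);
  for (int b = 0; b < n_perm; ++b) {
    const int ci = cols(b, 0) - 1, cj = cols(b, 1) - 1;
    for (int k = 0; k < n; ++k) {
      xv[k] = m(perms(b, k) - 1, ci);
      yv[k] = m(k, cj);
    }
    out[b] = mic_engine(xv, yv, B, max_clumps_factor).mic;
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
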