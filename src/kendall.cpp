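#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Kendall's tau-a: (concordant - discordant) / (n*(n-1)/2).
// Pairs tied in either input fall in the denominator but in neither tally.
// Knight's O(n log n) scheme: sort by (x, y), count discordances as merge
// sort inversions in y, and correct the concordant count for ties.

namespace {

// Number of inversions in v, counted by an iterative bottom-up merge sort.
double merge_count_inversions(std::vector<double>& v) {
  const size_t n = v.size();
  std::vector<double> buf(n);
  double inversions = 0.0;
  for (size_t width = 1; width < n; width *= 2) {
    for (size_t lo = 0; lo < n; lo += 2 * width) {
      size_t mid = std::min(lo + width, n);
      size_t hi = std::min(lo + 2 * width, n);
      if (mid >= hi) continue;
      size_t i = lo, j = mid, k = lo;
      while (i < mid && j < hi) {
        if (v[j] < v[i]) {          // strict: equal keys are not inversions
          inversions += static_cast<double>(mid - i);
          buf[k++] = v[j++];
        } else {
          buf[k++] = v[i++];
        }
      }
      while (i < mid) buf[k++] = v[i++];
      while (j < hi) buf[k++] = v[j++];
      std::copy(buf.begin() + lo, buf.begin() + hi, v.begin() + lo);
    }
  }
  return inversions;
}

// Sum over tie groups of t*(t-1)/2, for a sorted range comparator.
template <typename Pred>
double tie_pair_count(const std::vector<size_t>& idx, Pred same) {
  double total = 0.0;
  size_t run = 1;
  for (size_t i = 1; i < idx.size(); ++i) {
    if (same(idx[i - 1], idx[i])) {
      ++run;
    } else {
      total += 0.5 * run * (run - 1);
      run = 1;
    }
  }
  total += 0.5 * run * (run - 1);
  return total;
}

}  // namespace

// [[Rcpp::export]]
double kendall_tau_a_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  const size_t n = x.size();
  if (y.size() != static_cast<R_xlen_t>(n))
    Rcpp::stop("length mismatch: %d vs %d", (int)n, (int)y.size());
  if (n < 2) Rcpp::stop("kendall_tau_a needs at least 2 values");

  std::vector<size_t> idx(n);
  for (size_t i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  // tie counts: in x, in y, and jointly in (x, y)
  double n1 = tie_pair_count(idx, [&](size_t a, size_t b) {
    return x[a] == x[b];
  });
  double n3 = tie_pair_count(idx, [&](size_t a, size_t b) {
    return x[a] == x[b] && y[a] == y[b];
  });
  std::vector<size_t> yidx(idx);
  std::sort(yidx.begin(), yidx.end(), [&](size_t a, size_t b) {
    return y[a] < y[b];
  });
  double n2 = tie_pair_count(yidx, [&](size_t a, size_t b) {
    return y[a] == y[b];
  });

  std::vector<double> ysorted(n);
  for (size_t i = 0; i < n; ++i) ysorted[i] = y[idx[i]];
  double discordant = merge_count_inversions(ysorted);

  const double n0 = 0.5 * static_cast<double>(n) * (n - 1);
  // pairs untied in both = n0 - n1 - n2 + n3; of those, `discordant` are
  // discordant and the rest concordant
  const double concordant = n0 - n1 - n2 + n3 - discordant;
  return (concordant - discordant) / n0;
}
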