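#include <Rcpp.h>
using namespace Rcpp;

// Fenwick (binary indexed) tree over abundances so that weighted draws
// and +-1 updates are O(log S) per Moran step.
struct Fenwick {
  int n;
  std::vector<long> t;
  Fenwick(int n_) : n(n_), t(n_ + 1, 0) {}
  void add(int i, long v) { for (++i; i <= n; i += i & -i) t[i] += v; }
  // smallest index with prefix sum > v
  int find(double v) const {
    int pos = 0;
    int logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << (logn - 1); pw > 0; pw >>= 1) {
      if (pos + pw <= n && t[pos + pw] <= v) {
        pos += pw;
        v -= t[pos];
      }
    }
    return pos;  // 0-based index
  }
};

// Hubbell/Moran zero-sum death-replacement dynamics for one local
// community.  Each step kills one individual chosen uniformly; the
// replacement is an immigrant drawn from the source pool with
// probability m (proportional to pool frequencies p), otherwise a local
// birth proportional to current local abundance.  Uses R's RNG so
// results are reproducible under set.seed().
//
// counts: initial abundances (length S, sum N); p: pool frequencies
// (sum 1); m: immigration probability; steps: number of update steps.
// [[Rcpp::export(name = ".moran_steps")]]
IntegerVector moran_steps(IntegerVector counts, NumericVector p,
                          double m, int steps) {
  const int S = counts.size();
  if (p.size() != S) stop("counts and p must have equal length");
  std::vector<double> cum(S);
  double tot = 0.0;
  for (int i = 0; i < S; ++i) { tot += p[i]; cum[i] = tot; }
  if (tot <= 0) stop("pool frequencies must sum to a positive value");

  Fenwick fw(S);
  long N = 0;
  for (int i = 0; i < S; ++i) {
    if (counts[i] < 0) stop("negative initial abundance");
    fw.add(i, counts[i]);
    N += counts[i];
  }
  if (N < 2) stop("community size must be >= 2");

  for (int t = 0; t < steps; ++t) {
    // death: uniform over individuals
    int i = fw.find(unif_rand() * (double)N);
    fw.add(i, -1);

    int j;
    if (unif_rand() < m) {
      // immigrant from the regional pool (static cumulative weights)
      double v = unif_rand() * tot;
      int lo = 0, hi = S - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum[mid] < v) lo = mid + 1; else hi = mid;
      }
      j = lo;
    } else {
      // local birth proportional to remaining abundances
      j = fw.find(unif_rand() * (double)(N - 1));
    }
    fw.add(j, 1);
  }

  IntegerVector out(S);
  // recover abundances from the tree by prefix differences
  long prev = 0;
  for (int i = 0; i < S; ++i) {
    long cumi = 0;
    for (int k = i + 1; k > 0; k -= k & -k) cumi += fw.t[k];
    out[i] = (int)(cumi - prev);
    prev = cumi;
  }
  return out;
}
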