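#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted between-sample mean nearest taxon distance for all
// sample pairs, computed against a (possibly relabelled) patristic
// distance matrix.  D is symmetric taxa x taxa; F is taxa x samples
// with column sums 1 over present taxa; perm is a 1-based taxon
// relabelling (identity for the observed value, random for the
// regional-pool null in betaNTI).
// [[Rcpp::export(name = ".bmntd_pairs")]]
NumericMatrix bmntd_pairs(NumericMatrix D, NumericMatrix F,
                          IntegerVector perm) {
  const int T = F.nrow(), S = F.ncol();
  if (D.nrow() != T || D.ncol() != T) stop("D must be taxa x taxa");
  if (perm.size() != T) stop("perm must have one entry per taxon");

  std::vector<std::vector<int>> pres(S);
  std::vector<bool> needed(T, false);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < T; ++i)
      if (F(i, s) > 0) { pres[s].push_back(i); needed[i] = true; }

  // ND[i + s*T] = min over j present in s of D[perm(i), perm(j)]
  std::vector<double> ND((size_t)T * S);
  const double *d = D.begin();
  for (int s = 0; s < S; ++s) {
    const std::vector<int> &P = pres[s];
    for (int i = 0; i < T; ++i) {
      if (!needed[i]) continue;
      // D symmetric: read down column perm(i) for cache locality
      const double *dcol = d + (size_t)T * (perm[i] - 1);
      double mn = R_PosInf;
      for (size_t a = 0; a < P.size(); ++a) {
        double v = dcol[perm[P[a]] - 1];
        if (v < mn) mn = v;
      }
      ND[(size_t)i + (size_t)s * T] = mn;
    }
  }

  NumericMatrix M(S, S);
  for (int k = 0; k < S - 1; ++k) {
    for (int l = k + 1; l < S; ++l) {
      double a = 0.0, b = 0.0;
      for (int i : pres[k]) a += F(i, k) * ND[(size_t)i + (size_t)l * T];
      for (int j : pres[l]) b += F(j, l) * ND[(size_t)j + (size_t)k * T];
      double v = 0.5 * (a + b);
      M(k, l) = v;
      M(l, k) = v;
    }
  }
  return M;
}
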