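#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) recursive inbreeding coefficients for a
// topologically sorted pedigree.  sire/dam are 1-based codes, 0 = unknown;
// every parent code must be smaller than its offspring's position.
//
// For animal i, diag(A)_i = sum_j L_j^2 d_j over the ancestors j of i
// (including i itself, L_i = 1), where L is accumulated by pushing half of
// each animal's coefficient onto its parents while walking ancestor ids in
// decreasing order, and d_j is the Mendelian sampling variance
//   d_j = 0.5 - 0.25 (F_s + F_d)         both parents known
//   d_j = 0.75 - 0.25 F_known            one parent known
//   d_j = 1                              founder.
// [[Rcpp::export]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n, 1.0), L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s > i || d > i)
      stop("pedigree is not topologically sorted at position %d", i + 1);
    double Fs = s ? F[s - 1] : 0.0, Fd = d ? F[d - 1] : 0.0;
    if (s && d)
      D[i] = 0.5 - 0.25 * (Fs + Fd);
    else if (s || d)
      D[i] = 0.75 - 0.25 * (s ? Fs : Fd);
    else
      D[i] = 1.0;
    if (!s && !d) {
      F[i] = 0.0;
      continue;
    }
    double acc = 0.0;
    L[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      L[j] = 0.0;
      acc += lj * lj * D[j];
      int sj = sire[j], dj = dam[j];
      if (sj) L[sj - 1] += 0.5 * lj;
      if (dj) L[dj - 1] += 0.5 * lj;
    }
    F[i] = acc - 1.0;
  }
  return F;
}
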