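#include <Rcpp.h>
using namespace Rcpp;

// Chromosome-wise permutation engine for the windowed pooled-heterozygosity
// scan. Sites must be sorted by position so that every window is the index
// range [win_lo, win_hi) into the count vectors; SNP positions stay fixed,
// so the window ranges are permutation-invariant and only the count pairs
// move.
//
// Each permutation is drawn by a Fisher-Yates pass over R's unif_rand(),
// i.e. the stream is owned by R's RNG and fully determined by set.seed();
// the test suite replays the identical draws with runif() in pure R.
//
// Returns, per permutation, the minimum Hp over the windows ("minima") and,
// per window, the number of permutations with Hp <= the observed value
// ("exceed", for per-window empirical P values).
// [[Rcpp::export]]
List perm_hp_stats(NumericVector nmaj, NumericVector nmin,
                   IntegerVector win_lo, IntegerVector win_hi,
                   int n_perm, NumericVector obs_hp) {
  const int n = nmaj.size();
  const int n_win = win_lo.size();
  NumericVector minima(n_perm);
  IntegerVector exceed(n_win);
  std::vector<int> pool(n), perm(n);
  std::vector<double> cmaj(n + 1), cmin(n + 1);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < n; ++i) pool[i] = i;
    int N = n;
    for (int i = 0; i < n; ++i) {
      const int j = static_cast<int>(N * unif_rand());
      perm[i] = pool[j];
      pool[j] = pool[--N];
    }
    cmaj[0] = 0.0;
    cmin[0] = 0.0;
    for (int i = 0; i < n; ++i) {
      cmaj[i + 1] = cmaj[i] + nmaj[perm[i]];
      cmin[i + 1] = cmin[i] + nmin[perm[i]];
    }
    double mn = R_PosInf;
    for (int w = 0; w < n_win; ++w) {
      const double smaj = cmaj[win_hi[w]] - cmaj[win_lo[w]];
      const double smin = cmin[win_hi[w]] - cmin[win_lo[w]];
      const double tot = smaj + smin;
      const double h = tot > 0 ? 2.0 * smaj * smin / (tot * tot) : NA_REAL;
      if (h < mn) mn = h;
      if (h <= obs_hp[w]) ++exceed[w];
    }
    minima[p] = mn;
  }
  return List::create(_["minima"] = minima, _["exceed"] = exceed);
}
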