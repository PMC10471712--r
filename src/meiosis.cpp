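#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Gamete formation under the Haldane model: per chromosome, the crossover
// count is Poisson(length in Morgans), crossover positions are uniform on the
// chromosome, and the starting chromatid is chosen with probability 1/2.
// No interference, no obligate chiasma; chromosomes segregate independently.
//
// Uses R's RNG so results are reproducible under set.seed().

// Fill `out` (pointer to m ints) with one recombinant haplotype of a parent
// whose haplotypes are given as contiguous arrays r1, r2 of length m.
static void one_gamete(const int* r1, const int* r2,
                       const IntegerVector& chr_first,
                       const IntegerVector& chr_last,
                       const NumericVector& pos_m, int* out) {
  const int n_chr = chr_first.size();
  std::vector<double> bp;
  for (int c = 0; c < n_chr; ++c) {
    const int a = chr_first[c], b = chr_last[c];   // 0-based inclusive
    const double start = pos_m[a];
    const double len = pos_m[b] - start;           // Morgans
    int cur = (unif_rand() < 0.5) ? 0 : 1;         // starting chromatid
    int k = (len > 0) ? static_cast<int>(R::rpois(len)) : 0;
    if (k == 0) {
      const int* h = cur ? r2 : r1;
      for (int l = a; l <= b; ++l) out[l] = h[l];
      continue;
    }
    bp.resize(k);
    for (int i = 0; i < k; ++i) bp[i] = start + unif_rand() * len;
    std::sort(bp.begin(), bp.end());
    int nxt = 0;
    for (int l = a; l <= b; ++l) {
      while (nxt < k && bp[nxt] <= pos_m[l]) { cur = 1 - cur; ++nxt; }
      out[l] = cur ? r2[l] : r1[l];
    }
  }
}

// Copy row `row` of a column-major matrix into a contiguous buffer.
static void copy_row(const IntegerMatrix& h, int row, int* out) {
  const int m = h.ncol(), n = h.nrow();
  const int* p = h.begin() + row;
  for (int l = 0; l < m; ++l) out[l] = p[static_cast<size_t>(l) * n];
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(IntegerMatrix h1, IntegerMatrix h2,
                          IntegerVector parent_rows, IntegerVector chr_first,
                          IntegerVector chr_last, NumericVector pos_m) {
  const int m = h1.ncol();
  const int n = parent_rows.size();
  IntegerMatrix g(n, m);
  std::vector<int> buf(m), r1(m), r2(m);
  int prev_row = -1;
  for (int i = 0; i < n; ++i) {
    const int row = parent_rows[i] - 1;
    if (row != prev_row) {  // consecutive draws from one parent reuse the copy
      copy_row(h1, row, r1.data());
      copy_row(h2, row, r2.data());
      prev_row = row;
    }
    one_gamete(r1.data(), r2.data(), chr_first, chr_last, pos_m, buf.data());
    int* gp = g.begin() + i;
    for (int l = 0; l < m; ++l) gp[static_cast<size_t>(l) * n] = buf[l];
  }
  return g;
}

// One round of random mating without selfing: n_off offspring, each from two
// distinct parents drawn uniformly. Returns list(h1, h2) of the offspring.
//' @noRd
// [[Rcpp::export]]
List cpp_random_mate(IntegerMatrix h1, IntegerMatrix h2, int n_off,
                     IntegerVector chr_first, IntegerVector chr_last,
                     NumericVector pos_m) {
  const int n_par = h1.nrow(), m = h1.ncol();
  IntegerMatrix o1(n_off, m), o2(n_off, m);
  std::vector<int> buf(m), r1(m), r2(m);
  for (int i = 0; i < n_off; ++i) {
    int p1 = static_cast<int>(unif_rand() * n_par);
    int p2 = static_cast<int>(unif_rand() * n_par);
    while (p2 == p1) p2 = static_cast<int>(unif_rand() * n_par);
    copy_row(h1, p1, r1.data());
    copy_row(h2, p1, r2.data());
    one_gamete(r1.data(), r2.data(), chr_first, chr_last, pos_m, buf.data());
    for (int l = 0; l < m; ++l) o1(i, l) = buf[l];
    copy_row(h1, p2, r1.data());
    copy_row(h2, p2, r2.data());
    one_gamete(r1.data(), r2.data(), chr_first, chr_last, pos_m, buf.data());
    for (int l = 0; l < m; ++l) o2(i, l) = buf[l];
  }
  return List::create(_["h1"] = o1, _["h2"] = o2);
}
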