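#include <Rcpp.h>
using namespace Rcpp;

static double g_stat(const std::vector<int> &g1, const std::vector<int> &g2,
                     int r, int c) {
  int n = g1.size();
  std::vector<double> tab(r * c, 0.0), rt(r, 0.0), ct(c, 0.0);
  for (int i = 0; i < n; ++i) {
    tab[(g1[i] - 1) * c + (g2[i] - 1)] += 1.0;
    rt[g1[i] - 1] += 1.0;
    ct[g2[i] - 1] += 1.0;
  }
  double G = 0.0;
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < c; ++j) {
      double o = tab[i * c + j];
      if (o > 0) G += 2.0 * o * log(o * n / (rt[i] * ct[j]));
    }
  return G;
}

static void shuffle_int(std::vector<int> &v) {
  for (int i = (int) v.size() - 1; i > 0; --i) {
    int j = (int)(R::unif_rand() * (i + 1));
    std::swap(v[i], v[j]);
  }
}

// Log-likelihood-ratio G test of association between the single-locus
// genotype categories g1 and g2 (1-based codes over r and c classes),
// with p from `reps` permutations of g2 among individuals.
// Returns c(G_observed, p) with p = (hits + 1) / (reps + 1).
// [[Rcpp::export]]
NumericVector cpp_ld_gtest_perm(IntegerVector g1, IntegerVector g2,
                                int r, int c, int reps) {
  std::vector<int> a(g1.begin(), g1.end()), b(g2.begin(), g2.end());
  double obs = g_stat(a, b, r, c);
  int hits = 0;
  for (int rep = 0; rep < reps; ++rep) {
    shuffle_int(b);
    if (g_stat(a, b, r, c) >= obs - 1e-12) ++hits;
  }
  NumericVector out = NumericVector::create(obs, (double)(hits + 1) / (reps + 1));
  return out;
}

// Weir-Cockerham multilocus f (F_IS) for one population.
// Each element of `loci` is the vector of non-missing allele codes at one
// locus, consecutive pairs forming individuals. Components b (among
// individuals) and c (within individuals) are summed over loci and alleles
// before the ratio f = 1 - sum(c) / sum(b + c).
static double wc_fis(const std::vector<std::vector<int>> &loci,
                     bool &defined) {
  double B = 0.0, C = 0.0;
  for (const auto &copies : loci) {
    int n = copies.size() / 2;
    if (n < 2) continue;
    std::map<int, int> cnt;
    for (int x : copies) cnt[x]++;
    if (cnt.size() < 2) continue;
    for (auto &kv : cnt) {
      int a = kv.first;
      double p = (double) kv.second / (2.0 * n);
      int nhet = 0;
      for (int i = 0; i < n; ++i) {
        int a1 = copies[2 * i], a2 = copies[2 * i + 1];
        if ((a1 == a) != (a2 == a)) ++nhet;
      }
      double h = (double) nhet / n;
      B += (double) n / (n - 1) * (p * (1 - p) - (2.0 * n - 1) / (4.0 * n) * h);
      C += h / 2.0;
    }
  }
  if (B + C <= 0) { defined = false; return NA_REAL; }
  defined = true;
  return 1.0 - C / (B + C);
}

// Two-sided permutation test of F_IS = 0: allele copies are shuffled among
// individuals independently within each locus. Returns c(fis, p).
// [[Rcpp::export]]
NumericVector cpp_hwe_fis_perm(List loci_copies, int reps) {
  int L = loci_copies.size();
  std::vector<std::vector<int>> loci(L);
  for (int l = 0; l < L; ++l) {
    IntegerVector v = loci_copies[l];
    loci[l].assign(v.begin(), v.end());
  }
  bool ok;
  double obs = wc_fis(loci, ok);
  if (!ok) return NumericVector::create(NA_REAL, 1.0);
  int hits = 0;
  for (int rep = 0; rep < reps; ++rep) {
    for (int l = 0; l < L; ++l) shuffle_int(loci[l]);
    bool ok2;
    double f = wc_fis(loci, ok2);
    if (ok2 && std::abs(f) >= std::abs(obs) - 1e-12) ++hits;
  }
  return NumericVector::create(obs, (double)(hits + 1) / (reps + 1));
}

// Monte-Carlo null distribution of the homozygote count under HWE:
// `reps` samples of n genotypes assembled from the allele frequencies
// `freq`. Returns the simulated homozygote counts.
// [[Rcpp::export]]
IntegerVector cpp_hom_count_mc(NumericVector freq, int n, int reps) {
  int A = freq.size();
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    int hom = 0;
    for (int i = 0; i < n; ++i) {
      double u1 = R::unif_rand(), u2 = R::unif_rand(), acc = 0.0;
      int a1 = A - 1, a2 = A - 1;
      for (int a = 0; a < A; ++a) { acc += freq[a]; if (u1 <= acc) { a1 = a; break; } }
      acc = 0.0;
      for (int a = 0; a < A; ++a) { acc += freq[a]; if (u2 <= acc) { a2 = a; break; } }
      if (a1 == a2) ++hom;
    }
    out[r] = hom;
  }
  return out;
}
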