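#include <Rcpp.h>
using namespace Rcpp;

static inline int fwd_mutate(int state, int model, double p_multi,
                             double p_geom, int &counter) {
  if (model == 0) return ++counter; // IAM: fresh allele code
  int step = 1;
  if (model == 2 && R::unif_rand() < p_multi) {
    step = 1 + (int) R::rgeom(p_geom);
  }
  if (R::unif_rand() < 0.5) step = -step;
  int s = state + step;
  if (s < 2) s = 4 - s; // reflecting boundary at 2 repeat units
  return s;
}

// Forward-time Wright-Fisher simulation of D demes over the census
// trajectory `census` (generations x demes), with row-stochastic migration
// (mig[d,s] = probability that an offspring born in deme d draws its
// parents from deme s), partial selfing, and per-transmission mutation.
// model: 0 = IAM, 1 = SMM, 2 = TPM. IAM counter starts at iam_base.
// Returns the final-generation allele matrices (one per deme, rows =
// individuals, columns = 2 x loci, locus-major pairs) plus realized
// migrant counts per generation x deme.
// [[Rcpp::export]]
List cpp_forward_sim(IntegerMatrix census, NumericMatrix mig, double selfing,
                     int n_loci, double mu, int model, double p_multi,
                     double p_geom, int founder_allele, int iam_base) {
  int n_gen = census.nrow(), D = census.ncol();
  int counter = iam_base;
  std::vector<IntegerMatrix> pop(D), nxt(D);
  for (int d = 0; d < D; ++d) {
    pop[d] = IntegerMatrix(census(0, d), 2 * n_loci);
    std::fill(pop[d].begin(), pop[d].end(), founder_allele);
  }
  IntegerMatrix migrants(n_gen, D);

  for (int g = 1; g < n_gen; ++g) {
    for (int d = 0; d < D; ++d) {
      int N = census(g, d);
      IntegerMatrix newpop(N, 2 * n_loci);
      for (int i = 0; i < N; ++i) {
        // deme of parents
        double u = R::unif_rand(), acc = 0.0;
        int src = D - 1;
        for (int s = 0; s < D; ++s) {
          acc += mig(d, s);
          if (u <= acc) { src = s; break; }
        }
        if (src != d) migrants(g, d)++;
        int Ns = census(g - 1, src);
        int p1 = (int)(R::unif_rand() * Ns);
        int p2 = (R::unif_rand() < selfing) ? p1 : (int)(R::unif_rand() * Ns);
        for (int l = 0; l < n_loci; ++l) {
          int a1 = pop[src](p1, 2 * l + (R::unif_rand() < 0.5 ? 1 : 0));
          int a2 = pop[src](p2, 2 * l + (R::unif_rand() < 0.5 ? 1 : 0));
          if (R::unif_rand() < mu) a1 = fwd_mutate(a1, model, p_multi, p_geom, counter);
          if (R::unif_rand() < mu) a2 = fwd_mutate(a2, model, p_multi, p_geom, counter);
          newpop(i, 2 * l) = a1;
          newpop(i, 2 * l + 1) = a2;
        }
      }
      nxt[d] = newpop;
    }
    for (int d = 0; d < D; ++d) pop[d] = nxt[d];
  }
  List out(D);
  for (int d = 0; d < D; ++d) out[d] = pop[d];
  return List::create(_["demes"] = out, _["migrants"] = migrants);
}
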