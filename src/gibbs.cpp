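#include <Rcpp.h>
using namespace Rcpp;

// Dirichlet draw into `out` (length k) with parameters alpha[]
static void rdirichlet(const std::vector<double> &alpha, std::vector<double> &out) {
  double s = 0.0;
  size_t k = alpha.size();
  for (size_t i = 0; i < k; ++i) {
    out[i] = R::rgamma(alpha[i], 1.0);
    s += out[i];
  }
  if (s <= 0) {
    for (size_t i = 0; i < k; ++i) out[i] = 1.0 / k;
  } else {
    for (size_t i = 0; i < k; ++i) out[i] /= s;
  }
}

// Gibbs sampler for the independent-allele-frequency admixture model.
// geno: n x 2L matrix of allele indices per locus (1-based, 0 = missing,
// locus-major pairs). n_alleles[l] = number of distinct alleles at locus l.
// Latent origins z of each allele copy are sampled given (Q, P);
// q_i ~ Dirichlet(alpha + per-cluster copy counts);
// p_{k,l} ~ Dirichlet(lambda + per-allele counts assigned to k);
// alpha is updated by a Metropolis step under a Uniform(0, 10) prior when
// infer_alpha is true. Returns post-burn-in means of Q and P, the data
// log-likelihood trace, and the alpha trace.
// [[Rcpp::export]]
List cpp_admixture_gibbs(IntegerMatrix geno, IntegerVector n_alleles, int K,
                         double lambda, double alpha_init, bool infer_alpha,
                         double alpha_sd, int burnin, int iters) {
  int n = geno.nrow(), L = n_alleles.size();
  double alpha = alpha_init;
  // z[i][c] for copy c (2L per individual); -1 = missing
  std::vector<std::vector<int>> z(n, std::vector<int>(2 * L, -1));
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 2 * L; ++c)
      if (geno(i, c) > 0) z[i][c] = (int)(R::unif_rand() * K);

  // P[k][l] = vector over alleles; Q[i] over clusters
  std::vector<std::vector<std::vector<double>>> P(
      K, std::vector<std::vector<double>>(L));
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) P[k][l].resize(n_alleles[l]);
  std::vector<std::vector<double>> Q(n, std::vector<double>(K));

  NumericMatrix Q_mean(n, K);
  List P_mean(L);
  std::vector<NumericMatrix> Pm(L);
  for (int l = 0; l < L; ++l) Pm[l] = NumericMatrix(K, n_alleles[l]);
  NumericVector loglik(iters), alpha_trace(iters);
  int n_keep = 0;
  std::vector<double> dir_par, dir_out, probs(K);

  for (int it = 0; it < iters; ++it) {
    // P | z
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        int A = n_alleles[l];
        dir_par.assign(A, lambda);
        for (int i = 0; i < n; ++i)
          for (int c = 2 * l; c < 2 * l + 2; ++c)
            if (z[i][c] == k) dir_par[geno(i, c) - 1] += 1.0;
        dir_out.resize(A);
        rdirichlet(dir_par, dir_out);
        P[k][l] = dir_out;
      }
    }
    // Q | z
    for (int i = 0; i < n; ++i) {
      dir_par.assign(K, alpha);
      for (int c = 0; c < 2 * L; ++c)
        if (z[i][c] >= 0) dir_par[z[i][c]] += 1.0;
      dir_out.resize(K);
      rdirichlet(dir_par, dir_out);
      Q[i] = dir_out;
    }
    // z | Q, P and the data log-likelihood at the current (Q, P)
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 2 * l; c < 2 * l + 2; ++c) {
          int a = geno(i, c);
          if (a == 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            probs[k] = Q[i][k] * P[k][l][a - 1];
            tot += probs[k];
          }
          ll += log(tot);
          double u = R::unif_rand() * tot, acc = 0.0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += probs[k];
            if (u <= acc) { pick = k; break; }
          }
          z[i][c] = pick;
        }
      }
    }
    loglik[it] = ll;
    // alpha | Q (Metropolis, Uniform(0, 10) prior)
    if (infer_alpha && K > 1) {
      double prop = alpha + R::norm_rand() * alpha_sd;
      if (prop > 0 && prop < 10) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slq += log(std::max(Q[i][k], 1e-300));
        double cur = n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) + (alpha - 1) * slq;
        double nxt = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) + (prop - 1) * slq;
        if (log(R::unif_rand()) < nxt - cur) alpha = prop;
      }
    }
    alpha_trace[it] = alpha;
    // accumulate post-burn-in means
    if (it >= burnin) {
      ++n_keep;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Q_mean(i, k) += Q[i][k];
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          for (int a = 0; a < n_alleles[l]; ++a) Pm[l](k, a) += P[k][l][a];
    }
  }
  if (n_keep > 0) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) Q_mean(i, k) /= n_keep;
    for (int l = 0; l < L; ++l) {
      for (int k = 0; k < K; ++k)
        for (int a = 0; a < n_alleles[l]; ++a) Pm[l](k, a) /= n_keep;
    }
  }
  for (int l = 0; l < L; ++l) P_mean[l] = Pm[l];
  return List::create(_["Q"] = Q_mean, _["P"] = P_mean, _["loglik"] = loglik,
                      _["alpha"] = alpha_trace);
}
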