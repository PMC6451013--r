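#include <Rcpp.h>
using namespace Rcpp;

// One mutation step under the configured microsatellite model.
// model: 0 = IAM, 1 = SMM, 2 = TPM. `counter` supplies fresh IAM states.
static inline int mutate_state(int state, int model, double p_multi,
                               double p_geom, int &counter) {
  if (model == 0) return ++counter;
  int step = 1;
  if (model == 2 && R::unif_rand() < p_multi) {
    step = 1 + (int) R::rgeom(p_geom);
  }
  if (R::unif_rand() < 0.5) step = -step;
  int s = state + step;
  if (s < 2) s = 4 - s; // reflecting boundary at 2 repeat units
  return s;
}

// Simulate `reps` neutral coalescent genealogies of n gene copies with
// mutation parameter theta (= 4 Ne mu), drop mutations on the branches,
// and return the realized allele count k and plug-in gene diversity
// 1 - sum(p^2) of each replicate.
// [[Rcpp::export]]
List cpp_coalescent_sim(int n, double theta, int model, double p_multi,
                        double p_geom, int reps) {
  IntegerVector k_out(reps);
  NumericVector het_out(reps);
  int n_nodes = 2 * n - 1;
  std::vector<int> left(n_nodes, -1), right(n_nodes, -1);
  std::vector<double> t_node(n_nodes), blen(n_nodes);
  std::vector<int> active(n), state(n_nodes);
  std::vector<int> stack(n_nodes);

  for (int r = 0; r < reps; ++r) {
    // Kingman genealogy: random pair merges with exponential waiting times
    double t = 0.0;
    for (int i = 0; i < n; ++i) { active[i] = i; t_node[i] = 0.0; }
    int n_active = n, next_node = n;
    while (n_active > 1) {
      double rate = n_active * (n_active - 1) / 2.0;
      t += R::exp_rand() / rate;
      int i = (int)(R::unif_rand() * n_active);
      int j = (int)(R::unif_rand() * (n_active - 1));
      if (j >= i) ++j;
      int a = active[i], b = active[j];
      int p = next_node++;
      t_node[p] = t;
      left[p] = a; right[p] = b;
      blen[a] = t - t_node[a];
      blen[b] = t - t_node[b];
      // replace the two merged lineages by their parent
      if (i > j) std::swap(i, j);
      active[i] = p;
      active[j] = active[n_active - 1];
      --n_active;
    }
    int root = next_node - 1;
    // pre-order pass from the root applying Poisson numbers of mutations
    int counter = 0;
    state[root] = 1000;
    int top = 0;
    stack[top++] = root;
    while (top > 0) {
      int v = stack[--top];
      if (left[v] < 0) continue;
      for (int c : {left[v], right[v]}) {
        int nm = (int) R::rpois(0.5 * theta * blen[c]);
        int s = state[v];
        for (int m = 0; m < nm; ++m) s = mutate_state(s, model, p_multi, p_geom, counter);
        state[c] = s;
        stack[top++] = c;
      }
    }
    // tip allele configuration
    std::map<int, int> tab;
    for (int i = 0; i < n; ++i) tab[state[i]]++;
    double ssq = 0.0;
    for (auto &kv : tab) {
      double p = (double) kv.second / n;
      ssq += p * p;
    }
    k_out[r] = (int) tab.size();
    het_out[r] = 1.0 - ssq;
    // reset tree arrays for next replicate
    for (int v = n; v < n_nodes; ++v) { left[v] = right[v] = -1; }
  }
  return List::create(_["k"] = k_out, _["het"] = het_out);
}
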