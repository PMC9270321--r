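#include <Rcpp.h>
using namespace Rcpp;

// Single-chain single-site Gibbs sampler for the {0,1} Ising model
// P(x) propto exp(sum_i tau_i x_i + sum_{i<j} theta_ij x_i x_j).
// Full conditional: P(x_i = 1 | rest) = logistic(tau_i + sum_j theta_ij x_j).
// One sweep updates every site once in index order. The chain is advanced
// `burn_in` sweeps, then a row is recorded every `thin` sweeps. Uses R's RNG
// so results are reproducible under set.seed().

// [[Rcpp::export(name = ".ising_gibbs_chain")]]
IntegerMatrix ising_gibbs_chain(NumericMatrix theta, NumericVector tau,
                                int n, int burn_in, int thin) {
  const int p = theta.nrow();
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  for (int j = 0; j < p; ++j) x[j] = (unif_rand() < 0.5) ? 1 : 0;

  long total = (long)burn_in + (long)n * thin;
  int kept = 0;
  for (long sweep = 1; sweep <= total && kept < n; ++sweep) {
    for (int j = 0; j < p; ++j) {
      double e = tau[j];
      for (int k = 0; k < p; ++k)
        if (x[k]) e += theta(j, k);
      double pr = 1.0 / (1.0 + std::exp(-e));
      x[j] = (unif_rand() < pr) ? 1 : 0;
    }
    if (sweep > burn_in && ((sweep - burn_in) % thin == 0)) {
      for (int j = 0; j < p; ++j) out(kept, j) = x[j];
      ++kept;
    }
  }
  return out;
}
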