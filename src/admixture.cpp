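#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with K clusters:
//   z_ilc | Q,P  ~ Categorical( Q[i,k] * P[k, l, x_ilc] )
//   P[k,l,.]     ~ Dirichlet(lambda + allele counts assigned to k)
//   Q[i,.]       ~ Dirichlet(alpha + copy counts of i assigned to each k)
// X: n x 2L matrix of allele indices (1-based within locus, 0 = missing).
// Alleles of locus l live in columns off[l] .. off[l]+nAlleles[l]-1 of P.
// Uses R's RNG so results are reproducible under set.seed().

// Marsaglia-Tsang gamma(shape, 1) sampler on R's uniform/normal streams;
// much faster than R::rgamma for the millions of Dirichlet draws per chain.
static double rgamma_fast(double a) {
  if (a < 1.0) {
    double u = unif_rand();
    return rgamma_fast(a + 1.0) * std::pow(u, 1.0 / a);
  }
  const double d = a - 1.0 / 3.0;
  const double c = 1.0 / (3.0 * std::sqrt(d));
  for (;;) {
    double x, v;
    do { x = norm_rand(); v = 1.0 + c * x; } while (v <= 0.0);
    v = v * v * v;
    double u = unif_rand();
    if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
    if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
  }
}

// [[Rcpp::export]]
List gibbs_admixture(IntegerMatrix X, IntegerVector nAlleles, int K,
                     int burnin, int n_iter, double alpha, double lambda) {
  const int n = X.nrow();
  const int L = nAlleles.size();
  if (X.ncol() != 2 * L) stop("X must have 2 columns per locus");
  std::vector<int> off(L);
  int A = 0;
  for (int l = 0; l < L; ++l) { off[l] = A; A += nAlleles[l]; }

  NumericMatrix P(K, A), Q(n, K);
  NumericMatrix Psum(K, A), Qsum(n, K);
  IntegerMatrix Z(n, 2 * L);
  NumericVector lnp(n_iter);

  // random initial assignments
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 2 * L; ++c)
      Z(i, c) = (int)(unif_rand() * K);

  std::vector<double> prob(K);
  for (int t = 0; t < burnin + n_iter; ++t) {
    // P | Z : Dirichlet(lambda + counts)
    std::vector<double> cnt((size_t)K * A, 0.0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 2 * L; ++c) {
        int a = X(i, c);
        if (a > 0) cnt[(size_t)Z(i, c) * A + off[c / 2] + a - 1] += 1.0;
      }
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < nAlleles[l]; ++a) {
          double g = rgamma_fast(lambda + cnt[(size_t)k * A + off[l] + a]);
          P(k, off[l] + a) = g;
          s += g;
        }
        for (int a = 0; a < nAlleles[l]; ++a) P(k, off[l] + a) /= s;
      }
    // Q | Z : Dirichlet(alpha + per-individual cluster counts)
    for (int i = 0; i < n; ++i) {
      std::vector<double> nk(K, 0.0);
      for (int c = 0; c < 2 * L; ++c)
        if (X(i, c) > 0) nk[Z(i, c)] += 1.0;
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = rgamma_fast(alpha + nk[k]);
        Q(i, k) = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }
    // Z | Q,P ; the per-copy normalizer is the observed-data likelihood term
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 2 * L; ++c) {
        int a = X(i, c);
        if (a == 0) continue;
        int col = off[c / 2] + a - 1;
        double s = 0.0;
        for (int k = 0; k < K; ++k) { prob[k] = Q(i, k) * P(k, col); s += prob[k]; }
        ll += std::log(s);
        double u = unif_rand() * s, acc = 0.0;
        int z = K - 1;
        for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { z = k; break; } }
        Z(i, c) = z;
      }
    if (t >= burnin) {
      lnp[t - burnin] = ll;
      Qsum += Q;
      Psum += P;
    }
  }
  return List::create(_["Q"] = Qsum / (double)n_iter,
                      _["P"] = Psum / (double)n_iter,
                      _["lnp_trace"] = lnp);
}
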