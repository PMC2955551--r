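#include <Rcpp.h>
using namespace Rcpp;

// Gibbs updates for the admixture model: each diploid gene copy carries a
// latent cluster assignment z; cluster allele frequencies P and individual
// ancestry proportions Q have Dirichlet full conditionals; the Dirichlet
// admixture parameter alpha gets a Metropolis step with a uniform prior on
// (0, alpha_max]. Gene copies are passed as parallel vectors over
// non-missing calls only: `ind` (1-based individual) and `fa` (1-based
// flattened locus-allele column); `locus_of_flat` maps flat columns back to
// loci so P rows renormalize within each locus block.

static void update_z_core(const NumericMatrix &Q, const NumericMatrix &P,
                          const IntegerVector &ind, const IntegerVector &fa,
                          IntegerVector &z, double &loglik) {
  const int ncop = ind.size(), K = Q.ncol();
  std::vector<double> w(K);
  loglik = 0.0;
  for (int c = 0; c < ncop; ++c) {
    const int i = ind[c] - 1, j = fa[c] - 1;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      w[k] = Q(i, k) * P(k, j);
      tot += w[k];
    }
    if (!(tot > 0.0))
      stop("zero assignment probability for a gene copy (degenerate state)");
    loglik += std::log(tot);
    double u = R::runif(0.0, tot);
    int k = 0;
    double cum = w[0];
    while (k < K - 1 && u > cum) cum += w[++k];
    z[c] = k + 1;
  }
}

static void update_p_core(const IntegerVector &z, const IntegerVector &fa,
                          const IntegerVector &locus_of_flat, int K,
                          double lambda, NumericMatrix &P) {
  const int Atot = locus_of_flat.size(), ncop = z.size();
  std::vector<double> cnt((size_t)K * Atot, 0.0);
  for (int c = 0; c < ncop; ++c) cnt[(size_t)(z[c] - 1) * Atot + (fa[c] - 1)] += 1.0;
  int L = 0;
  for (int j = 0; j < Atot; ++j) L = std::max(L, locus_of_flat[j]);
  std::vector<double> rowsum((size_t)K * L);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < Atot; ++j) {
      double g = R::rgamma(lambda + cnt[(size_t)k * Atot + j], 1.0);
      if (g < 1e-300) g = 1e-300;
      P(k, j) = g;
    }
    std::fill(rowsum.begin() + (size_t)k * L, rowsum.begin() + (size_t)(k + 1) * L, 0.0);
    for (int j = 0; j < Atot; ++j)
      rowsum[(size_t)k * L + (locus_of_flat[j] - 1)] += P(k, j);
    for (int j = 0; j < Atot; ++j)
      P(k, j) /= rowsum[(size_t)k * L + (locus_of_flat[j] - 1)];
  }
}

static void update_q_core(const IntegerVector &z, const IntegerVector &ind,
                          int N, int K, const NumericVector &alpha,
                          NumericMatrix &Q) {
  const int ncop = z.size();
  std::vector<double> m((size_t)N * K, 0.0);
  for (int c = 0; c < ncop; ++c) m[(size_t)(ind[c] - 1) * K + (z[c] - 1)] += 1.0;
  for (int i = 0; i < N; ++i) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double g = R::rgamma(alpha[k] + m[(size_t)i * K + k], 1.0);
      if (g < 1e-300) g = 1e-300;
      Q(i, k) = g;
      tot += g;
    }
    for (int k = 0; k < K; ++k) Q(i, k) /= tot;
  }
}

// Metropolis update of alpha given Q; slq[k] = sum_i log Q(i, k)
static void update_alpha_core(const NumericMatrix &Q, NumericVector &alpha,
                              double sd, double amax, bool separate) {
  const int N = Q.nrow(), K = Q.ncol();
  std::vector<double> slq(K, 0.0);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) slq[k] += std::log(Q(i, k));
  if (separate) {
    for (int k = 0; k < K; ++k) {
      double cur = alpha[k];
      double prop = cur + R::norm_rand() * sd;
      if (prop <= 0.0 || prop > amax) continue;  // outside the prior: reject
      double S = 0.0;
      for (int kk = 0; kk < K; ++kk) S += alpha[kk];
      double Sp = S - cur + prop;
      double logr = N * (R::lgammafn(Sp) - R::lgammafn(S) -
                         R::lgammafn(prop) + R::lgammafn(cur)) +
                    (prop - cur) * slq[k];
      if (logr >= 0.0 || R::unif_rand() < std::exp(logr)) alpha[k] = prop;
    }
  } else {
    double cur = alpha[0];
    double prop = cur + R::norm_rand() * sd;
    if (prop <= 0.0 || prop > amax) return;
    double slq_all = 0.0;
    for (int k = 0; k < K; ++k) slq_all += slq[k];
    double logr = N * (R::lgammafn(K * prop) - R::lgammafn(K * cur) -
                       K * (R::lgammafn(prop) - R::lgammafn(cur))) +
                  (prop - cur) * slq_all;
    if (logr >= 0.0 || R::unif_rand() < std::exp(logr))
      for (int k = 0; k < K; ++k) alpha[k] = prop;
  }
}

// [[Rcpp::export(.cpp_update_z)]]
List cpp_update_z(NumericMatrix Q, NumericMatrix P, IntegerVector ind,
                  IntegerVector fa) {
  IntegerVector z(ind.size());
  double loglik = 0.0;
  update_z_core(Q, P, ind, fa, z, loglik);
  return List::create(_["z"] = z, _["loglik"] = loglik);
}

// [[Rcpp::export(.cpp_update_p)]]
NumericMatrix cpp_update_p(IntegerVector z, IntegerVector fa,
                           IntegerVector locus_of_flat, int K, double lambda) {
  NumericMatrix P(K, locus_of_flat.size());
  update_p_core(z, fa, locus_of_flat, K, lambda, P);
  return P;
}

// [[Rcpp::export(.cpp_update_q)]]
NumericMatrix cpp_update_q(IntegerVector z, IntegerVector ind, int N, int K,
                           NumericVector alpha) {
  NumericMatrix Q(N, K);
  update_q_core(z, ind, N, K, alpha, Q);
  return Q;
}

// [[Rcpp::export(.cpp_update_alpha)]]
NumericVector cpp_update_alpha(NumericMatrix Q, NumericVector alpha,
                               double sd, double amax, bool separate) {
  NumericVector a = clone(alpha);
  update_alpha_core(Q, a, sd, amax, separate);
  return a;
}

// [[Rcpp::export(.cpp_loglik)]]
double cpp_loglik(NumericMatrix Q, NumericMatrix P, IntegerVector ind,
                  IntegerVector fa) {
  const int ncop = ind.size(), K = Q.ncol();
  double loglik = 0.0;
  for (int c = 0; c < ncop; ++c) {
    const int i = ind[c] - 1, j = fa[c] - 1;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += Q(i, k) * P(k, j);
    loglik += std::log(tot);
  }
  return loglik;
}

// [[Rcpp::export(.cpp_admix_gibbs)]]
List cpp_admix_gibbs(IntegerVector ind, IntegerVector fa,
                     IntegerVector locus_of_flat, int N, int K,
                     double lambda, int burn_in, int iterations, int thin,
                     bool infer_alpha, bool separate_alpha,
                     double alpha_init, double alpha_sd, double alpha_max) {
  const int Atot = locus_of_flat.size();
  NumericMatrix Q(N, K), P(K, Atot);
  NumericVector alpha(K, alpha_init);
  IntegerVector z(ind.size());

  // init: uniform random assignments, then P and Q from full conditionals
  for (int c = 0; c < ind.size(); ++c)
    z[c] = 1 + (int)std::floor(R::unif_rand() * K) % K;
  update_p_core(z, fa, locus_of_flat, K, lambda, P);
  update_q_core(z, ind, N, K, alpha, Q);

  const int total = burn_in + iterations;
  const int nkeep = iterations / thin;
  NumericVector logliks(nkeep);
  NumericMatrix Qsum(N, K), Psum(K, Atot);
  NumericVector alpha_sum(K);
  int kept = 0;
  double loglik = 0.0;

  for (int it = 1; it <= total; ++it) {
    update_z_core(Q, P, ind, fa, z, loglik);
    update_p_core(z, fa, locus_of_flat, K, lambda, P);
    update_q_core(z, ind, N, K, alpha, Q);
    if (infer_alpha) update_alpha_core(Q, alpha, alpha_sd, alpha_max,
                                       separate_alpha);
    if (!R_finite(loglik)) stop("non-finite log-likelihood at iteration %d", it);
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < nkeep) {
      logliks[kept++] = loglik;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < Atot; ++j) Psum(k, j) += P(k, j);
      for (int k = 0; k < K; ++k) alpha_sum[k] += alpha[k];
    }
  }
  if (kept == 0) stop("no samples kept: check iterations and thin");
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= kept;
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < Atot; ++j) Psum(k, j) /= kept;
  for (int k = 0; k < K; ++k) alpha_sum[k] /= kept;
  return List::create(_["Q"] = Qsum, _["P"] = Psum, _["alpha"] = alpha_sum,
                      _["logliks"] = logliks, _["n_kept"] = kept);
}
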