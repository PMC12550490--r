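#include <Rcpp.h>
using namespace Rcpp;

// Hidden state k = discretized TMRCA interval [bnd[k], bnd[k+1]) in units of
// 2*N0 generations; the last interval absorbs all mass above bnd[K-1].
//
// SMC' transition kernel, conditioned on current TMRCA t (taken at tmid[s]):
//   - no recombination in the bin gap: mass exp(-rho * t) stays at t;
//   - otherwise a recombination point u ~ Uniform(0, t) detaches one lineage,
//     which re-coalesces upward from u:
//       * in (u, t) two partner lineages are available (total rate
//         2*lambda(v)); with probability 1/2 the floating lineage rejoins its
//         own stub (back-coalescence, TMRCA unchanged), else the new TMRCA
//         is the coalescence height v;
//       * above t only the ancestral lineage remains (rate lambda(v)).
// With piecewise-constant lambda each segment integrates in closed form; the
// uniform u-integral is midpoint quadrature per atomic segment below t.

// The u-integral and the two-lineage race below t share exponential decay
// factors across segments, so each from-state row is built in one O(K)
// sweep: `M` carries the u-weighted mass of floating lineages surviving to
// the start of the current segment.
// [[Rcpp::export]]
NumericMatrix smcp_transition_cpp(NumericVector tmid, NumericVector bnd,
                                  NumericVector lambda, double rho) {
  const int K = tmid.size();
  NumericMatrix A(K, K);
  for (int s = 0; s < K; ++s) {
    const double t = tmid[s];
    const double pnr = std::exp(-rho * t);
    double self_extra = 0.0; // back-coalescence mass returning to state s
    double M = 0.0;          // u-mass surviving to the current segment start
    for (int j = 0; j <= s; ++j) {
      const double a = bnd[j];
      const double b = std::min(bnd[j + 1], t);
      if (b <= a) continue;
      const double len = b - a;
      const double w = len / t;                    // P(u in this segment)
      const double dfull = std::exp(-2.0 * lambda[j] * len);
      const double dhalf = std::exp(-2.0 * lambda[j] * 0.5 * len); // from u_mid
      // lineages that recombined in earlier segments race through this one
      double coal = M * (1.0 - dfull) * 0.5;
      // lineages recombining at this segment's midpoint
      coal += w * (1.0 - dhalf) * 0.5;
      A(s, j) += coal;        // coalesced with the other (non-stub) lineage
      self_extra += coal;     // symmetric mass rejoins its own stub: TMRCA = t
      M = M * dfull + w * dhalf;
    }
    // single-lineage race above t
    for (int j = s; j < K; ++j) {
      if (j == K - 1) { A(s, j) += M; break; }
      const double a = std::max(bnd[j], t);
      const double b = bnd[j + 1];
      if (b <= a) continue;
      const double dec = std::exp(-lambda[j] * (b - a));
      A(s, j) += M * (1.0 - dec);
      M *= dec;
    }
    for (int k = 0; k < K; ++k) A(s, k) *= (1.0 - pnr);
    A(s, s) += pnr + (1.0 - pnr) * self_extra;
    // numerical guard: renormalize the row
    double rs = 0.0;
    for (int k = 0; k < K; ++k) rs += A(s, k);
    for (int k = 0; k < K; ++k) A(s, k) /= rs;
  }
  return A;
}

// Marginal (equilibrium) distribution of the discretized TMRCA: a single
// pair coalescing at rate lambda(v) from time 0; tail lumped into the last
// interval.
// [[Rcpp::export]]
NumericVector tmrca_equilibrium_cpp(NumericVector bnd, NumericVector lambda) {
  const int K = lambda.size();
  NumericVector p(K);
  double S = 1.0;
  for (int k = 0; k < K - 1; ++k) {
    const double dec = std::exp(-lambda[k] * (bnd[k + 1] - bnd[k]));
    p[k] = S * (1.0 - dec);
    S *= dec;
  }
  p[K - 1] = S;
  return p;
}

// Expected complete-data log-likelihood (EM Q function) for given expected
// counts, evaluated directly in C++ so the M-step optimizer stays cheap.
// [[Rcpp::export]]
double smc_q_cpp(NumericVector tmid, NumericVector bnd, NumericVector lambda,
                 double rho, double theta, NumericMatrix xi,
                 NumericVector het, NumericVector hom, NumericVector gamma1) {
  const int K = tmid.size();
  NumericMatrix A = smcp_transition_cpp(tmid, bnd, lambda, rho);
  NumericVector pi = tmrca_equilibrium_cpp(bnd, lambda);
  double q = 0.0;
  for (int s = 0; s < K; ++s)
    for (int k = 0; k < K; ++k)
      if (xi(s, k) > 0.0) q += xi(s, k) * std::log(std::max(A(s, k), 1e-300));
  for (int k = 0; k < K; ++k) {
    const double eh = 1.0 - std::exp(-theta * tmid[k]);
    q += het[k] * std::log(std::max(eh, 1e-300));
    q += hom[k] * std::log(std::max(1.0 - eh, 1e-300));
    if (gamma1[k] > 0.0) q += gamma1[k] * std::log(std::max(pi[k], 1e-300));
  }
  return q;
}

// Scaled forward-backward for the binned het/hom/missing sequence.
// obs: integer vector, 0 = HOM, 1 = HET, 2 = MISSING (emission prob 1).
// Returns log-likelihood, expected transition counts xi (K x K), expected
// het/hom emission counts per state, posterior at the first bin, and the
// per-bin posterior column sums (for posterior-sum invariant checks).
// [[Rcpp::export]]
List forward_backward_cpp(IntegerVector obs, NumericMatrix A,
                          NumericVector ehet, NumericVector pi,
                          bool want_posterior = false) {
  const int n = obs.size();
  const int K = ehet.size();
  NumericMatrix alpha(K, n), beta(K, n);
  NumericVector cvec(n);
  auto emit = [&](int o, int k) -> double {
    if (o == 1) return ehet[k];
    if (o == 0) return 1.0 - ehet[k];
    return 1.0;
  };
  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(k, 0) = pi[k] * emit(obs[0], k); c0 += alpha(k, 0); }
  for (int k = 0; k < K; ++k) alpha(k, 0) /= c0;
  cvec[0] = c0;
  for (int i = 1; i < n; ++i) {
    double ci = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(j, i - 1) * A(j, k);
      s *= emit(obs[i], k);
      alpha(k, i) = s;
      ci += s;
    }
    for (int k = 0; k < K; ++k) alpha(k, i) /= ci;
    cvec[i] = ci;
  }
  // backward
  for (int k = 0; k < K; ++k) beta(k, n - 1) = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += A(j, k) * emit(obs[i + 1], k) * beta(k, i + 1);
      beta(j, i) = s / cvec[i + 1];
    }
  }
  // expected counts
  NumericMatrix xi(K, K);
  NumericVector het_cnt(K), hom_cnt(K), gamma1(K), post_sums(want_posterior ? n : 0);
  for (int i = 0; i < n; ++i) {
    double gs = 0.0;
    for (int k = 0; k < K; ++k) {
      const double g = alpha(k, i) * beta(k, i);
      gs += g;
      if (obs[i] == 1) het_cnt[k] += g;
      else if (obs[i] == 0) hom_cnt[k] += g;
      if (i == 0) gamma1[k] = g;
    }
    if (want_posterior) post_sums[i] = gs;
  }
  for (int i = 0; i + 1 < n; ++i) {
    for (int j = 0; j < K; ++j) {
      const double aj = alpha(j, i);
      if (aj == 0.0) continue;
      for (int k = 0; k < K; ++k) {
        xi(j, k) += aj * A(j, k) * emit(obs[i + 1], k) * beta(k, i + 1) / cvec[i + 1];
      }
    }
  }
  double ll = 0.0;
  for (int i = 0; i < n; ++i) ll += std::log(cvec[i]);
  return List::create(_["loglik"] = ll, _["xi"] = xi, _["het"] = het_cnt,
                      _["hom"] = hom_cnt, _["gamma1"] = gamma1,
                      _["posterior_sums"] = post_sums);
}
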