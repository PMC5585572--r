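#include <Rcpp.h>
using namespace Rcpp;

// Single-flip Metropolis sampler for the finite-window Gibbs measure
// mu(raster) proportional to exp(sum_{s=0}^{T-R} phi(window at s)).
// raster: N x T 0/1 integer matrix, modified in place on a copy.
// events: list of L integer matrices, each k x 2 with columns
//   (neuron 0-based, tau 0-based).
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerMatrix cpp_metropolis_raster(IntegerMatrix raster, NumericVector h,
                                    List events, int R, int n_sweeps,
                                    double flips_per_neuron) {
  const int N = raster.nrow(), T = raster.ncol();
  const int L = h.size();
  IntegerMatrix w = clone(raster);

  // incidence: for each neuron, the (term, tau) pairs that involve it
  std::vector< std::vector< std::pair<int,int> > > inc(N);
  std::vector< std::vector<int> > ev_neuron(L), ev_tau(L);
  for (int l = 0; l < L; ++l) {
    IntegerMatrix m = events[l];
    for (int e = 0; e < m.nrow(); ++e) {
      int i = m(e, 0), tau = m(e, 1);
      ev_neuron[l].push_back(i);
      ev_tau[l].push_back(tau);
      inc[i].push_back(std::make_pair(l, tau));
    }
  }

  const long long per_sweep =
    (long long)std::ceil(flips_per_neuron * (double)N * (double)T);
  RNGScope scope;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (long long f = 0; f < per_sweep; ++f) {
      int i = (int)(unif_rand() * N); if (i == N) i = N - 1;
      int t = (int)(unif_rand() * T); if (t == T) t = T - 1;
      int old_bit = w(i, t);
      int new_bit = 1 - old_bit;
      double dE = 0.0;
      for (size_t q = 0; q < inc[i].size(); ++q) {
        int l = inc[i][q].first, tau = inc[i][q].second;
        int s = t - tau;               // window start, 0-based
        if (s < 0 || s > T - R) continue;
        int others = 1;
        const std::vector<int>& en = ev_neuron[l];
        const std::vector<int>& et = ev_tau[l];
        for (size_t e = 0; e < en.size(); ++e) {
          if (en[e] == i && et[e] == tau) continue;
          if (w(en[e], s + et[e]) == 0) { others = 0; break; }
        }
        if (others) dE += h[l] * (double)(new_bit - old_bit);
      }
      if (dE >= 0.0 || unif_rand() < std::exp(dE)) w(i, t) = new_bit;
    }
  }
  return w;
}

// Exact energy difference of flipping (neuron, t): re-evaluates only the
// windows covering the flipped bin. Mirrors the sampler's inner loop so it
// can be cross-checked against a global energy recomputation.
// [[Rcpp::export]]
double cpp_local_energy_delta(IntegerMatrix raster, NumericVector h,
                              List events, int R, int neuron, int t) {
  const int T = raster.ncol();
  const int L = h.size();
  int old_bit = raster(neuron, t);
  double dE = 0.0;
  for (int l = 0; l < L; ++l) {
    IntegerMatrix m = events[l];
    for (int e = 0; e < m.nrow(); ++e) {
      if (m(e, 0) != neuron) continue;
      int s = t - m(e, 1);
      if (s < 0 || s > T - R) continue;
      int others = 1;
      for (int e2 = 0; e2 < m.nrow(); ++e2) {
        if (e2 == e) continue;
        if (raster(m(e2, 0), s + m(e2, 1)) == 0) { others = 0; break; }
      }
      if (others) dE += h[l] * (double)((1 - old_bit) - old_bit);
    }
  }
  return dE;
}

// Sample T - D new columns of a Gibbs chain given cumulative transition
// rows. cumP: S x 2^N cumulative probabilities; nxt: successor states
// (0-based); w0: initial state (0-based). Returns the sequence of sampled
// column codes (length T - D).
// [[Rcpp::export]]
IntegerVector cpp_chain_sample(NumericMatrix cumP, IntegerMatrix nxt,
                               int w0, int n_steps) {
  const int n_cols = cumP.ncol();
  IntegerVector out(n_steps);
  int w = w0;
  RNGScope scope;
  for (int t = 0; t < n_steps; ++t) {
    double u = unif_rand();
    int c = 0;
    while (c < n_cols - 1 && cumP(w, c) < u) ++c;
    out[t] = c;
    w = nxt(w, c);
  }
  return out;
}
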