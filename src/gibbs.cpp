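#include <Rcpp.h>
using namespace Rcpp;

// Lexicographic pair index for 0-based i < j over L columns.
static inline long pair_index(int i, int j, int L) {
  return (long)i * L - (long)i * (i + 1) / 2 + (j - i - 1);
}

// Sequential-scan heat-bath Gibbs sampler for a Potts model with
// P(S) proportional to exp(-H(S)), H = sum_{i<j} J_ij(s_i,s_j) + sum_i h_i(s_i).
// J is the P x q x q array flattened column-major (index p + P*a + P*q*b for
// block p, row state a, column state b; rows index the smaller column's state).
// One chain: `burnin` full sweeps, then one recorded sequence every `thin`
// sweeps until n are collected.  Uses R's RNG, so set.seed() gives
// reproducibility.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericMatrix h, NumericVector Jflat,
                               int L, int q, int n, int burnin, int thin,
                               IntegerVector s0) {
  long P = (long)L * (L - 1) / 2;
  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) s[i] = s0[i];
  IntegerMatrix out(n, L);
  std::vector<double> e(q), w(q);
  int total = burnin + n * thin;
  int rec = 0;
  for (int sweep = 1; sweep <= total; ++sweep) {
    for (int i = 0; i < L; ++i) {
      for (int a = 0; a < q; ++a) e[a] = h(i, a);
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        if (i < j) {
          long p = pair_index(i, j, L);
          int sj = s[j];
          for (int a = 0; a < q; ++a)
            e[a] += Jflat[p + P * a + P * (long)q * sj];
        } else {
          long p = pair_index(j, i, L);
          int sj = s[j];
          for (int a = 0; a < q; ++a)
            e[a] += Jflat[p + P * sj + P * (long)q * a];
        }
      }
      double emin = e[0];
      for (int a = 1; a < q; ++a) if (e[a] < emin) emin = e[a];
      double z = 0.0;
      for (int a = 0; a < q; ++a) { w[a] = std::exp(-(e[a] - emin)); z += w[a]; }
      double u = R::runif(0.0, 1.0) * z, cum = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) { cum += w[a]; if (u <= cum) { pick = a; break; } }
      s[i] = pick;
    }
    if (sweep > burnin && (sweep - burnin) % thin == 0 && rec < n) {
      for (int i = 0; i < L; ++i) out(rec, i) = s[i] + 1;
      ++rec;
    }
  }
  return out;
}
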