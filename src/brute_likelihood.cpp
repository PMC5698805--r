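#include <Rcpp.h>
#include <functional>
#include <vector>
using namespace Rcpp;

// Exhaustive two-locus pedigree likelihood by direct enumeration over all
// ordered diplotype assignments consistent with the observed marker
// genotypes. Deliberately independent of the peeling engine: no clique
// elimination, just a depth-first sum of products over per-person states.
// For a marker with k alleles, a haplotype h in 0..2k-1 encodes
// (disease allele d in {0,1}, marker allele m in 0..k-1): h = k*d + m;
// a state s in 0..(2k)^2-1 encodes (paternal h, maternal h): s = 2k*hp + hm.

// [[Rcpp::export]]
double brute_likelihood_cpp(IntegerVector father, IntegerVector mother,
                            IntegerVector affection,
                            IntegerVector geno_a, IntegerVector geno_b,
                            double q, NumericVector pen,
                            bool affecteds_only, double theta,
                            NumericVector freqs) {
  const int n = father.size();
  const int k = freqs.size();
  const int nh = 2 * k;
  const int ns = nh * nh;
  auto hap_d = [k](int h) { return h / k; };
  auto hap_m = [k](int h) { return h % k; };

  // transmission: T[s][h] = P(parent with state s transmits haplotype h)
  std::vector<std::vector<double> > T(ns, std::vector<double>(nh, 0.0));
  for (int s = 0; s < ns; ++s) {
    int hA = s / nh, hB = s % nh;
    T[s][hA] += 0.5 * (1.0 - theta);
    T[s][k * hap_d(hA) + hap_m(hB)] += 0.5 * theta;
    T[s][hB] += 0.5 * (1.0 - theta);
    T[s][k * hap_d(hB) + hap_m(hA)] += 0.5 * theta;
  }
  std::vector<double> fh(nh), prior(ns);
  for (int h = 0; h < nh; ++h)
    fh[h] = (hap_d(h) ? q : 1.0 - q) * freqs[hap_m(h)];
  for (int s = 0; s < ns; ++s) prior[s] = fh[s / nh] * fh[s % nh];

  // per-person candidate states (consistent with the observed unordered
  // marker genotype) and unary weights
  std::vector<std::vector<int> > cand(n);
  std::vector<std::vector<double> > w(n);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < ns; ++s) {
      int ma = hap_m(s / nh), mb = hap_m(s % nh);
      if (geno_a[i] >= 0) {
        int lo = std::min(ma, mb), hi = std::max(ma, mb);
        if (lo != geno_a[i] || hi != geno_b[i]) continue;
      }
      int nd = hap_d(s / nh) + hap_d(s % nh);
      double weight = 1.0;
      if (affection[i] == 2) weight = pen[nd];
      else if (affection[i] == 1 && !affecteds_only) weight = 1.0 - pen[nd];
      if (father[i] < 0) weight *= prior[s];
      if (weight > 0.0) {
        cand[i].push_back(s);
        w[i].push_back(weight);
      }
    }
  }

  std::vector<int> state(n, 0);
  // depth-first product-sum; persons must be topologically ordered
  // (parents before children)
  std::function<double(int)> dfs = [&](int idx) -> double {
    if (idx == n) return 1.0;
    double acc = 0.0;
    for (size_t c = 0; c < cand[idx].size(); ++c) {
      int s = cand[idx][c];
      double weight = w[idx][c];
      if (father[idx] >= 0) {
        int sf = state[father[idx]], sm = state[mother[idx]];
        weight *= T[sf][s / nh] * T[sm][s % nh];
        if (weight == 0.0) continue;
      }
      state[idx] = s;
      acc += weight * dfs(idx + 1);
    }
    return acc;
  };
  return dfs(0);
}
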