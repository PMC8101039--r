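#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Pairwise genotype-linkage counts over molecules.
// Observations must be sorted by (molecule, site); site indices are 1-based
// and ordered by genomic position, pos[site-1] is the coordinate.
// Each molecule observes a site at most once, so every molecule contributes
// at most one link to any pair.
// [[Rcpp::export]]
List count_pair_links_cpp(IntegerVector mol, IntegerVector site,
                          IntegerVector spin, IntegerVector chrom,
                          NumericVector pos, double max_dist) {
  R_xlen_t n = mol.size();
  long long nsite = pos.size();
  std::unordered_map<long long, std::pair<int, int> > acc;
  acc.reserve(1 << 20);
  R_xlen_t start = 0;
  while (start < n) {
    R_xlen_t end = start;
    while (end < n && mol[end] == mol[start]) ++end;
    for (R_xlen_t a = start; a < end; ++a) {
      double pa = pos[site[a] - 1];
      int ca = chrom[site[a] - 1];
      for (R_xlen_t b = a + 1; b < end; ++b) {
        // sites are sorted by (chrom, pos): stop at a chromosome change
        // or once the separation exceeds the cap
        if (chrom[site[b] - 1] != ca) break;
        if (pos[site[b] - 1] - pa > max_dist) break;
        long long key = (long long)(site[a] - 1) * nsite + (site[b] - 1);
        std::pair<int, int>& e = acc[key];
        if (spin[a] * spin[b] > 0) e.first++; else e.second++;
      }
    }
    start = end;
  }
  std::vector<long long> keys;
  keys.reserve(acc.size());
  for (std::unordered_map<long long, std::pair<int, int> >::iterator it =
           acc.begin(); it != acc.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());
  R_xlen_t m = keys.size();
  IntegerVector oi(m), oj(m), np(m), nm(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    std::pair<int, int>& e = acc[keys[k]];
    oi[k] = (int)(keys[k] / nsite) + 1;
    oj[k] = (int)(keys[k] % nsite) + 1;
    np[k] = e.first;
    nm[k] = e.second;
  }
  return List::create(_["i"] = oi, _["j"] = oj,
                      _["n_plus"] = np, _["n_minus"] = nm);
}

namespace {

struct Csr {
  std::vector<int> off;
  std::vector<int> adj;
  std::vector<double> w;
};

// Symmetric adjacency in compressed sparse rows; edge list is 1-based i<j.
Csr build_csr(int n, const IntegerVector& pi, const IntegerVector& pj,
              const NumericVector& pw) {
  Csr g;
  R_xlen_t m = pi.size();
  std::vector<int> deg(n, 0);
  for (R_xlen_t e = 0; e < m; ++e) { deg[pi[e] - 1]++; deg[pj[e] - 1]++; }
  g.off.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) g.off[i + 1] = g.off[i] + deg[i];
  g.adj.assign(g.off[n], 0);
  g.w.assign(g.off[n], 0.0);
  std::vector<int> fill(g.off.begin(), g.off.end() - 1);
  for (R_xlen_t e = 0; e < m; ++e) {
    int a = pi[e] - 1, b = pj[e] - 1;
    g.adj[fill[a]] = b; g.w[fill[a]++] = pw[e];
    g.adj[fill[b]] = a; g.w[fill[b]++] = pw[e];
  }
  return g;
}

double flip_gain(const Csr& g, const std::vector<int>& s, int i) {
  double d = 0;
  for (int t = g.off[i]; t < g.off[i + 1]; ++t) d += g.w[t] * s[g.adj[t]];
  return s[i] * d;
}

}  // namespace

// Energy minimization of the 1D spin model by rounds of single-spin flips
// (ascending site order) followed by suffix switches swept left to right
// with the boundary penalty maintained incrementally. Ties (delta E == 0)
// are rejected, so the result is deterministic given the initial spins.
// [[Rcpp::export]]
List ising_minimize_cpp(int n, IntegerVector pi, IntegerVector pj,
                        NumericVector pw, IntegerVector init,
                        int max_rounds) {
  Csr g = build_csr(n, pi, pj, pw);
  std::vector<int> s(init.begin(), init.end());
  std::vector<int> log_flips, log_switches;
  bool converged = false;
  // moves must beat a tolerance scaled to the total coupling weight, so
  // rounding noise in the incrementally maintained boundary penalty (exact
  // zero at linkage gaps) is never mistaken for an improvement
  double wsum = 0;
  for (size_t e = 0; e < g.w.size(); ++e) wsum += std::fabs(g.w[e]);
  const double tol = 1e-9 * (1.0 + wsum);
  while ((int)log_flips.size() < max_rounds) {
    int nflip = 0, nswitch = 0;
    for (int i = 0; i < n; ++i) {
      if (flip_gain(g, s, i) < -tol) { s[i] = -s[i]; ++nflip; }
    }
    double T = 0;
    for (int k = 0; k + 1 < n; ++k) {
      double a = 0, b = 0;
      for (int t = g.off[k]; t < g.off[k + 1]; ++t) {
        int j = g.adj[t];
        if (j > k) a += g.w[t] * s[j]; else b += g.w[t] * s[j];
      }
      T += s[k] * (a - b);
      if (T < -tol) {
        for (int j = k + 1; j < n; ++j) s[j] = -s[j];
        T = -T;
        ++nswitch;
      }
    }
    log_flips.push_back(nflip);
    log_switches.push_back(nswitch);
    if (nflip + nswitch == 0) { converged = true; break; }
  }
  return List::create(_["spins"] = IntegerVector(s.begin(), s.end()),
                      _["flips"] = IntegerVector(log_flips.begin(), log_flips.end()),
                      _["switches"] = IntegerVector(log_switches.begin(), log_switches.end()),
                      _["converged"] = converged);
}

// Per-site spin-flip penalties delta E_i = s_i * sum_j M_ij s_j.
// [[Rcpp::export]]
NumericVector flip_penalties_cpp(int n, IntegerVector pi, IntegerVector pj,
                                 NumericVector pw, IntegerVector spins) {
  Csr g = build_csr(n, pi, pj, pw);
  std::vector<int> s(spins.begin(), spins.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = flip_gain(g, s, i);
  return out;
}

// Boundary switch penalties delta E_{k|k+1} = sum_{i<=k} sum_{j>k} M_ij s_i s_j,
// for k = 1..n-1, by one incremental left-to-right scan.
// [[Rcpp::export]]
NumericVector switch_penalties_cpp(int n, IntegerVector pi, IntegerVector pj,
                                   NumericVector pw, IntegerVector spins) {
  Csr g = build_csr(n, pi, pj, pw);
  std::vector<int> s(spins.begin(), spins.end());
  NumericVector out(n > 0 ? n - 1 : 0);
  double T = 0;
  for (int k = 0; k + 1 < n; ++k) {
    double a = 0, b = 0;
    for (int t = g.off[k]; t < g.off[k + 1]; ++t) {
      int j = g.adj[t];
      if (j > k) a += g.w[t] * s[j]; else b += g.w[t] * s[j];
    }
    T += s[k] * (a - b);
    out[k] = T;
  }
  return out;
}
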