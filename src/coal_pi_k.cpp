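#include <Rcpp.h>
using namespace Rcpp;

// Fast constant-size coalescent simulation of (pi, K) for the Fu's FS
// simulated null.  Time is in units of 2N generations; theta is the
// per-locus scaled mutation rate (E[pi] = theta).  Mutations are dropped
// per branch as Poisson(theta/2 * branch length); pi is accumulated from
// the i(n-i) pair counts of each mutated branch, and the number of
// distinct haplotypes K is obtained by contracting mutation-free branches
// with union-find.  Uses R's RNG so results follow set.seed().

static int uf_find(std::vector<int>& uf, int x) {
  while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
  return x;
}

// [[Rcpp::export]]
NumericMatrix coal_pi_k_cpp(int n, double theta, int B) {
  if (n < 2) stop("n must be >= 2");
  NumericMatrix out(B, 2);
  int m = 2 * n - 1;                       // total nodes
  std::vector<int> active(n), cnt(m);
  std::vector<double> start(m);
  std::vector<int> uf(m);
  double npairs = n * (n - 1.0) / 2.0;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < m; ++i) uf[i] = i;
    int k = n;
    for (int i = 0; i < n; ++i) { active[i] = i; cnt[i] = 1; start[i] = 0.0; }
    double t = 0.0, pi_sum = 0.0;
    int next_node = n;
    while (k > 1) {
      double lam = k * (k - 1.0) / 2.0;
      t += R::rexp(1.0 / lam);
      int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = active[i], c = active[j];
      int p = next_node++;
      cnt[p] = cnt[a] + cnt[c];
      start[p] = t;
      int ch[2] = {a, c};
      for (int s = 0; s < 2; ++s) {
        double len = t - start[ch[s]];
        double mmut = R::rpois(0.5 * theta * len);
        if (mmut > 0) {
          pi_sum += mmut * (double)cnt[ch[s]] * (n - cnt[ch[s]]);
        } else {
          uf[uf_find(uf, ch[s])] = uf_find(uf, p);
        }
      }
      // replace the two merged lineages by the parent
      if (i > j) std::swap(i, j);
      active[i] = p;
      active[j] = active[k - 1];
      --k;
    }
    // count distinct haplotypes among tips
    std::vector<int> roots;
    roots.reserve(n);
    int K = 0;
    for (int i = 0; i < n; ++i) {
      int r = uf_find(uf, i);
      bool seen = false;
      for (size_t q = 0; q < roots.size(); ++q)
        if (roots[q] == r) { seen = true; break; }
      if (!seen) { roots.push_back(r); ++K; }
    }
    out(b, 0) = pi_sum / npairs;
    out(b, 1) = K;
  }
  return out;
}
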