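#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// tau-EO bipartition of a (sub)graph by modularity.
//
// Starts from a random half/half split and repeatedly relocates one node
// across the cut: nodes are ranked by fitness lambda_i = kin_i/k_i - a_{c_i}
// (ascending; worst first) and rank j is chosen with probability ~ j^-tau.
// The best configuration seen is kept; the search stops after
// `max_nonimprove` consecutive moves without a new best modularity.
//
// `adj` is a 0-based adjacency list restricted to the subgraph; degrees are
// subgraph degrees. Uses R's RNG, so results are reproducible via set.seed().
// [[Rcpp::export]]
List eo_bipartition_cpp(List adj, IntegerVector deg, double tau,
                        int max_nonimprove) {
  const int n = adj.size();
  std::vector<std::vector<int> > nb(n);
  long degsum = 0;
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj[i];
    nb[i].assign(a.begin(), a.end());
    degsum += deg[i];
  }
  const double M = degsum / 2.0;
  IntegerVector side(n, 0);
  if (M < 1 || n < 2)
    return List::create(_["side"] = side, _["q"] = 0.0);

  // random balanced initial split (Fisher-Yates on node ids)
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
  for (int i = 0; i < n / 2; ++i) side[perm[i]] = 1;

  std::vector<int> kin(n, 0);
  double K[2] = {0.0, 0.0};
  long sumkin = 0;
  for (int i = 0; i < n; ++i) {
    K[side[i]] += deg[i];
    for (size_t j = 0; j < nb[i].size(); ++j)
      if (side[nb[i][j]] == side[i]) ++kin[i];
    sumkin += kin[i];
  }

  // rank-selection weights: P(rank j) ~ j^-tau, j = 1 worst
  std::vector<double> cum(n);
  double acc = 0.0;
  for (int j = 0; j < n; ++j) {
    acc += std::pow((double)(j + 1), -tau);
    cum[j] = acc;
  }

  const double twoM = 2.0 * M;
  double a0 = K[0] / twoM, a1 = K[1] / twoM;
  double Q = (sumkin / 2.0) / M - a0 * a0 - a1 * a1;
  double bestQ = Q;
  IntegerVector best = clone(side);

  std::vector<int> idx(n);
  std::vector<double> fit(n);
  int nonimp = 0;
  long iter = 0, iter_cap = 50L * (long)max_nonimprove + 100000L;

  while (nonimp < max_nonimprove && iter < iter_cap) {
    ++iter;
    for (int i = 0; i < n; ++i) {
      double ai = (side[i] == 0) ? a0 : a1;
      fit[i] = (deg[i] > 0) ? ((double)kin[i] / deg[i] - ai) : 0.0;
      idx[i] = i;
    }
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return fit[a] < fit[b]; });
    double u = unif_rand() * acc;
    int r = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (r >= n) r = n - 1;
    int v = idx[r];

    // flip v across the cut, updating kin/K incrementally
    int olds = side[v], news = 1 - olds;
    int kin_old = kin[v];
    for (size_t j = 0; j < nb[v].size(); ++j) {
      int u2 = nb[v][j];
      if (side[u2] == olds) --kin[u2]; else ++kin[u2];
    }
    kin[v] = deg[v] - kin_old;
    sumkin += 2L * (kin[v] - kin_old);
    K[olds] -= deg[v];
    K[news] += deg[v];
    side[v] = news;
    a0 = K[0] / twoM;
    a1 = K[1] / twoM;
    Q = (sumkin / 2.0) / M - a0 * a0 - a1 * a1;

    if (Q > bestQ + 1e-12) {
      bestQ = Q;
      best = clone(side);
      nonimp = 0;
    } else {
      ++nonimp;
    }
  }
  return List::create(_["side"] = best, _["q"] = bestQ);
}
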