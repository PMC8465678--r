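// Random-walk corpus generation: biased second-order walks on a weighted
// similarity graph (node2vec law) and uniform within-layer walks on the
// bipartite association layers (meta-path miRNA-disease alternation).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int sample_cum(const std::vector<double>& cum, double u) {
  // cum is a strictly increasing cumulative-weight vector; u in [0, total)
  return int(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

// [[Rcpp::export]]
List nv_walks_cpp(const arma::mat& W, int walk_length, int walks_per_node,
                  double p, double q, int seed) {
  const int n = W.n_rows;
  std::mt19937 gen(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // neighbor lists (self-loops excluded)
  std::vector<std::vector<int>> nbr(n);
  std::vector<std::vector<double>> wt(n);
  for (int v = 0; v < n; ++v)
    for (int x = 0; x < n; ++x)
      if (x != v && W(v, x) > 0) { nbr[v].push_back(x); wt[v].push_back(W(v, x)); }

  List out;
  std::vector<double> cum;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int s = 0; s < n; ++s) {
      std::vector<int> walk;
      walk.push_back(s);
      if (!nbr[s].empty()) {
        int prev = -1, cur = s;
        while ((int)walk.size() < walk_length) {
          const std::vector<int>& nb = nbr[cur];
          if (nb.empty()) break;
          cum.assign(nb.size(), 0.0);
          double tot = 0.0;
          for (size_t k = 0; k < nb.size(); ++k) {
            double a = 1.0;
            if (prev >= 0) {
              int x = nb[k];
              if (x == prev) a = 1.0 / p;                     // d_tx = 0
              else if (W(prev, x) > 0) a = 1.0;               // d_tx = 1
              else a = 1.0 / q;                               // d_tx = 2
            }
            tot += a * wt[cur][k];
            cum[k] = tot;
          }
          int pick = sample_cum(cum, unif(gen) * tot);
          prev = cur;
          cur = nb[pick];
          walk.push_back(cur);
        }
      }
      IntegerVector w(walk.size());
      for (size_t k = 0; k < walk.size(); ++k) w[k] = walk[k] + 1;
      out.push_back(w);
    }
  }
  return out;
}

// [[Rcpp::export]]
List mp_walks_cpp(List nbrs, int walk_length, int walks_per_node, int seed) {
  const int n = nbrs.size();
  std::mt19937 gen(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nbrs[i];
    for (int k = 0; k < v.size(); ++k) nb[i].push_back(v[k] - 1);
  }
  List out;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int s = 0; s < n; ++s) {
      if (nb[s].empty()) continue;  // node isolated in this layer
      std::vector<int> walk;
      walk.push_back(s);
      int cur = s;
      while ((int)walk.size() < walk_length) {
        const std::vector<int>& v = nb[cur];
        if (v.empty()) break;
        cur = v[std::min((size_t)(unif(gen) * v.size()), v.size() - 1)];
        walk.push_back(cur);
      }
      IntegerVector w(walk.size());
      for (size_t k = 0; k < walk.size(); ++k) w[k] = walk[k] + 1;
      out.push_back(w);
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat sgns_cpp(List walks, int n_nodes, int dim, int window, int negative,
                   int epochs, double lr0, int seed) {
  std::mt19937 gen(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // corpus and unigram^{3/4} noise table
  std::vector<std::vector<int>> corpus;
  std::vector<double> cnt(n_nodes, 0.0);
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    std::vector<int> v(w.size());
    for (int k = 0; k < w.size(); ++k) { v[k] = w[k] - 1; cnt[v[k]] += 1.0; }
    corpus.push_back(v);
  }
  std::vector<double> noise_cum(n_nodes, 0.0);
  double tot = 0.0;
  for (int i = 0; i < n_nodes; ++i) { tot += std::pow(cnt[i], 0.75); noise_cum[i] = tot; }
  if (tot <= 0) stop("empty walk corpus");

  arma::mat emb(n_nodes, dim), ctx(n_nodes, dim, arma::fill::zeros);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) emb(i, d) = (unif(gen) - 0.5) / dim;

  long long total_pos = 0;
  for (auto& w : corpus) total_pos += (long long)w.size();
  total_pos *= epochs;
  long long done = 0;

  arma::rowvec neu(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (auto& w : corpus) {
      const int L = w.size();
      for (int i = 0; i < L; ++i) {
        double lr = lr0 * (1.0 - (double)done / (double)(total_pos + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        ++done;
        const int c = w[i];
        neu.zeros();
        bool any = false;
        for (int j = std::max(0, i - window); j <= std::min(L - 1, i + window); ++j) {
          if (j == i) continue;
          any = true;
          const int t = w[j];
          { // positive
            double f = arma::dot(emb.row(c), ctx.row(t));
            double g = lr * (1.0 - 1.0 / (1.0 + std::exp(-f)));
            neu += g * ctx.row(t);
            ctx.row(t) += g * emb.row(c);
          }
          for (int m = 0; m < negative; ++m) {
            int k = sample_cum(noise_cum, unif(gen) * tot);
            if (k == t) continue;
            double f = arma::dot(emb.row(c), ctx.row(k));
            double g = -lr / (1.0 + std::exp(-f));
            neu += g * ctx.row(k);
            ctx.row(k) += g * emb.row(c);
          }
        }
        if (any) emb.row(c) += neu;
      }
    }
  }
  return emb;
}
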