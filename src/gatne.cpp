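// Trainer for the attributed multi-layer heterogeneous network embedding.
// Per-layer node representation: v_{i,r} = beta_r * Dz' x_i + h_z(x_i)
//                                          + alpha_r * M_r' (D_i a_{i,r})
// where D_i stacks the K-step aggregated edge embeddings of node i over all
// layers and a_{i,r} = softmax(w_r' tanh(W_r D_i)) is the cross-layer
// attention. Optimized by skip-gram with negative sampling over within-layer
// meta-path walks. Synchronous minibatch SGD: gradients on the aggregated
// edge embeddings are buffered and flushed through the mean/tanh aggregation
// to the g transforms once per batch, after which the aggregation cache is
// rebuilt.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
List gatne_train_cpp(const arma::mat& X, IntegerVector ztype, List layer_nbrs,
                     List walks, List params, int K, int window, int negative,
                     int epochs, double lr0, int batch, int seed, bool train_ab,
                     bool max_pool) {
  const int n = X.n_rows;
  const int R = layer_nbrs.size();
  std::mt19937 gen(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // ---- unpack parameters ----
  List Wh_in = params["Wh"], bh_in = params["bh"], Wg_in = params["Wg"],
       bg_in = params["bg"], Watt_in = params["Watt"], watt_in = params["watt"],
       M_in = params["M"], Dz_in = params["Dz"];
  std::vector<arma::mat> Wh(2), Dz(2);
  std::vector<arma::vec> bh(2);
  for (int zz = 0; zz < 2; ++zz) {
    Wh[zz] = as<arma::mat>(Wh_in[zz]);
    bh[zz] = as<arma::vec>(bh_in[zz]);
    Dz[zz] = as<arma::mat>(Dz_in[zz]);
  }
  std::vector<std::vector<arma::mat>> Wg(2, std::vector<arma::mat>(R));
  std::vector<std::vector<arma::vec>> bg(2, std::vector<arma::vec>(R));
  for (int zz = 0; zz < 2; ++zz) {
    List wgl = Wg_in[zz], bgl = bg_in[zz];
    for (int r = 0; r < R; ++r) { Wg[zz][r] = as<arma::mat>(wgl[r]); bg[zz][r] = as<arma::vec>(bgl[r]); }
  }
  std::vector<arma::mat> Watt(R), M(R);
  std::vector<arma::vec> watt(R);
  for (int r = 0; r < R; ++r) {
    Watt[r] = as<arma::mat>(Watt_in[r]);
    watt[r] = as<arma::vec>(watt_in[r]);
    M[r] = as<arma::mat>(M_in[r]);
  }
  arma::vec alpha = as<arma::vec>(params["alpha"]);
  arma::vec beta = as<arma::vec>(params["beta"]);
  arma::mat Ctx = as<arma::mat>(params["Ctx"]);
  const int DE = Wg[0][0].n_cols;

  // ---- adjacency ----
  std::vector<std::vector<std::vector<int>>> nb(R, std::vector<std::vector<int>>(n));
  for (int r = 0; r < R; ++r) {
    List lr_ = layer_nbrs[r];
    for (int i = 0; i < n; ++i) {
      IntegerVector v = lr_[i];
      for (int k = 0; k < v.size(); ++k) nb[r][i].push_back(v[k] - 1);
    }
  }
  arma::uvec idx_z[2];
  {
    std::vector<arma::uword> a, b;
    for (int i = 0; i < n; ++i) (ztype[i] == 1 ? a : b).push_back(i);
    idx_z[0] = arma::uvec(a); idx_z[1] = arma::uvec(b);
  }

  // ---- aggregation cache: lvl[r][k] (n x DE), k = 0..K ----
  std::vector<std::vector<arma::mat>> lvl(R);
  auto compute_cache = [&](int r) {
    lvl[r].assign(K + 1, arma::mat(n, DE));
    arma::mat& d0 = lvl[r][0];
    for (int zz = 0; zz < 2; ++zz)
      if (idx_z[zz].n_elem)
        d0.rows(idx_z[zz]) = X.rows(idx_z[zz]) * Wg[zz][r] +
          arma::repmat(bg[zz][r].t(), idx_z[zz].n_elem, 1);
    for (int k = 1; k <= K; ++k) {
      arma::mat& prev = lvl[r][k - 1];
      arma::mat& cur = lvl[r][k];
      for (int i = 0; i < n; ++i) {
        const std::vector<int>& v = nb[r][i];
        if (v.empty()) { cur.row(i) = prev.row(i); continue; }
        if (max_pool) {
          arma::rowvec m = prev.row(v[0]);
          for (size_t kk = 1; kk < v.size(); ++kk) m = arma::max(m, prev.row(v[kk]));
          cur.row(i) = arma::tanh(m);
        } else {
          arma::rowvec m(DE, arma::fill::zeros);
          for (int j : v) m += prev.row(j);
          cur.row(i) = arma::tanh(m / (double)v.size());
        }
      }
    }
  };
  for (int r = 0; r < R; ++r) compute_cache(r);

  // ---- noise tables: per layer, per node type, unigram^{3/4} over corpus ----
  std::vector<std::vector<std::vector<int>>> noise_id(R, std::vector<std::vector<int>>(2));
  std::vector<std::vector<std::vector<double>>> noise_cum(R, std::vector<std::vector<double>>(2));
  long long total_centers = 0;
  for (int r = 0; r < R; ++r) {
    std::vector<double> cnt(n, 0.0);
    List wl = walks[r];
    for (int w = 0; w < wl.size(); ++w) {
      IntegerVector vv = wl[w];
      total_centers += vv.size();
      for (int k = 0; k < vv.size(); ++k) cnt[vv[k] - 1] += 1.0;
    }
    for (int zz = 0; zz < 2; ++zz) {
      double tot = 0.0;
      for (arma::uword ii = 0; ii < idx_z[zz].n_elem; ++ii) {
        int i = idx_z[zz](ii);
        if (cnt[i] > 0) {
          tot += std::pow(cnt[i], 0.75);
          noise_id[r][zz].push_back(i);
          noise_cum[r][zz].push_back(tot);
        }
      }
      if (noise_id[r][zz].empty()) {  // fallback: uniform over the type
        for (arma::uword ii = 0; ii < idx_z[zz].n_elem; ++ii) {
          noise_id[r][zz].push_back(idx_z[zz](ii));
          noise_cum[r][zz].push_back((double)(ii + 1));
        }
      }
    }
  }
  total_centers *= epochs;

  // ---- gradient buffers for aggregated edge embeddings ----
  std::vector<arma::mat> Gd(R, arma::mat(n, DE, arma::fill::zeros));
  std::vector<bool> Gd_dirty(R, false);
  double lr = lr0;
  auto flush = [&]() {
    bool any = false;
    for (int r = 0; r < R; ++r) {
      if (!Gd_dirty[r]) continue;
      any = true;
      arma::mat G = Gd[r];
      for (int k = K; k >= 1; --k) {
        arma::mat Gn(n, DE, arma::fill::zeros);
        for (int i = 0; i < n; ++i) {
          const std::vector<int>& v = nb[r][i];
          if (v.empty()) { Gn.row(i) += G.row(i); continue; }
          arma::rowvec gm = G.row(i) % (1.0 - arma::square(lvl[r][k].row(i)));
          if (max_pool) {
            // route each dimension's gradient to the argmax neighbor
            for (int d = 0; d < DE; ++d) {
              int best = v[0];
              double bv = lvl[r][k - 1](v[0], d);
              for (size_t kk = 1; kk < v.size(); ++kk)
                if (lvl[r][k - 1](v[kk], d) > bv) { bv = lvl[r][k - 1](v[kk], d); best = v[kk]; }
              Gn(best, d) += gm[d];
            }
          } else {
            gm /= (double)v.size();
            for (int j : v) Gn.row(j) += gm;
          }
        }
        G = Gn;
      }
      for (int zz = 0; zz < 2; ++zz) {
        if (!idx_z[zz].n_elem) continue;
        arma::mat Gz = G.rows(idx_z[zz]);
        Wg[zz][r] -= lr * (X.rows(idx_z[zz]).t() * Gz);
        bg[zz][r] -= lr * arma::sum(Gz, 0).t();
      }
      Gd[r].zeros();
      Gd_dirty[r] = false;
    }
    if (any) for (int r = 0; r < R; ++r) compute_cache(r);
  };

  long long done = 0;
  int since_flush = 0;
  const int BE = Wh[0].n_cols;
  arma::mat Dm(DE, R), Tm(Watt[0].n_rows, R);
  arma::vec b(BE), v(BE), gv(BE), attr(BE), y(DE), gy(DE), s_(R), a(R), ga(R), gs(R);
  arma::vec gw(watt[0].n_elem), pre(watt[0].n_elem), gd(DE);
  arma::mat gW(Watt[0].n_rows, Watt[0].n_cols);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < R; ++r) {
      List wl = walks[r];
      for (int w = 0; w < wl.size(); ++w) {
        IntegerVector vv = wl[w];
        const int L = vv.size();
        for (int pos = 0; pos < L; ++pos) {
          lr = lr0 * (1.0 - (double)done / (double)(total_centers + 1));
          if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
          ++done;
          const int i = vv[pos] - 1;
          const int zi = ztype[i] - 1;
          // ---- forward ----
          const arma::rowvec& xi = X.row(i);
          b = (xi * Wh[zi]).t() + bh[zi];
          for (int rp = 0; rp < R; ++rp) Dm.col(rp) = lvl[rp][K].row(i).t();
          Tm = arma::tanh(Watt[r] * Dm);                 // att x R
          s_ = (watt[r].t() * Tm).t();                   // R
          a = arma::exp(s_ - s_.max());
          a /= arma::accu(a);
          y = Dm * a;                                    // DE
          attr = (xi * Dz[zi]).t();                      // BE
          v = beta[r] * attr + b + alpha[r] * (M[r].t() * y);
          // ---- skip-gram with negative sampling ----
          gv.zeros();
          bool any = false;
          for (int j = std::max(0, pos - window); j <= std::min(L - 1, pos + window); ++j) {
            if (j == pos) continue;
            any = true;
            const int t = vv[j] - 1;
            const int zt = ztype[t] - 1;
            double g = sigm(arma::dot(Ctx.row(t), v)) - 1.0;
            gv += g * Ctx.row(t).t();
            Ctx.row(t) -= lr * g * v.t();
            const std::vector<double>& cum = noise_cum[r][zt];
            const std::vector<int>& ids = noise_id[r][zt];
            const double tot = cum.back();
            for (int m = 0; m < negative; ++m) {
              int kk = ids[std::lower_bound(cum.begin(), cum.end(), unif(gen) * tot) - cum.begin()];
              if (kk == t) continue;
              double gk = sigm(arma::dot(Ctx.row(kk), v));
              gv += gk * Ctx.row(kk).t();
              Ctx.row(kk) -= lr * gk * v.t();
            }
          }
          if (!any) continue;
          // ---- backward ----
          if (train_ab) beta[r] -= lr * arma::dot(attr, gv);
          Dz[zi] -= lr * beta[r] * (xi.t() * gv.t());
          Wh[zi] -= lr * (xi.t() * gv.t());
          bh[zi] -= lr * gv;
          gy = alpha[r] * (M[r] * gv);
          if (train_ab) alpha[r] -= lr * arma::dot(M[r].t() * y, gv);
          M[r] -= lr * alpha[r] * (y * gv.t());
          ga = Dm.t() * gy;
          gs = a % (ga - arma::dot(a, ga));
          gw.zeros();
          gW.zeros();
          for (int rp = 0; rp < R; ++rp) {
            gw += gs[rp] * Tm.col(rp);
            pre = gs[rp] * (watt[r] % (1.0 - arma::square(Tm.col(rp))));
            gW += pre * Dm.col(rp).t();
            gd = Watt[r].t() * pre + a[rp] * gy;
            Gd[rp].row(i) += gd.t();
            Gd_dirty[rp] = true;
          }
          watt[r] -= lr * gw;
          Watt[r] -= lr * gW;
          if (++since_flush >= batch) { flush(); since_flush = 0; }
        }
      }
    }
  }
  flush();

  // ---- repack ----
  List Wh_o(2), bh_o(2), Dz_o(2), Wg_o(2), bg_o(2);
  for (int zz = 0; zz < 2; ++zz) {
    Wh_o[zz] = Wh[zz]; bh_o[zz] = bh[zz]; Dz_o[zz] = Dz[zz];
    List wgl(R), bgl(R);
    for (int r = 0; r < R; ++r) { wgl[r] = Wg[zz][r]; bgl[r] = bg[zz][r]; }
    Wg_o[zz] = wgl; bg_o[zz] = bgl;
  }
  List Watt_o(R), watt_o(R), M_o(R);
  for (int r = 0; r < R; ++r) { Watt_o[r] = Watt[r]; watt_o[r] = watt[r]; M_o[r] = M[r]; }
  return List::create(_["Wh"] = Wh_o, _["bh"] = bh_o, _["Wg"] = Wg_o,
                      _["bg"] = bg_o, _["Watt"] = Watt_o, _["watt"] = watt_o,
                      _["M"] = M_o, _["Dz"] = Dz_o, _["alpha"] = alpha,
                      _["beta"] = beta, _["Ctx"] = Ctx);
}
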