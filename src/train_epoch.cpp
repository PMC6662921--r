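// Minibatch Adam epoch for the shared-trunk feed-forward nets.
//
// The R side owns all randomness (parameter initialization and the
// minibatch permutation); this kernel performs one epoch of deterministic
// arithmetic: forward pass with batch normalization, backpropagation, and
// per-tensor Adam updates, mirroring the reference R implementation in
// R/nn.R step for step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Single fused pass over the tensor: update both moments and the
// parameter in place, minimizing memory traffic (Adam runs once per
// minibatch on every weight, so this dominates the epoch cost).
static inline void adam_fused(double* p, const double* g, double* m,
                              double* v, arma::uword n, double lr,
                              double b1, double b2, double t) {
  const double c1 = 1.0 / (1.0 - std::pow(b1, t));
  const double c2 = 1.0 / (1.0 - std::pow(b2, t));
  for (arma::uword i = 0; i < n; ++i) {
    const double gi = g[i];
    m[i] = b1 * m[i] + (1 - b1) * gi;
    v[i] = b2 * v[i] + (1 - b2) * gi * gi;
    p[i] -= lr * (m[i] * c1) / (std::sqrt(v[i] * c2) + 1e-8);
  }
}

static inline void adam_update(arma::mat& param, const arma::mat& grad,
                               arma::mat& m, arma::mat& v, double lr,
                               double b1, double b2, double t) {
  adam_fused(param.memptr(), grad.memptr(), m.memptr(), v.memptr(),
             param.n_elem, lr, b1, b2, t);
}

static inline void adam_update_vec(arma::rowvec& param,
                                   const arma::rowvec& grad, arma::rowvec& m,
                                   arma::rowvec& v, double lr, double b1,
                                   double b2, double t) {
  adam_fused(param.memptr(), grad.memptr(), m.memptr(), v.memptr(),
             param.n_elem, lr, b1, b2, t);
}

// [[Rcpp::export]]
List cpp_train_epoch(const arma::mat& X, const arma::mat& Y,
                     const arma::rowvec& task_w, List net, List states,
                     const arma::uvec& perm, int batch_size, double lr,
                     double b1, double b2, double bn_mom, double bn_eps,
                     int step_offset) {
  List layers = net["layers"];
  const int n_layers = layers.size();

  std::vector<arma::mat> W(n_layers);
  std::vector<arma::rowvec> gamma(n_layers), beta(n_layers),
      run_mean(n_layers), run_var(n_layers);
  List st_layers = states["layers"];
  std::vector<arma::mat> mW(n_layers), vW(n_layers);
  std::vector<arma::rowvec> mg(n_layers), vg(n_layers), mb(n_layers),
      vb(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    List ly = layers[l];
    W[l] = as<arma::mat>(ly["W"]);
    gamma[l] = as<arma::rowvec>(ly["gamma"]);
    beta[l] = as<arma::rowvec>(ly["beta"]);
    run_mean[l] = as<arma::rowvec>(ly["run_mean"]);
    run_var[l] = as<arma::rowvec>(ly["run_var"]);
    List st = st_layers[l];
    List stW = st["W"], stg = st["gamma"], stb = st["beta"];
    mW[l] = as<arma::mat>(stW["m"]);
    vW[l] = as<arma::mat>(stW["v"]);
    mg[l] = as<arma::rowvec>(stg["m"]);
    vg[l] = as<arma::rowvec>(stg["v"]);
    mb[l] = as<arma::rowvec>(stb["m"]);
    vb[l] = as<arma::rowvec>(stb["v"]);
  }
  arma::mat head_W = as<arma::mat>(net["head_W"]);
  arma::rowvec head_b = as<arma::rowvec>(net["head_b"]);
  List st_hW = states["head_W"], st_hb = states["head_b"];
  arma::mat m_hW = as<arma::mat>(st_hW["m"]);
  arma::mat v_hW = as<arma::mat>(st_hW["v"]);
  arma::rowvec m_hb = as<arma::rowvec>(st_hb["m"]);
  arma::rowvec v_hb = as<arma::rowvec>(st_hb["v"]);

  const arma::uword n = X.n_rows;
  int step = step_offset;

  std::vector<arma::mat> Xin(n_layers), Zhat(n_layers), A(n_layers);
  std::vector<arma::rowvec> inv_std(n_layers);

  for (arma::uword s = 0; s < n; s += batch_size) {
    arma::uword e = std::min(n - 1, s + batch_size - 1);
    arma::uword m_b = e - s + 1;
    if (m_b < 2) continue;  // batch norm needs at least two rows
    arma::uvec idx = perm.subvec(s, e);
    arma::mat H = X.rows(idx);
    arma::mat Yb = Y.rows(idx);

    // forward (training mode)
    for (int l = 0; l < n_layers; ++l) {
      Xin[l] = H;
      arma::mat Z = H * W[l];
      arma::rowvec mu = arma::mean(Z, 0);
      Z.each_row() -= mu;
      arma::rowvec var = arma::mean(arma::square(Z), 0);
      inv_std[l] = 1.0 / arma::sqrt(var + bn_eps);
      Z.each_row() %= inv_std[l];
      Zhat[l] = Z;
      Z.each_row() %= gamma[l];
      Z.each_row() += beta[l];
      A[l] = Z;
      H = arma::clamp(Z, 0.0, arma::datum::inf);
      run_mean[l] = bn_mom * run_mean[l] + (1 - bn_mom) * mu;
      run_var[l] = bn_mom * run_var[l] + (1 - bn_mom) * var;
    }
    arma::mat logits = H * head_W;
    logits.each_row() += head_b;
    arma::mat P = 1.0 / (1.0 + arma::exp(-logits));
    ++step;

    arma::mat dlogits = (P - Yb) / double(m_b);
    dlogits.each_row() %= task_w;
    arma::mat g_hW = H.t() * dlogits;
    arma::rowvec g_hb = arma::sum(dlogits, 0);
    arma::mat dH = dlogits * head_W.t();

    adam_update(head_W, g_hW, m_hW, v_hW, lr, b1, b2, step);
    adam_update_vec(head_b, g_hb, m_hb, v_hb, lr, b1, b2, step);

    for (int l = n_layers - 1; l >= 0; --l) {
      arma::mat dA = dH % (A[l] > 0);
      arma::rowvec g_gamma = arma::sum(dA % Zhat[l], 0);
      arma::rowvec g_beta = arma::sum(dA, 0);
      arma::mat dZhat = dA;
      dZhat.each_row() %= gamma[l];
      arma::rowvec sum_d = arma::sum(dZhat, 0);
      arma::rowvec sum_dz = arma::sum(dZhat % Zhat[l], 0);
      arma::mat dZ = double(m_b) * dZhat;
      dZ.each_row() -= sum_d;
      dZ -= Zhat[l].each_row() % sum_dz;
      dZ.each_row() %= inv_std[l] / double(m_b);
      arma::mat g_W = Xin[l].t() * dZ;
      if (l > 0) dH = dZ * W[l].t();

      adam_update(W[l], g_W, mW[l], vW[l], lr, b1, b2, step);
      adam_update_vec(gamma[l], g_gamma, mg[l], vg[l], lr, b1, b2, step);
      adam_update_vec(beta[l], g_beta, mb[l], vb[l], lr, b1, b2, step);
    }
  }

  List out_layers(n_layers), out_states(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    out_layers[l] = List::create(
        _["W"] = W[l], _["gamma"] = as<NumericVector>(wrap(gamma[l])),
        _["beta"] = as<NumericVector>(wrap(beta[l])),
        _["run_mean"] = as<NumericVector>(wrap(run_mean[l])),
        _["run_var"] = as<NumericVector>(wrap(run_var[l])));
    out_states[l] = List::create(
        _["W"] = List::create(_["m"] = mW[l], _["v"] = vW[l]),
        _["gamma"] = List::create(_["m"] = as<NumericVector>(wrap(mg[l])),
                                  _["v"] = as<NumericVector>(wrap(vg[l]))),
        _["beta"] = List::create(_["m"] = as<NumericVector>(wrap(mb[l])),
                                 _["v"] = as<NumericVector>(wrap(vb[l]))));
  }
  return List::create(
      _["net"] = List::create(
          _["layers"] = out_layers, _["head_W"] = head_W,
          _["head_b"] = as<NumericVector>(wrap(head_b))),
      _["states"] = List::create(
          _["layers"] = out_states,
          _["head_W"] = List::create(_["m"] = m_hW, _["v"] = v_hW),
          _["head_b"] =
              List::create(_["m"] = as<NumericVector>(wrap(m_hb)),
                           _["v"] = as<NumericVector>(wrap(v_hb)))),
      _["steps"] = step);
}
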