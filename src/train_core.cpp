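// Single-precision training core: forward/backward passes through the
// encoder, decoder and latent operator chains for the composite objective,
// plus the Adam loop over sliding windows. Mirrors the double-precision R
// reference implementation (ekatp_loss_grad / train_ekatp engine = "r"),
// which is kept as the oracle it is tested against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::stop;

namespace {

struct Net {
  std::vector<fmat> W;
  std::vector<fvec> b;
  bool tanh_act;
};

struct NetGrad {
  std::vector<fmat> dW;
  std::vector<fvec> db;
};

Net net_from_list(const List& net, bool tanh_act) {
  Net out;
  out.tanh_act = tanh_act;
  List W = net["W"], b = net["b"];
  for (int l = 0; l < W.size(); ++l) {
    out.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(W[l])));
    out.b.push_back(conv_to<fvec>::from(Rcpp::as<vec>(b[l])));
  }
  return out;
}

List net_to_list(const Net& net) {
  List W(net.W.size()), b(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    W[l] = conv_to<mat>::from(net.W[l]);
    b[l] = conv_to<vec>::from(net.b[l]);
  }
  return List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b);
}

void net_forward(const Net& net, fmat X, std::vector<fmat>& A) {
  const size_t nl = net.W.size();
  A.resize(nl + 1);
  A[0] = std::move(X);
  for (size_t l = 0; l < nl; ++l) {
    fmat Z = net.W[l] * A[l];
    Z.each_col() += net.b[l];
    if (l + 1 < nl && net.tanh_act) Z = tanh(Z);
    A[l + 1] = std::move(Z);
  }
}

// Returns the gradient w.r.t. the network input; fills parameter gradients.
fmat net_backward(const Net& net, const std::vector<fmat>& A, fmat dZ,
                  NetGrad& g) {
  const int nl = (int)net.W.size();
  g.dW.assign(nl, fmat());
  g.db.assign(nl, fvec());
  for (int l = nl - 1; l >= 0; --l) {
    g.dW[l] = dZ * A[l].t();
    g.db[l] = sum(dZ, 1);
    fmat dA = net.W[l].t() * dZ;
    if (l > 0 && net.tanh_act) dA %= (1.0f - square(A[l]));
    dZ = std::move(dA);
  }
  return dZ;
}

inline fmat cf_apply(const fvec& a, const fmat& Y) {
  const uword L = Y.n_rows;
  fmat out(L, Y.n_cols);
  out.rows(0, L - 2) = Y.rows(1, L - 1);
  out.row(L - 1) = a.t() * Y;
  return out;
}

inline fmat cb_apply(const fvec& b, const fmat& Y) {
  const uword L = Y.n_rows;
  fmat out(L, Y.n_cols);
  out.row(0) = b.t() * Y;
  out.rows(1, L - 1) = Y.rows(0, L - 2);
  return out;
}

// Pull one gradient step back through a forward-companion application with
// input Y; accumulates the coefficient gradient and returns the input grad.
inline fmat cf_pullback(const fvec& a, const fmat& Y, const fmat& G,
                        fvec& da) {
  const uword L = Y.n_rows;
  da += Y * G.row(L - 1).t();
  fmat Gn = a * G.row(L - 1);
  Gn.rows(1, L - 1) += G.rows(0, L - 2);
  return Gn;
}

inline fmat cb_pullback(const fvec& b, const fmat& Y, const fmat& G,
                        fvec& db) {
  const uword L = Y.n_rows;
  db += Y * G.row(0).t();
  fmat Gn = b * G.row(0);
  Gn.rows(0, L - 2) += G.rows(1, L - 1);
  return Gn;
}

inline double mean_sq(const fmat& M) {
  return accu(conv_to<mat>::from(square(M))) / (double)M.n_elem;
}

struct Grads {
  NetGrad enc, dec;
  fvec da, db;
  fmat dK;
};

// One batched evaluation of the composite objective and its gradient.
// Fall: n x ((2k+1) * B), column block j (B columns) at window offset
// j - (k + 1). Losses are written to rep[0..5] (id, fwd, bwd, idy, con,
// total).
void loss_grad(const Net& enc, const Net& dec, const fvec& a, const fvec& b,
               const fmat& K, bool dense, const fmat& Fall, int B, int k,
               const vec& w, double* rep, Grads& g, bool want_grad) {
  const int jc = k;  // 0-based center block index
  const uword L = dense ? K.n_rows : a.n_elem;
  const uword n = Fall.n_rows;
  auto blk = [&](int j) { return span(j * B, (j + 1) * B - 1); };

  std::vector<fmat> Ae;
  net_forward(enc, Fall, Ae);
  const fmat& Yall = Ae.back();
  fmat Y0 = Yall.cols(blk(jc));
  fmat Fc = Fall.cols(blk(jc));

  std::vector<fmat> ZC(k + 1), ZD;
  ZC[0] = Y0;
  for (int s = 1; s <= k; ++s)
    ZC[s] = dense ? fmat(K * ZC[s - 1]) : cf_apply(a, ZC[s - 1]);
  std::vector<std::vector<fmat>> U, V;
  if (!dense) {
    ZD.resize(k + 1);
    ZD[0] = Y0;
    for (int s = 1; s <= k; ++s) ZD[s] = cb_apply(b, ZD[s - 1]);
    U.resize(k + 1);
    V.resize(k + 1);
    for (int s = 1; s <= k; ++s) {
      U[s].resize(s + 1);
      U[s][0] = ZC[s];
      for (int r = 1; r <= s; ++r) U[s][r] = cb_apply(b, U[s][r - 1]);
      V[s].resize(s + 1);
      V[s][0] = ZD[s];
      for (int r = 1; r <= s; ++r) V[s][r] = cf_apply(a, V[s][r - 1]);
    }
  }

  const int nblocks = dense ? 1 + k : 1 + 4 * k;
  fmat Xdec(L, (uword)nblocks * B);
  Xdec.cols(blk(0)) = Y0;
  for (int s = 1; s <= k; ++s) {
    Xdec.cols(blk(s)) = ZC[s];
    if (!dense) {
      Xdec.cols(blk(k + s)) = ZD[s];
      Xdec.cols(blk(2 * k + s)) = U[s][s];
      Xdec.cols(blk(3 * k + s)) = V[s][s];
    }
  }
  std::vector<fmat> Ad;
  net_forward(dec, Xdec, Ad);
  const fmat& Fdec = Ad.back();

  const float sc_amb = 2.0f / (float)(n * B);
  const float sc_lat = 2.0f / (float)(L * B);
  const float wid = w(0), wfwd = w(1), wbwd = w(2), widy = w(3), wcon = w(4);
  double l_id = 0, l_fwd = 0, l_bwd = 0, l_idy = 0, l_con = 0;

  fmat R_id = Fdec.cols(blk(0)) - Fc;
  l_id = mean_sq(R_id);
  std::vector<fmat> R_fwd(k + 1), E_f(k + 1), R_bwd, E_b, R_u, R_v;
  if (!dense) {
    R_bwd.resize(k + 1); E_b.resize(k + 1);
    R_u.resize(k + 1); R_v.resize(k + 1);
  }
  for (int s = 1; s <= k; ++s) {
    R_fwd[s] = Fdec.cols(blk(s)) - Fall.cols(blk(jc + s));
    l_fwd += mean_sq(R_fwd[s]) / k;
    E_f[s] = ZC[s] - Yall.cols(blk(jc + s));
    l_idy += mean_sq(E_f[s]) / k;
    if (!dense) {
      R_bwd[s] = Fdec.cols(blk(k + s)) - Fall.cols(blk(jc - s));
      l_bwd += mean_sq(R_bwd[s]) / k;
      E_b[s] = ZD[s] - Yall.cols(blk(jc - s));
      l_idy += mean_sq(E_b[s]) / k;
      R_u[s] = Fdec.cols(blk(2 * k + s)) - Fc;
      R_v[s] = Fdec.cols(blk(3 * k + s)) - Fc;
      l_con += (mean_sq(R_u[s]) + mean_sq(R_v[s])) / k;
    }
  }
  rep[0] = l_id; rep[1] = l_fwd; rep[2] = l_bwd; rep[3] = l_idy; rep[4] = l_con;
  rep[5] = wid * l_id + wfwd * l_fwd + wbwd * l_bwd + widy * l_idy +
           wcon * l_con;
  if (!want_grad) return;

  fmat dXdec(size(Fdec), fill::zeros);
  dXdec.cols(blk(0)) = (wid * sc_amb) * R_id;
  for (int s = 1; s <= k; ++s) {
    dXdec.cols(blk(s)) = (wfwd / k * sc_amb) * R_fwd[s];
    if (!dense) {
      dXdec.cols(blk(k + s)) = (wbwd / k * sc_amb) * R_bwd[s];
      dXdec.cols(blk(2 * k + s)) = (wcon / k * sc_amb) * R_u[s];
      dXdec.cols(blk(3 * k + s)) = (wcon / k * sc_amb) * R_v[s];
    }
  }
  fmat dLat = net_backward(dec, Ad, std::move(dXdec), g.dec);

  fmat gYall(size(Yall), fill::zeros);
  g.da = dense ? fvec() : fvec(L, fill::zeros);
  g.db = dense ? fvec() : fvec(L, fill::zeros);
  g.dK = dense ? fmat(L, L, fill::zeros) : fmat();

  std::vector<fmat> gZC(k + 1), gZD;
  if (!dense) gZD.resize(k + 1);
  for (int s = 1; s <= k; ++s) {
    gZC[s] = dLat.cols(blk(s)) + (widy / k * sc_lat) * E_f[s];
    gYall.cols(blk(jc + s)) -= (widy / k * sc_lat) * E_f[s];
    if (!dense) {
      gZD[s] = dLat.cols(blk(k + s)) + (widy / k * sc_lat) * E_b[s];
      gYall.cols(blk(jc - s)) -= (widy / k * sc_lat) * E_b[s];
    }
  }

  if (!dense) {
    for (int s = 1; s <= k; ++s) {
      fmat gu = dLat.cols(blk(2 * k + s));
      for (int r = s; r >= 1; --r) gu = cb_pullback(b, U[s][r - 1], gu, g.db);
      gZC[s] += gu;
      fmat gv = dLat.cols(blk(3 * k + s));
      for (int r = s; r >= 1; --r) gv = cf_pullback(a, V[s][r - 1], gv, g.da);
      gZD[s] += gv;
    }
  }

  fmat gY0 = dLat.cols(blk(0));
  fmat gcur(size(Y0), fill::zeros);
  for (int s = k; s >= 1; --s) {
    gcur += gZC[s];
    if (dense) {
      g.dK += gcur * ZC[s - 1].t();
      gcur = K.t() * gcur;
    } else {
      gcur = cf_pullback(a, ZC[s - 1], gcur, g.da);
    }
  }
  gY0 += gcur;
  if (!dense) {
    gcur.zeros();
    for (int s = k; s >= 1; --s) {
      gcur += gZD[s];
      gcur = cb_pullback(b, ZD[s - 1], gcur, g.db);
    }
    gY0 += gcur;
  }
  gYall.cols(blk(jc)) += gY0;
  net_backward(enc, Ae, std::move(gYall), g.enc);
}

struct AdamState {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
};

template <class M>
inline void adam_upd(M& p, M& m, M& v, const M& grad, float lr, float c1,
                     float c2) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  m = b1 * m + (1.0f - b1) * grad;
  v = b2 * v + (1.0f - b2) * square(grad);
  p -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_train")]]
List cpp_train(const List& enc_in, const List& dec_in, const List& op_in,
               bool dense, bool tanh_act, const arma::mat& F,
               const arma::imat& perms, int k, int batch_size, double lr,
               bool freeze, const arma::vec& w) {
  Net enc = net_from_list(enc_in, tanh_act);
  Net dec = net_from_list(dec_in, tanh_act);
  fvec a, b;
  fmat K;
  if (dense) {
    K = conv_to<fmat>::from(Rcpp::as<mat>(op_in["K"]));
  } else {
    a = conv_to<fvec>::from(Rcpp::as<vec>(op_in["a"]));
    b = conv_to<fvec>::from(Rcpp::as<vec>(op_in["b"]));
  }
  const uword L = dense ? K.n_rows : a.n_elem;
  const fmat Ff = conv_to<fmat>::from(F);
  const int epochs = perms.n_rows, nwin = perms.n_cols;
  const int W = 2 * k + 1;

  AdamState ae, ad;
  auto init_state = [](const Net& net, AdamState& st) {
    for (size_t l = 0; l < net.W.size(); ++l) {
      st.mW.push_back(fmat(size(net.W[l]), fill::zeros));
      st.vW.push_back(fmat(size(net.W[l]), fill::zeros));
      st.mb.push_back(fvec(net.b[l].n_elem, fill::zeros));
      st.vb.push_back(fvec(net.b[l].n_elem, fill::zeros));
    }
  };
  init_state(enc, ae);
  init_state(dec, ad);
  fvec ma(L, fill::zeros), va(L, fill::zeros), mb_(L, fill::zeros),
      vb_(L, fill::zeros);
  fmat mK, vK;
  if (dense) { mK.zeros(L, L); vK.zeros(L, L); }

  mat history(epochs, 6, fill::zeros);
  Grads g;
  double rep[6];
  long tstep = 0;
  const float flr = (float)lr;

  for (int ep = 0; ep < epochs; ++ep) {
    const int nb = (nwin + batch_size - 1) / batch_size;
    rowvec acc(6, fill::zeros);
    for (int ib = 0; ib < nb; ++ib) {
      const int lo = ib * batch_size;
      const int hi = std::min(nwin, lo + batch_size) - 1;
      const int B = hi - lo + 1;
      fmat Fall(Ff.n_rows, (uword)W * B);
      for (int j = 0; j < W; ++j) {
        const int off = j - k;
        for (int bb = 0; bb < B; ++bb)
          Fall.col((uword)j * B + bb) = Ff.col(perms(ep, lo + bb) + off);
      }
      loss_grad(enc, dec, a, b, K, dense, Fall, B, k, w, rep, g, true);
      if (!std::isfinite(rep[5]))
        stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      ++tstep;
      const float c1 = 1.0f - std::pow(0.9f, (float)tstep);
      const float c2 = 1.0f - std::pow(0.999f, (float)tstep);
      if (!freeze) {
        for (size_t l = 0; l < enc.W.size(); ++l) {
          adam_upd(enc.W[l], ae.mW[l], ae.vW[l], g.enc.dW[l], flr, c1, c2);
          adam_upd(enc.b[l], ae.mb[l], ae.vb[l], g.enc.db[l], flr, c1, c2);
        }
        for (size_t l = 0; l < dec.W.size(); ++l) {
          adam_upd(dec.W[l], ad.mW[l], ad.vW[l], g.dec.dW[l], flr, c1, c2);
          adam_upd(dec.b[l], ad.mb[l], ad.vb[l], g.dec.db[l], flr, c1, c2);
        }
      }
      if (dense) {
        adam_upd(K, mK, vK, g.dK, flr, c1, c2);
      } else {
        adam_upd(a, ma, va, g.da, flr, c1, c2);
        adam_upd(b, mb_, vb_, g.db, flr, c1, c2);
      }
      for (int j = 0; j < 6; ++j) acc(j) += rep[j];
    }
    history.row(ep) = acc / nb;
    if (!dense &&
        (std::abs(a(0)) < 1e-6f || std::abs(b(L - 1)) < 1e-6f))
      stop("companion constraint violated at epoch %d (a1 = %g, bL = %g)",
           ep + 1, (double)a(0), (double)b(L - 1));
    Rcpp::checkUserInterrupt();
  }

  List op_out = dense
      ? List::create(Rcpp::Named("K") = conv_to<mat>::from(K))
      : List::create(Rcpp::Named("a") = conv_to<vec>::from(a),
                     Rcpp::Named("b") = conv_to<vec>::from(b));
  return List::create(Rcpp::Named("enc") = net_to_list(enc),
                      Rcpp::Named("dec") = net_to_list(dec),
                      Rcpp::Named("op") = op_out,
                      Rcpp::Named("history") = history);
}
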