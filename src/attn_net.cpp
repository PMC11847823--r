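// Core forward/backward passes of the attention-DANN network.
// Mirrors the R reference implementations (layer_norm,
// spectral_self_attention, graph_layer, spatial_attention, temporal_encode,
// temporal_attention, heads) exactly; the test suite asserts agreement with
// the R layer functions and with finite-difference gradients.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct Config {
  int K, F, U, m, w, C;
  bool abl_channel, abl_freq, abl_spectral, abl_graph, abl_spatial,
       abl_bilstm, abl_temporal;
  bool use_graph;  // S supplied and graph layer not ablated
};

struct Params {
  rowvec ln_gamma, ln_beta;
  mat Wg; rowvec bg;
  mat Wb; rowvec cb; vec ub;
  mat Wa; rowvec ca; vec ua;
  mat Wy; vec by;
  vec wd; double bd;
  mat Wl; vec bl;                       // bilstm-ablated dense
  mat Wx_f, Wh_f, Wx_b, Wh_b; vec b_f, b_b;
};

struct Grads {
  rowvec ln_gamma, ln_beta;
  mat Wg; rowvec bg;
  mat Wb; rowvec cb; vec ub;
  mat Wa; rowvec ca; vec ua;
  mat Wy; vec by;
  vec wd; double bd = 0.0;
  mat Wl; vec bl;
  mat Wx_f, Wh_f, Wx_b, Wh_b; vec b_f, b_b;
};

Params unpack(const Rcpp::List& p, const Config& cfg) {
  Params P;
  P.ln_gamma = Rcpp::as<rowvec>(p["ln_gamma"]);
  P.ln_beta  = Rcpp::as<rowvec>(p["ln_beta"]);
  P.Wg = Rcpp::as<mat>(p["Wg"]); P.bg = Rcpp::as<rowvec>(p["bg"]);
  P.Wb = Rcpp::as<mat>(p["Wb"]); P.cb = Rcpp::as<rowvec>(p["cb"]);
  P.ub = Rcpp::as<vec>(p["ub"]);
  P.Wa = Rcpp::as<mat>(p["Wa"]); P.ca = Rcpp::as<rowvec>(p["ca"]);
  P.ua = Rcpp::as<vec>(p["ua"]);
  P.Wy = Rcpp::as<mat>(p["Wy"]); P.by = Rcpp::as<vec>(p["by"]);
  P.wd = Rcpp::as<vec>(p["wd"]); P.bd = Rcpp::as<double>(p["bd"]);
  if (cfg.abl_bilstm) {
    P.Wl = Rcpp::as<mat>(p["Wl"]); P.bl = Rcpp::as<vec>(p["bl"]);
  } else {
    P.Wx_f = Rcpp::as<mat>(p["Wx_f"]); P.Wh_f = Rcpp::as<mat>(p["Wh_f"]);
    P.b_f = Rcpp::as<vec>(p["b_f"]);
    P.Wx_b = Rcpp::as<mat>(p["Wx_b"]); P.Wh_b = Rcpp::as<mat>(p["Wh_b"]);
    P.b_b = Rcpp::as<vec>(p["b_b"]);
  }
  return P;
}

Grads zero_grads(const Params& P, const Config& cfg) {
  Grads g;
  g.ln_gamma = zeros<rowvec>(P.ln_gamma.n_elem);
  g.ln_beta = zeros<rowvec>(P.ln_beta.n_elem);
  g.Wg = zeros(size(P.Wg)); g.bg = zeros<rowvec>(P.bg.n_elem);
  g.Wb = zeros(size(P.Wb)); g.cb = zeros<rowvec>(P.cb.n_elem);
  g.ub = zeros<vec>(P.ub.n_elem);
  g.Wa = zeros(size(P.Wa)); g.ca = zeros<rowvec>(P.ca.n_elem);
  g.ua = zeros<vec>(P.ua.n_elem);
  g.Wy = zeros(size(P.Wy)); g.by = zeros<vec>(P.by.n_elem);
  g.wd = zeros<vec>(P.wd.n_elem);
  if (cfg.abl_bilstm) {
    g.Wl = zeros(size(P.Wl)); g.bl = zeros<vec>(P.bl.n_elem);
  } else {
    g.Wx_f = zeros(size(P.Wx_f)); g.Wh_f = zeros(size(P.Wh_f));
    g.b_f = zeros<vec>(P.b_f.n_elem);
    g.Wx_b = zeros(size(P.Wx_b)); g.Wh_b = zeros(size(P.Wh_b));
    g.b_b = zeros<vec>(P.b_b.n_elem);
  }
  return g;
}

mat row_softmax(const mat& M) {
  mat E = exp(M.each_col() - max(M, 1));
  return E.each_col() / sum(E, 1);
}

vec softmax_vec(const vec& v) {
  vec e = exp(v - v.max());
  return e / accu(e);
}

mat row_softmax_back(const mat& P, const mat& dP) {
  return P % (dP.each_col() - sum(dP % P, 1));
}

vec softmax_back_vec(const vec& p, const vec& dp) {
  return p % (dp - dot(dp, p));
}

inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// caches for one sample
struct SampleCache {
  cube Xhat, N, Z, H, Mpre;        // (K,F|U,w)
  cube P1;                          // (K,K,w)
  cube P2;                          // (F,F,w)
  cube Uh;                          // (K,U,w)
  mat Phi;                          // (w,K)
  mat Xseq;                         // (w, K*U)
  mat G;                            // (w, 2m)
  // lstm caches (per direction): gates (4m x w), c (m x w), H (w x m)
  mat zf_i, zf_f, zf_g, zf_o, cf, tcf, Hf;
  mat zb_i, zb_f, zb_g, zb_o, cb_, tcb, Hb;
  mat Ah;                           // (w, 2m)
  vec psi, tvec, td;
  vec p_class; double p_domain;
};

void lstm_dir(const mat& Xseq, const mat& Wx, const mat& Wh, const vec& b,
              bool reverse, mat& gi, mat& gf, mat& gg, mat& go, mat& cs,
              mat& tcs, mat& H) {
  int w = Xseq.n_rows, m = b.n_elem / 4;
  gi.set_size(m, w); gf.set_size(m, w); gg.set_size(m, w); go.set_size(m, w);
  cs.set_size(m, w); tcs.set_size(m, w); H.set_size(w, m);
  vec h = zeros<vec>(m), c = zeros<vec>(m);
  for (int s = 0; s < w; ++s) {
    int t = reverse ? (w - 1 - s) : s;
    vec z = Wx * Xseq.row(t).t() + Wh * h + b;
    vec i_ = 1.0 / (1.0 + exp(-z.subvec(0, m - 1)));
    vec f_ = 1.0 / (1.0 + exp(-z.subvec(m, 2 * m - 1)));
    vec g_ = tanh(z.subvec(2 * m, 3 * m - 1));
    vec o_ = 1.0 / (1.0 + exp(-z.subvec(3 * m, 4 * m - 1)));
    c = f_ % c + i_ % g_;
    vec tc = tanh(c);
    h = o_ % tc;
    gi.col(t) = i_; gf.col(t) = f_; gg.col(t) = g_; go.col(t) = o_;
    cs.col(t) = c; tcs.col(t) = tc;
    H.row(t) = h.t();
  }
}

void lstm_dir_back(const mat& dH, const mat& Xseq, const mat& Wx,
                   const mat& Wh, bool reverse,
                   const mat& gi, const mat& gf, const mat& gg, const mat& go,
                   const mat& cs, const mat& tcs, const mat& Hst,
                   mat& dWx, mat& dWh, vec& db, mat& dX) {
  int w = dH.n_rows, m = dH.n_cols;
  vec dh_carry = zeros<vec>(m), dc_carry = zeros<vec>(m);
  for (int s = w - 1; s >= 0; --s) {
    int t = reverse ? (w - 1 - s) : s;
    vec dh = dH.row(t).t() + dh_carry;
    vec o_ = go.col(t), i_ = gi.col(t), f_ = gf.col(t), g_ = gg.col(t);
    vec tc = tcs.col(t);
    vec do_ = dh % tc;
    vec dtc = dh % o_ % (1.0 - tc % tc) + dc_carry;
    vec c_prev = (s == 0) ? zeros<vec>(m)
                          : vec(cs.col(reverse ? (w - s) : (s - 1)));
    vec di = dtc % g_, df = dtc % c_prev, dg = dtc % i_;
    dc_carry = dtc % f_;
    vec dz(4 * m);
    dz.subvec(0, m - 1) = di % i_ % (1.0 - i_);
    dz.subvec(m, 2 * m - 1) = df % f_ % (1.0 - f_);
    dz.subvec(2 * m, 3 * m - 1) = dg % (1.0 - g_ % g_);
    dz.subvec(3 * m, 4 * m - 1) = do_ % o_ % (1.0 - o_);
    vec h_prev = (s == 0) ? zeros<vec>(m)
                          : vec(Hst.row(reverse ? (w - s) : (s - 1)).t());
    dWx += dz * Xseq.row(t);
    dWh += dz * h_prev.t();
    db += dz;
    dX.row(t) += (Wx.t() * dz).t();
    dh_carry = Wh.t() * dz;
  }
}

void forward_sample(const cube& X, const Params& P, const Config& cfg,
                    const mat& S, const vec* drop_mask, SampleCache& C) {
  int K = cfg.K, F = cfg.F, U = cfg.U, m = cfg.m, w = cfg.w;
  C.Xhat.set_size(K, F, w); C.N.set_size(K, F, w); C.Z.set_size(K, F, w);
  C.H.set_size(K, U, w); C.Mpre.set_size(K, U, w);
  if (!cfg.abl_spectral && !cfg.abl_channel) C.P1.set_size(K, K, w);
  if (!cfg.abl_spectral && !cfg.abl_freq) C.P2.set_size(F, F, w);
  if (!cfg.abl_spatial) C.Uh.set_size(K, U, w);
  C.Phi.set_size(w, K);
  C.Xseq.set_size(w, K * U);
  for (int t = 0; t < w; ++t) {
    mat X0 = X.slice(t);                          // K x F
    vec mu = mean(X0, 1);
    mat cent = X0.each_col() - mu;
    vec v = mean(cent % cent, 1);
    mat xhat = cent.each_col() / sqrt(v + 1e-5);
    C.Xhat.slice(t) = xhat;
    mat N = xhat.each_row() % P.ln_gamma;
    N.each_row() += P.ln_beta;
    C.N.slice(t) = N;
    mat Z;
    if (cfg.abl_spectral) {
      Z = N;
    } else {
      mat B1, B2;
      if (!cfg.abl_channel) {
        mat P1 = row_softmax(N * N.t() / F);
        C.P1.slice(t) = P1;
        B1 = P1 * N + N;
      } else B1 = N;
      if (!cfg.abl_freq) {
        mat P2 = row_softmax(N.t() * N / K);
        C.P2.slice(t) = P2;
        B2 = N * P2.t() + N;
      } else B2 = N;
      Z = B1 + B2;
    }
    C.Z.slice(t) = Z;
    mat M = (cfg.use_graph ? mat(S * Z * P.Wg) : mat(Z * P.Wg));
    M.each_row() += P.bg;
    C.Mpre.slice(t) = M;
    mat H = M;
    H.transform([](double x) { return x > 0 ? x : std::exp(x) - 1.0; });
    C.H.slice(t) = H;
    vec phi;
    mat V;
    if (cfg.abl_spatial) {
      phi = ones<vec>(K) / K;
      V = H / K;
    } else {
      mat HW = H * P.Wb;
      mat Uh = tanh(HW.each_row() + P.cb);
      C.Uh.slice(t) = Uh;
      phi = softmax_vec(Uh * P.ub);
      V = H.each_col() % phi;
    }
    C.Phi.row(t) = phi.t();
    C.Xseq.row(t) = vectorise(V).t();             // column-major, as in R
  }
  // temporal encoding
  if (cfg.abl_bilstm) {
    C.G = (C.Xseq * P.Wl.t());
    C.G.each_row() += P.bl.t();
  } else {
    lstm_dir(C.Xseq, P.Wx_f, P.Wh_f, P.b_f, false,
             C.zf_i, C.zf_f, C.zf_g, C.zf_o, C.cf, C.tcf, C.Hf);
    lstm_dir(C.Xseq, P.Wx_b, P.Wh_b, P.b_b, true,
             C.zb_i, C.zb_f, C.zb_g, C.zb_o, C.cb_, C.tcb, C.Hb);
    C.G = join_rows(C.Hf, C.Hb);
  }
  // temporal attention
  if (cfg.abl_temporal) {
    C.psi = ones<vec>(w) / w;
    C.tvec = mean(C.G, 0).t();
  } else {
    mat GW = C.G * P.Wa;
    C.Ah = tanh(GW.each_row() + P.ca);
    C.psi = softmax_vec(C.Ah * P.ua);
    C.tvec = (C.psi.t() * C.G).t();
  }
  C.td = drop_mask ? vec(C.tvec % (*drop_mask)) : C.tvec;
  C.p_class = softmax_vec(P.Wy * C.td + P.by);
  C.p_domain = sigm(dot(P.wd, C.tvec) + P.bd);
  (void)m;
}

void backward_sample(const SampleCache& C, const Params& P, const Config& cfg,
                     const mat& S, Grads& g,
                     const vec* dlogit_y, double dlogit_d, bool has_domain,
                     const vec* drop_mask, double lambda) {
  int K = cfg.K, F = cfg.F, U = cfg.U, m = cfg.m, w = cfg.w;
  int m2 = C.tvec.n_elem;
  vec dt = zeros<vec>(m2);
  if (dlogit_y) {
    g.Wy += (*dlogit_y) * C.td.t();
    g.by += *dlogit_y;
    vec dtd = P.Wy.t() * (*dlogit_y);
    dt += drop_mask ? vec(dtd % (*drop_mask)) : dtd;
  }
  if (has_domain) {
    g.wd += dlogit_d * C.tvec;
    g.bd += dlogit_d;
    dt -= lambda * dlogit_d * P.wd;   // gradient reversal
  }
  mat dG;
  if (cfg.abl_temporal) {
    dG = repmat(dt.t() / w, w, 1);
  } else {
    vec dpsi = C.G * dt;
    dG = C.psi * dt.t();
    vec de = softmax_back_vec(C.psi, dpsi);
    g.ua += C.Ah.t() * de;
    mat dAh = de * P.ua.t();
    mat dApre = dAh % (1.0 - C.Ah % C.Ah);
    g.Wa += C.G.t() * dApre;
    g.ca += sum(dApre, 0);
    dG += dApre * P.Wa.t();
  }
  mat dXseq;
  if (cfg.abl_bilstm) {
    g.Wl += dG.t() * C.Xseq;
    g.bl += sum(dG, 0).t();
    dXseq = dG * P.Wl;
  } else {
    dXseq = zeros(w, K * U);
    lstm_dir_back(dG.cols(0, m - 1), C.Xseq, P.Wx_f, P.Wh_f, false,
                  C.zf_i, C.zf_f, C.zf_g, C.zf_o, C.cf, C.tcf, C.Hf,
                  g.Wx_f, g.Wh_f, g.b_f, dXseq);
    lstm_dir_back(dG.cols(m, 2 * m - 1), C.Xseq, P.Wx_b, P.Wh_b, true,
                  C.zb_i, C.zb_f, C.zb_g, C.zb_o, C.cb_, C.tcb, C.Hb,
                  g.Wx_b, g.Wh_b, g.b_b, dXseq);
  }
  for (int t = 0; t < w; ++t) {
    mat dVm = reshape(dXseq.row(t).t(), K, U);
    const mat& H = C.H.slice(t);
    mat dH;
    if (cfg.abl_spatial) {
      dH = dVm / K;
    } else {
      vec phi = C.Phi.row(t).t();
      dH = dVm.each_col() % phi;
      vec dphi = sum(dVm % H, 1);
      vec de = softmax_back_vec(phi, dphi);
      const mat& Uh = C.Uh.slice(t);
      g.ub += Uh.t() * de;
      mat dUh = de * P.ub.t();
      mat dUpre = dUh % (1.0 - Uh % Uh);
      g.Wb += H.t() * dUpre;
      g.cb += sum(dUpre, 0);
      dH += dUpre * P.Wb.t();
    }
    mat elu_g = C.Mpre.slice(t);
    elu_g.transform([](double x) { return x > 0 ? 1.0 : std::exp(x); });
    mat dM = dH % elu_g;
    mat SZ = cfg.use_graph ? mat(S * C.Z.slice(t)) : C.Z.slice(t);
    g.Wg += SZ.t() * dM;
    g.bg += sum(dM, 0);
    mat dZ = dM * P.Wg.t();
    if (cfg.use_graph) dZ = S * dZ;   // S symmetric
    const mat& N = C.N.slice(t);
    mat dN;
    if (cfg.abl_spectral) {
      dN = dZ;
    } else {
      dN = zeros(K, F);
      if (!cfg.abl_channel) {
        const mat& P1 = C.P1.slice(t);
        dN += dZ + P1.t() * dZ;
        mat dP1 = dZ * N.t();
        mat dA1 = row_softmax_back(P1, dP1);
        dN += (dA1 + dA1.t()) * N / F;
      } else dN += dZ;
      if (!cfg.abl_freq) {
        const mat& P2 = C.P2.slice(t);
        dN += dZ + dZ * P2;
        mat dP2 = dZ.t() * N;
        mat dA2 = row_softmax_back(P2, dP2);
        dN += N * (dA2 + dA2.t()) / K;
      } else dN += dZ;
    }
    g.ln_gamma += sum(dN % C.Xhat.slice(t), 0);
    g.ln_beta += sum(dN, 0);
  }
}

Config make_config(const Rcpp::List& cfg, bool have_S) {
  Config c;
  c.K = cfg["n_channels"]; c.F = cfg["n_freqs"]; c.U = cfg["gnl_units"];
  c.m = cfg["lstm_units"]; c.w = cfg["w"]; c.C = cfg["n_classes"];
  std::vector<std::string> abl =
    Rcpp::as<std::vector<std::string>>(cfg["ablate"]);
  auto has = [&](const char* f) {
    return std::find(abl.begin(), abl.end(), f) != abl.end();
  };
  c.abl_channel = has("channel_attn");
  c.abl_freq = has("freq_attn");
  c.abl_spectral = has("spectral_block");
  c.abl_graph = has("graph_layer");
  c.abl_spatial = has("spatial_attn");
  c.abl_bilstm = has("bilstm");
  c.abl_temporal = has("temporal_attn");
  c.use_graph = have_S && !c.abl_graph;
  return c;
}

// slice sample b (0-based) of a (B, w, K, F) R array into a (K, F, w) cube
cube sample_cube(const Rcpp::NumericVector& X, int B, int w, int K, int F,
                 int b) {
  cube out(K, F, w);
  const double* x = X.begin();
  for (int f = 0; f < F; ++f)
    for (int k = 0; k < K; ++k)
      for (int t = 0; t < w; ++t)
        out(k, f, t) = x[b + (size_t)B * (t + (size_t)w * (k + (size_t)K * f))];
  return out;
}

} // namespace

// Accumulate gradients for one SGD step (source batch + optional target
// batch). Returns the gradient list plus batch losses and the worst
// simplex deviation of the attention weights seen during the step.
// [[Rcpp::export]]
Rcpp::List cpp_batch_grad(Rcpp::NumericVector Xsrc, Rcpp::IntegerVector y,
                          Rcpp::NumericVector Xtgt,
                          Rcpp::List params, Rcpp::List cfg_list,
                          Rcpp::Nullable<Rcpp::NumericMatrix> S_,
                          Rcpp::Nullable<Rcpp::NumericMatrix> drop_masks_,
                          double lambda, bool use_domain) {
  bool have_S = S_.isNotNull();
  Config cfg = make_config(cfg_list, have_S);
  Params P = unpack(params, cfg);
  mat S = have_S ? Rcpp::as<mat>(S_.get()) : mat();
  Rcpp::IntegerVector dsrc = Xsrc.attr("dim");
  int Bs = dsrc[0];
  int Bt = 0;
  if (Xtgt.size() > 0) {
    Rcpp::IntegerVector dtgt = Xtgt.attr("dim");
    Bt = dtgt[0];
  }
  mat masks;
  bool use_drop = drop_masks_.isNotNull();
  if (use_drop) masks = Rcpp::as<mat>(drop_masks_.get());  // 2m x Bs

  Grads g = zero_grads(P, cfg);
  double loss_y = 0, loss_d = 0, dev = 0;
  SampleCache C;
  for (int b = 0; b < Bs; ++b) {
    cube Xc = sample_cube(Xsrc, Bs, cfg.w, cfg.K, cfg.F, b);
    vec mask;
    if (use_drop) mask = masks.col(b);
    forward_sample(Xc, P, cfg, S, use_drop ? &mask : nullptr, C);
    int yy = y[b] - 1;
    loss_y += -std::log(std::max(C.p_class(yy), 1e-12));
    vec dly = C.p_class; dly(yy) -= 1.0; dly /= Bs;
    double dld = 0; bool hd = false;
    if (use_domain) {
      loss_d += -std::log(std::max(1.0 - C.p_domain, 1e-12));
      dld = (C.p_domain - 0.0) / Bs; hd = true;
    }
    dev = std::max(dev, abs(sum(C.Phi, 1) - 1.0).max());
    dev = std::max(dev, std::abs(accu(C.psi) - 1.0));
    backward_sample(C, P, cfg, S, g, &dly, dld, hd,
                    use_drop ? &mask : nullptr, lambda);
  }
  if (use_domain) {
    for (int b = 0; b < Bt; ++b) {
      cube Xc = sample_cube(Xtgt, Bt, cfg.w, cfg.K, cfg.F, b);
      forward_sample(Xc, P, cfg, S, nullptr, C);
      loss_d += -std::log(std::max(C.p_domain, 1e-12));
      backward_sample(C, P, cfg, S, g, nullptr, (C.p_domain - 1.0) / Bt,
                      true, nullptr, lambda);
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("ln_gamma") = g.ln_gamma, Rcpp::Named("ln_beta") = g.ln_beta,
    Rcpp::Named("Wg") = g.Wg, Rcpp::Named("bg") = g.bg,
    Rcpp::Named("Wb") = g.Wb, Rcpp::Named("cb") = g.cb,
    Rcpp::Named("ub") = g.ub,
    Rcpp::Named("Wa") = g.Wa, Rcpp::Named("ca") = g.ca,
    Rcpp::Named("ua") = g.ua,
    Rcpp::Named("Wy") = g.Wy, Rcpp::Named("by") = g.by,
    Rcpp::Named("wd") = g.wd, Rcpp::Named("bd") = g.bd);
  if (cfg.abl_bilstm) {
    out["Wl"] = g.Wl; out["bl"] = g.bl;
  } else {
    out["Wx_f"] = g.Wx_f; out["Wh_f"] = g.Wh_f; out["b_f"] = g.b_f;
    out["Wx_b"] = g.Wx_b; out["Wh_b"] = g.Wh_b; out["b_b"] = g.b_b;
  }
  return Rcpp::List::create(Rcpp::Named("grads") = out,
                            Rcpp::Named("loss_y") = loss_y,
                            Rcpp::Named("loss_d") = loss_d,
                            Rcpp::Named("simplex_dev") = dev);
}

// Inference over all videos of one subject tensor: class probabilities,
// domain probabilities, and the attention maps.
// [[Rcpp::export]]
Rcpp::List cpp_predict(Rcpp::NumericVector X, Rcpp::List params,
                       Rcpp::List cfg_list,
                       Rcpp::Nullable<Rcpp::NumericMatrix> S_) {
  bool have_S = S_.isNotNull();
  Config cfg = make_config(cfg_list, have_S);
  Params P = unpack(params, cfg);
  mat S = have_S ? Rcpp::as<mat>(S_.get()) : mat();
  Rcpp::IntegerVector d = X.attr("dim");
  int n = d[0];
  mat probs(n, cfg.C), Psi(n, cfg.w);
  cube Phi(n, cfg.w, cfg.K);
  vec pdom(n);
  SampleCache C;
  for (int b = 0; b < n; ++b) {
    cube Xc = sample_cube(X, n, cfg.w, cfg.K, cfg.F, b);
    forward_sample(Xc, P, cfg, S, nullptr, C);
    probs.row(b) = C.p_class.t();
    Psi.row(b) = C.psi.t();
    pdom(b) = C.p_domain;
    for (int t = 0; t < cfg.w; ++t)
      for (int k = 0; k < cfg.K; ++k)
        Phi(b, t, k) = C.Phi(t, k);
  }
  return Rcpp::List::create(Rcpp::Named("probabilities") = probs,
                            Rcpp::Named("Phi") = Phi,
                            Rcpp::Named("Psi") = Psi,
                            Rcpp::Named("p_domain") = pdom);
}
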