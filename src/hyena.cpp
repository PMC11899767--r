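// Batched forward and backward passes of the Hyena decoder stack.
// Mirrors the reference R implementation (R/hyena_ops.R, R/hyena_model.R)
// operation for operation; the R path remains the oracle in tests.
//
// Activations are [L*B x d] matrices with position t varying fastest
// within each window block, matching the R layout, so the same memory can
// be viewed as [L x B*d] for per-channel FFT work (Armadillo is
// column-major like R).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static int next_pow2(int n) {
  int p = 1;
  while (p < n) p <<= 1;
  return p;
}

static mat addb(mat X, const rowvec& b) {
  X.each_row() += b;
  return X;
}

// ---- layer norm ----

struct LnCache { mat xhat; vec istd; };

static mat ln_fwd(const mat& X, const vec& g, const vec& b, LnCache& cc) {
  vec mu = mean(X, 1);
  mat xc = X.each_col() - mu;
  vec istd = 1.0 / sqrt(mean(square(xc), 1) + 1e-5);
  cc.xhat = xc.each_col() % istd;
  cc.istd = istd;
  mat y = cc.xhat;
  y.each_row() %= g.t();
  y.each_row() += b.t();
  return y;
}

static mat ln_bwd(const mat& dy, const LnCache& cc, const vec& g,
                  vec& dg, vec& db) {
  dg = sum(dy % cc.xhat, 0).t();
  db = sum(dy, 0).t();
  mat dxh = dy;
  dxh.each_row() %= g.t();
  vec m1 = mean(dxh, 1);
  vec m2 = mean(dxh % cc.xhat, 1);
  mat dx = dxh;
  dx.each_col() -= m1;
  dx -= cc.xhat.each_col() % m2;
  dx.each_col() %= cc.istd;
  return dx;
}

// ---- causal depthwise short convolution ----

static mat shift_down(const mat& X, int j, int L, int B) {
  if (j == 0) return X;
  mat out(X.n_rows, X.n_cols, fill::zeros);
  for (int b = 0; b < B; ++b) {
    if (L - j > 0)
      out.rows(b * L + j, b * L + L - 1) = X.rows(b * L, b * L + L - 1 - j);
  }
  return out;
}

static mat shift_up(const mat& X, int j, int L, int B) {
  if (j == 0) return X;
  mat out(X.n_rows, X.n_cols, fill::zeros);
  for (int b = 0; b < B; ++b) {
    if (L - j > 0)
      out.rows(b * L, b * L + L - 1 - j) = X.rows(b * L + j, b * L + L - 1);
  }
  return out;
}

static mat shortconv_fwd(const mat& X, const mat& K, int L, int B,
                         std::vector<mat>& shifts) {
  int w = K.n_rows;
  mat Y(X.n_rows, X.n_cols, fill::zeros);
  shifts.clear();
  for (int j = 0; j < w; ++j) {
    shifts.push_back(shift_down(X, j, L, B));
    mat term = shifts[j];
    term.each_row() %= K.row(j);
    Y += term;
  }
  return Y;
}

static mat shortconv_bwd(const mat& dY, const mat& K,
                         const std::vector<mat>& shifts, int L, int B,
                         mat& dK) {
  int w = K.n_rows;
  dK.set_size(w, K.n_cols);
  mat dM(dY.n_rows, dY.n_cols, fill::zeros);
  for (int j = 0; j < w; ++j) {
    dK.row(j) = sum(shifts[j] % dY, 0);
    mat term = dY;
    term.each_row() %= K.row(j);
    dM += shift_up(term, j, L, B);
  }
  return dM;
}

// ---- implicit filter ----

struct FiltCache { mat Z, H1, A1, h_raw, D, h; bool decay; };

static mat pos_features(int L, int P, double scale) {
  int K = (P - 1) / 2;
  mat Z(L, P);
  double sc = std::max(scale, 2.0);
  for (int t = 0; t < L; ++t) Z(t, 0) = t / scale;
  for (int k = 0; k < K; ++k) {
    double expo = (K == 1) ? 0.0 : (double)k / (K - 1);
    double period = 2.0 * std::pow(sc, expo);
    double w = 2.0 * M_PI / period;
    for (int t = 0; t < L; ++t) {
      Z(t, 1 + k) = std::sin(w * t);
      Z(t, 1 + K + k) = std::cos(w * t);
    }
  }
  return Z;
}

static mat filter_fwd(const Rcpp::List& fp, int L, double scale,
                      bool use_decay, FiltCache& cc) {
  mat Wf1 = fp["Wf1"]; vec bf1 = fp["bf1"];
  mat Wf2 = fp["Wf2"]; vec bf2 = fp["bf2"];
  cc.Z = pos_features(L, Wf1.n_rows, scale);
  cc.H1 = addb(cc.Z * Wf1, bf1.t());
  cc.A1 = sin(cc.H1);
  cc.h_raw = addb(cc.A1 * Wf2, bf2.t());
  cc.decay = use_decay && fp.containsElementNamed("log_alpha");
  if (cc.decay) {
    vec alpha = exp(Rcpp::as<vec>(fp["log_alpha"]));
    cc.D.set_size(L, alpha.n_elem);
    for (uword c = 0; c < alpha.n_elem; ++c)
      for (int t = 0; t < L; ++t) cc.D(t, c) = std::exp(-t * alpha(c));
    cc.h = cc.h_raw % cc.D;
  } else {
    cc.h = cc.h_raw;
  }
  return cc.h;
}

static Rcpp::List filter_bwd(const Rcpp::List& fp, const FiltCache& cc,
                             const mat& dh) {
  mat Wf2 = fp["Wf2"];
  mat dh_raw = dh;
  Rcpp::List out;
  if (cc.decay) {
    dh_raw = dh % cc.D;
    int L = dh.n_rows;
    vec t0(L);
    for (int t = 0; t < L; ++t) t0(t) = t;
    mat tmp = dh % cc.h_raw % cc.D;
    tmp.each_col() %= -t0;
    vec dalpha = sum(tmp, 0).t();
    vec dlog_alpha = dalpha % exp(Rcpp::as<vec>(fp["log_alpha"]));
    out["log_alpha"] = dlog_alpha;
  }
  mat dA1 = dh_raw * Wf2.t();
  mat dH1 = dA1 % cos(cc.H1);
  Rcpp::List g = Rcpp::List::create(
    Rcpp::Named("Wf1") = cc.Z.t() * dH1,
    Rcpp::Named("bf1") = sum(dH1, 0).t(),
    Rcpp::Named("Wf2") = cc.A1.t() * dh_raw,
    Rcpp::Named("bf2") = sum(dh_raw, 0).t());
  if (cc.decay) g["log_alpha"] = out["log_alpha"];
  return g;
}

// ---- batched FFT convolution ----

// view [L*B x d] memory as [L x B*d] (no copy of semantics; reshape copies
// but order is preserved), zero-pad to nfft and FFT column-wise
static cx_mat fft_pad(const mat& M, int L, int B, int d, int nfft) {
  mat V = reshape(M, L, B * d);
  mat P(nfft, B * d, fill::zeros);
  P.rows(0, L - 1) = V;
  return fft(P);
}

static mat ifft_take(const cx_mat& S, int L, int B, int d) {
  mat Y = real(ifft(S));
  Y = Y.rows(0, L - 1);
  return reshape(Y, L * B, d);
}

static cx_mat expand_hf(const cx_mat& Hf, int B, int d) {
  cx_mat E(Hf.n_rows, (uword)B * d);
  for (int c = 0; c < d; ++c)
    for (int b = 0; b < B; ++b) E.col((uword)c * B + b) = Hf.col(c);
  return E;
}

// ---- GELU ----

static mat gelu_fwd(const mat& x, mat& th) {
  const double c0 = std::sqrt(2.0 / M_PI);
  th = tanh(c0 * (x + 0.044715 * pow(x, 3)));
  return 0.5 * x % (1.0 + th);
}

static mat gelu_bwd(const mat& dy, const mat& x, const mat& th) {
  const double c0 = std::sqrt(2.0 / M_PI);
  mat dinner = c0 * (1.0 + 3 * 0.044715 * square(x));
  return dy % (0.5 * (1.0 + th) + 0.5 * x % (1.0 - square(th)) % dinner);
}

// ---- per-block caches ----

struct BlockCache {
  LnCache ln1, ln2;
  std::vector<mat> sc_shifts;
  mat X_in, x1, x2, v, a, yconv, g, U2, ff_pre, ge_th, ge_y;
  FiltCache filt;
  cx_mat Hf, Af;
};

struct FwdState {
  mat logits, hidden, X_last;
  LnCache lnf;
  std::vector<BlockCache> blocks;
  uvec ids;
  int L, B, nfft;
};

static void forward_pass(const Rcpp::List& params, const Rcpp::List& config,
                         const Rcpp::IntegerMatrix& tok, bool keep,
                         FwdState& st) {
  int B = tok.nrow(), L = tok.ncol();
  int d = Rcpp::as<int>(config["d_model"]);
  int n_layer = Rcpp::as<int>(config["n_layer"]);
  int L_in = Rcpp::as<int>(config["L_in"]);
  bool use_decay = Rcpp::as<bool>(config["use_decay"]);
  if (L > L_in) Rcpp::stop("forward: window longer than L_in");
  int nfft = next_pow2(std::max(2 * L - 1, 1));
  mat tok_emb = params["tok_emb"];
  Rcpp::List blocks = params["blocks"];

  st.L = L; st.B = B; st.nfft = nfft;
  st.ids.set_size((uword)L * B);
  mat X((uword)L * B, d);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < L; ++t) {
      uword r = (uword)b * L + t;
      st.ids(r) = tok(b, t);
      X.row(r) = tok_emb.row(tok(b, t));
    }
  st.blocks.resize(n_layer);
  for (int li = 0; li < n_layer; ++li) {
    Rcpp::List blk = blocks[li];
    BlockCache& cc = st.blocks[li];
    if (keep) cc.X_in = X;
    mat W_in = blk["W_in"]; vec b_in = blk["b_in"];
    mat K = blk["K"];
    mat W_out = blk["W_out"]; vec b_out = blk["b_out"];
    mat Wff1 = blk["Wff1"]; vec bff1 = blk["bff1"];
    mat Wff2 = blk["Wff2"]; vec bff2 = blk["bff2"];
    mat Z1 = ln_fwd(X, Rcpp::as<vec>(blk["ln1_g"]), Rcpp::as<vec>(blk["ln1_b"]), cc.ln1);
    mat P3 = addb(Z1 * W_in, b_in.t());
    mat S = shortconv_fwd(P3, K, L, B, cc.sc_shifts);
    cc.x1 = S.cols(0, d - 1);
    cc.x2 = S.cols(d, 2 * d - 1);
    cc.v = S.cols(2 * d, 3 * d - 1);
    cc.a = cc.x1 % cc.v;
    mat h = filter_fwd(blk["filter"], L, (double)L_in, use_decay, cc.filt);
    mat hp(nfft, d, fill::zeros);
    hp.rows(0, L - 1) = h;
    cc.Hf = fft(hp);
    cc.Af = fft_pad(cc.a, L, B, d, nfft);
    cc.yconv = ifft_take(cc.Af % expand_hf(cc.Hf, B, d), L, B, d);
    cc.g = cc.x2 % cc.yconv;
    mat out = addb(cc.g * W_out, b_out.t());
    cc.U2 = X + out;
    mat Z2 = ln_fwd(cc.U2, Rcpp::as<vec>(blk["ln2_g"]), Rcpp::as<vec>(blk["ln2_b"]), cc.ln2);
    cc.ff_pre = addb(Z2 * Wff1, bff1.t());
    cc.ge_y = gelu_fwd(cc.ff_pre, cc.ge_th);
    mat F2 = addb(cc.ge_y * Wff2, bff2.t());
    X = cc.U2 + F2;
    if (!keep) {
      cc.sc_shifts.clear();
      cc.Af.reset();
    }
  }
  st.X_last = X;
  st.hidden = ln_fwd(X, Rcpp::as<vec>(params["ln_f_g"]),
                     Rcpp::as<vec>(params["ln_f_b"]), st.lnf);
  mat W_head = params["W_head"]; vec b_head = params["b_head"];
  st.logits = addb(st.hidden * W_head, b_head.t());
}

static Rcpp::List backward_pass(const Rcpp::List& params,
                                const Rcpp::List& config, FwdState& st,
                                const mat& dlogits) {
  int d = Rcpp::as<int>(config["d_model"]);
  int n_layer = Rcpp::as<int>(config["n_layer"]);
  int L = st.L, B = st.B, nfft = st.nfft;
  Rcpp::List blocks = params["blocks"];
  mat W_head = params["W_head"];
  mat gW_head = st.hidden.t() * dlogits;
  vec gb_head = sum(dlogits, 0).t();
  mat dH = dlogits * W_head.t();
  vec g_lnf_g, g_lnf_b;
  mat dX = ln_bwd(dH, st.lnf, Rcpp::as<vec>(params["ln_f_g"]), g_lnf_g, g_lnf_b);
  Rcpp::List gblocks(n_layer);
  for (int li = n_layer - 1; li >= 0; --li) {
    Rcpp::List blk = blocks[li];
    BlockCache& cc = st.blocks[li];
    mat W_out = blk["W_out"];
    mat W_in = blk["W_in"];
    mat Wff1 = blk["Wff1"]; mat Wff2 = blk["Wff2"];
    mat K = blk["K"];
    // feed-forward sublayer
    mat gWff2 = cc.ge_y.t() * dX;
    vec gbff2 = sum(dX, 0).t();
    mat dge = dX * Wff2.t();
    mat dff_pre = gelu_bwd(dge, cc.ff_pre, cc.ge_th);
    vec ln2_g = blk["ln2_g"]; vec ln2_b = blk["ln2_b"];
    mat ln2y = cc.ln2.xhat;
    ln2y.each_row() %= ln2_g.t();
    ln2y.each_row() += ln2_b.t();
    mat gWff1 = ln2y.t() * dff_pre;
    vec gbff1 = sum(dff_pre, 0).t();
    mat dZ2 = dff_pre * Wff1.t();
    vec dg2, db2;
    mat dU2 = dX + ln_bwd(dZ2, cc.ln2, ln2_g, dg2, db2);
    // output projection and gating
    mat gW_out = cc.g.t() * dU2;
    vec gb_out = sum(dU2, 0).t();
    mat dg_ = dU2 * W_out.t();
    mat dx2 = dg_ % cc.yconv;
    mat dyconv = dg_ % cc.x2;
    cx_mat Df = fft_pad(dyconv, L, B, d, nfft);
    mat da = ifft_take(Df % conj(expand_hf(cc.Hf, B, d)), L, B, d);
    mat slab = real(ifft(cx_mat(Df % conj(cc.Af))));
    slab = slab.rows(0, L - 1);
    // sum over batch: columns are (b, c) with b fastest
    mat dh(L, d);
    for (int c = 0; c < d; ++c) {
      vec acc(L, fill::zeros);
      for (int b = 0; b < B; ++b) acc += slab.col((uword)c * B + b);
      dh.col(c) = acc;
    }
    Rcpp::List gfilter = filter_bwd(blk["filter"], cc.filt, dh);
    mat dx1 = da % cc.v;
    mat dv = da % cc.x1;
    mat dS = join_rows(dx1, dx2, dv);
    mat dK;
    mat dP3 = shortconv_bwd(dS, K, cc.sc_shifts, L, B, dK);
    vec ln1_g = blk["ln1_g"]; vec ln1_b = blk["ln1_b"];
    mat ln1y = cc.ln1.xhat;
    ln1y.each_row() %= ln1_g.t();
    ln1y.each_row() += ln1_b.t();
    mat gW_in = ln1y.t() * dP3;
    vec gb_in = sum(dP3, 0).t();
    mat dZ1 = dP3 * W_in.t();
    vec dg1, db1;
    mat dx_ln1 = ln_bwd(dZ1, cc.ln1, ln1_g, dg1, db1);
    gblocks[li] = Rcpp::List::create(
      Rcpp::Named("ln1_g") = dg1, Rcpp::Named("ln1_b") = db1,
      Rcpp::Named("W_in") = gW_in, Rcpp::Named("b_in") = gb_in,
      Rcpp::Named("K") = dK, Rcpp::Named("filter") = gfilter,
      Rcpp::Named("W_out") = gW_out, Rcpp::Named("b_out") = gb_out,
      Rcpp::Named("ln2_g") = dg2, Rcpp::Named("ln2_b") = db2,
      Rcpp::Named("Wff1") = gWff1, Rcpp::Named("bff1") = gbff1,
      Rcpp::Named("Wff2") = gWff2, Rcpp::Named("bff2") = gbff2);
    dX = dU2 + dx_ln1;
  }
  mat tok_emb = params["tok_emb"];
  mat gemb(tok_emb.n_rows, tok_emb.n_cols, fill::zeros);
  for (uword r = 0; r < dX.n_rows; ++r) gemb.row(st.ids(r)) += dX.row(r);
  return Rcpp::List::create(
    Rcpp::Named("tok_emb") = gemb, Rcpp::Named("blocks") = gblocks,
    Rcpp::Named("ln_f_g") = g_lnf_g, Rcpp::Named("ln_f_b") = g_lnf_b,
    Rcpp::Named("W_head") = gW_head, Rcpp::Named("b_head") = gb_head);
}

// forward only: logits and final hidden states, matrix form [L*B x .]
// [[Rcpp::export(name = ".cpp_forward")]]
Rcpp::List cpp_forward(Rcpp::List params, Rcpp::List config,
                       Rcpp::IntegerMatrix tok) {
  FwdState st;
  forward_pass(params, config, tok, false, st);
  return Rcpp::List::create(Rcpp::Named("logits") = st.logits,
                            Rcpp::Named("hidden") = st.hidden);
}

// next-token cross-entropy and parameter gradients for one batch.
// Targets: the following token within each window, scored only when it is
// a nucleotide id (0..3).
// [[Rcpp::export(name = ".cpp_loss_grad")]]
Rcpp::List cpp_loss_grad(Rcpp::List params, Rcpp::List config,
                         Rcpp::IntegerMatrix tok, bool with_grad) {
  FwdState st;
  forward_pass(params, config, tok, with_grad, st);
  int B = tok.nrow(), L = tok.ncol();
  int V = st.logits.n_cols;
  std::vector<uword> valid;
  std::vector<int> tgt;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t + 1 < L; ++t) {
      int y = tok(b, t + 1);
      if (y >= 0 && y <= 3) {
        valid.push_back((uword)b * L + t);
        tgt.push_back(y);
      }
    }
  if (valid.empty()) Rcpp::stop("loss: no scorable positions in batch");
  double loss = 0.0;
  mat dlogits;
  if (with_grad) dlogits.zeros(st.logits.n_rows, V);
  double inv_n = 1.0 / valid.size();
  for (size_t i = 0; i < valid.size(); ++i) {
    rowvec lr = st.logits.row(valid[i]);
    double m = lr.max();
    double lse = m + std::log(accu(exp(lr - m)));
    loss += lse - lr(tgt[i]);
    if (with_grad) {
      rowvec p = exp(lr - lse) * inv_n;
      p(tgt[i]) -= inv_n;
      dlogits.row(valid[i]) = p;
    }
  }
  loss *= inv_n;
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("n_tok") = (int)valid.size());
  if (with_grad) out["grads"] = backward_pass(params, config, st, dlogits);
  return out;
}
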