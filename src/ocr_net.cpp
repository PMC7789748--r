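// Three-stage scene-text recognizer: convolutional feature extraction
// (with one residual block), bidirectional LSTM sequence modeling, and an
// attention-based character decoder, with full backpropagation and
// AdaDelta updates.  Written against Armadillo; everything is
// deterministic given the seed.
//
// Conventions
//  - An image is a column of X (H*W x B), pixel index p = y + x*H.
//  - Activations per image: mat (C x H*W), same pixel indexing.
//  - im2col rows are grouped k*C + c for kernel offset k = dy*3 + dx.
//  - Character classes 0..K-1, EOS = K; decoder input tokens 0..K-1 plus
//    GO = K.  Embedding has K+1 rows; output layer has K+1 logits.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Cfg {
  int H, W, C1, C2, He, Hd, E, A, K, maxlen, L, kloc;
  int H1, W1, H2, W2, T, D;
};

static Cfg read_cfg(const Rcpp::List& cfg) {
  Cfg c;
  c.H = cfg["input_h"]; c.W = cfg["input_w"];
  c.C1 = cfg["conv1"]; c.C2 = cfg["conv2"];
  c.He = cfg["enc_hidden"]; c.Hd = cfg["dec_hidden"];
  c.E = cfg["emb_dim"]; c.A = cfg["att_dim"];
  c.K = cfg["charset_size"]; c.maxlen = cfg["max_len"];
  c.L = cfg["loc_channels"]; c.kloc = cfg["loc_kernel"];
  c.H1 = c.H / 2; c.W1 = c.W / 2; c.H2 = c.H1 / 2; c.W2 = c.W1 / 2;
  c.T = c.W2; c.D = c.C2 * c.H2;
  return c;
}

static const char* PARAM_NAMES[] = {
  "conv1_W", "conv1_b", "conv2_W", "conv2_b",
  "conv3a_W", "conv3a_b", "conv3b_W", "conv3b_b",
  "encf_Wx", "encf_Wh", "encf_b", "encb_Wx", "encb_Wh", "encb_b",
  "emb", "att_We", "att_Wd", "att_b", "att_v",
  "dec_Wx", "dec_Wh", "dec_b", "out_W", "out_b", "att_Wl", "att_K"
};
static const int N_PARAMS = 26;

struct Params {
  std::vector<mat> p;
  Params() : p(N_PARAMS) {}
  mat& operator[](int i) { return p[i]; }
  const mat& operator[](int i) const { return p[i]; }
  // named accessors
  mat& c1W() { return p[0]; }  mat& c1b() { return p[1]; }
  mat& c2W() { return p[2]; }  mat& c2b() { return p[3]; }
  mat& c3aW() { return p[4]; } mat& c3ab() { return p[5]; }
  mat& c3bW() { return p[6]; } mat& c3bb() { return p[7]; }
  mat& efWx() { return p[8]; } mat& efWh() { return p[9]; } mat& efb() { return p[10]; }
  mat& ebWx() { return p[11]; } mat& ebWh() { return p[12]; } mat& ebb() { return p[13]; }
  mat& emb() { return p[14]; }
  mat& aWe() { return p[15]; } mat& aWd() { return p[16]; } mat& ab() { return p[17]; }
  mat& av() { return p[18]; }
  mat& dWx() { return p[19]; } mat& dWh() { return p[20]; } mat& db() { return p[21]; }
  mat& oW() { return p[22]; }  mat& ob() { return p[23]; }
  mat& aWl() { return p[24]; } mat& aK() { return p[25]; }
  const mat& c1W() const { return p[0]; }  const mat& c1b() const { return p[1]; }
  const mat& c2W() const { return p[2]; }  const mat& c2b() const { return p[3]; }
  const mat& c3aW() const { return p[4]; } const mat& c3ab() const { return p[5]; }
  const mat& c3bW() const { return p[6]; } const mat& c3bb() const { return p[7]; }
  const mat& efWx() const { return p[8]; } const mat& efWh() const { return p[9]; }
  const mat& efb() const { return p[10]; }
  const mat& ebWx() const { return p[11]; } const mat& ebWh() const { return p[12]; }
  const mat& ebb() const { return p[13]; }
  const mat& emb() const { return p[14]; }
  const mat& aWe() const { return p[15]; } const mat& aWd() const { return p[16]; }
  const mat& ab() const { return p[17]; }  const mat& av() const { return p[18]; }
  const mat& dWx() const { return p[19]; } const mat& dWh() const { return p[20]; }
  const mat& db() const { return p[21]; }
  const mat& oW() const { return p[22]; }  const mat& ob() const { return p[23]; }
  const mat& aWl() const { return p[24]; } const mat& aK() const { return p[25]; }
};

// sliding windows of a length-T attention vector for the location
// convolution: A_win is kloc x T, row d holds alpha shifted by d - pad
static mat loc_windows(const vec& alpha, int kloc) {
  int T = alpha.n_elem, pad = kloc / 2;
  mat W(kloc, T, fill::zeros);
  for (int d = 0; d < kloc; ++d) {
    for (int j = 0; j < T; ++j) {
      int src = j + d - pad;
      if (src >= 0 && src < T) W(d, j) = alpha(src);
    }
  }
  return W;
}

static Params params_from_list(const Rcpp::List& lst) {
  Params P;
  for (int i = 0; i < N_PARAMS; ++i) {
    Rcpp::NumericMatrix m = lst[PARAM_NAMES[i]];
    P[i] = mat(m.begin(), m.nrow(), m.ncol());
  }
  return P;
}

static Rcpp::List params_to_list(const Params& P) {
  Rcpp::List out;
  for (int i = 0; i < N_PARAMS; ++i) {
    out[PARAM_NAMES[i]] = Rcpp::wrap(P[i]);
  }
  return out;
}

static Params zeros_like(const Params& P) {
  Params G;
  for (int i = 0; i < N_PARAMS; ++i) G[i] = zeros<mat>(P[i].n_rows, P[i].n_cols);
  return G;
}

// ---------------------------------------------------------------------------
// Elementwise helpers

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------------------------------------------------------------------
// Convolution primitives (3x3, pad 1, stride 1)

static void im2col3(const mat& A, int C, int H, int W, mat& col) {
  // A: C x H*W  ->  col: 9C x H*W
  col.zeros(9 * C, H * W);
  for (int k = 0; k < 9; ++k) {
    int dy = k / 3 - 1, dx = k % 3 - 1;
    for (int x = 0; x < W; ++x) {
      int xs = x + dx;
      if (xs < 0 || xs >= W) continue;
      int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      if (y0 >= y1) continue;
      // rows y0..y1-1 at output column (y + x*H) come from source (y+dy, xs)
      col.submat(k * C, x * H + y0, k * C + C - 1, x * H + y1 - 1) =
        A.submat(0, xs * H + y0 + dy, C - 1, xs * H + y1 - 1 + dy);
    }
  }
}

static void col2im3(const mat& dcol, int C, int H, int W, mat& dA) {
  dA.zeros(C, H * W);
  for (int k = 0; k < 9; ++k) {
    int dy = k / 3 - 1, dx = k % 3 - 1;
    for (int x = 0; x < W; ++x) {
      int xs = x + dx;
      if (xs < 0 || xs >= W) continue;
      int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      if (y0 >= y1) continue;
      dA.submat(0, xs * H + y0 + dy, C - 1, xs * H + y1 - 1 + dy) +=
        dcol.submat(k * C, x * H + y0, k * C + C - 1, x * H + y1 - 1);
    }
  }
}

static void maxpool2(const mat& A, int C, int H, int W, mat& out, umat& arg) {
  int Ho = H / 2, Wo = W / 2;
  out.set_size(C, Ho * Wo);
  arg.set_size(C, Ho * Wo);
  for (int xo = 0; xo < Wo; ++xo) {
    for (int yo = 0; yo < Ho; ++yo) {
      int po = yo + xo * Ho;
      uword cand[4] = {
        (uword)(2 * yo + (2 * xo) * H), (uword)(2 * yo + 1 + (2 * xo) * H),
        (uword)(2 * yo + (2 * xo + 1) * H), (uword)(2 * yo + 1 + (2 * xo + 1) * H)
      };
      for (int c = 0; c < C; ++c) {
        double best = A(c, cand[0]); uword bi = cand[0];
        for (int j = 1; j < 4; ++j) {
          if (A(c, cand[j]) > best) { best = A(c, cand[j]); bi = cand[j]; }
        }
        out(c, po) = best; arg(c, po) = bi;
      }
    }
  }
}

static void maxpool2_back(const mat& dout, const umat& arg, int C, int H, int W,
                          mat& dA) {
  dA.zeros(C, H * W);
  for (uword p = 0; p < dout.n_cols; ++p) {
    for (int c = 0; c < C; ++c) dA(c, arg(c, p)) += dout(c, p);
  }
}

// ---------------------------------------------------------------------------
// Per-batch caches

struct ConvCache {
  // per image (small matrices stay cache-resident on one core)
  std::vector<mat> col1, col2, col3a, col3b;      // im2col inputs
  std::vector<mat> a1, a2, z1, r;                 // post-relu / pre-relu acts
  std::vector<mat> p1, p2;                        // pooled
  std::vector<umat> arg1, arg2;
};

struct LstmCache {
  // per time step: He x B each
  std::vector<mat> i, f, g, o, c, th, h, x;
};

// Run the feature extractor on a standardized batch X (H*W x B).
// Returns feature sequence: feats[t] is D x B.
static void conv_forward(const Cfg& cfg, const Params& P, const mat& X,
                         std::vector<mat>& feats, ConvCache& cc) {
  int B = X.n_cols;
  cc.col1.resize(B); cc.col2.resize(B); cc.col3a.resize(B); cc.col3b.resize(B);
  cc.a1.resize(B); cc.a2.resize(B); cc.z1.resize(B); cc.r.resize(B);
  cc.p1.resize(B); cc.p2.resize(B); cc.arg1.resize(B); cc.arg2.resize(B);
  feats.assign(cfg.T, mat(cfg.D, B));
  mat img(1, cfg.H * cfg.W);
  for (int b = 0; b < B; ++b) {
    img = X.col(b).t();
    im2col3(img, 1, cfg.H, cfg.W, cc.col1[b]);
    mat z = P.c1W() * cc.col1[b];
    z.each_col() += vectorise(P.c1b());
    cc.a1[b] = clamp(z, 0.0, datum::inf);
    maxpool2(cc.a1[b], cfg.C1, cfg.H, cfg.W, cc.p1[b], cc.arg1[b]);
    im2col3(cc.p1[b], cfg.C1, cfg.H1, cfg.W1, cc.col2[b]);
    mat z2 = P.c2W() * cc.col2[b];
    z2.each_col() += vectorise(P.c2b());
    cc.a2[b] = clamp(z2, 0.0, datum::inf);
    maxpool2(cc.a2[b], cfg.C2, cfg.H1, cfg.W1, cc.p2[b], cc.arg2[b]);
    // residual block on the pooled map
    im2col3(cc.p2[b], cfg.C2, cfg.H2, cfg.W2, cc.col3a[b]);
    mat z3 = P.c3aW() * cc.col3a[b];
    z3.each_col() += vectorise(P.c3ab());
    cc.z1[b] = z3;
    mat z3r = clamp(z3, 0.0, datum::inf);
    im2col3(z3r, cfg.C2, cfg.H2, cfg.W2, cc.col3b[b]);
    mat z4 = P.c3bW() * cc.col3b[b];
    z4.each_col() += vectorise(P.c3bb());
    cc.r[b] = z4 + cc.p2[b];
    mat A = clamp(cc.r[b], 0.0, datum::inf);
    // columns of the map become the feature sequence
    for (int t = 0; t < cfg.T; ++t) {
      for (int c = 0; c < cfg.C2; ++c) {
        for (int y = 0; y < cfg.H2; ++y) {
          feats[t](c * cfg.H2 + y, b) = A(c, y + t * cfg.H2);
        }
      }
    }
  }
}

// Backward through the feature extractor given dfeats[t] (D x B).
static void conv_backward(const Cfg& cfg, const Params& P,
                          const std::vector<mat>& dfeats, const ConvCache& cc,
                          Params& G) {
  int B = dfeats[0].n_cols;
  for (int b = 0; b < B; ++b) {
    mat dA(cfg.C2, cfg.H2 * cfg.W2, fill::zeros);
    for (int t = 0; t < cfg.T; ++t) {
      for (int c = 0; c < cfg.C2; ++c) {
        for (int y = 0; y < cfg.H2; ++y) {
          dA(c, y + t * cfg.H2) = dfeats[t](c * cfg.H2 + y, b);
        }
      }
    }
    mat dr = dA % conv_to<mat>::from(cc.r[b] > 0);
    mat dp2 = dr;                                // skip connection
    G.c3bW() += dr * cc.col3b[b].t();
    G.c3bb() += sum(dr, 1);
    mat dcol3b = P.c3bW().t() * dr;
    mat dz3r;
    col2im3(dcol3b, cfg.C2, cfg.H2, cfg.W2, dz3r);
    mat dz3 = dz3r % conv_to<mat>::from(cc.z1[b] > 0);
    G.c3aW() += dz3 * cc.col3a[b].t();
    G.c3ab() += sum(dz3, 1);
    mat dcol3a = P.c3aW().t() * dz3;
    mat dp2b;
    col2im3(dcol3a, cfg.C2, cfg.H2, cfg.W2, dp2b);
    dp2 += dp2b;
    mat da2;
    maxpool2_back(dp2, cc.arg2[b], cfg.C2, cfg.H1, cfg.W1, da2);
    da2 %= conv_to<mat>::from(cc.a2[b] > 0);
    G.c2W() += da2 * cc.col2[b].t();
    G.c2b() += sum(da2, 1);
    mat dcol2 = P.c2W().t() * da2;
    mat dp1;
    col2im3(dcol2, cfg.C1, cfg.H1, cfg.W1, dp1);
    mat da1;
    maxpool2_back(dp1, cc.arg1[b], cfg.C1, cfg.H, cfg.W, da1);
    da1 %= conv_to<mat>::from(cc.a1[b] > 0);
    G.c1W() += da1 * cc.col1[b].t();
    G.c1b() += sum(da1, 1);
    // input gradient not needed
  }
}

// One LSTM forward step with the input projection (Wx*x + b) already
// computed; gates stored in cache slot t.
static void lstm_step_pre(const mat& gx, const mat& Wh, const mat& x,
                          mat& h, mat& c, LstmCache& L, int t) {
  int Hn = h.n_rows;
  mat pre = gx + Wh * h;
  L.x[t] = x;
  L.i[t] = sigm(pre.rows(0, Hn - 1));
  L.f[t] = sigm(pre.rows(Hn, 2 * Hn - 1));
  L.g[t] = tanh(pre.rows(2 * Hn, 3 * Hn - 1));
  L.o[t] = sigm(pre.rows(3 * Hn, 4 * Hn - 1));
  mat cn = L.f[t] % c + L.i[t] % L.g[t];
  L.c[t] = cn;
  L.th[t] = tanh(cn);
  h = L.o[t] % L.th[t];
  L.h[t] = h;
  c = cn;
}

// One LSTM forward step; gates stored in cache slot t.
static void lstm_step(const mat& Wx, const mat& Wh, const mat& bvec,
                      const mat& x, mat& h, mat& c, LstmCache& L, int t) {
  int Hn = h.n_rows;
  mat pre = Wx * x + Wh * h;
  pre.each_col() += vectorise(bvec);
  L.x[t] = x;
  L.i[t] = sigm(pre.rows(0, Hn - 1));
  L.f[t] = sigm(pre.rows(Hn, 2 * Hn - 1));
  L.g[t] = tanh(pre.rows(2 * Hn, 3 * Hn - 1));
  L.o[t] = sigm(pre.rows(3 * Hn, 4 * Hn - 1));
  mat cn = L.f[t] % c + L.i[t] % L.g[t];
  L.c[t] = cn;
  L.th[t] = tanh(cn);
  h = L.o[t] % L.th[t];
  L.h[t] = h;
  c = cn;
}

// One LSTM backward step.  dh: gradient wrt h_t (in), dc: carry (in/out).
// c_prev/h_prev are the previous states.  Returns dx; adds to dh_prev.
static mat lstm_step_back(const mat& Wx, const mat& Wh,
                          const LstmCache& L, int t,
                          const mat& c_prev, const mat& h_prev,
                          mat& dh, mat& dc, mat& dh_prev,
                          mat& dWx, mat& dWh, mat& db) {
  mat do_ = dh % L.th[t];
  mat dth = dh % L.o[t];
  dc += dth % (1.0 - square(L.th[t]));
  mat di = dc % L.g[t];
  mat dg = dc % L.i[t];
  mat df = dc % c_prev;
  mat dc_prev = dc % L.f[t];
  mat dpre = join_cols(join_cols(di % L.i[t] % (1.0 - L.i[t]),
                                 df % L.f[t] % (1.0 - L.f[t])),
                       join_cols(dg % (1.0 - square(L.g[t])),
                                 do_ % L.o[t] % (1.0 - L.o[t])));
  dWx += dpre * L.x[t].t();
  dWh += dpre * h_prev.t();
  db += sum(dpre, 1);
  dh_prev += Wh.t() * dpre;
  dc = dc_prev;
  return Wx.t() * dpre;
}

// ---------------------------------------------------------------------------
// Full forward + backward for one teacher-forced batch.
// X: H*W x B standardized.  targets: Lmax x B (class 0..K, -1 pad).
// lens: B (number of supervised steps incl. EOS).
// Returns mean loss per sequence; fills G with gradients (summed over batch,
// then divided by B).

static double loss_grad(const Cfg& cfg, const Params& P, const mat& X,
                        const imat& targets, const ivec& lens, Params& G) {
  int B = X.n_cols;
  int Lmax = targets.n_rows;
  // ---- features
  std::vector<mat> feats;
  ConvCache cc;
  conv_forward(cfg, P, X, feats, cc);
  // ---- BiLSTM encoder
  LstmCache Lf, Lb;
  Lf.i.resize(cfg.T); Lf.f.resize(cfg.T); Lf.g.resize(cfg.T); Lf.o.resize(cfg.T);
  Lf.c.resize(cfg.T); Lf.th.resize(cfg.T); Lf.h.resize(cfg.T); Lf.x.resize(cfg.T);
  Lb = Lf;
  mat hf(cfg.He, B, fill::zeros), cf(cfg.He, B, fill::zeros);
  mat hb(cfg.He, B, fill::zeros), cb(cfg.He, B, fill::zeros);
  // batch the input projections of both directions over all time steps
  mat Xcat(cfg.D, cfg.T * B);
  for (int t = 0; t < cfg.T; ++t) Xcat.cols(t * B, (t + 1) * B - 1) = feats[t];
  mat Gf = P.efWx() * Xcat; Gf.each_col() += vectorise(P.efb());
  mat Gb = P.ebWx() * Xcat; Gb.each_col() += vectorise(P.ebb());
  for (int t = 0; t < cfg.T; ++t) {
    lstm_step_pre(Gf.cols(t * B, (t + 1) * B - 1), P.efWh(), feats[t],
                  hf, cf, Lf, t);
  }
  for (int t = cfg.T - 1; t >= 0; --t) {
    lstm_step_pre(Gb.cols(t * B, (t + 1) * B - 1), P.ebWh(), feats[t],
                  hb, cb, Lb, t);
  }
  // encoder outputs per sample: 2He x T
  std::vector<mat> Henc(B, mat(2 * cfg.He, cfg.T));
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < cfg.T; ++t) {
      Henc[b].submat(0, t, cfg.He - 1, t) = Lf.h[t].col(b);
      Henc[b].submat(cfg.He, t, 2 * cfg.He - 1, t) = Lb.h[t].col(b);
    }
  }
  std::vector<mat> WeH(B);          // att_We * Henc, A x T
  for (int b = 0; b < B; ++b) WeH[b] = P.aWe() * Henc[b];
  // ---- decoder with attention
  LstmCache Ld;
  Ld.i.resize(Lmax); Ld.f.resize(Lmax); Ld.g.resize(Lmax); Ld.o.resize(Lmax);
  Ld.c.resize(Lmax); Ld.th.resize(Lmax); Ld.h.resize(Lmax); Ld.x.resize(Lmax);
  std::vector<mat> alpha(Lmax, mat(cfg.T, B));     // attention weights
  std::vector<cube> acache(Lmax);                  // tanh activations A x T x B
  std::vector<cube> fcache(Lmax);                  // location features L x T x B
  std::vector<mat> ctxs(Lmax, mat(2 * cfg.He, B));
  std::vector<mat> probs(Lmax, mat(cfg.K + 1, B));
  std::vector<imat> intok(Lmax, imat(1, B));
  mat hd(cfg.Hd, B, fill::zeros), cd(cfg.Hd, B, fill::zeros);
  double loss = 0.0;
  int n_seq = B;
  for (int t = 0; t < Lmax; ++t) {
    acache[t].set_size(cfg.A, cfg.T, B);
    fcache[t].set_size(cfg.L, cfg.T, B);
    mat Wdh = P.aWd() * hd;                        // A x B
    for (int b = 0; b < B; ++b) {
      // location features from the previous alignment
      vec ap = (t == 0) ? vec(cfg.T, fill::zeros) : vec(alpha[t - 1].col(b));
      mat F = P.aK() * loc_windows(ap, cfg.kloc);  // L x T
      fcache[t].slice(b) = F;
      mat s = WeH[b] + P.aWl() * F;
      s.each_col() += Wdh.col(b) + vectorise(P.ab());
      mat a = tanh(s);
      acache[t].slice(b) = a;
      vec u = a.t() * vectorise(P.av());
      u -= u.max();
      vec e = exp(u);
      vec al = e / accu(e);
      alpha[t].col(b) = al;
      ctxs[t].col(b) = Henc[b] * al;
    }
    // decoder input: embedding of previous token + context
    mat emb_in(cfg.E, B);
    for (int b = 0; b < B; ++b) {
      int tok = (t == 0) ? cfg.K : targets(t - 1, b);
      if (tok < 0) tok = cfg.K;   // padded: feed GO; step is masked anyway
      intok[t](0, b) = tok;
      emb_in.col(b) = P.emb().row(tok).t();
    }
    mat xdec = join_cols(emb_in, ctxs[t]);
    lstm_step(P.dWx(), P.dWh(), P.db(), xdec, hd, cd, Ld, t);
    mat z = P.oW() * join_cols(Ld.h[t], ctxs[t]);
    z.each_col() += vectorise(P.ob());
    z.each_row() -= max(z, 0);
    mat ez = exp(z);
    mat pr = ez;
    pr.each_row() /= sum(ez, 0);
    probs[t] = pr;
    for (int b = 0; b < B; ++b) {
      if (t < lens(b)) loss += -std::log(std::max(pr(targets(t, b), b), 1e-12));
    }
  }
  loss /= n_seq;
  // ------------------------------------------------------------------ back
  std::vector<mat> dHenc(B, mat(2 * cfg.He, cfg.T, fill::zeros));
  mat dhd(cfg.Hd, B, fill::zeros), dcd(cfg.Hd, B, fill::zeros);
  // gradient wrt alpha[t] arriving from the location features of step t+1
  mat dalpha_next(cfg.T, B, fill::zeros);
  int pad = cfg.kloc / 2;
  for (int t = Lmax - 1; t >= 0; --t) {
    // softmax + CE
    mat dz = probs[t];
    for (int b = 0; b < B; ++b) {
      if (t < lens(b)) {
        dz(targets(t, b), b) -= 1.0;
      } else {
        dz.col(b).zeros();
      }
    }
    dz /= n_seq;
    mat hcat = join_cols(Ld.h[t], ctxs[t]);
    G.oW() += dz * hcat.t();
    G.ob() += sum(dz, 1);
    mat dhcat = P.oW().t() * dz;
    mat dh_t = dhcat.rows(0, cfg.Hd - 1) + dhd;
    mat dctx = dhcat.rows(cfg.Hd, cfg.Hd + 2 * cfg.He - 1);
    // LSTM step back
    mat c_prev = (t == 0) ? mat(cfg.Hd, B, fill::zeros) : Ld.c[t - 1];
    mat h_prev = (t == 0) ? mat(cfg.Hd, B, fill::zeros) : Ld.h[t - 1];
    mat dh_prev(cfg.Hd, B, fill::zeros);
    mat dx = lstm_step_back(P.dWx(), P.dWh(), Ld, t, c_prev, h_prev,
                            dh_t, dcd, dh_prev, G.dWx(), G.dWh(), G.db());
    // split decoder input gradient
    mat de = dx.rows(0, cfg.E - 1);
    dctx += dx.rows(cfg.E, cfg.E + 2 * cfg.He - 1);
    for (int b = 0; b < B; ++b) {
      G.emb().row(intok[t](0, b)) += de.col(b).t();
    }
    // attention backward (query is h_{t-1})
    mat dquery(cfg.Hd, B, fill::zeros);
    mat dalpha_prev(cfg.T, B, fill::zeros);
    for (int b = 0; b < B; ++b) {
      vec al = alpha[t].col(b);
      vec dal = Henc[b].t() * dctx.col(b) + dalpha_next.col(b);
      dHenc[b] += dctx.col(b) * al.t();
      vec du = al % (dal - dot(dal, al));
      const mat& a = acache[t].slice(b);
      G.av() += a * du;
      mat ds = (vectorise(P.av()) * du.t()) % (1.0 - square(a)); // A x T
      G.aWe() += ds * Henc[b].t();
      dHenc[b] += P.aWe().t() * ds;
      vec ds_sum = sum(ds, 1);
      G.ab() += ds_sum;
      G.aWd() += ds_sum * h_prev.col(b).t();
      dquery.col(b) = P.aWd().t() * ds_sum;
      // location-feature path
      const mat& F = fcache[t].slice(b);
      G.aWl() += ds * F.t();
      mat dF = P.aWl().t() * ds;                    // L x T
      vec ap = (t == 0) ? vec(cfg.T, fill::zeros) : vec(alpha[t - 1].col(b));
      mat Awin = loc_windows(ap, cfg.kloc);
      G.aK() += dF * Awin.t();
      if (t > 0) {
        mat dAwin = P.aK().t() * dF;                // kloc x T
        for (int d = 0; d < cfg.kloc; ++d) {
          for (int j = 0; j < cfg.T; ++j) {
            int src = j + d - pad;
            if (src >= 0 && src < cfg.T) dalpha_prev(src, b) += dAwin(d, j);
          }
        }
      }
    }
    dalpha_next = dalpha_prev;
    dhd = dh_prev + dquery;
  }
  // encoder gradients: collect dHenc into per-direction, per-step dh
  std::vector<mat> dfeats(cfg.T, mat(cfg.D, B, fill::zeros));
  {
    mat dh(cfg.He, B, fill::zeros), dc(cfg.He, B, fill::zeros);
    for (int t = cfg.T - 1; t >= 0; --t) {
      for (int b = 0; b < B; ++b) dh.col(b) += dHenc[b].submat(0, t, cfg.He - 1, t);
      mat c_prev = (t == 0) ? mat(cfg.He, B, fill::zeros) : Lf.c[t - 1];
      mat h_prev = (t == 0) ? mat(cfg.He, B, fill::zeros) : Lf.h[t - 1];
      mat dh_prev(cfg.He, B, fill::zeros);
      dfeats[t] += lstm_step_back(P.efWx(), P.efWh(), Lf, t, c_prev, h_prev,
                                  dh, dc, dh_prev, G.efWx(), G.efWh(), G.efb());
      dh = dh_prev;
    }
  }
  {
    // backward-direction LSTM ran t = T-1 .. 0; reverse order is t = 0 .. T-1
    mat dh(cfg.He, B, fill::zeros), dc(cfg.He, B, fill::zeros);
    for (int t = 0; t < cfg.T; ++t) {
      for (int b = 0; b < B; ++b)
        dh.col(b) += dHenc[b].submat(cfg.He, t, 2 * cfg.He - 1, t);
      mat c_prev = (t == cfg.T - 1) ? mat(cfg.He, B, fill::zeros) : Lb.c[t + 1];
      mat h_prev = (t == cfg.T - 1) ? mat(cfg.He, B, fill::zeros) : Lb.h[t + 1];
      mat dh_prev(cfg.He, B, fill::zeros);
      dfeats[t] += lstm_step_back(P.ebWx(), P.ebWh(), Lb, t, c_prev, h_prev,
                                  dh, dc, dh_prev, G.ebWx(), G.ebWh(), G.ebb());
      dh = dh_prev;
    }
  }
  conv_backward(cfg, P, dfeats, cc, G);
  return loss;
}

// ---------------------------------------------------------------------------
// Greedy decoding

// `allowed`: optional 0-based class indices the decoder may emit (EOS is
// always allowed); empty = unconstrained.
static void predict_batch(const Cfg& cfg, const Params& P, const mat& X,
                          int maxlen, imat& tokens, mat& tokprobs, ivec& outlen,
                          const std::vector<int>& allowed = std::vector<int>()) {
  int B = X.n_cols;
  std::vector<mat> feats;
  ConvCache cc;
  conv_forward(cfg, P, X, feats, cc);
  LstmCache Lf, Lb;
  Lf.i.resize(cfg.T); Lf.f.resize(cfg.T); Lf.g.resize(cfg.T); Lf.o.resize(cfg.T);
  Lf.c.resize(cfg.T); Lf.th.resize(cfg.T); Lf.h.resize(cfg.T); Lf.x.resize(cfg.T);
  Lb = Lf;
  mat hf(cfg.He, B, fill::zeros), cf(cfg.He, B, fill::zeros);
  mat hb(cfg.He, B, fill::zeros), cb(cfg.He, B, fill::zeros);
  mat Xcat(cfg.D, cfg.T * B);
  for (int t = 0; t < cfg.T; ++t) Xcat.cols(t * B, (t + 1) * B - 1) = feats[t];
  mat Gf = P.efWx() * Xcat; Gf.each_col() += vectorise(P.efb());
  mat Gb = P.ebWx() * Xcat; Gb.each_col() += vectorise(P.ebb());
  for (int t = 0; t < cfg.T; ++t)
    lstm_step_pre(Gf.cols(t * B, (t + 1) * B - 1), P.efWh(), feats[t],
                  hf, cf, Lf, t);
  for (int t = cfg.T - 1; t >= 0; --t)
    lstm_step_pre(Gb.cols(t * B, (t + 1) * B - 1), P.ebWh(), feats[t],
                  hb, cb, Lb, t);
  std::vector<mat> Henc(B, mat(2 * cfg.He, cfg.T));
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < cfg.T; ++t) {
      Henc[b].submat(0, t, cfg.He - 1, t) = Lf.h[t].col(b);
      Henc[b].submat(cfg.He, t, 2 * cfg.He - 1, t) = Lb.h[t].col(b);
    }
  }
  std::vector<mat> WeH(B);
  for (int b = 0; b < B; ++b) WeH[b] = P.aWe() * Henc[b];
  tokens.set_size(maxlen, B); tokens.fill(-1);
  tokprobs.set_size(maxlen, B); tokprobs.fill(0.0);
  outlen.set_size(B); outlen.fill(maxlen);
  std::vector<bool> done(B, false);
  ivec prev(B); prev.fill(cfg.K);    // GO
  mat hd(cfg.Hd, B, fill::zeros), cd(cfg.Hd, B, fill::zeros);
  LstmCache Ld;
  Ld.i.resize(1); Ld.f.resize(1); Ld.g.resize(1); Ld.o.resize(1);
  Ld.c.resize(1); Ld.th.resize(1); Ld.h.resize(1); Ld.x.resize(1);
  mat alpha_prev(cfg.T, B, fill::zeros);
  for (int t = 0; t < maxlen; ++t) {
    mat Wdh = P.aWd() * hd;
    mat ctx(2 * cfg.He, B);
    for (int b = 0; b < B; ++b) {
      mat F = P.aK() * loc_windows(vec(alpha_prev.col(b)), cfg.kloc);
      mat s = WeH[b] + P.aWl() * F;
      s.each_col() += Wdh.col(b) + vectorise(P.ab());
      mat a = tanh(s);
      vec u = a.t() * vectorise(P.av());
      u -= u.max();
      vec e = exp(u);
      vec al = e / accu(e);
      alpha_prev.col(b) = al;
      ctx.col(b) = Henc[b] * al;
    }
    mat emb_in(cfg.E, B);
    for (int b = 0; b < B; ++b) emb_in.col(b) = P.emb().row(prev(b)).t();
    mat xdec = join_cols(emb_in, ctx);
    lstm_step(P.dWx(), P.dWh(), P.db(), xdec, hd, cd, Ld, 0);
    mat z = P.oW() * join_cols(hd, ctx);
    z.each_col() += vectorise(P.ob());
    if (!allowed.empty()) {
      std::vector<bool> ok(cfg.K + 1, false);
      ok[cfg.K] = true;
      for (int a : allowed) if (a >= 0 && a < cfg.K) ok[a] = true;
      for (int k = 0; k <= cfg.K; ++k) {
        if (!ok[k]) z.row(k).fill(-datum::inf);
      }
    }
    z.each_row() -= max(z, 0);
    mat ez = exp(z);
    mat pr = ez;
    pr.each_row() /= sum(ez, 0);
    bool all_done = true;
    for (int b = 0; b < B; ++b) {
      if (done[b]) continue;
      uword best = pr.col(b).index_max();
      if ((int)best == cfg.K) {          // EOS
        done[b] = true;
        outlen(b) = t;
      } else {
        tokens(t, b) = best;
        tokprobs(t, b) = pr(best, b);
        prev(b) = best;
        all_done = false;
      }
    }
    if (all_done) break;
  }
  for (int b = 0; b < B; ++b) if (!done[b]) outlen(b) = maxlen;
}

// ---------------------------------------------------------------------------
// Raw-image helpers

static mat raw_to_batch(const Rcpp::RawMatrix& imgs, const std::vector<int>& idx) {
  int npx = imgs.ncol();
  mat X(npx, idx.size());
  for (size_t j = 0; j < idx.size(); ++j) {
    int r = idx[j];
    for (int p = 0; p < npx; ++p) {
      X(p, j) = ((double)(unsigned char)imgs(r, p) / 255.0 - 0.5) / 0.5;
    }
  }
  return X;
}

// ---------------------------------------------------------------------------
// Exports

// [[Rcpp::export(name = ".ocr_loss_grad_cpp")]]
Rcpp::List ocr_loss_grad_cpp(Rcpp::List params, Rcpp::List config,
                             Rcpp::NumericMatrix images,
                             Rcpp::IntegerMatrix targets,
                             Rcpp::IntegerVector lens) {
  Cfg cfg = read_cfg(config);
  Params P = params_from_list(params);
  // images: B x (H*W) in [0,1]
  int B = images.nrow();
  mat X(images.ncol(), B);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < images.ncol(); ++p)
      X(p, b) = (images(b, p) - 0.5) / 0.5;
  imat tg(targets.nrow(), targets.ncol());
  for (int i = 0; i < targets.nrow(); ++i)
    for (int j = 0; j < targets.ncol(); ++j) tg(i, j) = targets(i, j);
  ivec lv(lens.size());
  for (int i = 0; i < lens.size(); ++i) lv(i) = lens[i];
  Params G = zeros_like(P);
  double loss = loss_grad(cfg, P, X, tg, lv, G);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(G));
}

// [[Rcpp::export(name = ".ocr_predict_cpp")]]
Rcpp::List ocr_predict_cpp(Rcpp::List params, Rcpp::List config,
                           Rcpp::NumericMatrix images, int max_len,
                           Rcpp::IntegerVector allowed_classes) {
  Cfg cfg = read_cfg(config);
  Params P = params_from_list(params);
  int B = images.nrow();
  mat X(images.ncol(), B);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < images.ncol(); ++p)
      X(p, b) = (images(b, p) - 0.5) / 0.5;
  std::vector<int> allowed(allowed_classes.begin(), allowed_classes.end());
  imat tokens; mat tokprobs; ivec outlen;
  predict_batch(cfg, P, X, max_len, tokens, tokprobs, outlen, allowed);
  Rcpp::IntegerMatrix tk(tokens.n_rows, tokens.n_cols);
  Rcpp::NumericMatrix pp(tokens.n_rows, tokens.n_cols);
  for (uword i = 0; i < tokens.n_rows; ++i)
    for (uword j = 0; j < tokens.n_cols; ++j) {
      tk(i, j) = tokens(i, j); pp(i, j) = tokprobs(i, j);
    }
  Rcpp::IntegerVector ol(outlen.n_elem);
  for (uword i = 0; i < outlen.n_elem; ++i) ol[i] = outlen(i);
  return Rcpp::List::create(Rcpp::Named("tokens") = tk,
                            Rcpp::Named("probs") = pp,
                            Rcpp::Named("lens") = ol);
}

static double eval_accuracy(const Cfg& cfg, const Params& P,
                            const Rcpp::RawMatrix& imgs,
                            const Rcpp::IntegerMatrix& labels,
                            const Rcpp::IntegerVector& lens,
                            const std::vector<int>& idx) {
  if (idx.empty()) return 0.0;
  int maxlen = labels.nrow();
  int correct = 0;
  const int chunk = 64;
  for (size_t s = 0; s < idx.size(); s += chunk) {
    std::vector<int> sub(idx.begin() + s,
                         idx.begin() + std::min(idx.size(), s + chunk));
    mat X = raw_to_batch(imgs, sub);
    imat tokens; mat tokprobs; ivec outlen;
    predict_batch(cfg, P, X, maxlen + 2, tokens, tokprobs, outlen);
    for (size_t j = 0; j < sub.size(); ++j) {
      int r = sub[j];
      int L = lens[r] - 1;          // label length excl. EOS
      bool ok = (outlen(j) == L);
      if (ok) {
        for (int t = 0; t < L; ++t) {
          if (tokens(t, j) != labels(t, r)) { ok = false; break; }
        }
      }
      if (ok) ++correct;
    }
  }
  return (double)correct / idx.size();
}

// [[Rcpp::export(name = ".ocr_train_cpp")]]
Rcpp::List ocr_train_cpp(Rcpp::List params, Rcpp::List config,
                         Rcpp::RawMatrix train_images,
                         Rcpp::IntegerMatrix train_labels,
                         Rcpp::IntegerVector train_lens,
                         Rcpp::RawMatrix val_images,
                         Rcpp::IntegerMatrix val_labels,
                         Rcpp::IntegerVector val_lens,
                         int iterations, int batch_size, int seed,
                         int eval_every, int val_subset, double lr,
                         double rho, double clip, bool verbose,
                         Rcpp::IntegerVector val_idx) {
  Cfg cfg = read_cfg(config);
  Params P = params_from_list(params);
  Params Eg = zeros_like(P), Edx = zeros_like(P);
  Params best = P;
  double best_acc = -1.0;
  int n_train = train_images.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n_train - 1);
  // fixed validation subset for the learning curve: caller-selected
  // indices if provided (e.g. the low-noise stratum), else a random draw
  std::vector<int> vidx;
  if (val_idx.size() > 0) {
    vidx.assign(val_idx.begin(), val_idx.end());
  } else {
    int nv = val_images.nrow();
    int take = std::min(nv, val_subset);
    std::vector<int> all(nv);
    for (int i = 0; i < nv; ++i) all[i] = i;
    for (int i = nv - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(all[i], all[d(rng)]);
    }
    vidx.assign(all.begin(), all.begin() + take);
  }
  std::vector<double> cv_iter, cv_loss, cv_acc;
  double run_loss = 0.0; int run_n = 0;
  const double eps = 1e-6;
  int Lmax_lab = train_labels.nrow();
  for (int it = 1; it <= iterations; ++it) {
    std::vector<int> idx(batch_size);
    for (int b = 0; b < batch_size; ++b) idx[b] = pick(rng);
    mat X = raw_to_batch(train_images, idx);
    int Lmax = 0;
    for (int b = 0; b < batch_size; ++b) Lmax = std::max(Lmax, (int)train_lens[idx[b]]);
    imat tg(Lmax, batch_size); tg.fill(-1);
    ivec lv(batch_size);
    for (int b = 0; b < batch_size; ++b) {
      lv(b) = train_lens[idx[b]];
      for (int t = 0; t < lv(b) && t < Lmax_lab; ++t) tg(t, b) = train_labels(t, idx[b]);
    }
    Params G = zeros_like(P);
    double loss = loss_grad(cfg, P, X, tg, lv, G);
    run_loss += loss; run_n++;
    // global-norm gradient clipping
    double nrm2 = 0.0;
    for (int i = 0; i < N_PARAMS; ++i) nrm2 += accu(square(G[i]));
    double nrm = std::sqrt(nrm2);
    double gs = (nrm > clip) ? clip / nrm : 1.0;
    for (int i = 0; i < N_PARAMS; ++i) {
      mat g = G[i] * gs;
      Eg[i] = rho * Eg[i] + (1.0 - rho) * square(g);
      mat dx = -sqrt(Edx[i] + eps) / sqrt(Eg[i] + eps) % g;
      Edx[i] = rho * Edx[i] + (1.0 - rho) * square(dx);
      P[i] += lr * dx;
    }
    if (it % eval_every == 0 || it == iterations) {
      double acc = eval_accuracy(cfg, P, val_images, val_labels, val_lens, vidx);
      cv_iter.push_back(it);
      cv_loss.push_back(run_loss / std::max(1, run_n));
      cv_acc.push_back(acc);
      if (acc >= best_acc) { best_acc = acc; best = P; }
      if (verbose) {
        Rcpp::Rcout << "iter " << it << "  loss " << run_loss / std::max(1, run_n)
                    << "  val_acc " << acc << std::endl;
      }
      run_loss = 0.0; run_n = 0;
      Rcpp::checkUserInterrupt();
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = params_to_list(best),
    Rcpp::Named("final_params") = params_to_list(P),
    Rcpp::Named("best_val_accuracy") = best_acc,
    Rcpp::Named("curves") = Rcpp::DataFrame::create(
      Rcpp::Named("iteration") = cv_iter,
      Rcpp::Named("loss") = cv_loss,
      Rcpp::Named("val_accuracy") = cv_acc));
}
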