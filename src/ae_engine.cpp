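#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Compiled float32 training/inference engine for the multitask ViT
// autoencoder. Mirrors the R reference implementation (nn-layers.R /
// nn-model.R) operation for operation — same architecture, layer-norm
// epsilon, erf-based GELU and attention scaling — but runs in single
// precision (the conventional working precision for this model family)
// with preallocated workspaces. The R reference path serves as the
// numerical oracle for this engine in the test suite.

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;

static const float LN_EPS = 1e-5f;
static const float INV_SQRT2 = 0.70710678f;
static const float INV_SQRT2PI = 0.39894228f;

struct LnCache { fmat xhat; fvec inv; };

struct BlockCache {
  LnCache ln1, ln2;
  fmat Xin, Q, K, V, att /* (T*T) x (B*H) stacked */, attOut, X2;
  fmat fc1out, geluOut, geluDeriv;
};

struct Cfg {
  int imagePx, patchPx, encLayers, encDim, decLayers, decDim,
      clsLayers, heads, mlpRatio, nStates, nPatch, nSide;
};

typedef std::map<std::string, fmat> PMap;

static fmat getM(const PMap& P, const std::string& k) {
  PMap::const_iterator it = P.find(k);
  if (it == P.end()) stop("missing parameter " + k);
  return it->second;
}

static PMap toPMap(List params) {
  PMap P;
  CharacterVector nms = params.names();
  for (int i = 0; i < params.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    RObject o = params[i];
    if (Rf_isMatrix(o)) {
      P[nm] = arma::conv_to<fmat>::from(as<arma::mat>(o));
    } else {
      arma::vec v = as<arma::vec>(o);
      P[nm] = arma::conv_to<fmat>::from(arma::mat(v.memptr(), 1, v.n_elem));
    }
  }
  return P;
}

static Cfg toCfg(List cfg) {
  Cfg c;
  c.imagePx = as<int>(cfg["imagePx"]); c.patchPx = as<int>(cfg["patchPx"]);
  c.encLayers = as<int>(cfg["encLayers"]); c.encDim = as<int>(cfg["encDim"]);
  c.decLayers = as<int>(cfg["decLayers"]); c.decDim = as<int>(cfg["decDim"]);
  c.clsLayers = as<int>(cfg["clsLayers"]); c.heads = as<int>(cfg["heads"]);
  c.mlpRatio = as<int>(cfg["mlpRatio"]); c.nStates = as<int>(cfg["nStates"]);
  c.nSide = c.imagePx / c.patchPx;
  c.nPatch = c.nSide * c.nSide;
  return c;
}

// flat (column-major) pixel indices covered by each patch token, matching
// the R-side .patchIndex: tokens row-major over the patch grid from the
// bottom-left.
static arma::umat patchIndex(const Cfg& c) {
  arma::umat idx(c.nPatch, c.patchPx * c.patchPx);
  int t = 0;
  for (int pr = 0; pr < c.nSide; ++pr)
    for (int pc = 0; pc < c.nSide; ++pc, ++t) {
      int q = 0;
      for (int jj = 0; jj < c.patchPx; ++jj)
        for (int ii = 0; ii < c.patchPx; ++ii, ++q) {
          int row = pr * c.patchPx + ii;
          int col = pc * c.patchPx + jj;
          idx(t, q) = (arma::uword)(col * c.imagePx + row);
        }
    }
  return idx;
}

static void layernormF(const fmat& X, const fmat& g, const fmat& b,
                       fmat& out, LnCache& cc) {
  int D = X.n_cols;
  fvec mu = arma::mean(X, 1);
  cc.xhat = X.each_col() - mu;
  cc.inv = 1.0f / arma::sqrt(arma::mean(arma::square(cc.xhat), 1) + LN_EPS);
  cc.xhat.each_col() %= cc.inv;
  out = cc.xhat.each_row() % g.row(0);
  out.each_row() += b.row(0);
  (void)D;
}

static void layernormB(const LnCache& cc, const fmat& g, const fmat& dY,
                       fmat& dX, fmat& dg, fmat& db) {
  float D = (float)dY.n_cols;
  fmat dxhat = dY.each_row() % g.row(0);
  fvec t1 = arma::sum(dxhat, 1);
  fvec t2 = arma::sum(dxhat % cc.xhat, 1);
  fmat corr = cc.xhat.each_col() % t2;   // xhat * t2
  corr.each_col() += t1;                 // t1 + xhat * t2
  dX = dxhat - corr / D;
  dX.each_col() %= cc.inv;
  dg = arma::sum(dY % cc.xhat, 0);
  db = arma::sum(dY, 0);
}

static void geluF(const fmat& X, fmat& out, fmat& deriv) {
  out.set_size(X.n_rows, X.n_cols);
  deriv.set_size(X.n_rows, X.n_cols);
  const float* x = X.memptr();
  float* o = out.memptr();
  float* d = deriv.memptr();
  arma::uword n = X.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    float xi = x[i];
    float Phi = 0.5f * (1.0f + std::erf(xi * INV_SQRT2));
    float phi = INV_SQRT2PI * std::exp(-0.5f * xi * xi);
    o[i] = xi * Phi;
    d[i] = Phi + xi * phi;
  }
}

// multi-head attention on (B*T) x D token matrices; att stored as
// (T x T) stacked per (b, h) slice in a (T*T) x (B*H) matrix.
static void attnF(const fmat& Q, const fmat& K, const fmat& V,
                  int B, int T, int H, fmat& out, fmat& att) {
  int D = Q.n_cols, dh = D / H;
  float scale = 1.0f / std::sqrt((float)dh);
  out.set_size(B * T, D);
  att.set_size(T * T, B * H);
  for (int b = 0; b < B; ++b) {
    int r0 = b * T, r1 = r0 + T - 1;
    for (int h = 0; h < H; ++h) {
      int c0 = h * dh, c1 = c0 + dh - 1;
      fmat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scale;
      S.each_col() -= arma::max(S, 1);
      S = arma::exp(S);
      S.each_col() /= arma::sum(S, 1);
      att.col(b * H + h) = arma::vectorise(S);
      out.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
}

static void attnB(const fmat& dOut, const fmat& Q, const fmat& K,
                  const fmat& V, const fmat& att, int B, int T, int H,
                  fmat& dQ, fmat& dK, fmat& dV) {
  int D = Q.n_cols, dh = D / H;
  float scale = 1.0f / std::sqrt((float)dh);
  dQ.set_size(B * T, D); dK.set_size(B * T, D); dV.set_size(B * T, D);
  for (int b = 0; b < B; ++b) {
    int r0 = b * T, r1 = r0 + T - 1;
    for (int h = 0; h < H; ++h) {
      int c0 = h * dh, c1 = c0 + dh - 1;
      fmat A(const_cast<float*>(att.colptr(b * H + h)), T, T, false, true);
      fmat dOb = dOut.submat(r0, c0, r1, c1);
      fmat Vb = V.submat(r0, c0, r1, c1);
      fmat dA = dOb * Vb.t();
      dV.submat(r0, c0, r1, c1) = A.t() * dOb;
      fvec rs = arma::sum(dA % A, 1);
      fmat dS = A % (dA.each_col() - rs);
      dQ.submat(r0, c0, r1, c1) = (dS * K.submat(r0, c0, r1, c1)) * scale;
      dK.submat(r0, c0, r1, c1) = (dS.t() * Q.submat(r0, c0, r1, c1)) * scale;
    }
  }
}

static fmat blockF(const PMap& P, const std::string& pre, const fmat& X,
                   int B, int T, int H, BlockCache& cc) {
  cc.Xin = X;
  fmat h1;
  layernormF(X, getM(P, pre + ".ln1.g"), getM(P, pre + ".ln1.b"), h1, cc.ln1);
  int D = X.n_cols;
  fmat qkv = h1 * getM(P, pre + ".Wqkv");
  qkv.each_row() += getM(P, pre + ".bqkv").row(0);
  cc.Q = qkv.cols(0, D - 1);
  cc.K = qkv.cols(D, 2 * D - 1);
  cc.V = qkv.cols(2 * D, 3 * D - 1);
  attnF(cc.Q, cc.K, cc.V, B, T, H, cc.attOut, cc.att);
  fmat proj = cc.attOut * getM(P, pre + ".Wproj");
  proj.each_row() += getM(P, pre + ".bproj").row(0);
  cc.X2 = X + proj;
  fmat h2;
  layernormF(cc.X2, getM(P, pre + ".ln2.g"), getM(P, pre + ".ln2.b"), h2, cc.ln2);
  cc.fc1out = h2 * getM(P, pre + ".Wfc1");
  cc.fc1out.each_row() += getM(P, pre + ".bfc1").row(0);
  geluF(cc.fc1out, cc.geluOut, cc.geluDeriv);
  fmat out = cc.geluOut * getM(P, pre + ".Wfc2");
  out.each_row() += getM(P, pre + ".bfc2").row(0);
  return cc.X2 + out;
}

static fmat h2Of(const PMap& P, const std::string& pre, const BlockCache& cc) {
  fmat h2 = cc.ln2.xhat.each_row() % getM(P, pre + ".ln2.g").row(0);
  h2.each_row() += getM(P, pre + ".ln2.b").row(0);
  return h2;
}

static fmat h1Of(const PMap& P, const std::string& pre, const BlockCache& cc) {
  fmat h1 = cc.ln1.xhat.each_row() % getM(P, pre + ".ln1.g").row(0);
  h1.each_row() += getM(P, pre + ".ln1.b").row(0);
  return h1;
}

static fmat blockB(const PMap& P, const std::string& pre, BlockCache& cc,
                   const fmat& dOut, int B, int T, int H, PMap& G) {
  // MLP half
  fmat h2 = h2Of(P, pre, cc);
  G[pre + ".Wfc2"] = cc.geluOut.t() * dOut;
  G[pre + ".bfc2"] = arma::sum(dOut, 0);
  fmat dGelu = dOut * getM(P, pre + ".Wfc2").t();
  fmat dFc1 = dGelu % cc.geluDeriv;
  G[pre + ".Wfc1"] = h2.t() * dFc1;
  G[pre + ".bfc1"] = arma::sum(dFc1, 0);
  fmat dh2 = dFc1 * getM(P, pre + ".Wfc1").t();
  fmat dX2, dg, db;
  layernormB(cc.ln2, getM(P, pre + ".ln2.g"), dh2, dX2, dg, db);
  G[pre + ".ln2.g"] = dg; G[pre + ".ln2.b"] = db;
  dX2 += dOut;
  // attention half
  G[pre + ".Wproj"] = cc.attOut.t() * dX2;
  G[pre + ".bproj"] = arma::sum(dX2, 0);
  fmat dAttOut = dX2 * getM(P, pre + ".Wproj").t();
  fmat dQ, dK, dV;
  attnB(dAttOut, cc.Q, cc.K, cc.V, cc.att, B, T, H, dQ, dK, dV);
  fmat dQKV = arma::join_rows(dQ, dK, dV);
  fmat h1 = h1Of(P, pre, cc);
  G[pre + ".Wqkv"] = h1.t() * dQKV;
  G[pre + ".bqkv"] = arma::sum(dQKV, 0);
  fmat dh1 = dQKV * getM(P, pre + ".Wqkv").t();
  fmat dX, dg1, db1;
  layernormB(cc.ln1, getM(P, pre + ".ln1.g"), dh1, dX, dg1, db1);
  G[pre + ".ln1.g"] = dg1; G[pre + ".ln1.b"] = db1;
  return dX + dX2;
}

struct FwdState {
  Cfg c;
  int B;
  arma::umat idx;
  fmat tok, X0;           // patch tokens, embedded sequence input
  std::vector<BlockCache> enc, cls, dec;
  LnCache lnH, lnD;
  fmat clsTok, Xenc, XcTop, dprojIn, XdTop, lnDout, lnHout;
  fmat out01, logits;
};

static void forwardPass(const PMap& P, const Cfg& c, const fmat& Ximg,
                        FwdState& S) {
  S.c = c;
  S.B = Ximg.n_rows;
  S.idx = patchIndex(c);
  int B = S.B, T = c.nPatch + 1, p2 = c.patchPx * c.patchPx;
  // patchify
  S.tok.set_size(B * c.nPatch, p2);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.nPatch; ++t)
      for (int q = 0; q < p2; ++q)
        S.tok(b * c.nPatch + t, q) = Ximg(b, S.idx(t, q));
  fmat emb = S.tok * getM(P, "embed.W");
  emb.each_row() += getM(P, "embed.b").row(0);
  fmat X(B * T, c.encDim);
  fmat cls = getM(P, "embed.cls");
  fmat pos = getM(P, "embed.pos");  // (T x D) stored as matrix
  for (int b = 0; b < B; ++b) {
    X.row(b * T) = cls.row(0) + pos.row(0);
    for (int t = 0; t < c.nPatch; ++t)
      X.row(b * T + t + 1) = emb.row(b * c.nPatch + t) + pos.row(t + 1);
  }
  S.enc.resize(c.encLayers);
  for (int l = 0; l < c.encLayers; ++l)
    X = blockF(P, "enc" + std::to_string(l + 1), X, B, T, c.heads, S.enc[l]);
  S.Xenc = X;
  // classifier branch
  fmat Xc = X;
  S.cls.resize(c.clsLayers);
  for (int l = 0; l < c.clsLayers; ++l)
    Xc = blockF(P, "cls" + std::to_string(l + 1), Xc, B, T, c.heads, S.cls[l]);
  S.XcTop = Xc;
  S.clsTok.set_size(B, c.encDim);
  for (int b = 0; b < B; ++b) S.clsTok.row(b) = Xc.row(b * T);
  layernormF(S.clsTok, getM(P, "clsHead.ln.g"), getM(P, "clsHead.ln.b"),
             S.lnHout, S.lnH);
  S.logits = S.lnHout * getM(P, "clsHead.W");
  S.logits.each_row() += getM(P, "clsHead.b").row(0);
  // decoder branch
  fmat patchTok(B * c.nPatch, c.encDim);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.nPatch; ++t)
      patchTok.row(b * c.nPatch + t) = X.row(b * T + t + 1);
  S.dprojIn = patchTok;
  fmat Xd = patchTok * getM(P, "dec.proj.W");
  Xd.each_row() += getM(P, "dec.proj.b").row(0);
  fmat dpos = getM(P, "dec.pos");
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.nPatch; ++t)
      Xd.row(b * c.nPatch + t) += dpos.row(t);
  S.dec.resize(c.decLayers);
  for (int l = 0; l < c.decLayers; ++l)
    Xd = blockF(P, "dec" + std::to_string(l + 1), Xd, B, c.nPatch, c.heads,
                S.dec[l]);
  S.XdTop = Xd;
  layernormF(Xd, getM(P, "dec.ln.g"), getM(P, "dec.ln.b"), S.lnDout, S.lnD);
  fmat pix = S.lnDout * getM(P, "dec.out.W");
  pix.each_row() += getM(P, "dec.out.b").row(0);
  S.out01.set_size(B, c.imagePx * c.imagePx);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.nPatch; ++t)
      for (int q = 0; q < p2; ++q)
        S.out01(b, S.idx(t, q)) = pix(b * c.nPatch + t, q);
}

static PMap backwardPass(const PMap& P, FwdState& S, const fmat& dOut01,
                         const fmat& dLogits) {
  const Cfg& c = S.c;
  int B = S.B, T = c.nPatch + 1, p2 = c.patchPx * c.patchPx;
  PMap G;
  // decoder
  fmat dPix(B * c.nPatch, p2);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.nPatch; ++t)
      for (int q = 0; q < p2; ++q)
        dPix(b * c.nPatch + t, q) = dOut01(b, S.idx(t, q));
  G["dec.out.W"] = S.lnDout.t() * dPix;
  G["dec.out.b"] = arma::sum(dPix, 0);
  fmat dLnD = dPix * getM(P, "dec.out.W").t();
  fmat dXd, dg, db;
  layernormB(S.lnD, getM(P, "dec.ln.g"), dLnD, dXd, dg, db);
  G["dec.ln.g"] = dg; G["dec.ln.b"] = db;
  for (int l = c.decLayers; l >= 1; --l)
    dXd = blockB(P, "dec" + std::to_string(l), S.dec[l - 1], dXd, B,
                 c.nPatch, c.heads, G);
  fmat dpos(c.nPatch, c.decDim, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.nPatch; ++t)
      dpos.row(t) += dXd.row(b * c.nPatch + t);
  G["dec.pos"] = dpos;
  G["dec.proj.W"] = S.dprojIn.t() * dXd;
  G["dec.proj.b"] = arma::sum(dXd, 0);
  fmat dPatchTok = dXd * getM(P, "dec.proj.W").t();
  fmat dXfromDec(B * T, c.encDim, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.nPatch; ++t)
      dXfromDec.row(b * T + t + 1) = dPatchTok.row(b * c.nPatch + t);
  // classifier
  G["clsHead.W"] = S.lnHout.t() * dLogits;
  G["clsHead.b"] = arma::sum(dLogits, 0);
  fmat dLnH = dLogits * getM(P, "clsHead.W").t();
  fmat dClsTok, hg, hb;
  layernormB(S.lnH, getM(P, "clsHead.ln.g"), dLnH, dClsTok, hg, hb);
  G["clsHead.ln.g"] = hg; G["clsHead.ln.b"] = hb;
  fmat dXc(B * T, c.encDim, arma::fill::zeros);
  for (int b = 0; b < B; ++b) dXc.row(b * T) = dClsTok.row(b);
  for (int l = c.clsLayers; l >= 1; --l)
    dXc = blockB(P, "cls" + std::to_string(l), S.cls[l - 1], dXc, B, T,
                 c.heads, G);
  fmat dX = dXfromDec + dXc;
  for (int l = c.encLayers; l >= 1; --l)
    dX = blockB(P, "enc" + std::to_string(l), S.enc[l - 1], dX, B, T,
                c.heads, G);
  fmat dposE(T, c.encDim, arma::fill::zeros);
  fmat dCls(1, c.encDim, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    dCls.row(0) += dX.row(b * T);
    for (int t = 0; t < T; ++t) dposE.row(t) += dX.row(b * T + t);
  }
  G["embed.pos"] = dposE;
  G["embed.cls"] = dCls;
  fmat dTok(B * c.nPatch, c.encDim);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.nPatch; ++t)
      dTok.row(b * c.nPatch + t) = dX.row(b * T + t + 1);
  G["embed.W"] = S.tok.t() * dTok;
  G["embed.b"] = arma::sum(dTok, 0);
  return G;
}

static List pmapToList(const PMap& G, List templ) {
  CharacterVector nms = templ.names();
  List out(templ.size());
  out.attr("names") = nms;
  for (int i = 0; i < templ.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    PMap::const_iterator it = G.find(nm);
    if (it == G.end()) { out[i] = R_NilValue; continue; }
    RObject t = templ[i];
    arma::mat g = arma::conv_to<arma::mat>::from(it->second);
    if (Rf_isMatrix(t)) {
      out[i] = wrap(g);
    } else {
      arma::vec v = arma::vectorise(g);
      out[i] = NumericVector(v.begin(), v.end());
    }
  }
  return out;
}

// One fused training step: forward, loss, backward. Returns the loss
// components, gradients (named like the parameters) and the predictions.
// [[Rcpp::export(name = ".cpp_ae_step")]]
List cpp_ae_step(List params, List cfg, const arma::mat& X,
                 const arma::mat& gt01, IntegerVector y,
                 double alpha, double beta) {
  PMap P = toPMap(params);
  Cfg c = toCfg(cfg);
  fmat Xf = arma::conv_to<fmat>::from(X);
  fmat Gt = arma::conv_to<fmat>::from(gt01);
  for (int b = 0; b < y.size(); ++b)
    if (y[b] < 1 || y[b] > c.nStates)
      stop("state label out of range for the model's state count");
  FwdState S;
  forwardPass(P, c, Xf, S);
  int B = S.B, npix = c.imagePx * c.imagePx, K = c.nStates;
  // softmax + cross entropy
  fmat probs = S.logits;
  probs.each_col() -= arma::max(probs, 1);
  probs = arma::exp(probs);
  probs.each_col() /= arma::sum(probs, 1);
  double Lc = 0;
  for (int b = 0; b < B; ++b)
    Lc += -std::log(std::max(probs(b, y[b] - 1), 1e-12f));
  Lc /= B;
  fmat diff = S.out01 - Gt;
  double Ld = arma::accu(arma::square(arma::conv_to<arma::mat>::from(diff)))
              / ((double)B * npix);
  fmat dOut = (float)(alpha * 2.0 / (B * (double)npix)) * diff;
  fmat dLogits = probs;
  for (int b = 0; b < B; ++b) dLogits(b, y[b] - 1) -= 1.0f;
  dLogits *= (float)(beta / (double)B);
  PMap G = backwardPass(P, S, dOut, dLogits);
  return List::create(
    _["Ld"] = Ld, _["Lc"] = Lc,
    _["loss"] = alpha * Ld + beta * Lc,
    _["grads"] = pmapToList(G, params),
    _["probs"] = arma::conv_to<arma::mat>::from(probs));
}

// Forward-only pass. Optionally returns the head-averaged attention
// matrices of sample 1 for every encoder/classifier block (for rollout).
// [[Rcpp::export(name = ".cpp_ae_predict")]]
List cpp_ae_predict(List params, List cfg, const arma::mat& X,
                    bool wantAttention) {
  PMap P = toPMap(params);
  Cfg c = toCfg(cfg);
  fmat Xf = arma::conv_to<fmat>::from(X);
  FwdState S;
  forwardPass(P, c, Xf, S);
  fmat probs = S.logits;
  probs.each_col() -= arma::max(probs, 1);
  probs = arma::exp(probs);
  probs.each_col() /= arma::sum(probs, 1);
  if (!wantAttention)
    return List::create(
      _["out01"] = arma::conv_to<arma::mat>::from(S.out01),
      _["logits"] = arma::conv_to<arma::mat>::from(S.logits),
      _["probs"] = arma::conv_to<arma::mat>::from(probs));
  int T = c.nPatch + 1;
  List attEnc(c.encLayers), attCls(c.clsLayers);
  for (int l = 0; l < c.encLayers; ++l) {
    fmat A(T, T, arma::fill::zeros);
    for (int h = 0; h < c.heads; ++h)
      A += arma::reshape(S.enc[l].att.col(h), T, T);
    attEnc[l] = wrap(arma::conv_to<arma::mat>::from(A / (float)c.heads));
  }
  for (int l = 0; l < c.clsLayers; ++l) {
    fmat A(T, T, arma::fill::zeros);
    for (int h = 0; h < c.heads; ++h)
      A += arma::reshape(S.cls[l].att.col(h), T, T);
    attCls[l] = wrap(arma::conv_to<arma::mat>::from(A / (float)c.heads));
  }
  return List::create(
    _["out01"] = arma::conv_to<arma::mat>::from(S.out01),
    _["logits"] = arma::conv_to<arma::mat>::from(S.logits),
    _["probs"] = arma::conv_to<arma::mat>::from(probs),
    _["attEnc"] = attEnc, _["attCls"] = attCls);
}
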