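// Compiled forward/backward pass for the SMILES-pair classifier:
// embedding -> BiLSTM (last-state pooling per direction) -> MLP per drug,
// concatenation (drug A first) -> affine + sigmoid.
//
// Reverse-mode gradients are derived by hand; the R test-suite checks them
// against central finite differences and the pure-R reference forward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double CLAMP_EPS = 1e-7;  // probability clamp before log

struct LstmParams {
  arma::mat Wf, Wi, Wo, Wc;
  arma::vec bf, bi, bo, bc;
};

struct MlpParams {
  arma::mat Wh, Wo;
  arma::vec bh, bo;
};

struct Branch {
  arma::mat emb;  // vocab x embed
  LstmParams fwd, bwd;
  MlpParams mlp;
};

static LstmParams read_lstm(const List& l) {
  LstmParams p;
  p.Wf = as<arma::mat>(l["w_f"]);
  p.Wi = as<arma::mat>(l["w_i"]);
  p.Wo = as<arma::mat>(l["w_o"]);
  p.Wc = as<arma::mat>(l["w_c"]);
  p.bf = as<arma::vec>(l["b_f"]);
  p.bi = as<arma::vec>(l["b_i"]);
  p.bo = as<arma::vec>(l["b_o"]);
  p.bc = as<arma::vec>(l["b_c"]);
  return p;
}

static Branch read_branch(const List& l) {
  Branch b;
  b.emb = as<arma::mat>(l["emb"]);
  b.fwd = read_lstm(l["fwd"]);
  b.bwd = read_lstm(l["bwd"]);
  List m = l["mlp"];
  b.mlp.Wh = as<arma::mat>(m["W_h"]);
  b.mlp.bh = as<arma::vec>(m["b_h"]);
  b.mlp.Wo = as<arma::mat>(m["W_o"]);
  b.mlp.bo = as<arma::vec>(m["b_o"]);
  return b;
}

struct LstmGrad {
  arma::mat Wf, Wi, Wo, Wc;
  arma::vec bf, bi, bo, bc;
  void init(const LstmParams& p) {
    Wf.zeros(arma::size(p.Wf)); Wi.zeros(arma::size(p.Wi));
    Wo.zeros(arma::size(p.Wo)); Wc.zeros(arma::size(p.Wc));
    bf.zeros(arma::size(p.bf)); bi.zeros(arma::size(p.bi));
    bo.zeros(arma::size(p.bo)); bc.zeros(arma::size(p.bc));
  }
};

struct BranchGrad {
  arma::mat emb;
  LstmGrad fwd, bwd;
  arma::mat mWh, mWo;
  arma::vec mbh, mbo;
  void init(const Branch& b) {
    emb.zeros(arma::size(b.emb));
    fwd.init(b.fwd); bwd.init(b.bwd);
    mWh.zeros(arma::size(b.mlp.Wh)); mWo.zeros(arma::size(b.mlp.Wo));
    mbh.zeros(arma::size(b.mlp.bh)); mbo.zeros(arma::size(b.mlp.bo));
  }
};

// Per-step caches of one unidirectional run (columns in step order).
struct DirCache {
  arma::mat F, I, O, Ct, C, H;  // hidden x T
};

// Run one direction over X (embed x T, already in processing order).
static arma::vec run_dir(const arma::mat& X, const LstmParams& p,
                         DirCache& cache) {
  const arma::uword T = X.n_cols, H = p.bf.n_elem;
  cache.F.set_size(H, T); cache.I.set_size(H, T); cache.O.set_size(H, T);
  cache.Ct.set_size(H, T); cache.C.set_size(H, T); cache.H.set_size(H, T);
  arma::vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec z = arma::join_cols(X.col(t), h);
    arma::vec f = 1.0 / (1.0 + arma::exp(-(p.Wf * z + p.bf)));
    arma::vec i = 1.0 / (1.0 + arma::exp(-(p.Wi * z + p.bi)));
    arma::vec o = 1.0 / (1.0 + arma::exp(-(p.Wo * z + p.bo)));
    arma::vec ct = arma::tanh(p.Wc * z + p.bc);
    c = f % c + i % ct;
    h = o % arma::tanh(c);
    cache.F.col(t) = f; cache.I.col(t) = i; cache.O.col(t) = o;
    cache.Ct.col(t) = ct; cache.C.col(t) = c; cache.H.col(t) = h;
  }
  return h;
}

// Backprop one direction; dh_final is the gradient at the last hidden
// state. Returns dX (embed x T) and accumulates parameter grads.
static arma::mat back_dir(const arma::mat& X, const LstmParams& p,
                          const DirCache& cache, const arma::vec& dh_final,
                          LstmGrad& g) {
  const arma::uword T = X.n_cols, H = p.bf.n_elem, E = X.n_rows;
  arma::mat dX(E, T, arma::fill::zeros);
  arma::vec dh = dh_final, dc(H, arma::fill::zeros);
  for (arma::uword tt = T; tt-- > 0;) {
    arma::vec f = cache.F.col(tt), i = cache.I.col(tt), o = cache.O.col(tt);
    arma::vec ct = cache.Ct.col(tt), c = cache.C.col(tt);
    arma::vec c_prev = (tt > 0) ? arma::vec(cache.C.col(tt - 1))
                                : arma::vec(H, arma::fill::zeros);
    arma::vec h_prev = (tt > 0) ? arma::vec(cache.H.col(tt - 1))
                                : arma::vec(H, arma::fill::zeros);
    arma::vec tc = arma::tanh(c);
    arma::vec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    arma::vec df = dc % c_prev;
    arma::vec di = dc % ct;
    arma::vec dct = dc % i;
    arma::vec dc_prev = dc % f;
    arma::vec dzf = df % f % (1.0 - f);
    arma::vec dzi = di % i % (1.0 - i);
    arma::vec dzo = do_ % o % (1.0 - o);
    arma::vec dzc = dct % (1.0 - ct % ct);
    arma::vec z = arma::join_cols(X.col(tt), h_prev);
    g.Wf += dzf * z.t(); g.bf += dzf;
    g.Wi += dzi * z.t(); g.bi += dzi;
    g.Wo += dzo * z.t(); g.bo += dzo;
    g.Wc += dzc * z.t(); g.bc += dzc;
    arma::vec dz = p.Wf.t() * dzf + p.Wi.t() * dzi +
                   p.Wo.t() * dzo + p.Wc.t() * dzc;
    dX.col(tt) = dz.head(E);
    dh = dz.tail(H);
    dc = dc_prev;
  }
  return dX;
}

struct SeqWork {
  arma::uvec ids;           // real token ids, sequence order
  arma::mat Xf, Xr;         // embedded, forward and reversed order
  DirCache cf, cb;
  arma::vec u;              // concat(h_fwd, h_bwd)
  arma::vec pre, hid, feat; // MLP pre-activation, ReLU output, features
};

static void encode_seq(const Branch& br, const IntegerMatrix& ids, int n_real,
                       int col, SeqWork& w) {
  if (n_real < 1) stop("all-padding sequence cannot be encoded");
  const arma::uword T = (arma::uword)n_real;
  w.ids.set_size(T);
  for (arma::uword t = 0; t < T; ++t) {
    int id = ids(t, col);
    if (id < 0 || (arma::uword)id >= br.emb.n_rows)
      stop("token ID outside the embedding table");
    w.ids[t] = (arma::uword)id;
  }
  const arma::uword E = br.emb.n_cols;
  w.Xf.set_size(E, T);
  for (arma::uword t = 0; t < T; ++t) w.Xf.col(t) = br.emb.row(w.ids[t]).t();
  w.Xr = arma::fliplr(w.Xf);
  arma::vec hf = run_dir(w.Xf, br.fwd, w.cf);
  arma::vec hb = run_dir(w.Xr, br.bwd, w.cb);
  w.u = arma::join_cols(hf, hb);
  w.pre = br.mlp.Wh * w.u + br.mlp.bh;
  w.hid = arma::clamp(w.pre, 0.0, arma::datum::inf);
  w.feat = br.mlp.Wo * w.hid + br.mlp.bo;
}

// Backprop one drug through MLP + BiLSTM + embedding.
static void back_seq(const Branch& br, const SeqWork& w,
                     const arma::vec& dfeat, BranchGrad& g) {
  g.mWo += dfeat * w.hid.t();
  g.mbo += dfeat;
  arma::vec dhid = br.mlp.Wo.t() * dfeat;
  arma::vec dpre = dhid % arma::conv_to<arma::vec>::from(w.pre > 0);
  g.mWh += dpre * w.u.t();
  g.mbh += dpre;
  arma::vec du = br.mlp.Wh.t() * dpre;
  const arma::uword H = br.fwd.bf.n_elem;
  arma::mat dXf = back_dir(w.Xf, br.fwd, w.cf, du.head(H), g.fwd);
  arma::mat dXr = back_dir(w.Xr, br.bwd, w.cb, du.tail(H), g.bwd);
  dXf += arma::fliplr(dXr);
  for (arma::uword t = 0; t < w.Xf.n_cols; ++t)
    g.emb.row(w.ids[t]) += dXf.col(t).t();
}

static List lstm_grad_list(const LstmGrad& g) {
  return List::create(_["w_f"] = g.Wf, _["w_i"] = g.Wi, _["w_o"] = g.Wo,
                      _["w_c"] = g.Wc, _["b_f"] = g.bf, _["b_i"] = g.bi,
                      _["b_o"] = g.bo, _["b_c"] = g.bc);
}

static List branch_grad_list(const BranchGrad& g) {
  return List::create(
      _["emb"] = g.emb,
      _["fwd"] = lstm_grad_list(g.fwd),
      _["bwd"] = lstm_grad_list(g.bwd),
      _["mlp"] = List::create(_["W_h"] = g.mWh, _["b_h"] = g.mbh,
                              _["W_o"] = g.mWo, _["b_o"] = g.mbo));
}

// [[Rcpp::export]]
List cpp_net_batch(IntegerMatrix idsA, IntegerVector nA,
                   IntegerMatrix idsB, IntegerVector nB,
                   List branchA, List branchB,
                   NumericVector predW, double predB,
                   bool shared, NumericVector labels, bool wantGrad) {
  const int n = idsA.ncol();
  if (idsB.ncol() != n || nA.size() != n || nB.size() != n)
    stop("batch size mismatch between the two drug columns");
  const bool haveLabels = labels.size() > 0;
  if (haveLabels && labels.size() != n)
    stop("labels length must match the batch size");
  if (wantGrad && !haveLabels)
    stop("gradients require labels");

  Branch bA = read_branch(branchA);
  Branch bB = shared ? bA : read_branch(branchB);
  arma::vec w = as<arma::vec>(predW);
  const arma::uword K = bA.mlp.bo.n_elem;
  if (w.n_elem != 2 * K) stop("predictor weight must have length 2*mlp_out");

  BranchGrad gA, gB;
  arma::vec gw(2 * K, arma::fill::zeros);
  double gb = 0.0;
  if (wantGrad) {
    gA.init(bA);
    if (!shared) gB.init(bB);
  }

  NumericVector probs(n);
  double loss = 0.0;
  SeqWork wa, wb;
  for (int j = 0; j < n; ++j) {
    encode_seq(bA, idsA, nA[j], j, wa);
    encode_seq(bB, idsB, nB[j], j, wb);
    arma::vec v = arma::join_cols(wa.feat, wb.feat);
    double s = arma::dot(w, v) + predB;
    double p = 1.0 / (1.0 + std::exp(-s));
    probs[j] = p;
    if (haveLabels) {
      double t = labels[j];
      if (t != 0.0 && t != 1.0) stop("labels must be 0 or 1");
      double pc = std::min(std::max(p, CLAMP_EPS), 1.0 - CLAMP_EPS);
      loss += -(t * std::log(pc) + (1.0 - t) * std::log(1.0 - pc)) / n;
      if (wantGrad) {
        double ds = (p - t) / n;  // d(BCE o sigmoid)/ds
        gw += v * ds;
        gb += ds;
        arma::vec dv = w * ds;
        back_seq(bA, wa, dv.head(K), gA);
        back_seq(bB, wb, dv.tail(K), shared ? gA : gB);
      }
    }
  }

  List out = List::create(_["probs"] = probs,
                          _["loss"] = haveLabels ? wrap(loss) : R_NilValue);
  if (wantGrad) {
    List grads = List::create(
        _["branch_a"] = branch_grad_list(gA),
        _["predictor"] = List::create(
            _["w"] = NumericVector(gw.begin(), gw.end()), _["b"] = gb));
    if (!shared) grads["branch_b"] = branch_grad_list(gB);
    out["grads"] = grads;
  }
  return out;
}
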