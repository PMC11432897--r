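// Bi-LSTM engine shared by the sequence tagger and the DNN classifiers.
//
// Everything is dense double-precision Armadillo; training is plain
// backpropagation-through-time with Adam. All randomness (parameter
// initialisation, epoch shuffling) happens on the R side, so a call with the
// same inputs is bitwise deterministic.
//
// Parameter list layout (all arma::mat; empty 0x0 matrices mean "unused"):
//   Wword : V x d   word-embedding table (row 0 is reserved for UNK)
//   Wtag  : C x d   tag-embedding table
//   Wxf, Whf, bf : forward LSTM  (4H x Din, 4H x H, 4H x 1)
//   Wxb, Whb, bb : backward LSTM
//   Wout, bout   : output layer (K x 2H, K x 1); K = C for the tagger,
//                  K = 1 for classifiers
// Gate row blocks within the 4H dimension: [i | f | g | o].

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Net {
  arma::mat Wword, Wtag;
  arma::mat Wxf, Whf, bf;
  arma::mat Wxb, Whb, bb;
  arma::mat Wout, bout;

  std::vector<arma::mat*> all() {
    return {&Wword, &Wtag, &Wxf, &Whf, &bf, &Wxb, &Whb, &bb, &Wout, &bout};
  }
};

Net net_from_list(const List& p) {
  Net n;
  n.Wword = as<arma::mat>(p["Wword"]);
  n.Wtag  = as<arma::mat>(p["Wtag"]);
  n.Wxf = as<arma::mat>(p["Wxf"]); n.Whf = as<arma::mat>(p["Whf"]);
  n.bf  = as<arma::mat>(p["bf"]);
  n.Wxb = as<arma::mat>(p["Wxb"]); n.Whb = as<arma::mat>(p["Whb"]);
  n.bb  = as<arma::mat>(p["bb"]);
  n.Wout = as<arma::mat>(p["Wout"]); n.bout = as<arma::mat>(p["bout"]);
  return n;
}

List net_to_list(const Net& n) {
  return List::create(
      _["Wword"] = n.Wword, _["Wtag"] = n.Wtag,
      _["Wxf"] = n.Wxf, _["Whf"] = n.Whf, _["bf"] = n.bf,
      _["Wxb"] = n.Wxb, _["Whb"] = n.Whb, _["bb"] = n.bb,
      _["Wout"] = n.Wout, _["bout"] = n.bout);
}

Net net_zeros_like(Net& n) {
  Net g;
  std::vector<arma::mat*> src = n.all();
  std::vector<arma::mat*> dst = g.all();
  for (size_t k = 0; k < src.size(); ++k)
    *dst[k] = arma::zeros<arma::mat>(src[k]->n_rows, src[k]->n_cols);
  return g;
}

inline arma::mat sigm(const arma::mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// numerically stable log(1 + exp(z))
inline double softplus(double z) {
  return z > 0 ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
}

// Input construction ---------------------------------------------------------
// mode: 0 = tagger (text input), 1 = clf tag, 2 = clf text, 3 = clf concat
arma::mat build_input(const arma::uvec& words, const arma::mat& tags,
                      const Net& n, int mode) {
  if (mode == 1) return tags * n.Wtag;
  arma::mat Xw(words.n_elem, n.Wword.n_cols);
  for (arma::uword t = 0; t < words.n_elem; ++t)
    Xw.row(t) = n.Wword.row(words(t));
  if (mode == 0 || mode == 2) return Xw;
  return arma::join_rows(tags * n.Wtag, Xw);  // mode 3: [tag | word]
}

// LSTM forward over rows 0..T-1 of X ----------------------------------------
struct LSTMCache {
  arma::mat I, F, G, O, C, Th, Hs;  // each T x H
};

arma::mat lstm_forward(const arma::mat& X, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::mat& b,
                       LSTMCache& cc) {
  const arma::uword T = X.n_rows, H = Wh.n_cols;
  cc.I.set_size(T, H); cc.F.set_size(T, H); cc.G.set_size(T, H);
  cc.O.set_size(T, H); cc.C.set_size(T, H); cc.Th.set_size(T, H);
  cc.Hs.set_size(T, H);
  arma::vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec a = Wx * X.row(t).t() + Wh * h + b.col(0);
    arma::vec i = 1.0 / (1.0 + arma::exp(-a.subvec(0, H - 1)));
    arma::vec f = 1.0 / (1.0 + arma::exp(-a.subvec(H, 2 * H - 1)));
    arma::vec g = arma::tanh(a.subvec(2 * H, 3 * H - 1));
    arma::vec o = 1.0 / (1.0 + arma::exp(-a.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    arma::vec th = arma::tanh(c);
    h = o % th;
    cc.I.row(t) = i.t(); cc.F.row(t) = f.t(); cc.G.row(t) = g.t();
    cc.O.row(t) = o.t(); cc.C.row(t) = c.t(); cc.Th.row(t) = th.t();
    cc.Hs.row(t) = h.t();
  }
  return cc.Hs;
}

// BPTT matching lstm_forward; accumulates into gWx/gWh/gb, returns dX.
arma::mat lstm_backward(const arma::mat& X, const LSTMCache& cc,
                        const arma::mat& Wx, const arma::mat& Wh,
                        const arma::mat& dH, arma::mat& gWx, arma::mat& gWh,
                        arma::mat& gb) {
  const int T = X.n_rows;
  const arma::uword H = Wh.n_cols;
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  arma::vec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  arma::vec da(4 * H);
  for (int t = T - 1; t >= 0; --t) {
    arma::vec dh = dH.row(t).t() + dh_next;
    arma::vec i = cc.I.row(t).t(), f = cc.F.row(t).t(), g = cc.G.row(t).t(),
              o = cc.O.row(t).t(), th = cc.Th.row(t).t();
    arma::vec dc = dh % o % (1.0 - th % th) + dc_next;
    arma::vec c_prev = t > 0 ? arma::vec(cc.C.row(t - 1).t())
                             : arma::vec(H, arma::fill::zeros);
    arma::vec h_prev = t > 0 ? arma::vec(cc.Hs.row(t - 1).t())
                             : arma::vec(H, arma::fill::zeros);
    da.subvec(0, H - 1)         = (dc % g) % i % (1.0 - i);
    da.subvec(H, 2 * H - 1)     = (dc % c_prev) % f % (1.0 - f);
    da.subvec(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    da.subvec(3 * H, 4 * H - 1) = (dh % th) % o % (1.0 - o);
    gWx += da * X.row(t);
    gWh += da * h_prev.t();
    gb.col(0) += da;
    dX.row(t) = (Wx.t() * da).t();
    dh_next = Wh.t() * da;
    dc_next = dc % f;
  }
  return dX;
}

// Full forward pass; returns concatenated hidden states T x 2H.
arma::mat bilstm_states(const arma::mat& X, const Net& n, LSTMCache& cf,
                        LSTMCache& cb) {
  arma::mat Hf = lstm_forward(X, n.Wxf, n.Whf, n.bf, cf);
  arma::mat Hb_rev = lstm_forward(arma::flipud(X), n.Wxb, n.Whb, n.bb, cb);
  return arma::join_rows(Hf, arma::flipud(Hb_rev));
}

// Backward through both directions given dHc (T x 2H); returns dX.
arma::mat bilstm_backward(const arma::mat& X, const Net& n,
                          const LSTMCache& cf, const LSTMCache& cb,
                          const arma::mat& dHc, Net& g) {
  const arma::uword H = n.Whf.n_cols;
  arma::mat dHf = dHc.cols(0, H - 1);
  arma::mat dHb = dHc.cols(H, 2 * H - 1);
  arma::mat dX = lstm_backward(X, cf, n.Wxf, n.Whf, dHf, g.Wxf, g.Whf, g.bf);
  arma::mat Xr = arma::flipud(X);
  arma::mat dXr =
      lstm_backward(Xr, cb, n.Wxb, n.Whb, arma::flipud(dHb), g.Wxb, g.Whb, g.bb);
  return dX + arma::flipud(dXr);
}

// Route input gradient back to the embedding tables.
void input_grad(const arma::uvec& words, const arma::mat& tags, const Net& n,
                int mode, const arma::mat& dX, Net& g) {
  const arma::uword d = n.Wtag.n_cols ? n.Wtag.n_cols : n.Wword.n_cols;
  if (mode == 1) {
    g.Wtag += tags.t() * dX;
  } else if (mode == 0 || mode == 2) {
    for (arma::uword t = 0; t < words.n_elem; ++t)
      g.Wword.row(words(t)) += dX.row(t);
  } else {
    g.Wtag += tags.t() * dX.cols(0, d - 1);
    for (arma::uword t = 0; t < words.n_elem; ++t)
      g.Wword.row(words(t)) += dX.row(t).subvec(d, 2 * d - 1);
  }
}

struct DocData {
  arma::uvec words;
  arma::mat tags;
  arma::mat target;  // T x C for tagger
  double y;          // classifier label
};

DocData doc_from_list(const List& d, bool tagger) {
  DocData out;
  out.words = as<arma::uvec>(d["words"]);
  out.tags = as<arma::mat>(d["tags"]);
  if (tagger) {
    out.target = as<arma::mat>(d["target"]);
    out.y = 0.0;
  } else {
    out.y = as<double>(d["y"]);
  }
  return out;
}

// Per-document loss + gradient accumulation. Returns the loss.
double doc_loss_grad(const DocData& doc, const Net& n, int mode, Net& g) {
  arma::mat X = build_input(doc.words, doc.tags, n, mode);
  LSTMCache cf, cb;
  arma::mat Hc = bilstm_states(X, n, cf, cb);
  const arma::uword T = X.n_rows, H = n.Whf.n_cols;
  double loss = 0.0;
  arma::mat dHc(T, 2 * H, arma::fill::zeros);
  if (mode == 0) {
    // tagger: per-token independent sigmoids, loss averaged over tokens
    arma::mat Z = Hc * n.Wout.t();
    Z.each_row() += n.bout.col(0).t();
    for (arma::uword t = 0; t < T; ++t)
      for (arma::uword c = 0; c < Z.n_cols; ++c)
        loss += softplus(Z(t, c)) - doc.target(t, c) * Z(t, c);
    loss /= T;
    arma::mat dZ = (sigm(Z) - doc.target) / double(T);
    g.Wout += dZ.t() * Hc;
    g.bout.col(0) += arma::sum(dZ, 0).t();
    dHc = dZ * n.Wout;
  } else {
    // classifier: forward last state + backward first state -> single logit
    arma::rowvec s = arma::join_rows(Hc.row(T - 1).cols(0, H - 1),
                                     Hc.row(0).cols(H, 2 * H - 1));
    double z = arma::dot(n.Wout.row(0), s) + n.bout(0, 0);
    loss = softplus(z) - doc.y * z;
    double dz = 1.0 / (1.0 + std::exp(-z)) - doc.y;
    g.Wout.row(0) += dz * s;
    g.bout(0, 0) += dz;
    dHc.row(T - 1).cols(0, H - 1) += dz * n.Wout.row(0).cols(0, H - 1);
    dHc.row(0).cols(H, 2 * H - 1) += dz * n.Wout.row(0).cols(H, 2 * H - 1);
  }
  arma::mat dX = bilstm_backward(X, n, cf, cb, dHc, g);
  input_grad(doc.words, doc.tags, n, mode, dX, g);
  return loss;
}

int mode_code(const std::string& mode) {
  if (mode == "tagger") return 0;
  if (mode == "clf_tag") return 1;
  if (mode == "clf_text") return 2;
  if (mode == "clf_concat") return 3;
  stop("unknown mode: " + mode);
}

}  // namespace

// [[Rcpp::export]]
List cpp_bilstm_train(List docs, List params, List hyper, IntegerMatrix orders,
                      std::string mode) {
  const int m = mode_code(mode);
  const bool tagger = (m == 0);
  Net n = net_from_list(params);
  const int N = docs.size();
  const int epochs = as<int>(hyper["epochs"]);
  const int batch = as<int>(hyper["batch_size"]);
  const double lr = as<double>(hyper["learning_rate"]);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8, clip = 5.0;
  if (orders.nrow() != epochs || orders.ncol() != N)
    stop("orders must be epochs x N");

  std::vector<DocData> data;
  data.reserve(N);
  for (int i = 0; i < N; ++i)
    data.push_back(doc_from_list(docs[i], tagger));

  Net mom = net_zeros_like(n), vel = net_zeros_like(n);
  std::vector<arma::mat*> P = n.all(), M = mom.all(), V = vel.all();
  long step = 0;
  NumericVector loss_hist(epochs);

  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    int pos = 0;
    while (pos < N) {
      int bs = std::min(batch, N - pos);
      Net g = net_zeros_like(n);
      for (int k = 0; k < bs; ++k) {
        int idx = orders(e, pos + k);
        epoch_loss += doc_loss_grad(data[idx], n, m, g);
      }
      std::vector<arma::mat*> G = g.all();
      double sq = 0.0;
      for (auto* gm : G)
        if (gm->n_elem) { *gm /= bs; sq += arma::accu(arma::square(*gm)); }
      double norm = std::sqrt(sq);
      if (norm > clip)
        for (auto* gm : G)
          if (gm->n_elem) *gm *= clip / norm;
      ++step;
      const double bc1 = 1.0 - std::pow(b1, (double)step);
      const double bc2 = 1.0 - std::pow(b2, (double)step);
      for (size_t k = 0; k < P.size(); ++k) {
        if (!P[k]->n_elem) continue;
        *M[k] = b1 * (*M[k]) + (1.0 - b1) * (*G[k]);
        *V[k] = b2 * (*V[k]) + (1.0 - b2) * arma::square(*G[k]);
        *P[k] -= lr * ((*M[k]) / bc1) / (arma::sqrt((*V[k]) / bc2) + eps);
      }
      pos += bs;
    }
    loss_hist[e] = epoch_loss / N;
  }
  return List::create(_["params"] = net_to_list(n), _["loss"] = loss_hist);
}

// [[Rcpp::export]]
NumericMatrix cpp_tagger_predict(IntegerVector words, List params) {
  Net n = net_from_list(params);
  arma::uvec w = as<arma::uvec>(words);
  arma::mat tags;  // unused
  arma::mat X = build_input(w, tags, n, 0);
  LSTMCache cf, cb;
  arma::mat Hc = bilstm_states(X, n, cf, cb);
  arma::mat Z = Hc * n.Wout.t();
  Z.each_row() += n.bout.col(0).t();
  return wrap(sigm(Z));
}

// [[Rcpp::export]]
double cpp_clf_predict(List doc, List params, std::string mode) {
  const int m = mode_code(mode);
  if (m == 0) stop("use cpp_tagger_predict for the tagger");
  Net n = net_from_list(params);
  arma::uvec w = as<arma::uvec>(doc["words"]);
  arma::mat tags = as<arma::mat>(doc["tags"]);
  arma::mat X = build_input(w, tags, n, m);
  LSTMCache cf, cb;
  arma::mat Hc = bilstm_states(X, n, cf, cb);
  const arma::uword T = X.n_rows, H = n.Whf.n_cols;
  arma::rowvec s = arma::join_rows(Hc.row(T - 1).cols(0, H - 1),
                                   Hc.row(0).cols(H, 2 * H - 1));
  double z = arma::dot(n.Wout.row(0), s) + n.bout(0, 0);
  return 1.0 / (1.0 + std::exp(-z));
}
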