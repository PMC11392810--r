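// Convolutional/recurrent genus classifier: four parallel 1-D convolution
// branches over one-hot DNA, two bidirectional LSTM layers, two dense ReLU
// layers and a softmax head, with masking of right-padded positions.
// Forward, backpropagation-through-time and prediction are implemented here;
// the Adam update loop lives in R.
//
// Sequence batches are passed as integer matrices (n x T) with values
// 1..5 = A,C,G,T,N and 0 = padding; all (n*T x .) matrices are time-major:
// row t*n + i holds read i at position t.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static const int NBASE = 5;

// one-hot encode to a time-major (n*T x 5) matrix
static mat one_hot(const IntegerMatrix& seqs, int n, int T) {
  mat X(static_cast<uword>(n) * T, NBASE, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) {
      int b = seqs(i, t);
      if (b > 0) X(static_cast<uword>(t) * n + i, b - 1) = 1.0;
    }
  return X;
}

// im2col with same padding for kernel size k: column block o (offset
// o - h) is X shifted by (o - h) time steps
static mat im2col(const mat& X, int n, int T, int k) {
  int h = (k - 1) / 2;
  mat Xi(X.n_rows, static_cast<uword>(NBASE) * k, arma::fill::zeros);
  for (int o = 0; o < k; ++o) {
    int shift = o - h;
    for (int t = 0; t < T; ++t) {
      int ts = t + shift;
      if (ts < 0 || ts >= T) continue;
      Xi.submat(static_cast<uword>(t) * n, static_cast<uword>(o) * NBASE,
                static_cast<uword>(t) * n + n - 1,
                static_cast<uword>(o) * NBASE + NBASE - 1) =
          X.rows(static_cast<uword>(ts) * n, static_cast<uword>(ts) * n + n - 1);
    }
  }
  return Xi;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// dropout mask with inverted scaling, using R's RNG
static mat dropout_mask(uword nr, uword nc, double p) {
  mat m(nr, nc);
  double keep = 1.0 - p;
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i)
      m(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

struct LstmCache {
  mat G;   // activated gates [i f g o], (n*T x 4H), zero at masked steps
  mat C;   // cell states (n*T x H)
  mat H;   // hidden states (n*T x H)
};

// one LSTM direction; `fwd` = true processes t ascending. Valid positions
// are t < len_i (right padding); masked steps carry state through.
static void lstm_forward(const mat& Z, const mat& Wx, const mat& Wh,
                         const arma::rowvec& b, const IntegerVector& lens,
                         int n, int T, bool fwd, LstmCache& cache) {
  uword H = Wh.n_rows;
  mat G0 = Z * Wx;
  G0.each_row() += b;
  cache.G.zeros(G0.n_rows, 4 * H);
  cache.C.zeros(G0.n_rows, H);
  cache.H.zeros(G0.n_rows, H);
  mat h(n, H, arma::fill::zeros), c(n, H, arma::fill::zeros);
  for (int step = 0; step < T; ++step) {
    int t = fwd ? step : (T - 1 - step);
    uword r0 = static_cast<uword>(t) * n, r1 = r0 + n - 1;
    mat G = G0.rows(r0, r1) + h * Wh;
    mat gi = sigm(G.cols(0, H - 1));
    mat gf = sigm(G.cols(H, 2 * H - 1));
    mat gg = arma::tanh(G.cols(2 * H, 3 * H - 1));
    mat go = sigm(G.cols(3 * H, 4 * H - 1));
    mat cn = gf % c + gi % gg;
    mat hn = go % arma::tanh(cn);
    for (int i = 0; i < n; ++i) {
      if (t < lens[i]) {
        c.row(i) = cn.row(i);
        h.row(i) = hn.row(i);
        cache.G(r0 + i, arma::span(0, H - 1)) = gi.row(i);
        cache.G(r0 + i, arma::span(H, 2 * H - 1)) = gf.row(i);
        cache.G(r0 + i, arma::span(2 * H, 3 * H - 1)) = gg.row(i);
        cache.G(r0 + i, arma::span(3 * H, 4 * H - 1)) = go.row(i);
      }
      cache.C.row(r0 + i) = c.row(i);
      cache.H.row(r0 + i) = h.row(i);
    }
  }
}

// BPTT for one direction. dHseq may be empty; dh_init is the gradient on the
// final carried state. Returns dZ and accumulates weight grads.
static mat lstm_backward(const mat& Z, const mat& Wx, const mat& Wh,
                         const IntegerVector& lens, int n, int T, bool fwd,
                         const LstmCache& cache, const mat& dHseq,
                         const mat& dh_init, mat& dWx, mat& dWh,
                         arma::rowvec& db) {
  uword H = Wh.n_rows;
  mat DG(Z.n_rows, 4 * H, arma::fill::zeros);
  mat dh = dh_init.is_empty() ? mat(n, H, arma::fill::zeros) : dh_init;
  mat dc(n, H, arma::fill::zeros);
  dWh.zeros(H, 4 * H);
  for (int step = T - 1; step >= 0; --step) {
    int t = fwd ? step : (T - 1 - step);
    uword r0 = static_cast<uword>(t) * n, r1 = r0 + n - 1;
    if (!dHseq.is_empty()) dh += dHseq.rows(r0, r1);
    mat gi = cache.G.submat(r0, 0, r1, H - 1);
    mat gf = cache.G.submat(r0, H, r1, 2 * H - 1);
    mat gg = cache.G.submat(r0, 2 * H, r1, 3 * H - 1);
    mat go = cache.G.submat(r0, 3 * H, r1, 4 * H - 1);
    mat ct = cache.C.rows(r0, r1);
    // previous state in this direction's processing order
    int tp = fwd ? t - 1 : t + 1;
    mat cprev(n, H, arma::fill::zeros), hprev(n, H, arma::fill::zeros);
    if (tp >= 0 && tp < T) {
      uword p0 = static_cast<uword>(tp) * n;
      cprev = cache.C.rows(p0, p0 + n - 1);
      hprev = cache.H.rows(p0, p0 + n - 1);
    }
    mat tc = arma::tanh(ct);
    mat dct = dc + dh % go % (1.0 - tc % tc);
    mat dgi = dct % gg % gi % (1.0 - gi);
    mat dgf = dct % cprev % gf % (1.0 - gf);
    mat dgg = dct % gi % (1.0 - gg % gg);
    mat dgo = dh % tc % go % (1.0 - go);
    // rows with t >= len carry state through: zero gate grads there
    for (int i = 0; i < n; ++i) {
      if (t >= lens[i]) {
        dgi.row(i).zeros(); dgf.row(i).zeros();
        dgg.row(i).zeros(); dgo.row(i).zeros();
      }
    }
    mat dG(n, 4 * H);
    dG.cols(0, H - 1) = dgi;
    dG.cols(H, 2 * H - 1) = dgf;
    dG.cols(2 * H, 3 * H - 1) = dgg;
    dG.cols(3 * H, 4 * H - 1) = dgo;
    DG.rows(r0, r1) = dG;
    dWh += hprev.t() * dG;
    mat dh_prev = dG * Wh.t();
    mat dc_prev = dct % gf;
    for (int i = 0; i < n; ++i) {
      if (t >= lens[i]) {            // pass-through at masked steps
        dh_prev.row(i) += dh.row(i);
        dc_prev.row(i) = dc.row(i);
      }
    }
    dh = dh_prev;
    dc = dc_prev;
  }
  dWx = Z.t() * DG;
  db = arma::sum(DG, 0);
  return DG * Wx.t();
}

struct Net {
  std::vector<int> kernels;
  std::vector<mat> conv_w;
  std::vector<arma::rowvec> conv_b;
  mat l1f_Wx, l1f_Wh, l1b_Wx, l1b_Wh;
  mat l2f_Wx, l2f_Wh, l2b_Wx, l2b_Wh;
  arma::rowvec l1f_b, l1b_b, l2f_b, l2b_b;
  mat d1_W, d2_W, out_W;
  arma::rowvec d1_b, d2_b, out_b;
};

static mat getmat(const List& w, const std::string& nm) {
  return as<mat>(w[nm]);
}
static arma::rowvec getrow(const List& w, const std::string& nm) {
  return as<arma::rowvec>(w[nm]);
}

static Net load_net(const List& w, const IntegerVector& kernels) {
  Net net;
  for (int i = 0; i < kernels.size(); ++i) {
    int k = kernels[i];
    net.kernels.push_back(k);
    net.conv_w.push_back(getmat(w, "conv_w_" + std::to_string(k)));
    net.conv_b.push_back(getrow(w, "conv_b_" + std::to_string(k)));
  }
  net.l1f_Wx = getmat(w, "lstm1_fwd_Wx"); net.l1f_Wh = getmat(w, "lstm1_fwd_Wh");
  net.l1f_b = getrow(w, "lstm1_fwd_b");
  net.l1b_Wx = getmat(w, "lstm1_bwd_Wx"); net.l1b_Wh = getmat(w, "lstm1_bwd_Wh");
  net.l1b_b = getrow(w, "lstm1_bwd_b");
  net.l2f_Wx = getmat(w, "lstm2_fwd_Wx"); net.l2f_Wh = getmat(w, "lstm2_fwd_Wh");
  net.l2f_b = getrow(w, "lstm2_fwd_b");
  net.l2b_Wx = getmat(w, "lstm2_bwd_Wx"); net.l2b_Wh = getmat(w, "lstm2_bwd_Wh");
  net.l2b_b = getrow(w, "lstm2_bwd_b");
  net.d1_W = getmat(w, "dense1_W"); net.d1_b = getrow(w, "dense1_b");
  net.d2_W = getmat(w, "dense2_W"); net.d2_b = getrow(w, "dense2_b");
  net.out_W = getmat(w, "out_W"); net.out_b = getrow(w, "out_b");
  return net;
}

struct ForwardState {
  std::vector<mat> Xi;           // im2col per kernel
  mat A0;                        // post-ReLU, masked, (dropped) conv concat
  mat drop1;                     // dropout mask on A0 (empty in inference)
  LstmCache c1f, c1b, c2f, c2b;
  mat Z2;                        // layer-2 input (n*T x 2H)
  mat U;                         // final-state concat (n x 2H), post-dropout
  mat drop2, drop3;
  mat A1, A2;                    // dense activations post-ReLU
  mat P;                         // softmax probabilities
};

static void net_forward(const Net& net, const IntegerMatrix& seqs,
                        const IntegerVector& lens, int n, int T,
                        const NumericVector& drop, bool training,
                        ForwardState& st) {
  mat X = one_hot(seqs, n, T);
  uword F = net.conv_w[0].n_cols;
  uword C = F * net.kernels.size();
  st.A0.set_size(static_cast<uword>(n) * T, C);
  st.Xi.clear();
  for (size_t b = 0; b < net.kernels.size(); ++b) {
    mat Xi = im2col(X, n, T, net.kernels[b]);
    mat Y = Xi * net.conv_w[b];
    Y.each_row() += net.conv_b[b];
    Y.transform([](double v) { return v > 0 ? v : 0.0; });
    st.A0.cols(b * F, (b + 1) * F - 1) = Y;
    st.Xi.push_back(std::move(Xi));
  }
  // zero padded positions
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i)
      if (t >= lens[i]) st.A0.row(static_cast<uword>(t) * n + i).zeros();
  if (training && drop[0] > 0) {
    st.drop1 = dropout_mask(st.A0.n_rows, st.A0.n_cols, drop[0]);
    st.A0 %= st.drop1;
  }
  uword H = net.l1f_Wh.n_rows;
  lstm_forward(st.A0, net.l1f_Wx, net.l1f_Wh, net.l1f_b, lens, n, T, true, st.c1f);
  lstm_forward(st.A0, net.l1b_Wx, net.l1b_Wh, net.l1b_b, lens, n, T, false, st.c1b);
  st.Z2.set_size(st.A0.n_rows, 2 * H);
  st.Z2.cols(0, H - 1) = st.c1f.H;
  st.Z2.cols(H, 2 * H - 1) = st.c1b.H;
  lstm_forward(st.Z2, net.l2f_Wx, net.l2f_Wh, net.l2f_b, lens, n, T, true, st.c2f);
  lstm_forward(st.Z2, net.l2b_Wx, net.l2b_Wh, net.l2b_b, lens, n, T, false, st.c2b);
  st.U.set_size(n, 2 * H);
  st.U.cols(0, H - 1) = st.c2f.H.rows(static_cast<uword>(T - 1) * n,
                                      static_cast<uword>(T - 1) * n + n - 1);
  st.U.cols(H, 2 * H - 1) = st.c2b.H.rows(0, n - 1);
  if (training && drop[1] > 0) {
    st.drop2 = dropout_mask(st.U.n_rows, st.U.n_cols, drop[1]);
    st.U %= st.drop2;
  }
  st.A1 = st.U * net.d1_W;
  st.A1.each_row() += net.d1_b;
  st.A1.transform([](double v) { return v > 0 ? v : 0.0; });
  if (training && drop[2] > 0) {
    st.drop3 = dropout_mask(st.A1.n_rows, st.A1.n_cols, drop[2]);
    st.A1 %= st.drop3;
  }
  st.A2 = st.A1 * net.d2_W;
  st.A2.each_row() += net.d2_b;
  st.A2.transform([](double v) { return v > 0 ? v : 0.0; });
  mat logits = st.A2 * net.out_W;
  logits.each_row() += net.out_b;
  logits.each_col() -= arma::max(logits, 1);
  st.P = arma::exp(logits);
  st.P.each_col() /= arma::sum(st.P, 1);
}

// [[Rcpp::export(name = ".dt_forward")]]
NumericMatrix dt_forward(List weights, IntegerVector kernels,
                         IntegerMatrix seqs, IntegerVector lengths) {
  Net net = load_net(weights, kernels);
  int n = seqs.nrow(), T = seqs.ncol();
  ForwardState st;
  NumericVector drop = NumericVector::create(0.0, 0.0, 0.0);
  net_forward(net, seqs, lengths, n, T, drop, false, st);
  return wrap(st.P);
}

// [[Rcpp::export(name = ".dt_grad")]]
List dt_grad(List weights, IntegerVector kernels, IntegerMatrix seqs,
             IntegerVector lengths, IntegerVector labels,
             NumericVector dropout, bool training) {
  Net net = load_net(weights, kernels);
  int n = seqs.nrow(), T = seqs.ncol();
  ForwardState st;
  net_forward(net, seqs, lengths, n, T, dropout, training, st);
  int ncls = net.out_W.n_cols;
  // cross-entropy loss and output gradient
  double loss = 0.0;
  mat dlogits = st.P;
  int ncorrect = 0;
  for (int i = 0; i < n; ++i) {
    int y = labels[i] - 1;
    loss -= std::log(std::max(st.P(i, y), 1e-12));
    dlogits(i, y) -= 1.0;
    if ((int)arma::index_max(st.P.row(i)) == y) ++ncorrect;
  }
  loss /= n;
  dlogits /= n;
  List g;
  g["out_W"] = st.A2.t() * dlogits;
  g["out_b"] = arma::rowvec(arma::sum(dlogits, 0));
  mat dA2 = dlogits * net.out_W.t();
  dA2 %= arma::conv_to<mat>::from(st.A2 > 0);
  g["dense2_W"] = st.A1.t() * dA2;
  g["dense2_b"] = arma::rowvec(arma::sum(dA2, 0));
  mat dA1 = dA2 * net.d2_W.t();
  if (!st.drop3.is_empty()) dA1 %= st.drop3;
  dA1 %= arma::conv_to<mat>::from(st.A1 > 0);
  g["dense1_W"] = st.U.t() * dA1;
  g["dense1_b"] = arma::rowvec(arma::sum(dA1, 0));
  mat dU = dA1 * net.d1_W.t();
  if (!st.drop2.is_empty()) dU %= st.drop2;
  uword H = net.l1f_Wh.n_rows;
  mat empty;
  mat dWx, dWh; arma::rowvec db;
  mat dZ2 = lstm_backward(st.Z2, net.l2f_Wx, net.l2f_Wh, lengths, n, T, true,
                          st.c2f, empty, mat(dU.cols(0, H - 1)), dWx, dWh, db);
  g["lstm2_fwd_Wx"] = dWx; g["lstm2_fwd_Wh"] = dWh; g["lstm2_fwd_b"] = db;
  dZ2 += lstm_backward(st.Z2, net.l2b_Wx, net.l2b_Wh, lengths, n, T, false,
                       st.c2b, empty, mat(dU.cols(H, 2 * H - 1)), dWx, dWh, db);
  g["lstm2_bwd_Wx"] = dWx; g["lstm2_bwd_Wh"] = dWh; g["lstm2_bwd_b"] = db;
  mat dA0 = lstm_backward(st.A0, net.l1f_Wx, net.l1f_Wh, lengths, n, T, true,
                          st.c1f, mat(dZ2.cols(0, H - 1)), empty, dWx, dWh, db);
  g["lstm1_fwd_Wx"] = dWx; g["lstm1_fwd_Wh"] = dWh; g["lstm1_fwd_b"] = db;
  dA0 += lstm_backward(st.A0, net.l1b_Wx, net.l1b_Wh, lengths, n, T, false,
                       st.c1b, mat(dZ2.cols(H, 2 * H - 1)), empty, dWx, dWh, db);
  g["lstm1_bwd_Wx"] = dWx; g["lstm1_bwd_Wh"] = dWh; g["lstm1_bwd_b"] = db;
  if (!st.drop1.is_empty()) dA0 %= st.drop1;
  dA0 %= arma::conv_to<mat>::from(st.A0 > 0);
  uword F = net.conv_w[0].n_cols;
  for (size_t b = 0; b < net.kernels.size(); ++b) {
    mat dY = dA0.cols(b * F, (b + 1) * F - 1);
    g["conv_w_" + std::to_string(net.kernels[b])] = st.Xi[b].t() * dY;
    g["conv_b_" + std::to_string(net.kernels[b])] = arma::rowvec(arma::sum(dY, 0));
  }
  return List::create(_["loss"] = loss,
                      _["accuracy"] = (double)ncorrect / n,
                      _["grads"] = g);
}
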