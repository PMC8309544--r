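// Bidirectional LSTM binary classifier with Adam, trained by BPTT.
//
// Input layout: one example per row, T time-step blocks of D features
// (time-major). A forward and a backward LSTM (H cells each) read the
// sequence; their final hidden states are concatenated and mapped through
// a single dense sigmoid unit. Loss = mean binary cross-entropy +
// l1*|w|_1 + l2*|w|_2^2 over input/recurrent/dense weights (biases
// excluded). The positive class is re-up-sampled to 1:1 each epoch
// (whole cycles plus a remainder drawn without replacement); batches are
// reshuffled each epoch. All randomness flows from one std::mt19937, so
// results are bit-identical for a fixed seed on one platform.
//
// For speed the input projection Wx * x_t is evaluated for all T steps in
// one GEMM per batch (columns of Xall are grouped by step), and likewise
// the input-weight gradient dWx = dZ * Xall'.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat sigmoid_m(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct Dir {
  mat Wx, Wh;
  vec b;
  mat mWx, vWx, mWh, vWh;
  vec mb, vb;
};

struct Cache {
  cube I, F, G, O, C, H; // H x B x T, slices in processing order
  void resize(int H_, int B, int T) {
    I.set_size(H_, B, T); F.set_size(H_, B, T); G.set_size(H_, B, T);
    O.set_size(H_, B, T); C.set_size(H_, B, T); H.set_size(H_, B, T);
  }
};

// Xall: D x (B*T), column block t holds the batch at input step t
static mat input_proj(const Dir& d, const mat& Xall) {
  mat Zin = d.Wx * Xall;
  Zin.each_col() += d.b;
  return Zin;
}

// gate row order within the stacked 4H block: input, forget, cell, output
static void forward_dir(const Dir& d, const mat& Zin, int T, int B,
                        bool reverse, Cache& ca) {
  const int H = d.Wh.n_cols;
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? T - 1 - s : s;
    mat z = Zin.cols(t * B, t * B + B - 1) + d.Wh * h;
    mat gi = sigmoid_m(z.rows(0, H - 1));
    mat gf = sigmoid_m(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigmoid_m(z.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    ca.I.slice(s) = gi; ca.F.slice(s) = gf; ca.G.slice(s) = gg;
    ca.O.slice(s) = go; ca.C.slice(s) = c; ca.H.slice(s) = h;
  }
}

// final hidden state only (prediction path)
static mat forward_last(const mat& Wh, const mat& Zin, int T, int B,
                        bool reverse) {
  const int H = Wh.n_cols;
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? T - 1 - s : s;
    mat z = Zin.cols(t * B, t * B + B - 1) + Wh * h;
    mat gi = sigmoid_m(z.rows(0, H - 1));
    mat gf = sigmoid_m(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigmoid_m(z.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
  }
  return h;
}

static void backward_dir(const Dir& d, const mat& Xall, int T, int B,
                         bool reverse, const Cache& ca, const mat& dh_final,
                         mat& dWx, mat& dWh, vec& db) {
  const int H = d.Wh.n_cols;
  mat dh = dh_final, dc(H, B, fill::zeros);
  mat dZ(4 * H, B * T);
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? T - 1 - s : s;
    mat tc = tanh(ca.C.slice(s));
    const mat& gi = ca.I.slice(s);
    const mat& gf = ca.F.slice(s);
    const mat& gg = ca.G.slice(s);
    const mat& go = ca.O.slice(s);
    mat dct = dc + dh % go % (1.0 - tc % tc);
    mat dz(4 * H, B);
    dz.rows(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    dz.rows(0, H - 1) = (dct % gg) % gi % (1.0 - gi);
    if (s > 0)
      dz.rows(H, 2 * H - 1) = (dct % ca.C.slice(s - 1)) % gf % (1.0 - gf);
    else
      dz.rows(H, 2 * H - 1).zeros();
    dz.rows(2 * H, 3 * H - 1) = (dct % gi) % (1.0 - gg % gg);
    if (s > 0) dWh += dz * ca.H.slice(s - 1).t();
    dZ.cols(t * B, t * B + B - 1) = dz;
    dh = d.Wh.t() * dz;
    dc = dct % gf;
  }
  dWx += dZ * Xall.t();
  db += sum(dZ, 1);
}

template <typename W>
static void adam_step(W& w, W& m, W& v, const W& g, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / (1 - std::pow(b1, t))) / (sqrt(v / (1 - std::pow(b2, t))) + eps);
}

// gather rows of X into step-blocked layout: D x (B*T)
static void fill_batch(const mat& X, const std::vector<int>& order,
                       size_t b0, int B, int T, int D, mat& Xall) {
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < B; ++j) {
      int row = order[b0 + j];
      for (int dd = 0; dd < D; ++dd)
        Xall(dd, t * B + j) = X(row, t * D + dd);
    }
}

// [[Rcpp::export]]
List bilstm_train_cpp(const arma::mat& X, const arma::vec& y, int T, int D,
                      int H, double l1, double l2, double lr, int epochs,
                      int batch, bool bidirectional, bool upsample,
                      int seed) {
  const int N = X.n_rows;
  if ((int)X.n_cols != T * D) Rcpp::stop("input width does not match T * D");
  std::mt19937 rng(static_cast<unsigned int>(seed));
  auto uinit = [&](int rows, int cols) {
    double r = std::sqrt(6.0 / (rows + cols));
    std::uniform_real_distribution<double> U(-r, r);
    mat m(rows, cols);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i = 0; i < m.n_rows; ++i) m(i, j) = U(rng);
    return m;
  };
  auto make_dir = [&]() {
    Dir d;
    d.Wx = uinit(4 * H, D);
    d.Wh = uinit(4 * H, H);
    d.b = vec(4 * H, fill::zeros);
    d.b.subvec(H, 2 * H - 1).fill(1.0); // forget-gate bias
    d.mWx = zeros<mat>(4 * H, D); d.vWx = zeros<mat>(4 * H, D);
    d.mWh = zeros<mat>(4 * H, H); d.vWh = zeros<mat>(4 * H, H);
    d.mb = zeros<vec>(4 * H); d.vb = zeros<vec>(4 * H);
    return d;
  };
  Dir Fd = make_dir(), Bd;
  if (bidirectional) Bd = make_dir();
  const int outdim = bidirectional ? 2 * H : H;
  vec wout = vectorise(uinit(outdim, 1));
  double bout = 0.0;
  vec mw = zeros<vec>(outdim), vw = zeros<vec>(outdim);
  double mb0 = 0.0, vb0 = 0.0;

  std::vector<int> pos, neg;
  for (int i = 0; i < N; ++i) (y[i] == 1.0 ? pos : neg).push_back(i);
  if (upsample && pos.empty())
    Rcpp::stop("cannot balance: no positive examples");

  std::vector<double> losses(epochs);
  double adam_t = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::vector<int> order;
    if (upsample && pos.size() < neg.size()) {
      order = neg;
      size_t reps = neg.size() / pos.size();
      size_t rem = neg.size() - reps * pos.size();
      for (size_t r0 = 0; r0 < reps; ++r0)
        order.insert(order.end(), pos.begin(), pos.end());
      std::vector<int> pshuf = pos;
      std::shuffle(pshuf.begin(), pshuf.end(), rng);
      order.insert(order.end(), pshuf.begin(), pshuf.begin() + rem);
    } else {
      order.resize(N);
      std::iota(order.begin(), order.end(), 0);
    }
    std::shuffle(order.begin(), order.end(), rng);

    double ep_loss = 0.0;
    int ep_n = 0;
    for (size_t b0 = 0; b0 < order.size(); b0 += (size_t)batch) {
      const int B = (int)std::min((size_t)batch, order.size() - b0);
      mat Xall(D, B * T);
      vec yb(B);
      for (int j = 0; j < B; ++j) yb[j] = y[order[b0 + j]];
      fill_batch(X, order, b0, B, T, D, Xall);

      Cache cf, cb;
      cf.resize(H, B, T);
      forward_dir(Fd, input_proj(Fd, Xall), T, B, false, cf);
      if (bidirectional) {
        cb.resize(H, B, T);
        forward_dir(Bd, input_proj(Bd, Xall), T, B, true, cb);
      }

      mat hF = cf.H.slice(T - 1);
      rowvec u = wout.subvec(0, H - 1).t() * hF;
      if (bidirectional) u += wout.subvec(H, 2 * H - 1).t() * cb.H.slice(T - 1);
      u += bout;
      rowvec p = 1.0 / (1.0 + exp(-u));
      rowvec pc = clamp(p, 1e-12, 1.0 - 1e-12);
      double loss = -accu(yb.t() % log(pc) + (1.0 - yb.t()) % log(1.0 - pc)) / B;
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
      ep_loss += loss * B;
      ep_n += B;

      rowvec du = (p - yb.t()) / B;
      vec gw(outdim, fill::zeros);
      gw.subvec(0, H - 1) = hF * du.t();
      mat dhF = wout.subvec(0, H - 1) * du;
      mat dhB;
      if (bidirectional) {
        gw.subvec(H, 2 * H - 1) = cb.H.slice(T - 1) * du.t();
        dhB = wout.subvec(H, 2 * H - 1) * du;
      }
      double gb0 = accu(du);

      mat dWxF(4 * H, D, fill::zeros), dWhF(4 * H, H, fill::zeros);
      vec dbF(4 * H, fill::zeros);
      backward_dir(Fd, Xall, T, B, false, cf, dhF, dWxF, dWhF, dbF);
      mat dWxB, dWhB;
      vec dbB;
      if (bidirectional) {
        dWxB = zeros<mat>(4 * H, D); dWhB = zeros<mat>(4 * H, H);
        dbB = zeros<vec>(4 * H);
        backward_dir(Bd, Xall, T, B, true, cb, dhB, dWxB, dWhB, dbB);
      }

      // penalty gradients on weights (not biases)
      dWxF += l1 * sign(Fd.Wx) + 2.0 * l2 * Fd.Wx;
      dWhF += l1 * sign(Fd.Wh) + 2.0 * l2 * Fd.Wh;
      if (bidirectional) {
        dWxB += l1 * sign(Bd.Wx) + 2.0 * l2 * Bd.Wx;
        dWhB += l1 * sign(Bd.Wh) + 2.0 * l2 * Bd.Wh;
      }
      gw += l1 * sign(wout) + 2.0 * l2 * wout;

      adam_t += 1.0;
      adam_step(Fd.Wx, Fd.mWx, Fd.vWx, dWxF, lr, adam_t);
      adam_step(Fd.Wh, Fd.mWh, Fd.vWh, dWhF, lr, adam_t);
      adam_step(Fd.b, Fd.mb, Fd.vb, dbF, lr, adam_t);
      if (bidirectional) {
        adam_step(Bd.Wx, Bd.mWx, Bd.vWx, dWxB, lr, adam_t);
        adam_step(Bd.Wh, Bd.mWh, Bd.vWh, dWhB, lr, adam_t);
        adam_step(Bd.b, Bd.mb, Bd.vb, dbB, lr, adam_t);
      }
      adam_step(wout, mw, vw, gw, lr, adam_t);
      {
        const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
        mb0 = b1 * mb0 + (1 - b1) * gb0;
        vb0 = b2 * vb0 + (1 - b2) * gb0 * gb0;
        bout -= lr * (mb0 / (1 - std::pow(b1, adam_t))) /
                (std::sqrt(vb0 / (1 - std::pow(b2, adam_t))) + eps);
      }
    }
    losses[ep] = ep_loss / ep_n;
    if (ep % 10 == 9) Rcpp::checkUserInterrupt();
  }

  List w = List::create(
      Named("WxF") = Fd.Wx, Named("WhF") = Fd.Wh, Named("bF") = Fd.b,
      Named("wout") = wout, Named("bout") = bout);
  if (bidirectional) {
    w["WxB"] = Bd.Wx; w["WhB"] = Bd.Wh; w["bB"] = Bd.b;
  }
  return List::create(Named("weights") = w, Named("loss") = losses);
}

static vec as_vec_any(SEXP s) {
  Rcpp::NumericVector v(s);
  return vec(v.begin(), v.size());
}

static mat as_mat_any(SEXP s) {
  Rcpp::NumericMatrix m(s);
  return mat(m.begin(), m.nrow(), m.ncol());
}

// loss and analytic gradients at a given weight setting (no penalty);
// exists so tests can check the BPTT gradients against finite differences
// [[Rcpp::export]]
List bilstm_grad_cpp(List weights, const arma::mat& X, const arma::vec& y,
                     int T, int D, int H, bool bidirectional) {
  const int B = X.n_rows;
  Dir Fd, Bd;
  Fd.Wx = as_mat_any(weights["WxF"]);
  Fd.Wh = as_mat_any(weights["WhF"]);
  Fd.b = as_vec_any(weights["bF"]);
  vec wout = as_vec_any(weights["wout"]);
  double bout = Rcpp::as<double>(weights["bout"]);
  if (bidirectional) {
    Bd.Wx = as_mat_any(weights["WxB"]);
    Bd.Wh = as_mat_any(weights["WhB"]);
    Bd.b = as_vec_any(weights["bB"]);
  }
  mat Xall(D, B * T);
  std::vector<int> order(B);
  std::iota(order.begin(), order.end(), 0);
  fill_batch(X, order, 0, B, T, D, Xall);
  Cache cf, cb;
  cf.resize(H, B, T);
  forward_dir(Fd, input_proj(Fd, Xall), T, B, false, cf);
  if (bidirectional) {
    cb.resize(H, B, T);
    forward_dir(Bd, input_proj(Bd, Xall), T, B, true, cb);
  }
  mat hF = cf.H.slice(T - 1);
  rowvec u = wout.subvec(0, H - 1).t() * hF;
  if (bidirectional) u += wout.subvec(H, 2 * H - 1).t() * cb.H.slice(T - 1);
  u += bout;
  rowvec p = 1.0 / (1.0 + exp(-u));
  rowvec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  double loss = -accu(y.t() % log(pc) + (1.0 - y.t()) % log(1.0 - pc)) / B;
  rowvec du = (p - y.t()) / B;
  const int outdim = bidirectional ? 2 * H : H;
  vec gw(outdim, fill::zeros);
  gw.subvec(0, H - 1) = hF * du.t();
  mat dhF = wout.subvec(0, H - 1) * du;
  mat dWxF(4 * H, D, fill::zeros), dWhF(4 * H, H, fill::zeros);
  vec dbF(4 * H, fill::zeros);
  backward_dir(Fd, Xall, T, B, false, cf, dhF, dWxF, dWhF, dbF);
  List out = List::create(
      Named("loss") = loss, Named("dWxF") = dWxF, Named("dWhF") = dWhF,
      Named("dbF") = dbF, Named("dwout") = gw, Named("dbout") = accu(du));
  if (bidirectional) {
    gw.subvec(H, 2 * H - 1) = cb.H.slice(T - 1) * du.t();
    mat dhB = wout.subvec(H, 2 * H - 1) * du;
    mat dWxB(4 * H, D, fill::zeros), dWhB(4 * H, H, fill::zeros);
    vec dbB(4 * H, fill::zeros);
    backward_dir(Bd, Xall, T, B, true, cb, dhB, dWxB, dWhB, dbB);
    out["dWxB"] = dWxB; out["dWhB"] = dWhB; out["dbB"] = dbB;
    out["dwout"] = gw;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec bilstm_predict_cpp(List weights, const arma::mat& X, int T, int D,
                             int H, bool bidirectional) {
  const int N = X.n_rows;
  if ((int)X.n_cols != T * D) Rcpp::stop("input width does not match T * D");
  mat WxF = as_mat_any(weights["WxF"]);
  mat WhF = as_mat_any(weights["WhF"]);
  vec bF = as_vec_any(weights["bF"]);
  vec wout = as_vec_any(weights["wout"]);
  double bout = Rcpp::as<double>(weights["bout"]);
  mat WxB, WhB;
  vec bB;
  if (bidirectional) {
    WxB = as_mat_any(weights["WxB"]);
    WhB = as_mat_any(weights["WhB"]);
    bB = as_vec_any(weights["bB"]);
  }
  const int H2 = H;
  vec out(N);
  const int chunk = 1024;
  std::vector<int> order(N);
  std::iota(order.begin(), order.end(), 0);
  for (int b0 = 0; b0 < N; b0 += chunk) {
    const int B = std::min(chunk, N - b0);
    mat Xall(D, B * T);
    fill_batch(X, order, (size_t)b0, B, T, D, Xall);
    mat ZF = WxF * Xall;
    ZF.each_col() += bF;
    mat hF = forward_last(WhF, ZF, T, B, false);
    rowvec u = wout.subvec(0, H2 - 1).t() * hF;
    if (bidirectional) {
      mat ZB = WxB * Xall;
      ZB.each_col() += bB;
      mat hB = forward_last(WhB, ZB, T, B, true);
      u += wout.subvec(H2, 2 * H2 - 1).t() * hB;
    }
    u += bout;
    for (int j = 0; j < B; ++j) out[b0 + j] = 1.0 / (1.0 + std::exp(-u[j]));
  }
  return out;
}
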