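// Core numerics for the day-5 INR predictor: a dense branch over 5 static
// covariates, a stack of LSTM layers over the 4-step (INR, dose) series, and
// a dense head ending in one linear unit. Trained with mean absolute error
// and Adam. Parameters live in one flat vector; the layout contract is shared
// with R (see param_shapes() in R/network.R): static layers (W then b), LSTM
// layers (W_x, W_h, b with gate blocks ordered i|f|g|o), head layers (W, b),
// output (W, b). All matrices are stored column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Cfg {
  std::vector<int> sw;  // static branch widths
  int L, U, K, HU;      // lstm layers/units, head layers/units
  int n_static, T, C;   // static inputs, timesteps, series channels
};

static Cfg parse_cfg(const Rcpp::List& cfg) {
  Cfg c;
  Rcpp::IntegerVector sw = cfg["static_widths"];
  c.sw = std::vector<int>(sw.begin(), sw.end());
  c.L = Rcpp::as<int>(cfg["lstm_layers"]);
  c.U = Rcpp::as<int>(cfg["lstm_units"]);
  c.K = Rcpp::as<int>(cfg["head_layers"]);
  c.HU = Rcpp::as<int>(cfg["head_units"]);
  c.n_static = Rcpp::as<int>(cfg["n_static"]);
  c.T = Rcpp::as<int>(cfg["seq_len"]);
  c.C = Rcpp::as<int>(cfg["n_channels"]);
  return c;
}

struct Params {
  std::vector<mat> sW; std::vector<rowvec> sb;
  std::vector<mat> Wx, Wh; std::vector<rowvec> lb;
  std::vector<mat> hW; std::vector<rowvec> hb;
  mat oW; rowvec ob;
  size_t total;
};

// Unpack the flat vector into owned matrices (copies; sizes are small).
static Params unpack(const vec& p, const Cfg& c, bool zero = false) {
  Params v; size_t off = 0;
  auto take_mat = [&](int r, int cc) {
    mat m(r, cc);
    if (zero) m.zeros();
    else std::copy(p.memptr() + off, p.memptr() + off + (size_t)r * cc, m.memptr());
    off += (size_t)r * cc;
    return m;
  };
  auto take_row = [&](int n) {
    rowvec b(n);
    if (zero) b.zeros();
    else std::copy(p.memptr() + off, p.memptr() + off + n, b.memptr());
    off += n;
    return b;
  };
  int in = c.n_static;
  for (int w : c.sw) { v.sW.push_back(take_mat(in, w)); v.sb.push_back(take_row(w)); in = w; }
  int sin = c.C;
  for (int l = 0; l < c.L; ++l) {
    v.Wx.push_back(take_mat(sin, 4 * c.U));
    v.Wh.push_back(take_mat(c.U, 4 * c.U));
    v.lb.push_back(take_row(4 * c.U));
    sin = c.U;
  }
  int hin = (c.sw.empty() ? c.n_static : c.sw.back()) + c.U;
  for (int j = 0; j < c.K; ++j) { v.hW.push_back(take_mat(hin, c.HU)); v.hb.push_back(take_row(c.HU)); hin = c.HU; }
  v.oW = take_mat(hin, 1);
  v.ob = take_row(1);
  v.total = off;
  return v;
}

static vec pack(const Params& v, const Cfg& c) {
  vec p(v.total); size_t off = 0;
  auto put = [&](const mat& m) { std::copy(m.memptr(), m.memptr() + m.n_elem, p.memptr() + off); off += m.n_elem; };
  for (size_t j = 0; j < v.sW.size(); ++j) { put(v.sW[j]); put(v.sb[j]); }
  for (int l = 0; l < c.L; ++l) { put(v.Wx[l]); put(v.Wh[l]); put(v.lb[l]); }
  for (int j = 0; j < c.K; ++j) { put(v.hW[j]); put(v.hb[j]); }
  put(v.oW); put(v.ob);
  return p;
}

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cache {
  std::vector<mat> sA;                       // static activations, input first
  std::vector<std::vector<mat>> I, F, G, O, Th, Cc, H;  // [layer][t]
  std::vector<mat> X0;                       // raw series input per t
  std::vector<mat> hA;                       // head activations, input first
  vec yhat;
};

static void forward(const Params& v, const Cfg& c, const mat& Xs, const mat& Xq,
                    Cache& K) {
  const int n = Xs.n_rows;
  K.sA.clear(); K.hA.clear(); K.X0.clear();
  K.I.assign(c.L, {}); K.F.assign(c.L, {}); K.G.assign(c.L, {});
  K.O.assign(c.L, {}); K.Th.assign(c.L, {}); K.Cc.assign(c.L, {}); K.H.assign(c.L, {});

  mat A = Xs;
  K.sA.push_back(A);
  for (size_t j = 0; j < v.sW.size(); ++j) {
    A = A * v.sW[j];
    A.each_row() += v.sb[j];
    A.transform([](double x) { return x > 0 ? x : 0.0; });
    K.sA.push_back(A);
  }

  for (int t = 0; t < c.T; ++t) {
    mat xt(n, c.C);
    for (int ch = 0; ch < c.C; ++ch) xt.col(ch) = Xq.col((size_t)ch * c.T + t);
    K.X0.push_back(xt);
  }
  for (int l = 0; l < c.L; ++l) {
    mat h(n, c.U, fill::zeros), cc(n, c.U, fill::zeros);
    for (int t = 0; t < c.T; ++t) {
      const mat& xin = (l == 0) ? K.X0[t] : K.H[l - 1][t];
      mat Z = xin * v.Wx[l] + h * v.Wh[l];
      Z.each_row() += v.lb[l];
      mat Iv = sigmoid(Z.cols(0, c.U - 1));
      mat Fv = sigmoid(Z.cols(c.U, 2 * c.U - 1));
      mat Gv = tanh(Z.cols(2 * c.U, 3 * c.U - 1));
      mat Ov = sigmoid(Z.cols(3 * c.U, 4 * c.U - 1));
      cc = Fv % cc + Iv % Gv;
      mat th = tanh(cc);
      h = Ov % th;
      K.I[l].push_back(Iv); K.F[l].push_back(Fv); K.G[l].push_back(Gv);
      K.O[l].push_back(Ov); K.Th[l].push_back(th); K.Cc[l].push_back(cc);
      K.H[l].push_back(h);
    }
  }

  mat Uc = join_rows(K.sA.back(), K.H[c.L - 1][c.T - 1]);
  K.hA.push_back(Uc);
  mat B = Uc;
  for (int j = 0; j < c.K; ++j) {
    B = B * v.hW[j];
    B.each_row() += v.hb[j];
    B.transform([](double x) { return x > 0 ? x : 0.0; });
    K.hA.push_back(B);
  }
  K.yhat = vec(B * v.oW) + v.ob(0);
}

// Gradient of mean absolute error wrt all parameters; returns the loss.
static double backward(const Params& v, const Cfg& c, const Cache& K,
                       const vec& y, Params& g) {
  const int n = y.n_elem;
  vec r = K.yhat - y;
  double loss = mean(abs(r));
  vec dY = sign(r) / (double)n;

  g.oW += K.hA.back().t() * dY;
  g.ob(0) += accu(dY);
  mat dB = dY * v.oW.t();
  for (int j = c.K - 1; j >= 0; --j) {
    dB %= conv_to<mat>::from(K.hA[j + 1] > 0);
    g.hW[j] += K.hA[j].t() * dB;
    g.hb[j] += sum(dB, 0);
    dB = dB * v.hW[j].t();
  }
  const int sw = c.sw.empty() ? c.n_static : c.sw.back();
  mat dAS = dB.cols(0, sw - 1);
  mat dHtop = dB.cols(sw, sw + c.U - 1);

  std::vector<mat> dXup;  // gradient wrt this layer's inputs, per t
  for (int l = c.L - 1; l >= 0; --l) {
    mat dh_rec(n, c.U, fill::zeros), dc(n, c.U, fill::zeros);
    std::vector<mat> dXl(c.T);
    for (int t = c.T - 1; t >= 0; --t) {
      mat dh = dh_rec;
      if (l == c.L - 1 && t == c.T - 1) dh += dHtop;
      if (l < c.L - 1) dh += dXup[t];
      const mat& Iv = K.I[l][t]; const mat& Fv = K.F[l][t];
      const mat& Gv = K.G[l][t]; const mat& Ov = K.O[l][t];
      const mat& th = K.Th[l][t];
      mat dO = dh % th;
      dc += dh % Ov % (1.0 - square(th));
      mat Cprev = (t == 0) ? mat(n, c.U, fill::zeros) : K.Cc[l][t - 1];
      mat dF = dc % Cprev;
      mat dI = dc % Gv;
      mat dG = dc % Iv;
      mat dc_prev = dc % Fv;
      mat dZ(n, 4 * c.U);
      dZ.cols(0, c.U - 1) = dI % Iv % (1.0 - Iv);
      dZ.cols(c.U, 2 * c.U - 1) = dF % Fv % (1.0 - Fv);
      dZ.cols(2 * c.U, 3 * c.U - 1) = dG % (1.0 - square(Gv));
      dZ.cols(3 * c.U, 4 * c.U - 1) = dO % Ov % (1.0 - Ov);
      const mat& xin = (l == 0) ? K.X0[t] : K.H[l - 1][t];
      g.Wx[l] += xin.t() * dZ;
      mat Hprev = (t == 0) ? mat(n, c.U, fill::zeros) : K.H[l][t - 1];
      g.Wh[l] += Hprev.t() * dZ;
      g.lb[l] += sum(dZ, 0);
      dh_rec = dZ * v.Wh[l].t();
      dc = dc_prev;
      dXl[t] = dZ * v.Wx[l].t();
    }
    dXup = dXl;
  }

  mat dA = dAS;
  for (int j = (int)v.sW.size() - 1; j >= 0; --j) {
    dA %= conv_to<mat>::from(K.sA[j + 1] > 0);
    g.sW[j] += K.sA[j].t() * dA;
    g.sb[j] += sum(dA, 0);
    dA = dA * v.sW[j].t();
  }
  return loss;
}

// [[Rcpp::export]]
arma::vec nn_forward_cpp(const arma::vec& par, const arma::mat& Xs,
                         const arma::mat& Xq, const Rcpp::List& cfg) {
  Cfg c = parse_cfg(cfg);
  Params v = unpack(par, c);
  if (v.total != par.n_elem) Rcpp::stop("parameter vector length mismatch");
  Cache K;
  forward(v, c, Xs, Xq, K);
  return K.yhat;
}

// [[Rcpp::export]]
Rcpp::List nn_loss_grad_cpp(const arma::vec& par, const arma::mat& Xs,
                            const arma::mat& Xq, const arma::vec& y,
                            const Rcpp::List& cfg) {
  Cfg c = parse_cfg(cfg);
  Params v = unpack(par, c);
  if (v.total != par.n_elem) Rcpp::stop("parameter vector length mismatch");
  Cache K;
  forward(v, c, Xs, Xq, K);
  Params g = unpack(par, c, true);
  double loss = backward(v, c, K, y, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = pack(g, c));
}

// One epoch of minibatch Adam. `order` is a 0-based permutation of samples;
// batches are taken in that order. Returns updated parameter vector, Adam
// moments, step counter, and the mean over batch losses.
// [[Rcpp::export]]
Rcpp::List nn_train_epoch_cpp(const arma::vec& par, const arma::vec& m,
                              const arma::vec& vmom, const int step,
                              const arma::mat& Xs, const arma::mat& Xq,
                              const arma::vec& y,
                              const arma::uvec& order, const int batch_size,
                              const double lr, const double beta1,
                              const double beta2, const double eps,
                              const Rcpp::List& cfg) {
  Cfg c = parse_cfg(cfg);
  vec p = par, mm = m, vv = vmom;
  int t = step;
  const int n = y.n_elem;
  double loss_sum = 0.0; int n_batches = 0;
  Cache K;
  for (int s = 0; s < n; s += batch_size) {
    const int e = std::min(n, s + batch_size);
    uvec idx = order.subvec(s, e - 1);
    mat bXs = Xs.rows(idx), bXq = Xq.rows(idx);
    vec by = y.elem(idx);
    Params v = unpack(p, c);
    forward(v, c, bXs, bXq, K);
    Params g = unpack(p, c, true);
    double loss = backward(v, c, K, by, g);
    if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss at step %d", t + 1);
    vec gv = pack(g, c);
    ++t;
    mm = beta1 * mm + (1.0 - beta1) * gv;
    vv = beta2 * vv + (1.0 - beta2) * square(gv);
    vec mhat = mm / (1.0 - std::pow(beta1, t));
    vec vhat = vv / (1.0 - std::pow(beta2, t));
    p -= lr * mhat / (sqrt(vhat) + eps);
    loss_sum += loss; ++n_batches;
  }
  return Rcpp::List::create(
      Rcpp::Named("par") = p, Rcpp::Named("m") = mm, Rcpp::Named("v") = vv,
      Rcpp::Named("step") = t,
      Rcpp::Named("train_loss") = loss_sum / std::max(1, n_batches));
}
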