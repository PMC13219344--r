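// Compact stacked-LSTM binary classifier used as the reference recurrent
// model: two LSTM layers (h1, h2 units) with inverted dropout between them
// and a sigmoid output unit read from the final hidden state. Trained with
// Adam on binary cross-entropy via full backpropagation through time.
// Minibatches are processed as matrices (units x batch) so the inner loops
// are BLAS calls.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LstmLayer {
  mat W;   // (4h) x (d + h): input-to-gate and recurrent weights stacked
  vec b;   // 4h
  int h() const { return b.n_elem / 4; }
};

struct Net {
  LstmLayer l1, l2;
  vec w_out; // h2
  double b_out;
};

Net net_from_list(const Rcpp::List& w) {
  Net n;
  n.l1.W = Rcpp::as<mat>(w["W1"]);
  n.l1.b = Rcpp::as<vec>(w["b1"]);
  n.l2.W = Rcpp::as<mat>(w["W2"]);
  n.l2.b = Rcpp::as<vec>(w["b2"]);
  n.w_out = Rcpp::as<vec>(w["w_out"]);
  n.b_out = Rcpp::as<double>(w["b_out"]);
  return n;
}

Rcpp::List net_to_list(const Net& n) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = n.l1.W, Rcpp::Named("b1") = n.l1.b,
      Rcpp::Named("W2") = n.l2.W, Rcpp::Named("b2") = n.l2.b,
      Rcpp::Named("w_out") = n.w_out, Rcpp::Named("b_out") = n.b_out);
}

mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Per-step caches needed for BPTT.
struct StepCache {
  mat x, h_prev, c_prev, i, f, g, o, c, tanh_c;
};

// Forward pass of one layer over the full sequence for a minibatch.
// X_steps[t] is (d x batch). Returns hidden states per step and fills cache.
std::vector<mat> layer_forward(const LstmLayer& L,
                               const std::vector<mat>& X_steps,
                               std::vector<StepCache>* cache) {
  const int T = X_steps.size();
  const int h = L.h();
  const int batch = X_steps[0].n_cols;
  mat h_prev(h, batch, fill::zeros), c_prev(h, batch, fill::zeros);
  std::vector<mat> H(T);
  for (int t = 0; t < T; ++t) {
    mat z = L.W * join_cols(X_steps[t], h_prev);
    z.each_col() += L.b;
    mat i = sigm(z.rows(0, h - 1));
    mat f = sigm(z.rows(h, 2 * h - 1));
    mat g = tanh(z.rows(2 * h, 3 * h - 1));
    mat o = sigm(z.rows(3 * h, 4 * h - 1));
    mat c = f % c_prev + i % g;
    mat tc = tanh(c);
    mat hh = o % tc;
    if (cache) (*cache)[t] = {X_steps[t], h_prev, c_prev, i, f, g, o, c, tc};
    h_prev = hh;
    c_prev = c;
    H[t] = hh;
  }
  return H;
}

// BPTT through one layer. dH[t] holds dL/dh_t (may be zero except last).
// Returns gradient wrt the layer inputs per step; accumulates dW, db.
std::vector<mat> layer_backward(const LstmLayer& L,
                                const std::vector<StepCache>& cache,
                                const std::vector<mat>& dH_in, mat* dW,
                                vec* db) {
  const int T = cache.size();
  const int h = L.h();
  const int d = L.W.n_cols - h;
  const int batch = cache[0].x.n_cols;
  mat dh_next(h, batch, fill::zeros), dc_next(h, batch, fill::zeros);
  std::vector<mat> dX(T);
  for (int t = T - 1; t >= 0; --t) {
    const StepCache& s = cache[t];
    mat dh = dH_in[t] + dh_next;
    mat dc = dc_next + dh % s.o % (1 - s.tanh_c % s.tanh_c);
    mat do_ = dh % s.tanh_c % s.o % (1 - s.o);
    mat di = dc % s.g % s.i % (1 - s.i);
    mat df = dc % s.c_prev % s.f % (1 - s.f);
    mat dg = dc % s.i % (1 - s.g % s.g);
    mat dz = join_cols(join_cols(di, df), join_cols(dg, do_)); // 4h x batch
    *dW += dz * join_cols(s.x, s.h_prev).t();
    *db += sum(dz, 1);
    mat dxh = L.W.t() * dz; // (d + h) x batch
    dX[t] = dxh.rows(0, d - 1);
    dh_next = dxh.rows(d, d + h - 1);
    dc_next = dc % s.f;
  }
  return dX;
}

// Slice an (n, T, d) cube into per-step (d x batch) matrices for the rows
// in idx.
std::vector<mat> gather_steps(const cube& X, const uvec& idx) {
  const int T = X.n_cols, d = X.n_slices, batch = idx.n_elem;
  std::vector<mat> out(T, mat(d, batch));
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < d; ++j)
      for (int b = 0; b < batch; ++b) out[t](j, b) = X(idx[b], t, j);
  return out;
}

vec forward_probs(const Net& net, const cube& X, const uvec& idx) {
  std::vector<mat> xs = gather_steps(X, idx);
  std::vector<mat> H1 = layer_forward(net.l1, xs, nullptr);
  std::vector<mat> H2 = layer_forward(net.l2, H1, nullptr);
  rowvec z = net.w_out.t() * H2.back();
  return vectorise(1.0 / (1.0 + exp(-(z + net.b_out))));
}

struct Adam {
  mat mW1, vW1, mW2, vW2;
  vec mb1, vb1, mb2, vb2, mwo, vwo;
  double mbo = 0, vbo = 0;
  int t = 0;
  void init(const Net& n) {
    mW1 = vW1 = zeros(size(n.l1.W));
    mW2 = vW2 = zeros(size(n.l2.W));
    mb1 = vb1 = zeros(size(n.l1.b));
    mb2 = vb2 = zeros(size(n.l2.b));
    mwo = vwo = zeros(size(n.w_out));
  }
  template <typename M>
  void upd(M& p, M& m, M& v, const M& g, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    p -= lr * (m / (1 - std::pow(b1, t))) /
         (sqrt(v / (1 - std::pow(b2, t))) + eps);
  }
  void upd_scalar(double& p, double& m, double& v, double g, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * g * g;
    p -= lr * (m / (1 - std::pow(b1, t))) /
         (std::sqrt(v / (1 - std::pow(b2, t))) + eps);
  }
};

double mean_logloss(const vec& p, const vec& y) {
  vec pc = clamp(p, 1e-7, 1 - 1e-7);
  return -mean(y % log(pc) + (1 - y) % log(1 - pc));
}

}  // namespace

// [[Rcpp::export(name = ".lstm_init")]]
Rcpp::List lstm_init(int input_dim, int h1, int h2, int seed) {
  std::mt19937 rng(seed);
  std::normal_distribution<double> N(0.0, 1.0);
  auto glorot = [&](int rows, int cols) {
    double s = std::sqrt(2.0 / (rows + cols));
    mat M(rows, cols);
    for (uword k = 0; k < M.n_elem; ++k) M(k) = N(rng) * s;
    return M;
  };
  Net n;
  n.l1.W = glorot(4 * h1, input_dim + h1);
  n.l1.b = zeros<vec>(4 * h1);
  n.l1.b.subvec(h1, 2 * h1 - 1).fill(1.0); // forget-gate bias at 1
  n.l2.W = glorot(4 * h2, h1 + h2);
  n.l2.b = zeros<vec>(4 * h2);
  n.l2.b.subvec(h2, 2 * h2 - 1).fill(1.0);
  n.w_out = vectorise(glorot(h2, 1));
  n.b_out = 0.0;
  return net_to_list(n);
}

// [[Rcpp::export(name = ".lstm_forward")]]
Rcpp::NumericVector lstm_forward(Rcpp::List weights, Rcpp::NumericVector Xr) {
  Rcpp::IntegerVector dim = Xr.attr("dim");
  cube X(Xr.begin(), dim[0], dim[1], dim[2], false);
  Net net = net_from_list(weights);
  uvec idx = regspace<uvec>(0, dim[0] - 1);
  // chunk to bound the activation memory for large inputs
  vec out(dim[0]);
  const int chunk = 2048;
  for (int s = 0; s < dim[0]; s += chunk) {
    int e = std::min<int>(s + chunk, dim[0]) - 1;
    out.subvec(s, e) = forward_probs(net, X, idx.subvec(s, e));
  }
  return Rcpp::wrap(out);
}

// [[Rcpp::export(name = ".lstm_train")]]
Rcpp::List lstm_train(Rcpp::List weights, Rcpp::NumericVector Xr,
                      Rcpp::NumericVector yr, int epochs, int batch,
                      double lr, double dropout, int seed,
                      Rcpp::Nullable<Rcpp::NumericVector> Xval_r = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericVector> yval_r = R_NilValue) {
  Rcpp::IntegerVector dim = Xr.attr("dim");
  const int n = dim[0], T = dim[1], d = dim[2];
  cube X(Xr.begin(), n, T, d, false);
  vec y = Rcpp::as<vec>(yr);
  Net net = net_from_list(weights);
  const int h1 = net.l1.h(), h2 = net.l2.h();

  bool has_val = Xval_r.isNotNull();
  cube Xval;
  vec yval;
  if (has_val) {
    Rcpp::NumericVector Xv(Xval_r);
    Rcpp::IntegerVector dv = Xv.attr("dim");
    Xval = cube(Xv.begin(), dv[0], dv[1], dv[2]);
    yval = Rcpp::as<vec>(Rcpp::NumericVector(yval_r));
  }

  std::mt19937 rng(seed);
  Adam opt;
  opt.init(net);
  std::vector<double> tr_loss, va_loss;
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0;
    int n_batches = 0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(s + batch, n);
      uvec idx(e - s);
      for (int i = s; i < e; ++i) idx[i - s] = perm[i];
      int bsz = idx.n_elem;

      std::vector<mat> xs = gather_steps(X, idx);
      std::vector<StepCache> c1(T), c2(T);
      std::vector<mat> H1 = layer_forward(net.l1, xs, &c1);
      // inverted dropout on the layer-1 -> layer-2 activations
      std::vector<mat> masks(T);
      if (dropout > 0) {
        std::uniform_real_distribution<double> U(0.0, 1.0);
        for (int t = 0; t < T; ++t) {
          mat m(h1, bsz);
          for (uword k = 0; k < m.n_elem; ++k)
            m(k) = U(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
          masks[t] = m;
          H1[t] = H1[t] % m;
        }
      }
      std::vector<mat> H2 = layer_forward(net.l2, H1, &c2);

      rowvec z = net.w_out.t() * H2.back();
      vec p = vectorise(1.0 / (1.0 + exp(-(z + net.b_out))));
      vec yb(bsz);
      for (int i = 0; i < bsz; ++i) yb[i] = y[idx[i]];
      ep_loss += mean_logloss(p, yb);
      ++n_batches;

      // gradients
      vec dz_out = (p - yb) / bsz; // d(mean BCE)/d(logit)
      vec g_wo = H2.back() * dz_out;
      double g_bo = accu(dz_out);
      std::vector<mat> dH2(T, mat(h2, bsz, fill::zeros));
      dH2[T - 1] = net.w_out * dz_out.t();

      mat dW2(size(net.l2.W), fill::zeros);
      vec db2(size(net.l2.b), fill::zeros);
      std::vector<mat> dH1 = layer_backward(net.l2, c2, dH2, &dW2, &db2);
      if (dropout > 0)
        for (int t = 0; t < T; ++t) dH1[t] = dH1[t] % masks[t];
      mat dW1(size(net.l1.W), fill::zeros);
      vec db1(size(net.l1.b), fill::zeros);
      layer_backward(net.l1, c1, dH1, &dW1, &db1);

      // global-norm gradient clipping
      double norm2 = accu(dW1 % dW1) + accu(db1 % db1) + accu(dW2 % dW2) +
                     accu(db2 % db2) + accu(g_wo % g_wo) + g_bo * g_bo;
      double clip = 5.0, nrm = std::sqrt(norm2);
      if (nrm > clip) {
        double sc = clip / nrm;
        dW1 *= sc; db1 *= sc; dW2 *= sc; db2 *= sc; g_wo *= sc; g_bo *= sc;
      }

      ++opt.t;
      opt.upd(net.l1.W, opt.mW1, opt.vW1, dW1, lr);
      opt.upd(net.l1.b, opt.mb1, opt.vb1, db1, lr);
      opt.upd(net.l2.W, opt.mW2, opt.vW2, dW2, lr);
      opt.upd(net.l2.b, opt.mb2, opt.vb2, db2, lr);
      opt.upd(net.w_out, opt.mwo, opt.vwo, g_wo, lr);
      opt.upd_scalar(net.b_out, opt.mbo, opt.vbo, g_bo, lr);
    }
    tr_loss.push_back(ep_loss / std::max(n_batches, 1));
    if (has_val) {
      uvec vidx = regspace<uvec>(0, Xval.n_rows - 1);
      va_loss.push_back(mean_logloss(forward_probs(net, Xval, vidx), yval));
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = net_to_list(net),
      Rcpp::Named("train_loss") = tr_loss,
      Rcpp::Named("val_loss") = va_loss);
}
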