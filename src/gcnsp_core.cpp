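// Core numerics of the graph convolution with trainable sparse pooling.
// Gradients are hand-derived; the readable R-level counterpart is
// gcnspForward(), against which this path is tested.
//
// Model, per subject:
//   P1 = (A_hat X) W0 ; H1 = relu(P1) [dropout mask m1]
//   P2 = (A_hat H1) W1 ; Z = relu(P2)
//   ZG_0 = Z ; ZG_i = Theta_i ZG_{i-1}
//   zg  = [vec_rowmajor(ZG_1), ..., vec_rowmajor(ZG_n)] [dropout mask mzg]
//   logits = zg denseW ; probs = softmax(logits)
// Composite loss: mean cross-entropy + lambda * sum|Theta| (trainable
// thetas) + l2 * (|W0|^2 + |W1|^2 + |denseW|^2).
// A_hat X is precomputed once per training run and passed as a cube.
// All randomness (shuffles, dropout) draws from R's RNG, so training is
// bit-reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Params {
  mat W0, W1, denseW;
  std::vector<mat> Th;
};

static rowvec row_major(const mat& m) { return vectorise(m, 1); }

// forward for one subject; fills workspace matrices for reuse in backward
struct Work {
  mat P1, H1, AH1, P2;
  std::vector<mat> ZG;
  rowvec zg, pr;
};

static void forward_one(const mat& A, const mat& AXb, const Params& p,
                        const mat* m1, const vec* mzg, Work& w) {
  const uword nTheta = p.Th.size();
  w.P1 = AXb * p.W0;
  w.H1 = clamp(w.P1, 0.0, datum::inf);
  if (m1) w.H1 %= *m1;
  w.AH1 = A * w.H1;
  w.P2 = w.AH1 * p.W1;
  w.ZG.resize(nTheta + 1);
  w.ZG[0] = clamp(w.P2, 0.0, datum::inf);
  for (uword i = 0; i < nTheta; ++i) w.ZG[i + 1] = p.Th[i] * w.ZG[i];
  const uword P = p.denseW.n_rows;
  w.zg.set_size(P);
  uword off = 0;
  for (uword i = 1; i <= nTheta; ++i) {
    rowvec v = row_major(w.ZG[i]);
    w.zg.subvec(off, off + v.n_elem - 1) = v;
    off += v.n_elem;
  }
  if (mzg) w.zg %= mzg->t();
  rowvec logits = w.zg * p.denseW;
  rowvec ex = exp(logits - logits.max());
  w.pr = ex / accu(ex);
}

// backward for one subject; accumulates into g* (class-loss part only)
static void backward_one(const mat& A, const mat& AXb, const Params& p,
                         const Work& w, int yb, const mat* m1,
                         const vec* mzg, Params& g) {
  const uword nTheta = p.Th.size();
  const uword D2 = w.ZG[0].n_cols;
  rowvec dlogit = w.pr;
  dlogit[(uword)yb] -= 1.0;
  g.denseW += w.zg.t() * dlogit;
  rowvec dzg = (p.denseW * dlogit.t()).t();
  if (mzg) dzg %= mzg->t();
  std::vector<mat> dZG(nTheta + 1);
  uword off = 0;
  for (uword i = 1; i <= nTheta; ++i) {
    uword ni = w.ZG[i].n_rows;
    mat seg(const_cast<double*>(dzg.memptr()) + off, D2, ni, true, true);
    dZG[i] = seg.t();  // row-major unflatten
    off += ni * D2;
  }
  mat G = dZG[nTheta];
  for (uword i = nTheta; i >= 1; --i) {
    g.Th[i - 1] += G * w.ZG[i - 1].t();
    mat Gprev = p.Th[i - 1].t() * G;
    if (i > 1) G = dZG[i - 1] + Gprev;
    else {
      mat dP2 = Gprev % (w.P2 > 0);
      g.W1 += w.AH1.t() * dP2;
      mat dH1 = A * (dP2 * p.W1.t());
      if (m1) dH1 %= *m1;
      mat dP1 = dH1 % (w.P1 > 0);
      g.W0 += AXb.t() * dP1;
    }
  }
}

static Params params_from_r(const arma::mat& W0, const arma::mat& W1,
                            const Rcpp::List& thetas, const arma::mat& denseW) {
  Params p;
  p.W0 = W0; p.W1 = W1; p.denseW = denseW;
  p.Th.resize(thetas.size());
  for (int i = 0; i < thetas.size(); ++i) p.Th[i] = Rcpp::as<mat>(thetas[i]);
  return p;
}

static Rcpp::List params_to_r(const Params& p) {
  Rcpp::List th(p.Th.size());
  for (size_t i = 0; i < p.Th.size(); ++i) th[i] = p.Th[i];
  return Rcpp::List::create(Rcpp::Named("w0") = p.W0,
                            Rcpp::Named("w1") = p.W1,
                            Rcpp::Named("theta") = th,
                            Rcpp::Named("dense_w") = p.denseW);
}

// Evaluation / single-minibatch gradient entry point (also the prediction
// path). y = -1 marks unlabeled subjects (scored, not counted in the loss).
// [[Rcpp::export]]
Rcpp::List cpp_gcnsp_batch(const arma::mat& A,
                           const arma::cube& AX,
                           const arma::mat& W0,
                           const arma::mat& W1,
                           const Rcpp::List& thetas,
                           const arma::mat& denseW,
                           const arma::ivec& y,
                           const arma::cube& mask1,
                           const arma::mat& maskzg,
                           const bool wantGrad) {
  const uword B = AX.n_slices;
  Params p = params_from_r(W0, W1, thetas, denseW);
  const bool useMask = mask1.n_slices == B && maskzg.n_cols == B;

  Params g;
  if (wantGrad) {
    g.W0 = zeros(size(p.W0)); g.W1 = zeros(size(p.W1));
    g.denseW = zeros(size(p.denseW));
    g.Th.resize(p.Th.size());
    for (size_t i = 0; i < p.Th.size(); ++i) g.Th[i] = zeros(size(p.Th[i]));
  }

  mat probs(B, 2);
  double lossSum = 0.0;
  double nCorrect = 0;
  Work w;
  for (uword b = 0; b < B; ++b) {
    const mat* m1 = useMask ? &mask1.slice(b) : nullptr;
    vec mzgb;
    const vec* mzg = nullptr;
    if (useMask) { mzgb = maskzg.col(b); mzg = &mzgb; }
    forward_one(A, AX.slice(b), p, m1, mzg, w);
    probs.row(b) = w.pr;
    int yb = y[b];
    if (yb < 0) continue;
    lossSum += -std::log(std::max(w.pr[(uword)yb], 1e-12));
    if ((uword)index_max(w.pr) == (uword)yb) nCorrect += 1;
    if (wantGrad) backward_one(A, AX.slice(b), p, w, yb, m1, mzg, g);
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("probs") = probs,
    Rcpp::Named("loss_sum") = lossSum,
    Rcpp::Named("n_correct") = nCorrect);
  if (wantGrad) {
    Rcpp::List gl(g.Th.size());
    for (size_t i = 0; i < g.Th.size(); ++i) gl[i] = g.Th[i];
    out["g_w0"] = g.W0; out["g_w1"] = g.W1;
    out["g_theta"] = gl; out["g_dense"] = g.denseW;
  }
  return out;
}

// loss-free evaluation over a cube: mean class loss and accuracy
static void eval_set(const mat& A, const cube& AX, const ivec& y,
                     const Params& p, double reg, double& loss, double& acc) {
  Work w;
  double ls = 0; double nc = 0;
  for (uword b = 0; b < AX.n_slices; ++b) {
    forward_one(A, AX.slice(b), p, nullptr, nullptr, w);
    ls += -std::log(std::max(w.pr[(uword)y[b]], 1e-12));
    if ((uword)index_max(w.pr) == (uword)y[b]) nc += 1;
  }
  loss = ls / AX.n_slices + reg;
  acc = nc / AX.n_slices;
}

// R-RNG Fisher-Yates shuffle of 0..n-1
static uvec shuffle_r(uword n) {
  uvec idx = regspace<uvec>(0, n - 1);
  for (uword i = n - 1; i > 0; --i) {
    uword j = (uword)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

// Full training loop: minibatch Adam on the composite loss.
// [[Rcpp::export]]
Rcpp::List cpp_gcnsp_train(const arma::mat& A,
                           const arma::cube& AX,
                           const arma::ivec& y,
                           const arma::cube& AXval,
                           const arma::ivec& yval,
                           const arma::mat& W0,
                           const arma::mat& W1,
                           const Rcpp::List& thetas,
                           const arma::mat& denseW,
                           const arma::uvec& thetaTrainable,
                           const double lr, const double l2,
                           const double lambda, const double dropout,
                           const int batchSize, const int epochs,
                           const bool keepSnapshots) {
  Rcpp::RNGScope rngScope;
  const uword B = AX.n_slices;
  const uword N = A.n_rows;
  Params p = params_from_r(W0, W1, thetas, denseW);
  const uword nTheta = p.Th.size();
  const uword D1 = p.W0.n_cols;
  const uword P = p.denseW.n_rows;
  const bool hasVal = AXval.n_slices > 0;

  // Adam state
  Params m, v;
  m.W0 = zeros(size(p.W0)); v.W0 = m.W0;
  m.W1 = zeros(size(p.W1)); v.W1 = m.W1;
  m.denseW = zeros(size(p.denseW)); v.denseW = m.denseW;
  m.Th.resize(nTheta); v.Th.resize(nTheta);
  for (uword i = 0; i < nTheta; ++i) { m.Th[i] = zeros(size(p.Th[i])); v.Th[i] = m.Th[i]; }
  double t = 0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  auto adam = [&](mat& par, mat& ms, mat& vs, const mat& gr) {
    ms = b1 * ms + (1 - b1) * gr;
    vs = b2 * vs + (1 - b2) * square(gr);
    par -= lr * (ms / (1 - std::pow(b1, t))) /
           (sqrt(vs / (1 - std::pow(b2, t))) + eps);
  };

  mat history(epochs, 6);
  Rcpp::List snaps(keepSnapshots ? epochs : 0);
  Work w;
  Params g;
  g.Th.resize(nTheta);

  for (int ep = 0; ep < epochs; ++ep) {
    uvec ord = shuffle_r(B);
    for (uword start = 0; start < B; start += (uword)batchSize) {
      uword stop = std::min(start + (uword)batchSize, B) - 1;
      uword bs = stop - start + 1;
      g.W0 = zeros(size(p.W0)); g.W1 = zeros(size(p.W1));
      g.denseW = zeros(size(p.denseW));
      for (uword i = 0; i < nTheta; ++i) g.Th[i] = zeros(size(p.Th[i]));
      for (uword k = start; k <= stop; ++k) {
        uword b = ord[k];
        mat m1; vec mzg;
        const mat* m1p = nullptr; const vec* mzgp = nullptr;
        if (dropout > 0) {
          m1.set_size(N, D1); mzg.set_size(P);
          const double keep = 1.0 - dropout;
          for (uword q = 0; q < m1.n_elem; ++q)
            m1[q] = unif_rand() >= dropout ? 1.0 / keep : 0.0;
          for (uword q = 0; q < P; ++q)
            mzg[q] = unif_rand() >= dropout ? 1.0 / keep : 0.0;
          m1p = &m1; mzgp = &mzg;
        }
        forward_one(A, AX.slice(b), p, m1p, mzgp, w);
        backward_one(A, AX.slice(b), p, w, y[b], m1p, mzgp, g);
      }
      // mean class-loss gradient + penalty gradients
      g.W0 = g.W0 / bs + 2 * l2 * p.W0;
      g.W1 = g.W1 / bs + 2 * l2 * p.W1;
      g.denseW = g.denseW / bs + 2 * l2 * p.denseW;
      t += 1;
      adam(p.W0, m.W0, v.W0, g.W0);
      adam(p.W1, m.W1, v.W1, g.W1);
      adam(p.denseW, m.denseW, v.denseW, g.denseW);
      for (uword i = 0; i < nTheta; ++i) {
        if (!thetaTrainable[i]) continue;
        mat gt = g.Th[i] / bs + lambda * sign(p.Th[i]);
        adam(p.Th[i], m.Th[i], v.Th[i], gt);
      }
    }
    double reg = l2 * (accu(square(p.W0)) + accu(square(p.W1)) +
                       accu(square(p.denseW)));
    for (uword i = 0; i < nTheta; ++i)
      if (thetaTrainable[i]) reg += lambda * accu(abs(p.Th[i]));
    double trl, tra, vl = NA_REAL, va = NA_REAL;
    eval_set(A, AX, y, p, reg, trl, tra);
    if (hasVal) eval_set(A, AXval, yval, p, reg, vl, va);
    history(ep, 0) = ep + 1; history(ep, 1) = trl;
    history(ep, 2) = trl - reg;  // class-loss component
    history(ep, 3) = tra; history(ep, 4) = vl; history(ep, 5) = va;
    if (keepSnapshots) snaps[ep] = params_to_r(p);
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_to_r(p),
                            Rcpp::Named("history") = history,
                            Rcpp::Named("snapshots") = snaps);
}
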