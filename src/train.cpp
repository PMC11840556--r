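// Elastic-net-penalized dense feed-forward classifier, trained by Adam.
//
// The network has L in {0,1,2,3} hidden layers of k ReLU units, an identity
// input layer and a K=2 softmax output; the loss is mean binary cross-entropy
// over the batch plus lambda * [gamma * sum|w| + (1-gamma)/2 * sum w^2] over
// connection weights (biases unpenalized).
//
// Training runs in single precision (the standard numeric width for neural
// nets; cross-validation errors are misclassification counts and are
// insensitive to it). Two code paths:
//
//  * a generic per-network path (any L, mini-batches) used for final fits
//    and as the fallback for cross-validation;
//  * a fused cross-validation path for L in {0,1} under full-batch training:
//    all (lambda, gamma) cells x folds are trained simultaneously, with
//    first-layer weights of every virtual network packed into one
//    d0 x (d1*C*F) matrix so that the two O(d0) products per step are single
//    BLAS GEMMs. Each fold's held-out rows simply contribute zero gradient.
//
// Both paths draw initial weights from the same per-cell seeded splitmix64
// streams, independent of R's RNG.

#include <RcppArmadillo.h>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  void shuffle(uvec& idx) {
    for (uword i = idx.n_elem - 1; i > 0; --i) {
      uword j = (uword)(next() % (i + 1));
      std::swap(idx[i], idx[j]);
    }
  }
};

// ---------------------------------------------------------------- generic --

struct Net {
  int L, k, d0, d1;
  std::vector<fmat> W;  // layers 1..L+1
  std::vector<fmat> b;  // 1 x dout each
};

static Net init_net(int d0, int L, int k, uint64_t seed) {
  Net net;
  net.L = L; net.k = k; net.d0 = d0;
  net.d1 = (L == 0) ? 2 : k;
  SplitMix rng(seed);
  int din = d0;
  for (int l = 1; l <= L + 1; ++l) {
    int dout = (l == L + 1) ? 2 : k;
    if (L == 0) dout = 2;
    fmat W(din, dout);
    float s = 1.0f / std::sqrt((float)din);
    for (uword j = 0; j < W.n_cols; ++j)
      for (uword i = 0; i < W.n_rows; ++i)
        W(i, j) = s * (2.0f * (float)rng.unif() - 1.0f);
    net.W.push_back(W);
    net.b.push_back(fmat(1, dout, fill::zeros));
    din = dout;
    if (L == 0) break;
  }
  return net;
}

static inline void softmax2_rows(fmat& Z) {
  for (uword i = 0; i < Z.n_rows; ++i) {
    float d = Z(i, 0) - Z(i, 1);
    float p1 = 1.0f / (1.0f + std::exp(d));
    Z(i, 0) = 1.0f - p1;
    Z(i, 1) = p1;
  }
}

static fmat forward_net(const Net& net, const fmat& X,
                        std::vector<fmat>* acts) {
  fmat A = X;
  if (acts) acts->clear();
  for (size_t l = 0; l < net.W.size(); ++l) {
    fmat Z = A * net.W[l];
    Z.each_row() += net.b[l].row(0);
    if (l + 1 < net.W.size()) {
      Z.clamp(0.0f, std::numeric_limits<float>::max());
      if (acts) acts->push_back(Z);
      A = Z;
    } else {
      softmax2_rows(Z);
      return Z;
    }
  }
  return A;  // unreachable
}

struct AdamF {
  fmat m, v;
  AdamF(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(fmat& W, const fmat& G, int t, float lr, float b1, float b2) {
    m = b1 * m + (1.0f - b1) * G;
    v = b2 * v + (1.0f - b2) * square(G);
    float c1 = 1.0f - std::pow(b1, (float)t), c2 = 1.0f - std::pow(b2, (float)t);
    W -= lr * (m / c1) / (sqrt(v / c2) + 1e-8f);
  }
};

static void train_net(Net& net, const fmat& X, const fmat& Y,
                      float lambda, float gamma, int epochs, float lr,
                      float beta1, float beta2, int batch_size,
                      uint64_t shuffle_seed) {
  const int n = X.n_rows;
  const int bsz = std::min(batch_size, n);
  std::vector<AdamF> stW, stB;
  for (size_t l = 0; l < net.W.size(); ++l) {
    stW.emplace_back(net.W[l].n_rows, net.W[l].n_cols);
    stB.emplace_back(1, net.b[l].n_cols);
  }
  SplitMix srng(shuffle_seed);
  uvec order = regspace<uvec>(0, n - 1);
  std::vector<fmat> acts;
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    if (bsz < n) srng.shuffle(order);
    for (int start = 0; start < n; start += bsz) {
      int stop = std::min(start + bsz, n) - 1;
      uvec rows = order.subvec((uword)start, (uword)stop);
      fmat Xb = X.rows(rows), Yb = Y.rows(rows);
      float nb = (float)Xb.n_rows;
      ++t;
      fmat P = forward_net(net, Xb, &acts);
      fmat delta = (P - Yb) / nb;
      for (int l = (int)net.W.size() - 1; l >= 0; --l) {
        const fmat& Ain = (l == 0) ? Xb : acts[l - 1];
        fmat deltaPrev;
        if (l > 0) deltaPrev = delta * net.W[l].t();
        fmat dW = Ain.t() * delta;
        dW += lambda * (gamma * sign(net.W[l]) +
                        (1.0f - gamma) * net.W[l]);
        fmat db = sum(delta, 0);
        stW[l].step(net.W[l], dW, t, lr, beta1, beta2);
        stB[l].step(net.b[l], db, t, lr, beta1, beta2);
        if (l > 0)
          delta = deltaPrev % conv_to<fmat>::from(acts[l - 1] > 0.0f);
      }
    }
  }
}

// ------------------------------------------------------------ fused CV ----

// All cells x folds trained at once, full batch, L in {0,1}.
// Returns n x C held-out P(yes).
static mat cv_fused(const fmat& X, const fmat& Y, const ivec& fold_id,
                    int L, int k, const vec& lambdas, const vec& gammas,
                    const Rcpp::NumericMatrix& cell_seeds, int epochs,
                    float lr, float beta1, float beta2) {
  const int n = X.n_rows, d0 = X.n_cols, C = lambdas.n_elem;
  const int F = fold_id.max();
  const int CF = C * F;
  const int d1 = (L == 0) ? 2 : k;
  const int W = d1 * CF;

  // virtual cell vc = c*F + f
  std::vector<float> nb(CF);
  {
    std::vector<int> fc(F, 0);
    for (int i = 0; i < n; ++i) fc[fold_id[i] - 1]++;
    for (int c = 0; c < C; ++c)
      for (int f = 0; f < F; ++f) nb[c * F + f] = (float)(n - fc[f]);
  }

  fmat W1(d0, W), b1(1, W, fill::zeros);
  fmat W2, b2;                    // fused deep layer (L = 1 only)
  if (L == 1) { W2.set_size(k, 2 * CF); b2 = fmat(1, 2 * CF, fill::zeros); }
  for (int c = 0; c < C; ++c)
    for (int f = 0; f < F; ++f) {
      int vc = c * F + f;
      SplitMix rng((uint64_t)cell_seeds(c, f));
      float s = 1.0f / std::sqrt((float)d0);
      for (int j = 0; j < d1; ++j)
        for (int i = 0; i < d0; ++i)
          W1(i, vc * d1 + j) = s * (2.0f * (float)rng.unif() - 1.0f);
      if (L == 1) {
        float s2 = 1.0f / std::sqrt((float)k);
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < k; ++i)
            W2(i, vc * 2 + j) = s2 * (2.0f * (float)rng.unif() - 1.0f);
      }
    }

  // per-column penalty factors for the fused matrices
  frowvec l1w1(W), l2w1(W), l1w2, l2w2;
  for (int vc = 0; vc < CF; ++vc) {
    float lam = (float)lambdas[vc / F], gam = (float)gammas[vc / F];
    for (int j = 0; j < d1; ++j) {
      l1w1[vc * d1 + j] = lam * gam;
      l2w1[vc * d1 + j] = lam * (1.0f - gam);
    }
  }
  if (L == 1) {
    l1w2.set_size(2 * CF); l2w2.set_size(2 * CF);
    for (int vc = 0; vc < CF; ++vc) {
      float lam = (float)lambdas[vc / F], gam = (float)gammas[vc / F];
      for (int j = 0; j < 2; ++j) {
        l1w2[vc * 2 + j] = lam * gam;
        l2w2[vc * 2 + j] = lam * (1.0f - gam);
      }
    }
  }

  fmat M1(d0, W, fill::zeros), V1(d0, W, fill::zeros);
  fmat Mb1(1, W, fill::zeros), Vb1(1, W, fill::zeros);
  fmat M2, V2, Mb2, Vb2;
  if (L == 1) {
    M2.zeros(k, 2 * CF); V2.zeros(k, 2 * CF);
    Mb2.zeros(1, 2 * CF); Vb2.zeros(1, 2 * CF);
  }

  fmat Z1(n, W), D1(n, W), dW1(d0, W);
  fmat dW2, D2;
  if (L == 1) { dW2.set_size(k, 2 * CF); D2.set_size(n, 2 * CF); }

  auto adam_fused = [&](fmat& Wm, fmat& Mm, fmat& Vm, const fmat& G,
                        const frowvec* l1, const frowvec* l2, int t) {
    const float a = lr / (1.0f - std::pow(beta1, (float)t));
    const float b = 1.0f / std::sqrt(1.0f - std::pow(beta2, (float)t));
    const uword R = Wm.n_rows;
    for (uword j = 0; j < Wm.n_cols; ++j) {
      float* w = Wm.colptr(j);
      float* mm = Mm.colptr(j);
      float* vv = Vm.colptr(j);
      const float* g0 = G.colptr(j);
      const float p1 = l1 ? (*l1)[j] : 0.0f;
      const float p2 = l2 ? (*l2)[j] : 0.0f;
      for (uword i = 0; i < R; ++i) {
        float g = g0[i] + p1 * (float)((w[i] > 0.0f) - (w[i] < 0.0f)) +
                  p2 * w[i];
        mm[i] = beta1 * mm[i] + (1.0f - beta1) * g;
        vv[i] = beta2 * vv[i] + (1.0f - beta2) * g * g;
        w[i] -= a * mm[i] / (b * std::sqrt(vv[i]) + 1e-8f);
      }
    }
  };

  for (int t = 1; t <= epochs; ++t) {
    Z1 = X * W1;
    Z1.each_row() += b1.row(0);
    if (L == 0) {
      for (int vc = 0; vc < CF; ++vc) {
        const int f = vc % F + 1;
        const float inb = 1.0f / nb[vc];
        float* zn = Z1.colptr(vc * 2);
        float* zy = Z1.colptr(vc * 2 + 1);
        float* dn = D1.colptr(vc * 2);
        float* dy = D1.colptr(vc * 2 + 1);
        for (int i = 0; i < n; ++i) {
          if (fold_id[i] == f) { dn[i] = 0.0f; dy[i] = 0.0f; continue; }
          float p1 = 1.0f / (1.0f + std::exp(zn[i] - zy[i]));
          dn[i] = ((1.0f - p1) - Y(i, 0)) * inb;
          dy[i] = (p1 - Y(i, 1)) * inb;
        }
      }
    } else {
      Z1.clamp(0.0f, std::numeric_limits<float>::max());  // A1 in place
      std::vector<float> zn(n), zy(n);
      for (int vc = 0; vc < CF; ++vc) {
        const int f = vc % F + 1;
        const float inb = 1.0f / nb[vc];
        const float* w2n = W2.colptr(vc * 2);
        const float* w2y = W2.colptr(vc * 2 + 1);
        const float bn = b2(0, vc * 2), by = b2(0, vc * 2 + 1);
        float* dn = D2.colptr(vc * 2);
        float* dy = D2.colptr(vc * 2 + 1);
        for (int i = 0; i < n; ++i) { zn[i] = bn; zy[i] = by; }
        for (int u = 0; u < k; ++u) {  // column-contiguous accumulation
          const float* a = Z1.colptr(vc * k + u);
          const float wn = w2n[u], wy = w2y[u];
          for (int i = 0; i < n; ++i) {
            zn[i] += a[i] * wn;
            zy[i] += a[i] * wy;
          }
        }
        for (int i = 0; i < n; ++i) {
          if (fold_id[i] == f) { dn[i] = 0.0f; dy[i] = 0.0f; continue; }
          float p1 = 1.0f / (1.0f + std::exp(zn[i] - zy[i]));
          dn[i] = ((1.0f - p1) - Y(i, 0)) * inb;
          dy[i] = (p1 - Y(i, 1)) * inb;
        }
        // dW2 block, delta1 block
        float* d1n = D1.colptr(vc * k);
        for (int u = 0; u < k; ++u) {
          const float* a = Z1.colptr(vc * k + u);
          float su_n = 0.0f, su_y = 0.0f;
          float* d1c = d1n + (ptrdiff_t)n * u;
          for (int i = 0; i < n; ++i) {
            su_n += a[i] * dn[i];
            su_y += a[i] * dy[i];
            d1c[i] = (a[i] > 0.0f) ? (dn[i] * w2n[u] + dy[i] * w2y[u]) : 0.0f;
          }
          dW2(u, vc * 2) = su_n;
          dW2(u, vc * 2 + 1) = su_y;
        }
      }
      adam_fused(W2, M2, V2, dW2, &l1w2, &l2w2, t);
      fmat db2 = sum(D2, 0);
      adam_fused(b2, Mb2, Vb2, db2, nullptr, nullptr, t);
    }
    dW1 = X.t() * D1;
    adam_fused(W1, M1, V1, dW1, &l1w1, &l2w1, t);
    fmat db1 = sum(D1, 0);
    adam_fused(b1, Mb1, Vb1, db1, nullptr, nullptr, t);
  }

  // held-out predictions
  mat out(n, C);
  Z1 = X * W1;
  Z1.each_row() += b1.row(0);
  if (L == 1) Z1.clamp(0.0f, std::numeric_limits<float>::max());
  for (int c = 0; c < C; ++c)
    for (int f = 0; f < F; ++f) {
      int vc = c * F + f;
      for (int i = 0; i < n; ++i) {
        if (fold_id[i] != f + 1) continue;
        float zn, zy;
        if (L == 0) {
          zn = Z1(i, vc * 2);
          zy = Z1(i, vc * 2 + 1);
        } else {
          zn = b2(0, vc * 2); zy = b2(0, vc * 2 + 1);
          for (int u = 0; u < k; ++u) {
            float av = Z1(i, vc * k + u);
            zn += av * W2(u, vc * 2);
            zy += av * W2(u, vc * 2 + 1);
          }
        }
        out(i, c) = 1.0 / (1.0 + std::exp((double)zn - (double)zy));
      }
    }
  return out;
}

// ------------------------------------------------------------- exports ----

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List W, b;
  for (size_t l = 0; l < net.W.size(); ++l) {
    W.push_back(Rcpp::wrap(conv_to<mat>::from(net.W[l])));
    b.push_back(Rcpp::wrap(conv_to<mat>::from(net.b[l])));
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b);
}

// [[Rcpp::export(name = ".cpp_train_cells")]]
Rcpp::List cpp_train_cells(const arma::mat& X, const arma::mat& Y,
                           int L, int k,
                           const arma::vec& lambdas, const arma::vec& gammas,
                           const Rcpp::NumericVector& cell_seeds,
                           int epochs, double lr, double beta1, double beta2,
                           int batch_size, double shuffle_seed) {
  const fmat Xf = conv_to<fmat>::from(X), Yf = conv_to<fmat>::from(Y);
  const int C = lambdas.n_elem;
  Rcpp::List out(C);
  for (int c = 0; c < C; ++c) {
    Net net = init_net(X.n_cols, L, k, (uint64_t)cell_seeds[c]);
    train_net(net, Xf, Yf, (float)lambdas[c], (float)gammas[c], epochs,
              (float)lr, (float)beta1, (float)beta2, batch_size,
              (uint64_t)shuffle_seed);
    out[c] = net_to_list(net);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_forward")]]
arma::mat cpp_forward(const Rcpp::List& cellnet, const arma::mat& X, int L) {
  Rcpp::List Wl = cellnet["W"], bl = cellnet["b"];
  mat A = X;
  for (int l = 0; l < Wl.size(); ++l) {
    mat W = Rcpp::as<mat>(Wl[l]);
    mat b = Rcpp::as<mat>(bl[l]);
    mat Z = A * W;
    Z.each_row() += b.row(0);
    if (l + 1 < Wl.size()) {
      Z.clamp(0.0, std::numeric_limits<double>::max());
      A = Z;
    } else {
      for (uword i = 0; i < Z.n_rows; ++i) {
        double p1 = 1.0 / (1.0 + std::exp(Z(i, 0) - Z(i, 1)));
        Z(i, 0) = 1.0 - p1;
        Z(i, 1) = p1;
      }
      return Z;
    }
  }
  return A;
}

// [[Rcpp::export(name = ".cpp_cv_grid")]]
arma::mat cpp_cv_grid(const arma::mat& X, const arma::mat& Y,
                      const arma::ivec& fold_id, int L, int k,
                      const arma::vec& lambdas, const arma::vec& gammas,
                      const Rcpp::NumericMatrix& cell_seeds,
                      int epochs, double lr, double beta1, double beta2,
                      int batch_size, const Rcpp::NumericVector& shuffle_seeds) {
  const int n = X.n_rows, C = lambdas.n_elem;
  const int F = fold_id.max();
  const fmat Xf = conv_to<fmat>::from(X), Yf = conv_to<fmat>::from(Y);

  int max_train = 0;
  {
    std::vector<int> fc(F, 0);
    for (int i = 0; i < n; ++i) fc[fold_id[i] - 1]++;
    for (int f = 0; f < F; ++f) max_train = std::max(max_train, n - fc[f]);
  }
  if (L <= 1 && batch_size >= max_train)
    return cv_fused(Xf, Yf, fold_id, L, k, lambdas, gammas, cell_seeds,
                    epochs, (float)lr, (float)beta1, (float)beta2);

  // generic fallback: per fold, per cell
  mat prob_yes(n, C, fill::value(datum::nan));
  for (int f = 1; f <= F; ++f) {
    uvec test = find(fold_id == f);
    if (test.n_elem == 0) continue;
    uvec train = find(fold_id != f);
    fmat Xtr = Xf.rows(train), Ytr = Yf.rows(train), Xte = Xf.rows(test);
    for (int c = 0; c < C; ++c) {
      Net net = init_net(X.n_cols, L, k, (uint64_t)cell_seeds(c, f - 1));
      train_net(net, Xtr, Ytr, (float)lambdas[c], (float)gammas[c], epochs,
                (float)lr, (float)beta1, (float)beta2, batch_size,
                (uint64_t)shuffle_seeds[f - 1]);
      fmat P = forward_net(net, Xte, nullptr);
      for (uword i = 0; i < test.n_elem; ++i)
        prob_yes(test[i], c) = (double)P(i, 1);
    }
  }
  return prob_yes;
}
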