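// Multilayer-perceptron training core.
//
// Feed-forward network with an arbitrary number of hidden layers:
// ReLU on all hidden layers except the last, logistic sigmoid on the last
// hidden layer and on the single output unit (binary classification,
// P(positive class)).  Inverted dropout on hidden activations during
// training, Adam optimisation of the binary cross-entropy, optional early
// stopping on a monitoring set with best-weight restoration.
//
// All randomness (weight init, epoch shuffling, dropout masks) derives from
// a private generator seeded explicitly, so training is bit-reproducible for
// a given seed regardless of R's RNG state.  Single-threaded on purpose.
// Adam updates are fused pointer loops and dropout uses a splitmix64 stream:
// with ~20k parameters and minibatches of 32 the run time is dominated by
// small-GEMM overhead, so temporaries are kept off the per-batch path.

#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

namespace {

// splitmix64: cheap, high-quality stream for dropout masks
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  inline uint64_t next() {
    uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

inline arma::mat sigmoid(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// mean binary cross-entropy, clamped away from log(0)
inline double bce(const arma::vec& p, const arma::vec& y) {
  const double eps = 1e-12;
  arma::vec pc = arma::clamp(p, eps, 1.0 - eps);
  return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
}

struct Net {
  std::vector<arma::mat> W;  // layer l: (d_in x d_out)
  std::vector<arma::rowvec> b;
  int n_hidden;

  // forward pass without dropout; returns output probabilities
  arma::vec forward(const arma::mat& X) const {
    arma::mat A = X;
    const int L = static_cast<int>(W.size());
    for (int l = 0; l < L; ++l) {
      arma::mat Z = A * W[l];
      Z.each_row() += b[l];
      if (l == L - 1 || l == n_hidden - 1) {
        A = sigmoid(Z);             // last hidden layer and output unit
      } else {
        A = arma::clamp(Z, 0.0, arma::datum::inf);  // ReLU
      }
    }
    return arma::vec(A.col(0));
  }
};

// fused Adam step: no temporaries
inline void adam_update(double* w, double* m, double* v, const double* g,
                        size_t n, double lr, double b1, double b2,
                        double corr1, double corr2, double eps) {
  for (size_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    w[i] -= lr * (m[i] / corr1) / (std::sqrt(v[i] / corr2) + eps);
  }
}

}  // namespace

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
List cpp_mlp_train(const arma::mat& X, const arma::vec& y,
                   const arma::mat& Xmon, const arma::vec& ymon,
                   const IntegerVector& hidden,
                   double dropout, double lr,
                   int epochs, int batch_size, int patience,
                   double seed) {
  const int n = X.n_rows;
  const int d = X.n_cols;
  const int H = hidden.size();
  const bool monitor = Xmon.n_rows > 0 && patience > 0;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> norm(0.0, 1.0);
  SplitMix64 drop_rng(rng() ^ 0xD1B54A32D192ED03ULL);

  // layer dimensions: d -> hidden... -> 1
  std::vector<int> dims(H + 2);
  dims[0] = d;
  for (int i = 0; i < H; ++i) dims[i + 1] = hidden[i];
  dims[H + 1] = 1;

  Net net;
  net.n_hidden = H;
  net.W.resize(H + 1);
  net.b.resize(H + 1);
  for (int l = 0; l <= H; ++l) {
    const int fin = dims[l], fout = dims[l + 1];
    // He scaling for ReLU layers, Glorot for sigmoid-activated layers
    const bool relu_layer = (l < H - 1);
    const double sd = relu_layer ? std::sqrt(2.0 / fin)
                                 : std::sqrt(2.0 / (fin + fout));
    net.W[l].set_size(fin, fout);
    for (arma::uword j = 0; j < net.W[l].n_cols; ++j)
      for (arma::uword i = 0; i < net.W[l].n_rows; ++i)
        net.W[l](i, j) = sd * norm(rng);
    net.b[l] = arma::rowvec(fout, arma::fill::zeros);
  }

  // Adam state
  std::vector<arma::mat> mW(H + 1), vW(H + 1);
  std::vector<arma::rowvec> mb(H + 1), vb(H + 1);
  for (int l = 0; l <= H; ++l) {
    mW[l].zeros(arma::size(net.W[l]));
    vW[l].zeros(arma::size(net.W[l]));
    mb[l].zeros(1, net.b[l].n_elem);
    vb[l].zeros(1, net.b[l].n_elem);
  }
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  const double keep = 1.0 - dropout;
  long step = 0;

  const double initial_loss = bce(net.forward(X), y);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  double best_mon = arma::datum::inf;
  int wait = 0, epochs_run = 0;
  std::vector<arma::mat> bestW = net.W;
  std::vector<arma::rowvec> bestb = net.b;
  std::vector<double> mon_history;

  std::vector<arma::mat> A(H + 2), D(H + 1);
  arma::mat Spre;  // pre-dropout activation of the sigmoid hidden layer
  arma::mat Xb, delta, back, gW;
  arma::rowvec gb;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with the private RNG
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> pick(0, i);
      std::swap(idx[i], idx[pick(rng)]);
    }
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      const int m = stop - start;
      arma::uvec rows(m);
      for (int i = 0; i < m; ++i) rows[i] = idx[start + i];
      Xb = X.rows(rows);
      arma::vec yb = y.elem(rows);

      // forward with inverted dropout on hidden activations
      A[0] = Xb;
      for (int l = 0; l <= H; ++l) {
        arma::mat Z = A[l] * net.W[l];
        Z.each_row() += net.b[l];
        if (l == H) {
          A[l + 1] = sigmoid(Z);
        } else {
          arma::mat act = (l == H - 1)
              ? sigmoid(Z)
              : arma::clamp(Z, 0.0, arma::datum::inf);
          if (l == H - 1) Spre = act;
          if (dropout > 0.0) {
            D[l].set_size(arma::size(act));
            double* dm = D[l].memptr();
            double* am = act.memptr();
            const size_t ne = act.n_elem;
            const double inv_keep = 1.0 / keep;
            for (size_t e = 0; e < ne; ++e) {
              const double mask = (drop_rng.unif() < keep) ? inv_keep : 0.0;
              dm[e] = mask;
              am[e] *= mask;
            }
          }
          A[l + 1] = act;
        }
      }

      // backward
      delta = (A[H + 1] - yb) / static_cast<double>(m);  // dL/dZ_out
      ++step;
      const double corr1 = 1.0 - std::pow(b1, static_cast<double>(step));
      const double corr2 = 1.0 - std::pow(b2, static_cast<double>(step));
      for (int l = H; l >= 0; --l) {
        gW = A[l].t() * delta;
        gb = arma::sum(delta, 0);
        if (l > 0) {
          back = delta * net.W[l].t();
          double* bk = back.memptr();
          const double* al = A[l].memptr();
          const size_t ne = back.n_elem;
          if (dropout > 0.0) {
            const double* dm = D[l - 1].memptr();
            for (size_t e = 0; e < ne; ++e) bk[e] *= dm[e];
          }
          if (l - 1 == H - 1) {
            const double* sp = Spre.memptr();
            for (size_t e = 0; e < ne; ++e) bk[e] *= sp[e] * (1.0 - sp[e]);
          } else {
            for (size_t e = 0; e < ne; ++e) if (al[e] <= 0.0) bk[e] = 0.0;
          }
        }
        adam_update(net.W[l].memptr(), mW[l].memptr(), vW[l].memptr(),
                    gW.memptr(), net.W[l].n_elem, lr, b1, b2,
                    corr1, corr2, adam_eps);
        adam_update(net.b[l].memptr(), mb[l].memptr(), vb[l].memptr(),
                    gb.memptr(), net.b[l].n_elem, lr, b1, b2,
                    corr1, corr2, adam_eps);
        if (l > 0) delta = back;
      }
    }
    epochs_run = ep + 1;

    if (monitor) {
      const double mloss = bce(net.forward(Xmon), ymon);
      mon_history.push_back(mloss);
      if (mloss < best_mon - 1e-6) {
        best_mon = mloss;
        bestW = net.W;
        bestb = net.b;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    }
  }

  if (monitor && best_mon < arma::datum::inf) {
    net.W = bestW;
    net.b = bestb;
  }

  const double final_loss = bce(net.forward(X), y);

  List Wout(H + 1), bout(H + 1);
  for (int l = 0; l <= H; ++l) {
    Wout[l] = net.W[l];
    bout[l] = arma::vec(net.b[l].t());
  }
  return List::create(
      _["W"] = Wout, _["b"] = bout,
      _["initial_loss"] = initial_loss,
      _["final_loss"] = final_loss,
      _["epochs_run"] = epochs_run,
      _["monitor_loss"] = monitor ? best_mon : NA_REAL,
      _["monitor_history"] = mon_history);
}

// [[Rcpp::export]]
arma::vec cpp_mlp_predict(const List& W, const List& b, const arma::mat& X,
                          int n_hidden) {
  Net net;
  net.n_hidden = n_hidden;
  const int L = W.size();
  net.W.resize(L);
  net.b.resize(L);
  for (int l = 0; l < L; ++l) {
    net.W[l] = as<arma::mat>(W[l]);
    arma::vec bb = as<arma::vec>(b[l]);
    net.b[l] = bb.t();
  }
  return net.forward(X);
}
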