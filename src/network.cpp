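#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3-6-11 logistic perceptron. Weight matrices are (from x to), i.e.
// w_ih is 3x6 with w_ih(i,j) the weight from input i to hidden j.
// All randomness (epoch shuffles) goes through R's RNG so that a single
// set.seed() makes whole simulation runs bit-reproducible.

static inline double logistic(double v) { return 1.0 / (1.0 + std::exp(-v)); }

// Batch forward pass: X is n x n_in, returns n x n_out.
// [[Rcpp::export]]
NumericMatrix net_forward_cpp(const NumericMatrix& X,
                              const NumericMatrix& w_ih, const NumericVector& b_h,
                              const NumericMatrix& w_ho, const NumericVector& b_o) {
  const int n = X.nrow();
  const int ni = w_ih.nrow(), nh = w_ih.ncol(), no = w_ho.ncol();
  if (X.ncol() != ni || w_ho.nrow() != nh || b_h.size() != nh || b_o.size() != no)
    stop("weight/input dimension mismatch");
  NumericMatrix Y(n, no);
  std::vector<double> h(nh);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < nh; ++j) {
      double v = b_h[j];
      for (int i = 0; i < ni; ++i) v += w_ih(i, j) * X(r, i);
      h[j] = logistic(v);
    }
    for (int k = 0; k < no; ++k) {
      double v = b_o[k];
      for (int j = 0; j < nh; ++j) v += w_ho(j, k) * h[j];
      Y(r, k) = logistic(v);
    }
  }
  return Y;
}

// Online stochastic gradient descent on the per-sample squared error
// eps(n) = 1/2 * sum_j (d_j - y_j)^2, presenting the rows of X in a freshly
// shuffled order each epoch. The full gradient for one sample is computed
// from the pre-update weights, then applied. Returns updated weights.
// [[Rcpp::export]]
List net_train_cpp(const NumericMatrix& X, const NumericMatrix& D,
                   const NumericMatrix& w_ih_, const NumericVector& b_h_,
                   const NumericMatrix& w_ho_, const NumericVector& b_o_,
                   int epochs, double eta, bool shuffle) {
  const int n = X.nrow();
  const int ni = w_ih_.nrow(), nh = w_ih_.ncol(), no = w_ho_.ncol();
  if (D.nrow() != n || D.ncol() != no || X.ncol() != ni)
    stop("training pair dimension mismatch");
  // flat working copies (column-major like R)
  std::vector<double> w_ih(w_ih_.begin(), w_ih_.end());
  std::vector<double> b_h(b_h_.begin(), b_h_.end());
  std::vector<double> w_ho(w_ho_.begin(), w_ho_.end());
  std::vector<double> b_o(b_o_.begin(), b_o_.end());
  const double* Xp = X.begin();
  const double* Dp = D.begin();
  std::vector<double> h(nh), y(no), go(no), gh(nh);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  RNGScope rngscope;
  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle && n > 1) {
      // Fisher-Yates on R's RNG: deterministic under set.seed()
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(ord[i], ord[j]);
      }
    }
    for (int s = 0; s < n; ++s) {
      const int r = ord[s];
      for (int j = 0; j < nh; ++j) {
        double v = b_h[j];
        for (int i = 0; i < ni; ++i) v += w_ih[i + j * ni] * Xp[r + i * n];
        h[j] = logistic(v);
      }
      for (int k = 0; k < no; ++k) {
        double v = b_o[k];
        for (int j = 0; j < nh; ++j) v += w_ho[j + k * nh] * h[j];
        y[k] = logistic(v);
      }
      // local gradients: go_k = e_k * y_k (1 - y_k), back through w_ho
      for (int k = 0; k < no; ++k)
        go[k] = (Dp[r + k * n] - y[k]) * y[k] * (1.0 - y[k]);
      for (int j = 0; j < nh; ++j) {
        double acc = 0.0;
        for (int k = 0; k < no; ++k) acc += go[k] * w_ho[j + k * nh];
        gh[j] = acc * h[j] * (1.0 - h[j]);
      }
      for (int k = 0; k < no; ++k) {
        const double g = eta * go[k];
        for (int j = 0; j < nh; ++j) w_ho[j + k * nh] += g * h[j];
        b_o[k] += g;
      }
      for (int j = 0; j < nh; ++j) {
        const double g = eta * gh[j];
        for (int i = 0; i < ni; ++i) w_ih[i + j * ni] += g * Xp[r + i * n];
        b_h[j] += g;
      }
    }
  }
  NumericMatrix W1(ni, nh), W2(nh, no);
  std::copy(w_ih.begin(), w_ih.end(), W1.begin());
  std::copy(w_ho.begin(), w_ho.end(), W2.begin());
  return List::create(_["w_ih"] = W1, _["b_h"] = NumericVector(b_h.begin(), b_h.end()),
                      _["w_ho"] = W2, _["b_o"] = NumericVector(b_o.begin(), b_o.end()));
}
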