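// Small deterministic multi-layer perceptron regressor (two hidden layers,
// tanh activations, scalar linear output) trained by full-batch Adam with an
// L2 weight penalty. Used to map similarity profiles to pseudotime; kept in
// C++ because cross-validated grid search retrains it many times.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  mat W1, W2;
  vec b1, b2, w3;
  double b3;
};

Net init_net(int p, int h1, int h2, unsigned int seed) {
  std::mt19937 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  Net n;
  auto fill = [&](mat &m, int r, int c, double sd) {
    m.set_size(r, c);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i = 0; i < m.n_rows; ++i) m(i, j) = gauss(rng) * sd;
  };
  fill(n.W1, p, h1, std::sqrt(1.0 / p));
  fill(n.W2, h1, h2, std::sqrt(1.0 / h1));
  mat w3m;
  fill(w3m, h2, 1, std::sqrt(1.0 / h2));
  n.w3 = w3m.col(0);
  n.b1 = zeros<vec>(h1);
  n.b2 = zeros<vec>(h2);
  n.b3 = 0.0;
  return n;
}

vec forward(const Net &n, const mat &X, mat &A1, mat &A2) {
  A1 = X * n.W1;
  A1.each_row() += n.b1.t();
  A1 = tanh(A1);
  A2 = A1 * n.W2;
  A2.each_row() += n.b2.t();
  A2 = tanh(A2);
  return A2 * n.w3 + n.b3;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List mlp_train(const arma::mat &X, const arma::vec &y, int h1, int h2,
                     double lambda, int epochs, double lr, double tol,
                     int patience, unsigned int seed) {
  const int p = X.n_cols;
  const double N = static_cast<double>(X.n_rows);
  Net n = init_net(p, h1, h2, seed);

  // Adam state
  mat mW1(size(n.W1), fill::zeros), vW1(size(n.W1), fill::zeros);
  mat mW2(size(n.W2), fill::zeros), vW2(size(n.W2), fill::zeros);
  vec mw3(size(n.w3), fill::zeros), vw3(size(n.w3), fill::zeros);
  vec mb1(size(n.b1), fill::zeros), vb1(size(n.b1), fill::zeros);
  vec mb2(size(n.b2), fill::zeros), vb2(size(n.b2), fill::zeros);
  double mb3 = 0, vb3 = 0;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  double best = datum::inf;
  int stall = 0;
  mat A1, A2;
  double loss = datum::inf;
  for (int t = 1; t <= epochs; ++t) {
    vec pred = forward(n, X, A1, A2);
    vec err = pred - y;
    loss = dot(err, err) / N +
           lambda * (accu(square(n.W1)) + accu(square(n.W2)) + dot(n.w3, n.w3));

    // backprop (MSE)
    vec d3 = 2.0 * err / N;                      // dL/dpred
    vec gw3 = A2.t() * d3 + 2.0 * lambda * n.w3;
    double gb3 = accu(d3);
    mat d2 = (d3 * n.w3.t()) % (1.0 - square(A2));
    mat gW2 = A1.t() * d2 + 2.0 * lambda * n.W2;
    vec gb2 = sum(d2, 0).t();
    mat d1 = (d2 * n.W2.t()) % (1.0 - square(A1));
    mat gW1 = X.t() * d1 + 2.0 * lambda * n.W1;
    vec gb1 = sum(d1, 0).t();

    const double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
    auto adam_m = [&](mat &w, mat &m, mat &v, const mat &g) {
      m = beta1 * m + (1 - beta1) * g;
      v = beta2 * v + (1 - beta2) * square(g);
      w -= lr * (m / c1) / (sqrt(v / c2) + eps);
    };
    auto adam_v = [&](vec &w, vec &m, vec &v, const vec &g) {
      m = beta1 * m + (1 - beta1) * g;
      v = beta2 * v + (1 - beta2) * square(g);
      w -= lr * (m / c1) / (sqrt(v / c2) + eps);
    };
    adam_m(n.W1, mW1, vW1, gW1);
    adam_m(n.W2, mW2, vW2, gW2);
    adam_v(n.w3, mw3, vw3, gw3);
    adam_v(n.b1, mb1, vb1, gb1);
    adam_v(n.b2, mb2, vb2, gb2);
    mb3 = beta1 * mb3 + (1 - beta1) * gb3;
    vb3 = beta2 * vb3 + (1 - beta2) * gb3 * gb3;
    n.b3 -= lr * (mb3 / c1) / (std::sqrt(vb3 / c2) + eps);

    if (loss < best - tol) {
      best = loss;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }
  vec fitted = forward(n, X, A1, A2);
  double mse = accu(square(fitted - y)) / N;
  return Rcpp::List::create(
      Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
      Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
      Rcpp::Named("w3") = n.w3, Rcpp::Named("b3") = n.b3,
      Rcpp::Named("loss") = mse);
}

// [[Rcpp::export]]
arma::vec mlp_forward(const Rcpp::List &fit, const arma::mat &X) {
  Net n;
  n.W1 = Rcpp::as<mat>(fit["W1"]);
  n.b1 = Rcpp::as<vec>(fit["b1"]);
  n.W2 = Rcpp::as<mat>(fit["W2"]);
  n.b2 = Rcpp::as<vec>(fit["b2"]);
  n.w3 = Rcpp::as<vec>(fit["w3"]);
  n.b3 = Rcpp::as<double>(fit["b3"]);
  mat A1, A2;
  return forward(n, X, A1, A2);
}
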