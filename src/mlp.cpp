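// Multilayer-perceptron regressor: ReLU hidden layers, linear output,
// Adam-optimised mean-squared-error loss. Deterministic given the seed
// (std::mt19937 drives init, shuffling and nothing else).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                   const IntegerVector& hidden_sizes,
                   int epochs, int batch_size, double lr, int seed) {
  const arma::uword n = X.n_rows;
  const arma::uword d = X.n_cols;
  std::vector<arma::uword> sizes;
  sizes.push_back(d);
  for (int h : hidden_sizes) sizes.push_back((arma::uword)h);
  sizes.push_back(1);
  const size_t L = sizes.size() - 1;  // number of weight layers

  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    W[l].set_size(sizes[l], sizes[l + 1]);
    double sdev = std::sqrt(2.0 / (double)sizes[l]);  // He initialisation
    for (arma::uword i = 0; i < W[l].n_rows; ++i)
      for (arma::uword j = 0; j < W[l].n_cols; ++j)
        W[l](i, j) = sdev * gauss(rng);
    b[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
    mW[l] = arma::mat(sizes[l], sizes[l + 1], arma::fill::zeros);
    vW[l] = mW[l];
    mb[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
    vb[l] = mb[l];
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<arma::uword> perm(n);
  for (arma::uword i = 0; i < n; ++i) perm[i] = i;
  arma::vec loss_trace(epochs, arma::fill::zeros);

  std::vector<arma::mat> act(L + 1), delta(L);
  for (int epoch = 0; epoch < epochs; ++epoch) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double epoch_loss = 0.0;
    arma::uword n_batches = 0;
    for (arma::uword start = 0; start < n; start += (arma::uword)batch_size) {
      arma::uword end = std::min(n, start + (arma::uword)batch_size);
      arma::uvec idx(end - start);
      for (arma::uword i = start; i < end; ++i) idx[i - start] = perm[i];
      act[0] = X.rows(idx);
      // forward
      for (size_t l = 0; l < L; ++l) {
        act[l + 1] = act[l] * W[l];
        act[l + 1].each_row() += b[l];
        if (l + 1 < L) act[l + 1].transform([](double v) { return v > 0 ? v : 0.0; });
      }
      arma::vec resid = act[L].col(0) - y.elem(idx);
      double batch_loss = arma::dot(resid, resid) / resid.n_elem;
      if (!std::isfinite(batch_loss))
        stop("non-finite training loss at epoch %d", epoch + 1);
      epoch_loss += batch_loss;
      ++n_batches;
      // backward: dL/dout = 2 resid / m
      delta[L - 1] = arma::mat(resid * (2.0 / resid.n_elem));
      ++t;
      double c1 = 1.0 - std::pow(beta1, (double)t);
      double c2 = 1.0 - std::pow(beta2, (double)t);
      for (size_t l = L; l-- > 0;) {
        if (l + 1 < L) {
          delta[l] = delta[l + 1] * W[l + 1].t();
          delta[l] %= arma::conv_to<arma::mat>::from(act[l + 1] > 0);
        }
        arma::mat gW = act[l].t() * delta[l];
        arma::rowvec gb = arma::sum(delta[l], 0);
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * (gW % gW);
        W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * (gb % gb);
        b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }
    loss_trace[epoch] = epoch_loss / n_batches;
  }

  List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) {
    Wl[l] = wrap(W[l]);
    bl[l] = wrap(b[l]);
  }
  return List::create(_["weights"] = Wl, _["biases"] = bl,
                      _["loss_trace"] = loss_trace);
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const arma::mat& X, const List& weights,
                          const List& biases) {
  arma::mat a = X;
  const size_t L = weights.size();
  for (size_t l = 0; l < L; ++l) {
    arma::mat W = as<arma::mat>(weights[l]);
    arma::rowvec b = as<arma::rowvec>(biases[l]);
    a = a * W;
    a.each_row() += b;
    if (l + 1 < L) a.transform([](double v) { return v > 0 ? v : 0.0; });
  }
  return a.col(0);
}
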