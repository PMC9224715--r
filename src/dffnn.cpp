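// Training core for deep feed-forward regressors (ReLU hidden layers, linear
// scalar output, minibatch MSE minimisation). Seven first-order optimizers are
// implemented with their conventional default secondary hyperparameters; only
// the learning rate is caller-controlled. Arithmetic is single precision, the
// customary precision for this model class; weights cross the R boundary as
// doubles.

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#define GAITFFDB_HAVE_FTZ 1
#endif

using arma::fmat;
using arma::fvec;

namespace {

// Subnormal single-precision values (below ~1e-38, far beneath any
// meaningful gradient) stall the FPU by orders of magnitude once they
// accumulate in the optimizers' squared-moment state. Flush them to zero
// for the duration of a training call; the previous FP environment is
// restored on exit.
struct FlushDenormalsGuard {
#ifdef GAITFFDB_HAVE_FTZ
  unsigned int saved_csr;
  FlushDenormalsGuard() : saved_csr(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormalsGuard() { _mm_setcsr(saved_csr); }
#endif
};

enum class Alg { SGD, RMSProp, Adam, Adadelta, Adagrad, Adamax, Nadam };

Alg parse_alg(const std::string &name) {
  if (name == "SGD")      return Alg::SGD;
  if (name == "RMSProp")  return Alg::RMSProp;
  if (name == "Adam")     return Alg::Adam;
  if (name == "Adadelta") return Alg::Adadelta;
  if (name == "Adagrad")  return Alg::Adagrad;
  if (name == "Adamax")   return Alg::Adamax;
  if (name == "Nadam")    return Alg::Nadam;
  Rcpp::stop("unknown training algorithm: '" + name + "'");
}

constexpr float EPS = 1e-7f;      // numerical-stability epsilon
constexpr float BETA1 = 0.9f;     // first-moment decay (Adam family)
constexpr float BETA2 = 0.999f;   // second-moment decay (Adam family)
constexpr float RHO_RMS = 0.9f;   // RMSProp decay
constexpr float RHO_ADL = 0.95f;  // Adadelta decay
constexpr float ADAGRAD_INIT = 0.1f;  // Adagrad initial accumulator

// One optimizer slot per parameter tensor: up to two state tensors.
struct OptState {
  fmat s1, s2;
};

void apply_update(Alg alg, fmat &w, const fmat &g, OptState &st, float lr,
                  long t) {
  switch (alg) {
  case Alg::SGD:
    w -= lr * g;
    break;
  case Alg::RMSProp:
    st.s1 = RHO_RMS * st.s1 + (1.0f - RHO_RMS) * arma::square(g);
    w -= lr * g / (arma::sqrt(st.s1) + EPS);
    break;
  case Alg::Adam: {
    st.s1 = BETA1 * st.s1 + (1.0f - BETA1) * g;
    st.s2 = BETA2 * st.s2 + (1.0f - BETA2) * arma::square(g);
    const float c1 = 1.0f - std::pow(BETA1, (float)t);
    const float c2 = 1.0f - std::pow(BETA2, (float)t);
    w -= lr * (st.s1 / c1) / (arma::sqrt(st.s2 / c2) + EPS);
    break;
  }
  case Alg::Adadelta: {
    st.s1 = RHO_ADL * st.s1 + (1.0f - RHO_ADL) * arma::square(g);
    fmat upd = arma::sqrt(st.s2 + EPS) / arma::sqrt(st.s1 + EPS) % g;
    st.s2 = RHO_ADL * st.s2 + (1.0f - RHO_ADL) * arma::square(upd);
    w -= lr * upd;
    break;
  }
  case Alg::Adagrad:
    st.s1 += arma::square(g);
    w -= lr * g / (arma::sqrt(st.s1) + EPS);
    break;
  case Alg::Adamax: {
    st.s1 = BETA1 * st.s1 + (1.0f - BETA1) * g;
    st.s2 = arma::max(BETA2 * st.s2, arma::abs(g));
    const float c1 = 1.0f - std::pow(BETA1, (float)t);
    w -= (lr / c1) * st.s1 / (st.s2 + EPS);
    break;
  }
  case Alg::Nadam: {
    // Dozat's formulation: Nesterov look-ahead applied to the Adam step.
    st.s1 = BETA1 * st.s1 + (1.0f - BETA1) * g;
    st.s2 = BETA2 * st.s2 + (1.0f - BETA2) * arma::square(g);
    const float c1 = 1.0f - std::pow(BETA1, (float)t);
    const float c1n = 1.0f - std::pow(BETA1, (float)(t + 1));
    const float c2 = 1.0f - std::pow(BETA2, (float)t);
    fmat mhat = (BETA1 / c1n) * st.s1 + ((1.0f - BETA1) / c1) * g;
    w -= lr * mhat / (arma::sqrt(st.s2 / c2) + EPS);
    break;
  }
  }
}

}  // namespace

// Glorot-uniform initial weights and zero biases for the layer dimension
// chain input_dim -> width x depth -> 1, drawn from a seeded Mersenne
// twister so initialisation is reproducible independently of R's RNG state.
// [[Rcpp::export]]
Rcpp::List cpp_init_dffnn(int input_dim, int width, int depth, int seed) {
  if (input_dim < 1 || width < 1 || depth < 1)
    Rcpp::stop("layer dimensions must be positive");
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> dims;
  dims.push_back(input_dim);
  for (int l = 0; l < depth; ++l) dims.push_back(width);
  dims.push_back(1);

  Rcpp::List weights(dims.size() - 1), biases(dims.size() - 1);
  for (size_t l = 0; l + 1 < dims.size(); ++l) {
    const int fan_in = dims[l], fan_out = dims[l + 1];
    const double limit = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<float> unif((float)-limit, (float)limit);
    arma::mat W(fan_in, fan_out);
    for (arma::uword j = 0; j < W.n_elem; ++j)
      W(j) = (double)unif(rng);
    weights[l] = W;
    biases[l] = arma::vec(fan_out, arma::fill::zeros);
  }
  return Rcpp::List::create(Rcpp::Named("weights") = weights,
                            Rcpp::Named("biases") = biases);
}

// Minibatch training. `weights`/`biases` hold the initial state (row index =
// source neuron, column index = destination neuron). The per-epoch loss is
// the size-weighted mean of minibatch MSEs (equivalently total SSE / n).
// Returns updated parameters, the loss history, and a divergence flag; on a
// non-finite loss training stops and the run is flagged, not aborted.
// [[Rcpp::export]]
Rcpp::List cpp_train_dffnn(const arma::mat &X, const arma::vec &y,
                           Rcpp::List weights, Rcpp::List biases,
                           std::string algorithm, double learning_rate,
                           int n_epoch, int batch_size, int seed) {
  const int n = (int)X.n_rows;
  const int L = weights.size();
  if (n < 1) Rcpp::stop("empty training data");
  if (n_epoch < 1 || batch_size < 1)
    Rcpp::stop("n_epoch and batch_size must be positive");
  const Alg alg = parse_alg(algorithm);
  const float lr = (float)learning_rate;
  FlushDenormalsGuard ftz_guard;

  std::vector<fmat> W(L);
  std::vector<fvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(weights[l]));
    b[l] = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(biases[l]));
  }
  if ((int)W[0].n_rows != (int)X.n_cols)
    Rcpp::stop("input dimension does not match first weight matrix");

  std::vector<OptState> stW(L), stB(L);
  for (int l = 0; l < L; ++l) {
    const float init = (alg == Alg::Adagrad) ? ADAGRAD_INIT : 0.0f;
    stW[l].s1.set_size(arma::size(W[l])); stW[l].s1.fill(init);
    stW[l].s2.zeros(arma::size(W[l]));
    stB[l].s1.set_size(b[l].n_elem, 1);  stB[l].s1.fill(init);
    stB[l].s2.zeros(b[l].n_elem, 1);
  }

  const fmat Xf = arma::conv_to<fmat>::from(X);
  const fvec yf = arma::conv_to<fvec>::from(y);

  std::mt19937 rng((uint32_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  arma::vec loss_history(n_epoch, arma::fill::value(NA_REAL));
  bool diverged = false;
  long t = 0;  // global update counter for bias-corrected methods
  std::vector<fmat> A(L + 1), Z(L);

  for (int epoch = 0; epoch < n_epoch && !diverged; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_sse = 0.0;

    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      const int m = stop - start;
      arma::uvec idx(m);
      for (int i = 0; i < m; ++i) idx[i] = (arma::uword)order[start + i];

      // forward
      A[0] = Xf.rows(idx);
      for (int l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l].t();
        A[l + 1] = (l == L - 1) ? Z[l] : arma::clamp(Z[l], 0.0f,
                                                    arma::datum::inf);
      }
      const fvec err = A[L].col(0) - yf.elem(idx);
      epoch_sse += (double)arma::dot(err, err);

      // backward: dL/dyhat for the batch-mean MSE objective
      fmat delta = (2.0f / (float)m) * err;
      ++t;
      for (int l = L - 1; l >= 0; --l) {
        const fmat gW = A[l].t() * delta;
        const fmat gb = arma::sum(delta, 0).t();
        if (l > 0) {
          delta = delta * W[l].t();
          delta.elem(arma::find(Z[l - 1] <= 0.0f)).zeros();
        }
        apply_update(alg, W[l], gW, stW[l], lr, t);
        fmat bcol(b[l].n_elem, 1);
        bcol.col(0) = b[l];
        apply_update(alg, bcol, gb, stB[l], lr, t);
        b[l] = bcol.col(0);
      }
    }

    const double epoch_loss = epoch_sse / (double)n;
    loss_history[epoch] = epoch_loss;
    if (!std::isfinite(epoch_loss)) diverged = true;
  }

  Rcpp::List outW(L), outB(L);
  for (int l = 0; l < L; ++l) {
    outW[l] = arma::conv_to<arma::mat>::from(W[l]);
    outB[l] = arma::conv_to<arma::vec>::from(b[l]);
  }
  return Rcpp::List::create(Rcpp::Named("weights") = outW,
                            Rcpp::Named("biases") = outB,
                            Rcpp::Named("loss_history") = loss_history,
                            Rcpp::Named("diverged") = diverged);
}
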