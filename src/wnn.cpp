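// Dilated 2D convolution network used by the reconstruction cascade and the
// uncertainty estimator.  Valid (no-padding) convolutions only; all layers are
// expressed through an im2col lowering so the heavy lifting is a GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Layer {
  arma::mat W;  // n_out x (kh * kw * n_in)
  arma::vec b;  // n_out
  int kh, kw, dh, dw;
  bool relu;
};

std::vector<Layer> parseLayers(const List& layers) {
  std::vector<Layer> out;
  const int n = layers.size();
  out.reserve(n);
  for (int i = 0; i < n; ++i) {
    List li = layers[i];
    Layer L;
    L.W = as<arma::mat>(li["W"]);
    L.b = as<arma::vec>(li["b"]);
    L.kh = as<int>(li["kh"]);
    L.kw = as<int>(li["kw"]);
    L.dh = as<int>(li["dh"]);
    L.dw = as<int>(li["dw"]);
    L.relu = as<bool>(li["relu"]);
    if (L.W.n_rows != L.b.n_elem) stop("layer weight/bias mismatch");
    out.push_back(L);
  }
  return out;
}

// Lower the (H, W, C) activation cube into a (kh*kw*C) x (Ho*Wo) matrix of
// dilated receptive-field patches (column-major within each patch window).
arma::mat im2col(const arma::cube& x, const Layer& L, int Ho, int Wo) {
  const int C = x.n_slices;
  arma::mat cols(L.kh * L.kw * C, (arma::uword)Ho * Wo);
  int r = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < L.kw; ++j)
      for (int i = 0; i < L.kh; ++i)
        cols.row(r++) = arma::vectorise(
            x.slice(c).submat(i * L.dh, j * L.dw,
                              i * L.dh + Ho - 1, j * L.dw + Wo - 1)).t();
  return cols;
}

void col2imAdd(arma::cube& gx, const arma::mat& gcols, const Layer& L,
               int Ho, int Wo) {
  const int C = gx.n_slices;
  int r = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < L.kw; ++j)
      for (int i = 0; i < L.kh; ++i)
        gx.slice(c).submat(i * L.dh, j * L.dw,
                           i * L.dh + Ho - 1, j * L.dw + Wo - 1) +=
            arma::reshape(gcols.row(r++), Ho, Wo);
  ;
}

arma::cube toCube(const arma::mat& z, int Ho, int Wo) {
  arma::cube out(Ho, Wo, z.n_rows);
  for (arma::uword c = 0; c < z.n_rows; ++c)
    out.slice(c) = arma::reshape(z.row(c), Ho, Wo);
  return out;
}

}  // namespace

// [[Rcpp::export]]
arma::mat cppWnnForward(const arma::mat& input, const List& layers) {
  std::vector<Layer> ls = parseLayers(layers);
  arma::cube x(input.n_rows, input.n_cols, 1);
  x.slice(0) = input;
  for (size_t k = 0; k < ls.size(); ++k) {
    const Layer& L = ls[k];
    const int Ho = (int)x.n_rows - (L.kh - 1) * L.dh;
    const int Wo = (int)x.n_cols - (L.kw - 1) * L.dw;
    if (Ho < 1 || Wo < 1) stop("input extent smaller than the receptive field");
    arma::mat z = L.W * im2col(x, L, Ho, Wo);
    z.each_col() += L.b;
    if (L.relu) z.elem(arma::find(z < 0)).zeros();
    x = toCube(z, Ho, Wo);
  }
  if (x.n_slices != 1) stop("network must end in a single channel");
  return x.slice(0);
}

// Forward + loss + full backward pass for a single patch.
// loss = "mse": target is the desired output patch.
// loss = "nll": target holds squared residuals (y - mu)^2; the network output
//   is the raw sigma, rectified and floored before entering the Gaussian
//   negative log-likelihood.
// [[Rcpp::export]]
List cppWnnGrad(const arma::mat& input, const List& layers,
                const arma::mat& target, std::string loss,
                double sigmaFloor) {
  std::vector<Layer> ls = parseLayers(layers);
  const size_t n = ls.size();
  std::vector<arma::cube> acts(n + 1);
  std::vector<arma::mat> zs(n), colsCache(n);
  acts[0] = arma::cube(input.n_rows, input.n_cols, 1);
  acts[0].slice(0) = input;
  for (size_t k = 0; k < n; ++k) {
    const Layer& L = ls[k];
    const int Ho = (int)acts[k].n_rows - (L.kh - 1) * L.dh;
    const int Wo = (int)acts[k].n_cols - (L.kw - 1) * L.dw;
    if (Ho < 1 || Wo < 1) stop("input extent smaller than the receptive field");
    colsCache[k] = im2col(acts[k], L, Ho, Wo);
    arma::mat z = L.W * colsCache[k];
    z.each_col() += L.b;
    zs[k] = z;
    arma::mat a = z;
    if (L.relu) a.elem(arma::find(a < 0)).zeros();
    acts[k + 1] = toCube(a, Ho, Wo);
  }
  arma::mat out = acts[n].slice(0);
  if (out.n_rows != target.n_rows || out.n_cols != target.n_cols)
    stop("target extent does not match the network output");
  const double N = (double)out.n_elem;
  double lossVal;
  arma::mat dOut;
  if (loss == "mse") {
    arma::mat d = out - target;
    lossVal = arma::accu(arma::square(d)) / N;
    dOut = 2.0 * d / N;
  } else if (loss == "nll") {
    arma::mat sigma = out;
    sigma.elem(arma::find(sigma < 0)).zeros();
    sigma += sigmaFloor;
    lossVal = arma::accu(target / (2.0 * arma::square(sigma)) +
                         arma::log(sigma)) / N;
    arma::mat dSigma = (-target / arma::pow(sigma, 3) + 1.0 / sigma) / N;
    // Forward semantics are exact ReLU + floor; the backward pass leaks a
    // small slope through the rectified region so sigma points driven
    // negative can recover instead of going gradient-dead at the floor.
    arma::mat gate = arma::conv_to<arma::mat>::from(out > 0);
    gate.elem(arma::find(gate == 0)).fill(0.01);
    dOut = dSigma % gate;
  } else {
    stop("unknown loss");
  }

  List grads(n);
  arma::cube g(out.n_rows, out.n_cols, 1);
  g.slice(0) = dOut;
  for (int k = (int)n - 1; k >= 0; --k) {
    const Layer& L = ls[k];
    const int Ho = g.n_rows, Wo = g.n_cols;
    arma::mat G(L.W.n_rows, (arma::uword)Ho * Wo);
    for (arma::uword c = 0; c < g.n_slices; ++c)
      G.row(c) = arma::vectorise(g.slice(c)).t();
    if (L.relu) G %= arma::conv_to<arma::mat>::from(zs[k] > 0);
    arma::mat gW = G * colsCache[k].t();
    arma::vec gb = arma::sum(G, 1);
    grads[k] = List::create(Named("W") = gW, Named("b") = gb);
    if (k > 0) {
      arma::mat gcols = ls[k].W.t() * G;
      arma::cube gx(acts[k].n_rows, acts[k].n_cols, acts[k].n_slices,
                    arma::fill::zeros);
      col2imAdd(gx, gcols, L, Ho, Wo);
      g = gx;
    }
  }
  return List::create(Named("loss") = lossVal,
                      Named("output") = out,
                      Named("grads") = grads);
}
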