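// Compact fully convolutional 3D classifier: forward and backward passes.
//
// Architecture (fixed topology, configurable width/depth):
//   n blocks of [3x3x3 conv (zero pad 1) -> instance norm -> ReLU ->
//   2x average pooling], then dropout on the flattened features, one linear
//   layer to 2 logits, softmax. Loss: mean cross-entropy over the batch.
//
// Layouts (all column-major, voxel index v = x + d*y + d*d*z):
//   activations: V x C matrices (one column per channel)
//   conv weights: (C_in*27) x C_out, row r = c_in*27 + o with kernel offset
//     o = (dx+1) + 3*(dy+1) + 9*(dz+1), dx fastest
//   fc weights: F x 2 (feature vector = vectorized V_last x C_last block)
//
// Dropout masks are drawn from a splitmix64 stream seeded per batch so
// training is bit-reproducible across platforms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Zero-padded 3x3x3 im2col: X (V x C) -> K (V x C*27).
void im2col3(const arma::mat& X, int d, arma::mat& K) {
  const int C = X.n_cols;
  K.zeros();
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int z0 = std::max(0, -dz), z1 = d - 1 - std::max(0, dz);
        const int y0 = std::max(0, -dy), y1 = d - 1 - std::max(0, dy);
        const int x0 = std::max(0, -dx), x1 = d - 1 - std::max(0, dx);
        const int len = x1 - x0 + 1;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          const double* src = X.colptr(c);
          double* dst = K.colptr(c * 27 + o);
          for (int z = z0; z <= z1; ++z) {
            for (int y = y0; y <= y1; ++y) {
              const int v = x0 + d * (y + d * z);
              const int vs = (x0 + dx) + d * ((y + dy) + d * (z + dz));
              std::memcpy(dst + v, src + vs, len * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// Adjoint of im2col3: scatter-add dK (V x C*27) back into dX (V x C).
void col2im3(const arma::mat& dK, int d, arma::mat& dX) {
  const int C = dX.n_cols;
  dX.zeros();
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int z0 = std::max(0, -dz), z1 = d - 1 - std::max(0, dz);
        const int y0 = std::max(0, -dy), y1 = d - 1 - std::max(0, dy);
        const int x0 = std::max(0, -dx), x1 = d - 1 - std::max(0, dx);
        const int len = x1 - x0 + 1;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          const double* src = dK.colptr(c * 27 + o);
          double* dst = dX.colptr(c);
          for (int z = z0; z <= z1; ++z) {
            for (int y = y0; y <= y1; ++y) {
              const int v = x0 + d * (y + d * z);
              const int vs = (x0 + dx) + d * ((y + dy) + d * (z + dz));
              for (int i = 0; i < len; ++i) dst[vs + i] += src[v + i];
            }
          }
        }
      }
    }
  }
}

// 2x average pooling, floor semantics (a trailing odd slice is dropped).
arma::mat pool2(const arma::mat& A, int d, int dp) {
  const int C = A.n_cols;
  arma::mat P(dp * dp * dp, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    double* dst = P.colptr(c);
    for (int Z = 0; Z < dp; ++Z)
      for (int Y = 0; Y < dp; ++Y)
        for (int X = 0; X < dp; ++X) {
          double s = 0.0;
          for (int cz = 0; cz < 2; ++cz)
            for (int cy = 0; cy < 2; ++cy)
              for (int cx = 0; cx < 2; ++cx)
                s += src[(2 * X + cx) + d * ((2 * Y + cy) + d * (2 * Z + cz))];
          dst[X + dp * (Y + dp * Z)] = s / 8.0;
        }
  }
  return P;
}

arma::mat unpool2(const arma::mat& dP, int d, int dp) {
  const int C = dP.n_cols;
  arma::mat dA(d * d * d, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = dP.colptr(c);
    double* dst = dA.colptr(c);
    for (int Z = 0; Z < dp; ++Z)
      for (int Y = 0; Y < dp; ++Y)
        for (int X = 0; X < dp; ++X) {
          const double g = src[X + dp * (Y + dp * Z)] / 8.0;
          for (int cz = 0; cz < 2; ++cz)
            for (int cy = 0; cy < 2; ++cy)
              for (int cx = 0; cx < 2; ++cx)
                dst[(2 * X + cx) + d * ((2 * Y + cy) + d * (2 * Z + cz))] += g;
        }
  }
  return dA;
}

const double kNormEps = 1e-5;

struct BlockCache {
  arma::mat K;       // im2col of the block input
  arma::mat xhat;    // normalized pre-activation
  arma::rowvec invstd;
  int d_in, d_out;
};

struct NetShape {
  int n_blocks;
  std::vector<int> c_in, c_out, d_in, d_out;
  int feat;  // flattened feature length
};

NetShape shape_from(const List& cfg) {
  NetShape s;
  const int grid = as<int>(cfg["grid"]);
  IntegerVector ch = cfg["channels"];
  s.n_blocks = ch.size();
  int d = grid, cin = 1;
  for (int k = 0; k < s.n_blocks; ++k) {
    s.c_in.push_back(cin);
    s.c_out.push_back(ch[k]);
    s.d_in.push_back(d);
    s.d_out.push_back(d / 2);
    d /= 2;
    cin = ch[k];
    if (d < 1) stop("grid collapses below 1 voxel: too many blocks for this grid");
  }
  s.feat = cin * d * d * d;
  return s;
}

// Forward through the conv trunk for one sample; optionally fills caches.
arma::vec trunk_forward(const arma::mat& x0, const List& conv_w,
                        const List& conv_b, const NetShape& s,
                        std::vector<BlockCache>* caches) {
  arma::mat X = x0;  // V x C
  for (int k = 0; k < s.n_blocks; ++k) {
    const arma::mat& W = as<arma::mat>(conv_w[k]);
    const arma::vec& b = as<arma::vec>(conv_b[k]);
    const int d = s.d_in[k], V = d * d * d;
    arma::mat K(V, s.c_in[k] * 27);
    im2col3(X, d, K);
    arma::mat Z = K * W;
    Z.each_row() += b.t();
    // parameter-free instance norm per channel
    arma::rowvec mu = arma::mean(Z, 0);
    arma::rowvec var = arma::mean(arma::square(Z), 0) - arma::square(mu);
    arma::rowvec invstd = 1.0 / arma::sqrt(var + kNormEps);
    Z.each_row() -= mu;
    Z.each_row() %= invstd;
    arma::mat xhat;
    if (caches) xhat = Z;
    // ReLU
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    const int dp = s.d_out[k];
    arma::mat P = pool2(Z, d, dp);
    if (caches) {
      BlockCache bc;
      bc.K = std::move(K);
      bc.xhat = std::move(xhat);
      bc.invstd = invstd;
      bc.d_in = d;
      bc.d_out = dp;
      (*caches)[k] = std::move(bc);
    }
    X = std::move(P);
  }
  return arma::vectorise(X);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cnn_batch_predict_cpp")]]
arma::vec cnn_batch_predict_cpp(List params, List cfg, const arma::mat& xbatch) {
  const NetShape s = shape_from(cfg);
  const int V0 = s.d_in[0] * s.d_in[0] * s.d_in[0];
  if ((int)xbatch.n_rows != V0)
    stop("volume length %d does not match grid^3 = %d", (int)xbatch.n_rows, V0);
  List conv_w = params["conv_w"], conv_b = params["conv_b"];
  const arma::mat& fc_w = as<arma::mat>(params["fc_w"]);
  const arma::vec& fc_b = as<arma::vec>(params["fc_b"]);
  if ((int)fc_w.n_rows != s.feat) stop("fc weight shape mismatch");
  const int N = xbatch.n_cols;
  arma::vec out(N);
  for (int i = 0; i < N; ++i) {
    arma::mat x0 = xbatch.col(i);
    arma::vec f = trunk_forward(x0, conv_w, conv_b, s, nullptr);
    arma::vec logits = fc_w.t() * f + fc_b;
    const double m = logits.max();
    arma::vec e = arma::exp(logits - m);
    out[i] = e[1] / arma::accu(e);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cnn_batch_grad_cpp")]]
List cnn_batch_grad_cpp(List params, List cfg, const arma::mat& xbatch,
                        IntegerVector labels, double dropout_rate,
                        int dropout_seed) {
  const NetShape s = shape_from(cfg);
  const int V0 = s.d_in[0] * s.d_in[0] * s.d_in[0];
  if ((int)xbatch.n_rows != V0) stop("volume length does not match grid^3");
  const int N = xbatch.n_cols;
  if (labels.size() != N) stop("labels length != batch size");

  List conv_w = params["conv_w"], conv_b = params["conv_b"];
  const arma::mat& fc_w = as<arma::mat>(params["fc_w"]);
  const arma::vec& fc_b = as<arma::vec>(params["fc_b"]);

  // gradient accumulators
  std::vector<arma::mat> g_w(s.n_blocks);
  std::vector<arma::vec> g_b(s.n_blocks);
  for (int k = 0; k < s.n_blocks; ++k) {
    g_w[k].zeros(as<arma::mat>(conv_w[k]).n_rows, as<arma::mat>(conv_w[k]).n_cols);
    g_b[k].zeros(as<arma::vec>(conv_b[k]).n_elem);
  }
  arma::mat g_fc_w(fc_w.n_rows, fc_w.n_cols, arma::fill::zeros);
  arma::vec g_fc_b(2, arma::fill::zeros);

  SplitMix64 rng((uint64_t)(uint32_t)dropout_seed);
  double loss_sum = 0.0;

  for (int i = 0; i < N; ++i) {
    arma::mat x0 = xbatch.col(i);
    std::vector<BlockCache> caches(s.n_blocks);
    arma::vec f = trunk_forward(x0, conv_w, conv_b, s, &caches);

    // inverted dropout on the flattened features
    arma::vec mask(s.feat, arma::fill::ones);
    if (dropout_rate > 0.0) {
      const double keep = 1.0 - dropout_rate;
      for (int j = 0; j < s.feat; ++j)
        mask[j] = (rng.unif() >= dropout_rate) ? 1.0 / keep : 0.0;
    }
    arma::vec fd = f % mask;

    arma::vec logits = fc_w.t() * fd + fc_b;
    const double m = logits.max();
    arma::vec e = arma::exp(logits - m);
    arma::vec p = e / arma::accu(e);
    const int y = labels[i];
    if (y != 0 && y != 1) stop("labels must be 0/1");
    loss_sum += -std::log(std::max(p[y], 1e-300));

    arma::vec dlogits = p;
    dlogits[y] -= 1.0;
    g_fc_w += fd * dlogits.t();
    g_fc_b += dlogits;
    arma::vec df = (fc_w * dlogits) % mask;

    // back through the trunk
    const int dl = s.d_out[s.n_blocks - 1];
    arma::mat dP(df.memptr(), dl * dl * dl, s.c_out[s.n_blocks - 1]);
    for (int k = s.n_blocks - 1; k >= 0; --k) {
      BlockCache& bc = caches[k];
      arma::mat dA = unpool2(dP, bc.d_in, bc.d_out);
      // ReLU mask (xhat > 0)
      dA %= arma::conv_to<arma::mat>::from(bc.xhat > 0.0);
      // instance-norm backward per channel
      arma::rowvec mean_dh = arma::mean(dA, 0);
      arma::rowvec mean_dhx = arma::mean(dA % bc.xhat, 0);
      arma::mat dZ = dA;
      dZ.each_row() -= mean_dh;
      arma::mat xh_scaled = bc.xhat;
      xh_scaled.each_row() %= mean_dhx;
      dZ -= xh_scaled;
      dZ.each_row() %= bc.invstd;
      g_w[k] += bc.K.t() * dZ;
      g_b[k] += arma::sum(dZ, 0).t();
      if (k > 0) {
        const arma::mat& W = as<arma::mat>(conv_w[k]);
        arma::mat dK = dZ * W.t();
        arma::mat dX(bc.d_in * bc.d_in * bc.d_in, s.c_in[k]);
        col2im3(dK, bc.d_in, dX);
        dP = std::move(dX);
      }
    }
  }

  // biases are plain R vectors in the parameter list; return their gradients
  // dimensionless so shapes match the parameters exactly
  const double inv_n = 1.0 / N;
  List out_w(s.n_blocks), out_b(s.n_blocks);
  for (int k = 0; k < s.n_blocks; ++k) {
    out_w[k] = wrap(arma::mat(g_w[k] * inv_n));
    arma::vec gb = g_b[k] * inv_n;
    out_b[k] = NumericVector(gb.begin(), gb.end());
  }
  arma::vec gfb = g_fc_b * inv_n;
  return List::create(
      _["loss"] = loss_sum * inv_n,
      _["grads"] = List::create(_["conv_w"] = out_w, _["conv_b"] = out_b,
                                _["fc_w"] = wrap(arma::mat(g_fc_w * inv_n)),
                                _["fc_b"] = NumericVector(gfb.begin(), gfb.end())));
}
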