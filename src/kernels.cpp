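// Dense 3D convolution / pooling kernels and Gaussian voxelization.
//
// Volumes are stored as arma::mat with one row per channel and one column per
// voxel; voxel (x, y, z) of an N^3 grid lives in column x + N*(y + N*z).
// This matches the memory layout of an R array with dim c(C, N, N, N).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// voxelization
// ---------------------------------------------------------------------------

// Truncated Gaussian density kernel: exp(-2 d^2 / r^2) for d <= r, a quartic
// continuation for r < d <= 1.5 r (value and slope continuous at d = r,
// zero at 1.5 r), and exactly zero beyond.
static inline double density_kernel(double d, double r) {
  const double u = d / r;
  if (u <= 1.0) return std::exp(-2.0 * u * u);
  if (u <= 1.5) {
    const double e2 = std::exp(-2.0);
    const double u2 = u * u;
    return e2 * (0.96 * u2 * u2 - 3.92 * u2 + 3.96);
  }
  return 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_voxelize(IntegerVector channel, NumericMatrix coords,
                           NumericVector radius, int n_channels, int nvox,
                           double spacing, NumericVector center,
                           NumericMatrix rot, NumericVector trans) {
  const int n_atoms = channel.size();
  const int N = nvox;
  const size_t nv = (size_t)N * N * N;
  NumericVector out((size_t)n_channels * nv);
  out.attr("dim") = IntegerVector::create(n_channels, N, N, N);
  double* g = REAL(out);
  // voxel i sits at center + (i - N/2) * spacing, so voxel N/2 is exactly
  // at the grid center
  const double orig = -(double)(N / 2) * spacing;

  for (int a = 0; a < n_atoms; ++a) {
    // rotate about the grid center, then translate
    double px = coords(a, 0) - center[0];
    double py = coords(a, 1) - center[1];
    double pz = coords(a, 2) - center[2];
    double qx = rot(0, 0) * px + rot(0, 1) * py + rot(0, 2) * pz + trans[0];
    double qy = rot(1, 0) * px + rot(1, 1) * py + rot(1, 2) * pz + trans[1];
    double qz = rot(2, 0) * px + rot(2, 1) * py + rot(2, 2) * pz + trans[2];
    if (!std::isfinite(qx) || !std::isfinite(qy) || !std::isfinite(qz))
      stop("non-finite coordinate after transform for atom %d", a + 1);
    const double r = radius[a];
    const double cut = 1.5 * r;
    const int c = channel[a];
    // voxel index range overlapped by the truncated kernel
    int x0 = (int)std::ceil((qx - cut - orig) / spacing);
    int x1 = (int)std::floor((qx + cut - orig) / spacing);
    int y0 = (int)std::ceil((qy - cut - orig) / spacing);
    int y1 = (int)std::floor((qy + cut - orig) / spacing);
    int z0 = (int)std::ceil((qz - cut - orig) / spacing);
    int z1 = (int)std::floor((qz + cut - orig) / spacing);
    x0 = std::max(x0, 0); y0 = std::max(y0, 0); z0 = std::max(z0, 0);
    x1 = std::min(x1, N - 1); y1 = std::min(y1, N - 1); z1 = std::min(z1, N - 1);
    for (int z = z0; z <= z1; ++z) {
      const double dz = orig + z * spacing - qz;
      for (int y = y0; y <= y1; ++y) {
        const double dy = orig + y * spacing - qy;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > cut * cut) continue;
        for (int x = x0; x <= x1; ++x) {
          const double dx = orig + x * spacing - qx;
          const double d2 = dx * dx + dyz2;
          if (d2 > cut * cut) continue;
          const double dens = density_kernel(std::sqrt(d2), r);
          if (dens > 0.0)
            g[c + (size_t)n_channels * (x + (size_t)N * (y + (size_t)N * z))] += dens;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// conv / pool primitives
// ---------------------------------------------------------------------------

// im2col for a 3x3x3 kernel with padding 1: P is (27*C) x N^3, with the
// C-row block for kernel offset (kx, ky, kz) at row offset C*(kx+3*(ky+3*kz)).
static void im2col_k3(const arma::mat& X, int C, int N, arma::mat& P) {
  P.zeros();
  const double* xp = X.memptr();
  double* pp = P.memptr();
  const size_t nrowP = (size_t)27 * C;
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const size_t koff = (size_t)C * (kx + 3 * (ky + 3 * kz));
        for (int oz = 0; oz < N; ++oz) {
          const int iz = oz + kz - 1;
          if (iz < 0 || iz >= N) continue;
          for (int oy = 0; oy < N; ++oy) {
            const int iy = oy + ky - 1;
            if (iy < 0 || iy >= N) continue;
            const int ox0 = std::max(0, 1 - kx);
            const int ox1 = std::min(N, N + 1 - kx);  // exclusive
            if (ox1 <= ox0) continue;
            const int ix0 = ox0 + kx - 1;
            const double* src = xp + (size_t)C * (ix0 + (size_t)N * (iy + (size_t)N * iz));
            double* dst = pp + nrowP * (ox0 + (size_t)N * (oy + (size_t)N * oz)) + koff;
            for (int t = 0; t < ox1 - ox0; ++t)
              std::memcpy(dst + nrowP * t, src + (size_t)C * t, C * sizeof(double));
          }
        }
      }
}

// transpose of im2col_k3: scatter-add patch gradients back onto the volume
static void col2im_k3(const arma::mat& dP, int C, int N, arma::mat& dX) {
  dX.zeros();
  const double* pp = dP.memptr();
  double* xp = dX.memptr();
  const size_t nrowP = (size_t)27 * C;
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const size_t koff = (size_t)C * (kx + 3 * (ky + 3 * kz));
        for (int oz = 0; oz < N; ++oz) {
          const int iz = oz + kz - 1;
          if (iz < 0 || iz >= N) continue;
          for (int oy = 0; oy < N; ++oy) {
            const int iy = oy + ky - 1;
            if (iy < 0 || iy >= N) continue;
            const int ox0 = std::max(0, 1 - kx);
            const int ox1 = std::min(N, N + 1 - kx);
            if (ox1 <= ox0) continue;
            const int ix0 = ox0 + kx - 1;
            double* dst = xp + (size_t)C * (ix0 + (size_t)N * (iy + (size_t)N * iz));
            const double* src = pp + nrowP * (ox0 + (size_t)N * (oy + (size_t)N * oz)) + koff;
            for (int t = 0; t < ox1 - ox0; ++t) {
              const double* s = src + nrowP * t;
              double* d = dst + (size_t)C * t;
              for (int c = 0; c < C; ++c) d[c] += s[c];
            }
          }
        }
      }
}

// 2x2x2 average pooling, stride 2 (N even)
static arma::mat avgpool2(const arma::mat& X, int N) {
  const int M = N / 2;
  const int C = X.n_rows;
  arma::mat Y(C, (size_t)M * M * M, arma::fill::zeros);
  const double* xp = X.memptr();
  double* yp = Y.memptr();
  for (int z = 0; z < N; ++z)
    for (int y = 0; y < N; ++y) {
      double* yrow = yp + (size_t)C * M * ((y / 2) + (size_t)M * (z / 2));
      const double* xrow = xp + (size_t)C * N * (y + (size_t)N * z);
      for (int x = 0; x < N; ++x) {
        double* d = yrow + (size_t)C * (x / 2);
        const double* s = xrow + (size_t)C * x;
        for (int c = 0; c < C; ++c) d[c] += s[c];
      }
    }
  Y *= 0.125;
  return Y;
}

static arma::mat avgpool2_back(const arma::mat& dY, int N) {
  const int M = N / 2;
  const int C = dY.n_rows;
  arma::mat dX(C, (size_t)N * N * N);
  const double* yp = dY.memptr();
  double* xp = dX.memptr();
  for (int z = 0; z < N; ++z)
    for (int y = 0; y < N; ++y) {
      const double* yrow = yp + (size_t)C * M * ((y / 2) + (size_t)M * (z / 2));
      double* xrow = xp + (size_t)C * N * (y + (size_t)N * z);
      for (int x = 0; x < N; ++x) {
        const double* s = yrow + (size_t)C * (x / 2);
        double* d = xrow + (size_t)C * x;
        for (int c = 0; c < C; ++c) d[c] = 0.125 * s[c];
      }
    }
  return dX;
}

// fused in-place bias add + optional ReLU
static void bias_relu(arma::mat& M, const arma::vec& b, bool relu) {
  const int C = M.n_rows;
  const size_t n = M.n_cols;
  double* p = M.memptr();
  const double* bp = b.memptr();
  for (size_t j = 0; j < n; ++j, p += C)
    for (int c = 0; c < C; ++c) {
      double v = p[c] + bp[c];
      p[c] = (relu && v < 0) ? 0.0 : v;
    }
}

// in-place ReLU mask: dz[i] = 0 where the forward activation was clipped
static void relu_mask(arma::mat& dz, const arma::mat& y) {
  double* d = dz.memptr();
  const double* yp = y.memptr();
  const size_t n = dz.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (yp[i] <= 0) d[i] = 0.0;
}

// ---------------------------------------------------------------------------
// the fixed conv stack:
// pool - conv(C,32,k3) - relu - conv(32,32,k1) - relu - pool -
// conv(32,64,k3) - relu - conv(64,64,k1) - relu - pool -
// conv(64,128,k3) - relu - pool - conv(128,8,k3) - flatten - linear
// ---------------------------------------------------------------------------

struct NetParams {
  arma::mat W1, W2, W3, W4, W5, W6, WL;
  arma::vec b1, b2, b3, b4, b5, b6, bL;
};

static NetParams unpack(const List& w) {
  NetParams p;
  p.W1 = as<arma::mat>(w[0]);  p.b1 = as<arma::vec>(w[1]);
  p.W2 = as<arma::mat>(w[2]);  p.b2 = as<arma::vec>(w[3]);
  p.W3 = as<arma::mat>(w[4]);  p.b3 = as<arma::vec>(w[5]);
  p.W4 = as<arma::mat>(w[6]);  p.b4 = as<arma::vec>(w[7]);
  p.W5 = as<arma::mat>(w[8]);  p.b5 = as<arma::vec>(w[9]);
  p.W6 = as<arma::mat>(w[10]); p.b6 = as<arma::vec>(w[11]);
  p.WL = as<arma::mat>(w[12]); p.bL = as<arma::vec>(w[13]);
  return p;
}

static List pack(const NetParams& p) {
  return List::create(p.W1, p.b1, p.W2, p.b2, p.W3, p.b3, p.W4, p.b4,
                      p.W5, p.b5, p.W6, p.b6, p.WL, p.bL);
}

struct Workspace {           // per-sample activations (sizes fixed by C, N)
  arma::mat p1, P1, y1, y2;  // edge N/2
  arma::mat p2, P2, y3, y4;  // edge N/4
  arma::mat p3, P3, y5;      // edge N/8
  arma::mat p4, P4, z6;      // edge N/16
};

// forward pass; x is (C x N^3); returns raw class scores, fills ws
static arma::vec net_forward(const NetParams& p, const arma::mat& x, int C,
                             int N, Workspace& ws) {
  const int N2 = N / 2, N4 = N / 4, N8 = N / 8, N16 = N / 16;
  ws.p1 = avgpool2(x, N);
  ws.P1.set_size((size_t)27 * C, ws.p1.n_cols);
  im2col_k3(ws.p1, C, N2, ws.P1);
  ws.y1 = p.W1 * ws.P1;  bias_relu(ws.y1, p.b1, true);
  ws.y2 = p.W2 * ws.y1;  bias_relu(ws.y2, p.b2, true);
  ws.p2 = avgpool2(ws.y2, N2);
  ws.P2.set_size(27 * 32, ws.p2.n_cols);
  im2col_k3(ws.p2, 32, N4, ws.P2);
  ws.y3 = p.W3 * ws.P2;  bias_relu(ws.y3, p.b3, true);
  ws.y4 = p.W4 * ws.y3;  bias_relu(ws.y4, p.b4, true);
  ws.p3 = avgpool2(ws.y4, N4);
  ws.P3.set_size(27 * 64, ws.p3.n_cols);
  im2col_k3(ws.p3, 64, N8, ws.P3);
  ws.y5 = p.W5 * ws.P3;  bias_relu(ws.y5, p.b5, true);
  ws.p4 = avgpool2(ws.y5, N8);
  ws.P4.set_size(27 * 128, ws.p4.n_cols);
  im2col_k3(ws.p4, 128, N16, ws.P4);
  ws.z6 = p.W6 * ws.P4;  bias_relu(ws.z6, p.b6, false);  // no activation before flatten
  arma::vec f = arma::vectorise(ws.z6);
  return p.WL * f + p.bL;
}

// backward pass from d(scores); accumulates into g
static void net_backward(const NetParams& p, const Workspace& ws,
                         const arma::vec& ds, int C, int N, NetParams& g) {
  const int N2 = N / 2, N4 = N / 4, N8 = N / 8;
  arma::vec f = arma::vectorise(ws.z6);
  g.WL += ds * f.t();
  g.bL += ds;
  arma::vec df = p.WL.t() * ds;
  arma::mat dz6(df.memptr(), ws.z6.n_rows, ws.z6.n_cols);
  g.W6 += dz6 * ws.P4.t();
  g.b6 += arma::sum(dz6, 1);
  arma::mat dP4 = p.W6.t() * dz6;
  arma::mat dp4(128, ws.p4.n_cols);
  col2im_k3(dP4, 128, N / 16, dp4);
  arma::mat dz5 = avgpool2_back(dp4, N8);
  relu_mask(dz5, ws.y5);
  g.W5 += dz5 * ws.P3.t();
  g.b5 += arma::sum(dz5, 1);
  arma::mat dP3 = p.W5.t() * dz5;
  arma::mat dp3(64, ws.p3.n_cols);
  col2im_k3(dP3, 64, N8, dp3);
  arma::mat dz4 = avgpool2_back(dp3, N4);
  relu_mask(dz4, ws.y4);
  g.W4 += dz4 * ws.y3.t();
  g.b4 += arma::sum(dz4, 1);
  arma::mat dz3 = p.W4.t() * dz4;
  relu_mask(dz3, ws.y3);
  g.W3 += dz3 * ws.P2.t();
  g.b3 += arma::sum(dz3, 1);
  arma::mat dP2 = p.W3.t() * dz3;
  arma::mat dp2(32, ws.p2.n_cols);
  col2im_k3(dP2, 32, N4, dp2);
  arma::mat dz2 = avgpool2_back(dp2, N2);
  relu_mask(dz2, ws.y2);
  g.W2 += dz2 * ws.y1.t();
  g.b2 += arma::sum(dz2, 1);
  arma::mat dz1 = p.W2.t() * dz2;
  relu_mask(dz1, ws.y1);
  g.W1 += dz1 * ws.P1.t();
  g.b1 += arma::sum(dz1, 1);
}

static arma::vec log_softmax(const arma::vec& s) {
  const double m = s.max();
  return s - m - std::log(arma::accu(arma::exp(s - m)));
}

// [[Rcpp::export]]
List cpp_net_forward(List weights, NumericVector xbatch, int C, int N, int B,
                     bool want_flatten) {
  NetParams p = unpack(weights);
  const size_t nv = (size_t)N * N * N;
  const int K = p.bL.n_elem;
  const int flat = 8 * (N / 16) * (N / 16) * (N / 16);
  arma::mat scores(K, B), flats(want_flatten ? flat : 1, want_flatten ? B : 1);
  Workspace ws;
  for (int b = 0; b < B; ++b) {
    arma::mat x(const_cast<double*>(REAL(xbatch)) + (size_t)C * nv * b, C, nv,
                false, true);
    scores.col(b) = net_forward(p, x, C, N, ws);
    if (want_flatten) flats.col(b) = arma::vectorise(ws.z6);
  }
  return List::create(_["scores"] = scores, _["flatten"] = flats);
}

// standard deviations of the pre-activation of every parameterized layer
// (z1..z6 and the linear scores) over a calibration batch; used for
// layer-sequential variance calibration of fresh initializations
// [[Rcpp::export]]
NumericVector cpp_net_layer_stats(List weights, NumericVector xbatch, int C,
                                  int N, int B) {
  NetParams p = unpack(weights);
  const size_t nv = (size_t)N * N * N;
  Workspace ws;
  std::vector<arma::running_stat<double>> rs(7);
  for (int b = 0; b < B; ++b) {
    arma::mat x(const_cast<double*>(REAL(xbatch)) + (size_t)C * nv * b, C, nv,
                false, true);
    arma::vec s = net_forward(p, x, C, N, ws);
    // y1..y5 hold post-ReLU values; the spread of the positive part still
    // tracks the pre-activation scale, so use the raw gemm outputs where
    // kept (z6, scores) and the activations elsewhere
    for (double v : ws.y1) rs[0](v);
    for (double v : ws.y2) rs[1](v);
    for (double v : ws.y3) rs[2](v);
    for (double v : ws.y4) rs[3](v);
    for (double v : ws.y5) rs[4](v);
    for (double v : ws.z6) rs[5](v);
    for (double v : s) rs[6](v);
  }
  NumericVector out(7);
  for (int i = 0; i < 7; ++i) out[i] = rs[i].stddev();
  return out;
}

// One SGD step (PyTorch convention: v = mu*v + g; w = w - lr*v) on the mean
// cross-entropy gradient of a batch. Returns updated weights/velocity, the
// mean loss and the number of correct argmax predictions.
// [[Rcpp::export]]
List cpp_net_train_batch(List weights, List velocity, NumericVector xbatch,
                         IntegerVector labels, int C, int N, double lr,
                         double momentum) {
  NetParams p = unpack(weights);
  NetParams v = unpack(velocity);
  NetParams g;
  g.W1 = arma::zeros(arma::size(p.W1)); g.b1 = arma::zeros(arma::size(p.b1));
  g.W2 = arma::zeros(arma::size(p.W2)); g.b2 = arma::zeros(arma::size(p.b2));
  g.W3 = arma::zeros(arma::size(p.W3)); g.b3 = arma::zeros(arma::size(p.b3));
  g.W4 = arma::zeros(arma::size(p.W4)); g.b4 = arma::zeros(arma::size(p.b4));
  g.W5 = arma::zeros(arma::size(p.W5)); g.b5 = arma::zeros(arma::size(p.b5));
  g.W6 = arma::zeros(arma::size(p.W6)); g.b6 = arma::zeros(arma::size(p.b6));
  g.WL = arma::zeros(arma::size(p.WL)); g.bL = arma::zeros(arma::size(p.bL));

  const int B = labels.size();
  const size_t nv = (size_t)N * N * N;
  double loss = 0.0;
  int correct = 0;
  Workspace ws;
  for (int b = 0; b < B; ++b) {
    arma::mat x(const_cast<double*>(REAL(xbatch)) + (size_t)C * nv * b, C, nv,
                false, true);
    arma::vec s = net_forward(p, x, C, N, ws);
    arma::vec ls = log_softmax(s);
    const int y = labels[b];
    loss -= ls[y] / B;
    if ((int)s.index_max() == y) ++correct;
    arma::vec ds = arma::exp(ls) / B;  // d(mean CE)/d(scores)
    ds[y] -= 1.0 / B;
    net_backward(p, ws, ds, C, N, g);
  }

  auto step = [&](arma::mat& W, arma::mat& V, const arma::mat& G) {
    V = momentum * V + G;
    W -= lr * V;
  };
  auto stepv = [&](arma::vec& W, arma::vec& V, const arma::vec& G) {
    V = momentum * V + G;
    W -= lr * V;
  };
  step(p.W1, v.W1, g.W1); stepv(p.b1, v.b1, g.b1);
  step(p.W2, v.W2, g.W2); stepv(p.b2, v.b2, g.b2);
  step(p.W3, v.W3, g.W3); stepv(p.b3, v.b3, g.b3);
  step(p.W4, v.W4, g.W4); stepv(p.b4, v.b4, g.b4);
  step(p.W5, v.W5, g.W5); stepv(p.b5, v.b5, g.b5);
  step(p.W6, v.W6, g.W6); stepv(p.b6, v.b6, g.b6);
  step(p.WL, v.WL, g.WL); stepv(p.bL, v.bL, g.bL);

  return List::create(_["weights"] = pack(p), _["velocity"] = pack(v),
                      _["loss"] = loss, _["correct"] = correct);
}
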