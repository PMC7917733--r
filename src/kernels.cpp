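// Compiled kernels for the convolutional stream: 3x3 SAME convolution
// (im2col + BLAS gemm via Armadillo) and 2x2/stride-2 max pooling.
//
// Feature-map layout everywhere: a (C x H*W*B) matrix; within each image
// block the spatial index is column-major (row index fastest), and the B
// images of a batch are concatenated along columns.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Build the im2col matrix (9C x H*W*B) for a 3x3 kernel with zero padding 1.
// Patch row r = c + C * (3*dj + di) — channel fastest, so each patch tap is a
// contiguous memcpy of C doubles. The weight layout W (K x 9C) on the R side
// uses the same column order.
static void im2col_pad1(const arma::mat& x, int H, int W, int C, int B,
                        arma::mat& cols) {
  const int HW = H * W;
  const size_t Cz = (size_t)C * sizeof(double);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const int p = b * HW + j * H + i;
        double* cp = cols.colptr(p);
        for (int dj = 0; dj < 3; ++dj) {
          const int jj = j + dj - 1;
          for (int di = 0; di < 3; ++di) {
            const int ii = i + di - 1;
            double* dst = cp + (size_t)C * (3 * dj + di);
            if (ii >= 0 && ii < H && jj >= 0 && jj < W) {
              std::memcpy(dst, x.colptr(b * HW + jj * H + ii), Cz);
            } else {
              std::memset(dst, 0, Cz);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& x, const arma::mat& Wm,
                        const arma::vec& b, int H, int W, int C, int B) {
  arma::mat cols(9 * C, (size_t)H * W * B);
  im2col_pad1(x, H, W, C, B, cols);
  arma::mat y = Wm * cols;
  y.each_col() += b;
  return y;
}

// Gradients of the SAME convolution; the im2col matrix is recomputed from
// the stored layer input rather than cached (memory-for-time trade).
// dx is obtained as a convolution of dy with the flipped, transposed kernel.
// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat& x, const arma::mat& dy,
                   const arma::mat& Wm, int H, int W, int C, int B,
                   bool need_dx) {
  const int K = Wm.n_rows;
  arma::mat cols(9 * C, (size_t)H * W * B);
  im2col_pad1(x, H, W, C, B, cols);
  arma::mat dW = dy * cols.t();
  arma::vec db = arma::sum(dy, 1);
  List out = List::create(Named("dW") = dW, Named("db") = db);
  if (need_dx) {
    // Wb(c, k + K*(8 - t)) = Wm(k, c + C*t): transposed, kernel taps flipped
    arma::mat Wb(C, 9 * K);
    for (int t = 0; t < 9; ++t)
      for (int c = 0; c < C; ++c)
        for (int k = 0; k < K; ++k)
          Wb.at(c, k + K * (8 - t)) = Wm.at(k, c + C * t);
    arma::mat dycols(9 * K, (size_t)H * W * B);
    im2col_pad1(dy, H, W, K, B, dycols);
    arma::mat dx = Wb * dycols;
    out["dx"] = dx;
  }
  return out;
}

// ---- whole-network step for the Tiny VGG ---------------------------------
// The full forward/backward/Adam pass runs here so the multi-hundred-MB
// intermediates live as C++ temporaries instead of churning the R garbage
// collector. Parameters and Adam state are Armadillo views onto the R
// vectors and are updated in place.

static arma::mat view_mat(List L, const char* nm) {
  NumericMatrix M = as<NumericMatrix>(L[nm]);
  return arma::mat(M.begin(), M.nrow(), M.ncol(), false, true);
}
static arma::vec view_vec(List L, const char* nm) {
  NumericVector V = as<NumericVector>(L[nm]);
  return arma::vec(V.begin(), V.size(), false, true);
}

struct PoolOut { arma::mat y; arma::Mat<int> amax; };

static PoolOut pool2_fwd(const arma::mat& x, int H, int W, int B) {
  const int C = x.n_rows, H2 = H / 2, W2 = W / 2;
  const int HW = H * W, HW2 = H2 * W2;
  PoolOut out;
  out.y.set_size(C, (size_t)HW2 * B);
  out.amax.set_size(C, (size_t)HW2 * B);
  for (int b = 0; b < B; ++b)
    for (int j2 = 0; j2 < W2; ++j2)
      for (int i2 = 0; i2 < H2; ++i2) {
        const int p = b * HW2 + j2 * H2 + i2;
        const int s[4] = {
          b * HW + (2 * j2) * H + 2 * i2,
          b * HW + (2 * j2) * H + 2 * i2 + 1,
          b * HW + (2 * j2 + 1) * H + 2 * i2,
          b * HW + (2 * j2 + 1) * H + 2 * i2 + 1 };
        for (int c = 0; c < C; ++c) {
          double best = x.at(c, s[0]); int bi = s[0];
          for (int q = 1; q < 4; ++q) {
            const double v = x.at(c, s[q]);
            if (v > best) { best = v; bi = s[q]; }
          }
          out.y.at(c, p) = best;
          out.amax.at(c, p) = bi;
        }
      }
  return out;
}

static arma::mat pool2_bwd(const arma::mat& dy, const arma::Mat<int>& amax,
                           int H, int W, int B) {
  const int C = dy.n_rows;
  arma::mat dx(C, (size_t)H * W * B, arma::fill::zeros);
  const size_t P = dy.n_cols;
  for (size_t p = 0; p < P; ++p)
    for (int c = 0; c < C; ++c)
      dx.at(c, amax.at(c, p)) += dy.at(c, p);
  return dx;
}

static arma::mat conv_fwd_core(const arma::mat& x, const arma::mat& Wm,
                               const arma::vec& b, int H, int W, int C, int B) {
  arma::mat cols(9 * C, (size_t)H * W * B);
  im2col_pad1(x, H, W, C, B, cols);
  arma::mat y = Wm * cols;
  y.each_col() += b;
  return y;
}

static void conv_bwd_core(const arma::mat& x, const arma::mat& dy,
                          const arma::mat& Wm, int H, int W, int C, int B,
                          bool need_dx, arma::mat& dW, arma::vec& db,
                          arma::mat& dx) {
  const int K = Wm.n_rows;
  {
    arma::mat cols(9 * C, (size_t)H * W * B);
    im2col_pad1(x, H, W, C, B, cols);
    dW = dy * cols.t();
  }
  db = arma::sum(dy, 1);
  if (need_dx) {
    arma::mat Wb(C, 9 * K);
    for (int t = 0; t < 9; ++t)
      for (int c = 0; c < C; ++c)
        for (int k = 0; k < K; ++k)
          Wb.at(c, k + K * (8 - t)) = Wm.at(k, c + C * t);
    arma::mat dycols(9 * K, (size_t)H * W * B);
    im2col_pad1(dy, H, W, K, B, dycols);
    dx = Wb * dycols;
  }
}

static void adam_inplace(arma::mat& p, const arma::mat& g, arma::mat& m,
                         arma::mat& v, double lr, double t, double b1,
                         double b2, double eps) {
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  const size_t n = p.n_elem;
  double* pp = p.memptr(); double* mm = m.memptr(); double* vv = v.memptr();
  const double* gg = g.memptr();
  for (size_t i = 0; i < n; ++i) {
    mm[i] = b1 * mm[i] + (1.0 - b1) * gg[i];
    vv[i] = b2 * vv[i] + (1.0 - b2) * gg[i] * gg[i];
    pp[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
  }
}
static void adam_inplace_v(arma::vec& p, const arma::vec& g, arma::vec& m,
                           arma::vec& v, double lr, double t, double b1,
                           double b2, double eps) {
  arma::mat pm(p.memptr(), p.n_elem, 1, false, true);
  arma::mat mm(m.memptr(), m.n_elem, 1, false, true);
  arma::mat vm(v.memptr(), v.n_elem, 1, false, true);
  adam_inplace(pm, arma::mat(g), mm, vm, lr, t, b1, b2, eps);
}

// One Adam training step over a minibatch. params/ms/vs are lists of R
// matrices/vectors (Wc1,bc1,Wc2,bc2,Wc3,bc3,W1,b1,W2,b2), updated IN PLACE.
// x: (1 x S*S*B); yint: 1-based labels. Returns loss and #correct.
// [[Rcpp::export]]
List cpp_tvgg_train_step(const arma::mat& x, const IntegerVector& yint,
                         List params, List ms, List vs, int S, int B,
                         double lr, double t, double clipnorm,
                         double b1, double b2, double eps) {
  arma::mat Wc1 = view_mat(params, "Wc1"), Wc2 = view_mat(params, "Wc2"),
            Wc3 = view_mat(params, "Wc3"), W1 = view_mat(params, "W1"),
            W2 = view_mat(params, "W2");
  arma::vec bc1 = view_vec(params, "bc1"), bc2 = view_vec(params, "bc2"),
            bc3 = view_vec(params, "bc3"), b1v = view_vec(params, "b1"),
            b2v = view_vec(params, "b2");
  const int s2 = S / 2, s3 = s2 / 2, s4 = s3 / 2;
  const int K1 = Wc1.n_rows, K2 = Wc2.n_rows, K3 = Wc3.n_rows;
  // forward
  arma::mat a1, a2, a3;
  PoolOut p1, p2, p3;
  {
    arma::mat y1 = conv_fwd_core(x, Wc1, bc1, S, S, 1, B);
    p1 = pool2_fwd(y1, S, S, B);
  }
  a1 = arma::clamp(p1.y, 0.0, arma::datum::inf);
  {
    arma::mat y2 = conv_fwd_core(a1, Wc2, bc2, s2, s2, K1, B);
    p2 = pool2_fwd(y2, s2, s2, B);
  }
  a2 = arma::clamp(p2.y, 0.0, arma::datum::inf);
  {
    arma::mat y3 = conv_fwd_core(a2, Wc3, bc3, s3, s3, K2, B);
    p3 = pool2_fwd(y3, s3, s3, B);
  }
  a3 = arma::clamp(p3.y, 0.0, arma::datum::inf);
  arma::mat flat(a3.memptr(), (size_t)K3 * s4 * s4, B, false, true);
  arma::mat h1 = W1 * flat;
  h1.each_col() += b1v;
  h1 = arma::clamp(h1, 0.0, arma::datum::inf);
  arma::mat logits = W2 * h1;
  logits.each_col() += b2v;
  // softmax + cross-entropy
  arma::mat p = logits;
  p.each_row() -= arma::max(p, 0);
  p = arma::exp(p);
  p.each_row() /= arma::sum(p, 0);
  double loss = 0.0; int correct = 0;
  arma::mat dlog = p;
  for (int i = 0; i < B; ++i) {
    const int y = yint[i] - 1;
    loss -= std::log(std::max(p.at(y, i), 1e-300));
    dlog.at(y, i) -= 1.0;
    if ((int)arma::index_max(p.col(i)) == y) ++correct;
  }
  loss /= B;
  dlog /= B;
  // backward
  arma::mat gW2 = dlog * h1.t();
  arma::vec gb2 = arma::sum(dlog, 1);
  arma::mat dh1 = (W2.t() * dlog) % arma::conv_to<arma::mat>::from(h1 > 0);
  arma::mat gW1 = dh1 * flat.t();
  arma::vec gb1 = arma::sum(dh1, 1);
  arma::mat dflat = W1.t() * dh1;
  arma::mat gWc1, gWc2, gWc3, dx2, dx3, unused;
  arma::vec gbc1, gbc2, gbc3;
  {
    arma::mat dnext(dflat.memptr(), K3, (size_t)s4 * s4 * B, false, true);
    arma::mat dpool3 = dnext % arma::conv_to<arma::mat>::from(a3 > 0);
    arma::mat dy3 = pool2_bwd(dpool3, p3.amax, s3, s3, B);
    conv_bwd_core(a2, dy3, Wc3, s3, s3, K2, B, true, gWc3, gbc3, dx3);
  }
  {
    arma::mat dpool2 = dx3 % arma::conv_to<arma::mat>::from(a2 > 0);
    dx3.reset();
    arma::mat dy2 = pool2_bwd(dpool2, p2.amax, s2, s2, B);
    conv_bwd_core(a1, dy2, Wc2, s2, s2, K1, B, true, gWc2, gbc2, dx2);
  }
  {
    arma::mat dpool1 = dx2 % arma::conv_to<arma::mat>::from(a1 > 0);
    dx2.reset();
    arma::mat dy1 = pool2_bwd(dpool1, p1.amax, S, S, B);
    conv_bwd_core(x, dy1, Wc1, S, S, 1, B, false, gWc1, gbc1, unused);
  }
  // global gradient-norm clipping
  double sq = arma::accu(arma::square(gW2)) + arma::accu(arma::square(gb2)) +
    arma::accu(arma::square(gW1)) + arma::accu(arma::square(gb1)) +
    arma::accu(arma::square(gWc1)) + arma::accu(arma::square(gbc1)) +
    arma::accu(arma::square(gWc2)) + arma::accu(arma::square(gbc2)) +
    arma::accu(arma::square(gWc3)) + arma::accu(arma::square(gbc3));
  const double nrm = std::sqrt(sq);
  if (std::isfinite(nrm) && nrm > clipnorm) {
    const double sc = clipnorm / nrm;
    gW2 *= sc; gb2 *= sc; gW1 *= sc; gb1 *= sc;
    gWc1 *= sc; gbc1 *= sc; gWc2 *= sc; gbc2 *= sc; gWc3 *= sc; gbc3 *= sc;
  }
  // Adam, in place
  arma::mat mWc1 = view_mat(ms, "Wc1"), vWc1 = view_mat(vs, "Wc1");
  arma::mat mWc2 = view_mat(ms, "Wc2"), vWc2 = view_mat(vs, "Wc2");
  arma::mat mWc3 = view_mat(ms, "Wc3"), vWc3 = view_mat(vs, "Wc3");
  arma::mat mW1 = view_mat(ms, "W1"), vW1 = view_mat(vs, "W1");
  arma::mat mW2 = view_mat(ms, "W2"), vW2 = view_mat(vs, "W2");
  arma::vec mbc1 = view_vec(ms, "bc1"), vbc1 = view_vec(vs, "bc1");
  arma::vec mbc2 = view_vec(ms, "bc2"), vbc2 = view_vec(vs, "bc2");
  arma::vec mbc3 = view_vec(ms, "bc3"), vbc3 = view_vec(vs, "bc3");
  arma::vec mb1 = view_vec(ms, "b1"), vb1 = view_vec(vs, "b1");
  arma::vec mb2 = view_vec(ms, "b2"), vb2 = view_vec(vs, "b2");
  adam_inplace(Wc1, gWc1, mWc1, vWc1, lr, t, b1, b2, eps);
  adam_inplace_v(bc1, gbc1, mbc1, vbc1, lr, t, b1, b2, eps);
  adam_inplace(Wc2, gWc2, mWc2, vWc2, lr, t, b1, b2, eps);
  adam_inplace_v(bc2, gbc2, mbc2, vbc2, lr, t, b1, b2, eps);
  adam_inplace(Wc3, gWc3, mWc3, vWc3, lr, t, b1, b2, eps);
  adam_inplace_v(bc3, gbc3, mbc3, vbc3, lr, t, b1, b2, eps);
  adam_inplace(W1, gW1, mW1, vW1, lr, t, b1, b2, eps);
  adam_inplace_v(b1v, gb1, mb1, vb1, lr, t, b1, b2, eps);
  adam_inplace(W2, gW2, mW2, vW2, lr, t, b1, b2, eps);
  adam_inplace_v(b2v, gb2, mb2, vb2, lr, t, b1, b2, eps);
  return List::create(Named("loss") = loss, Named("correct") = correct);
}

// Forward-only pass returning class probabilities (K x B).
// [[Rcpp::export]]
arma::mat cpp_tvgg_predict(const arma::mat& x, List params, int S, int B) {
  arma::mat Wc1 = view_mat(params, "Wc1"), Wc2 = view_mat(params, "Wc2"),
            Wc3 = view_mat(params, "Wc3"), W1 = view_mat(params, "W1"),
            W2 = view_mat(params, "W2");
  arma::vec bc1 = view_vec(params, "bc1"), bc2 = view_vec(params, "bc2"),
            bc3 = view_vec(params, "bc3"), b1v = view_vec(params, "b1"),
            b2v = view_vec(params, "b2");
  const int s2 = S / 2, s3 = s2 / 2, s4 = s3 / 2;
  const int K3 = Wc3.n_rows;
  arma::mat a = conv_fwd_core(x, Wc1, bc1, S, S, 1, B);
  a = arma::clamp(pool2_fwd(a, S, S, B).y, 0.0, arma::datum::inf);
  a = conv_fwd_core(a, Wc2, bc2, s2, s2, Wc1.n_rows, B);
  a = arma::clamp(pool2_fwd(a, s2, s2, B).y, 0.0, arma::datum::inf);
  a = conv_fwd_core(a, Wc3, bc3, s3, s3, Wc2.n_rows, B);
  a = arma::clamp(pool2_fwd(a, s3, s3, B).y, 0.0, arma::datum::inf);
  arma::mat flat(a.memptr(), (size_t)K3 * s4 * s4, B, false, true);
  arma::mat h1 = W1 * flat;
  h1.each_col() += b1v;
  h1 = arma::clamp(h1, 0.0, arma::datum::inf);
  arma::mat logits = W2 * h1;
  logits.each_col() += b2v;
  logits.each_row() -= arma::max(logits, 0);
  logits = arma::exp(logits);
  logits.each_row() /= arma::sum(logits, 0);
  return logits;
}

// Fused Adam update: one pass over the parameter vector, returning updated
// (param, m, v). Saves a dozen large intermediate allocations per step on
// the multi-megabyte fully-connected weights.
// [[Rcpp::export]]
List cpp_adam_fused(const NumericVector& p, const NumericVector& g,
                    const NumericVector& m, const NumericVector& v,
                    double lr, double t, double b1, double b2, double eps) {
  const R_xlen_t n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = b1 * m[i] + (1.0 - b1) * g[i];
    const double vi = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    m2[i] = mi; v2[i] = vi;
    p2[i] = p[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  return List::create(Named("p") = p2, Named("m") = m2, Named("v") = v2);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::mat& x, int H, int W, int B) {
  const int C = x.n_rows, H2 = H / 2, W2 = W / 2;
  const int HW = H * W, HW2 = H2 * W2;
  arma::mat y(C, (size_t)HW2 * B);
  IntegerMatrix amax(C, HW2 * B);  // 0-based source column per output entry
  for (int b = 0; b < B; ++b) {
    for (int j2 = 0; j2 < W2; ++j2) {
      for (int i2 = 0; i2 < H2; ++i2) {
        const int p = b * HW2 + j2 * H2 + i2;
        const int s[4] = {
          b * HW + (2 * j2) * H + 2 * i2,
          b * HW + (2 * j2) * H + 2 * i2 + 1,
          b * HW + (2 * j2 + 1) * H + 2 * i2,
          b * HW + (2 * j2 + 1) * H + 2 * i2 + 1 };
        double* yp = y.colptr(p);
        for (int c = 0; c < C; ++c) {
          double best = x.at(c, s[0]);
          int bi = s[0];
          for (int q = 1; q < 4; ++q) {
            const double v = x.at(c, s[q]);
            if (v > best) { best = v; bi = s[q]; }  // first max wins ties
          }
          yp[c] = best;
          amax(c, p) = bi;
        }
      }
    }
  }
  return List::create(Named("y") = y, Named("amax") = amax);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_bwd(const arma::mat& dy, const IntegerMatrix& amax,
                           int H, int W, int B) {
  const int C = dy.n_rows;
  arma::mat dx(C, (size_t)H * W * B, arma::fill::zeros);
  const int P = dy.n_cols;
  for (int p = 0; p < P; ++p)
    for (int c = 0; c < C; ++c)
      dx.at(c, amax(c, p)) += dy.at(c, p);
  return dx;
}
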