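// Compact convolutional network for 224x224 grayscale thumbnails.
//
// Architecture (fixed): 2x average pooling to 112x112 (keeps the ~8 px
// cell radius resolvable), then four 3x3 convolution blocks of 16, 32, 64
// and 64 channels, each conv followed by batch normalisation and ReLU,
// with 2x max pooling after the first three blocks; global average pooling
// and a 4-way softmax head.
//
// Weights travel as an R list (column-major matrices) so models serialize
// with base R: W1..W4 conv kernels, g1..g4 / b1..b4 batch-norm scale and
// shift, W5 / b5 the linear head, rm1..rm4 / rv1..rv4 the running
// batch-norm statistics used at inference. This file provides the
// inference forward pass and the mini-batch gradient (batch statistics,
// exact backprop through the normalisation) used by the R-side optimizer.
//
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>

using namespace Rcpp;

static const int N_CONV = 4;
static const int CH[5] = {1, 16, 32, 64, 64};
static const int SZ[4] = {112, 56, 28, 14};  // spatial size at conv1..conv4
static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.8;

// 3x3, pad-1 im2col rows for one image, written into `out` starting at row0.
static void im2col3_into(const arma::cube& x, arma::mat& out, int row0) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int col = 0;
  for (int c = 0; c < C; ++c)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy, ++col)
        for (int j = 0; j < W; ++j) {
          int js = j + dx;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            int is = i + dy;
            if (is < 0 || is >= H) continue;
            out(row0 + i + j * H, col) = x(is, js, c);
          }
        }
}

static arma::cube col2im3(const arma::mat& d, int row0, int H, int W, int C) {
  arma::cube out(H, W, C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy, ++col)
        for (int j = 0; j < W; ++j) {
          int js = j + dx;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            int is = i + dy;
            if (is < 0 || is >= H) continue;
            out(is, js, c) += d(row0 + i + j * H, col);
          }
        }
  return out;
}

static arma::cube maxpool2(const arma::cube& x, arma::ucube& argmax) {
  int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  arma::cube out(H, W, C);
  argmax.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -1e300; unsigned int bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            int ii = 2 * i + di, jj = 2 * j + dj;
            double v = x(ii, jj, c);
            if (v > best) { best = v; bidx = ii + jj * x.n_rows; }
          }
        out(i, j, c) = best;
        argmax(i, j, c) = bidx;
      }
  return out;
}

static arma::cube maxpool2_back(const arma::cube& dout, const arma::ucube& argmax,
                                int H, int W) {
  int C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (unsigned int j = 0; j < dout.n_cols; ++j)
      for (unsigned int i = 0; i < dout.n_rows; ++i) {
        unsigned int p = argmax(i, j, c);
        dx(p % H, p / H, c) += dout(i, j, c);
      }
  return dx;
}

// 2x2 average pooling + fixed gray-level normalisation: 224x224 -> 112x112.
// A fixed affine map keeps absolute contrast and cell-density information
// that per-image standardisation would discard.
static arma::cube prep_input(const arma::mat& img) {
  arma::cube x(112, 112, 1);
  for (int j = 0; j < 112; ++j)
    for (int i = 0; i < 112; ++i)
      x(i, j, 0) = (img(2 * i, 2 * j) + img(2 * i + 1, 2 * j) +
                    img(2 * i, 2 * j + 1) + img(2 * i + 1, 2 * j + 1)) / 4.0;
  x = (x - 180.0) / 64.0;
  return x;
}

struct Params {
  arma::mat W[5];
  arma::vec g[N_CONV], b[5], rm[N_CONV], rv[N_CONV];
};

static Params unpack(const List& wl) {
  Params p;
  for (int l = 0; l < 5; ++l) {
    p.W[l] = as<arma::mat>(wl[std::string("W") + std::to_string(l + 1)]);
    p.b[l] = as<arma::vec>(wl[std::string("b") + std::to_string(l + 1)]);
  }
  for (int l = 0; l < N_CONV; ++l) {
    p.g[l] = as<arma::vec>(wl[std::string("g") + std::to_string(l + 1)]);
    p.rm[l] = as<arma::vec>(wl[std::string("rm") + std::to_string(l + 1)]);
    p.rv[l] = as<arma::vec>(wl[std::string("rv") + std::to_string(l + 1)]);
  }
  return p;
}

// Shared forward machinery. In training mode batch statistics are used and
// every intermediate needed by the backward pass is retained.
struct BatchState {
  int B;
  arma::mat cols[N_CONV];          // stacked im2col inputs per conv layer
  arma::mat ahat[N_CONV];          // normalised pre-activations
  arma::umat relu[N_CONV];         // ReLU activity masks
  arma::vec mu[N_CONV], var[N_CONV];
  std::vector<arma::ucube> argmax[3];
  arma::mat gap;                   // B x CH[4]
  arma::mat probs;                 // B x 4
};

static void forward_batch(const arma::cube& imgs, const Params& p,
                          bool train, BatchState& st) {
  int B = imgs.n_slices;
  st.B = B;
  std::vector<arma::cube> cur(B);
  for (int s = 0; s < B; ++s) cur[s] = prep_input(imgs.slice(s));

  for (int l = 0; l < N_CONV; ++l) {
    int H = SZ[l], npix = H * H;
    arma::mat cols(B * npix, 9 * CH[l], arma::fill::zeros);
    for (int s = 0; s < B; ++s) im2col3_into(cur[s], cols, s * npix);
    arma::mat a = cols * p.W[l];
    arma::vec mu(CH[l + 1]), var(CH[l + 1]);
    if (train) {
      for (int k = 0; k < CH[l + 1]; ++k) {
        mu(k) = arma::mean(a.col(k));
        var(k) = arma::mean(arma::square(a.col(k) - mu(k)));
      }
    } else {
      mu = p.rm[l]; var = p.rv[l];
    }
    arma::mat ahat(a.n_rows, a.n_cols), z(a.n_rows, a.n_cols);
    for (int k = 0; k < CH[l + 1]; ++k) {
      ahat.col(k) = (a.col(k) - mu(k)) / std::sqrt(var(k) + BN_EPS);
      z.col(k) = p.g[l](k) * ahat.col(k) + p.b[l](k);
    }
    arma::umat mask = z > 0;
    z %= arma::conv_to<arma::mat>::from(mask);
    if (train) {
      st.cols[l] = std::move(cols);
      st.ahat[l] = std::move(ahat);
      st.relu[l] = std::move(mask);
      st.mu[l] = mu; st.var[l] = var;
      if (l < 3) st.argmax[l].resize(B);
    }
    // reshape per image; pool after the first three blocks
    std::vector<arma::cube> nxt(B);
    for (int s = 0; s < B; ++s) {
      arma::mat zs = z.rows(s * npix, (s + 1) * npix - 1);
      arma::cube zc(zs.memptr(), H, H, CH[l + 1]);
      if (l < 3) {
        arma::ucube am;
        nxt[s] = maxpool2(zc, am);
        if (train) st.argmax[l][s] = std::move(am);
      } else nxt[s] = zc;
    }
    cur = std::move(nxt);
  }

  st.gap.set_size(B, CH[4]);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < CH[4]; ++c)
      st.gap(s, c) = arma::accu(cur[s].slice(c)) / (SZ[3] * SZ[3]);
  arma::mat logits = st.gap * p.W[4];
  logits.each_row() += p.b[4].t();
  st.probs.set_size(B, 4);
  for (int s = 0; s < B; ++s) {
    arma::rowvec lr = logits.row(s) - logits.row(s).max();
    arma::rowvec e = arma::exp(lr);
    st.probs.row(s) = e / arma::accu(e);
  }
}

// Inference forward pass (running batch-norm statistics):
// images 224x224xN -> class probability matrix N x 4.
// [[Rcpp::export]]
arma::mat cpp_cnn_forward(const arma::cube& imgs, const List& weights) {
  Params p = unpack(weights);
  BatchState st;
  forward_batch(imgs, p, false, st);
  return st.probs;
}

// Mean cross-entropy loss and gradients over a mini-batch (batch-norm in
// batch-statistics mode; labels 0-based). Returns the loss, the gradient
// list for the trainable parameters, and updated running statistics.
// [[Rcpp::export]]
List cpp_cnn_grad(const arma::cube& imgs, const arma::ivec& labels,
                  const List& weights) {
  Params p = unpack(weights);
  int B = imgs.n_slices;
  if ((int)labels.n_elem != B) stop("labels length must match image count");
  BatchState st;
  forward_batch(imgs, p, true, st);

  double loss = 0.0;
  arma::mat dlogit = st.probs;        // becomes d(meanloss)/dlogits, B x 4
  for (int s = 0; s < B; ++s) {
    int y = labels(s);
    if (y < 0 || y > 3) stop("labels must be in 0..3");
    loss += -std::log(std::max(st.probs(s, y), 1e-12));
    dlogit(s, y) -= 1.0;
  }
  loss /= B;
  dlogit /= B;

  Params g;
  g.W[4] = st.gap.t() * dlogit;
  g.b[4] = arma::sum(dlogit, 0).t();
  arma::mat dgap = dlogit * p.W[4].t();   // B x CH[4]

  // expand GAP gradient to the conv4 output grid
  int npix = SZ[3] * SZ[3];
  arma::mat dz(B * npix, CH[4]);
  for (int s = 0; s < B; ++s)
    for (int k = 0; k < CH[4]; ++k)
      dz.rows(s * npix, (s + 1) * npix - 1).col(k).fill(dgap(s, k) / npix);

  for (int l = N_CONV - 1; l >= 0; --l) {
    int H = SZ[l]; npix = H * H;
    int K = CH[l + 1];
    dz %= arma::conv_to<arma::mat>::from(st.relu[l]);
    g.g[l].set_size(K); g.b[l].set_size(K);
    arma::mat da(B * npix, K);
    double N = (double)(B * npix);
    for (int k = 0; k < K; ++k) {
      arma::vec dzk = dz.col(k);
      arma::vec xh = st.ahat[l].col(k);
      g.b[l](k) = arma::accu(dzk);
      g.g[l](k) = arma::dot(dzk, xh);
      arma::vec dxh = p.g[l](k) * dzk;
      double s1 = arma::accu(dxh);
      double s2 = arma::dot(dxh, xh);
      double invstd = 1.0 / std::sqrt(st.var[l](k) + BN_EPS);
      da.col(k) = invstd * (dxh - s1 / N - xh * (s2 / N));
    }
    g.W[l] = st.cols[l].t() * da;
    if (l > 0) {
      arma::mat dcols = da * p.W[l].t();
      int Hp = SZ[l - 1], npp = Hp * Hp;
      arma::mat dznext(B * npp, CH[l], arma::fill::zeros);
      for (int s = 0; s < B; ++s) {
        arma::cube dpool = col2im3(dcols, s * npix, H, H, CH[l]);
        arma::cube dback = maxpool2_back(dpool, st.argmax[l - 1][s], Hp, Hp);
        arma::mat dm(dback.memptr(), npp, CH[l]);
        dznext.rows(s * npp, (s + 1) * npp - 1) = dm;
      }
      dz = std::move(dznext);
    }
  }

  List grads = List::create(
    Named("W1") = g.W[0], Named("g1") = g.g[0], Named("b1") = g.b[0],
    Named("W2") = g.W[1], Named("g2") = g.g[1], Named("b2") = g.b[1],
    Named("W3") = g.W[2], Named("g3") = g.g[2], Named("b3") = g.b[2],
    Named("W4") = g.W[3], Named("g4") = g.g[3], Named("b4") = g.b[3],
    Named("W5") = g.W[4], Named("b5") = g.b[4]);
  List running = List::create(
    Named("rm1") = BN_MOMENTUM * p.rm[0] + (1 - BN_MOMENTUM) * st.mu[0],
    Named("rv1") = BN_MOMENTUM * p.rv[0] + (1 - BN_MOMENTUM) * st.var[0],
    Named("rm2") = BN_MOMENTUM * p.rm[1] + (1 - BN_MOMENTUM) * st.mu[1],
    Named("rv2") = BN_MOMENTUM * p.rv[1] + (1 - BN_MOMENTUM) * st.var[1],
    Named("rm3") = BN_MOMENTUM * p.rm[2] + (1 - BN_MOMENTUM) * st.mu[2],
    Named("rv3") = BN_MOMENTUM * p.rv[2] + (1 - BN_MOMENTUM) * st.var[2],
    Named("rm4") = BN_MOMENTUM * p.rm[3] + (1 - BN_MOMENTUM) * st.mu[3],
    Named("rv4") = BN_MOMENTUM * p.rv[3] + (1 - BN_MOMENTUM) * st.var[3]);
  return List::create(Named("loss") = loss, Named("grads") = grads,
                      Named("running") = running);
}
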