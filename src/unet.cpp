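// Compact U-Net-style encoder-decoder for pixel-wise segmentation.
//
// Fixed topology (width w, K classes), all convs 3x3/pad 1 except the final
// 1x1 classifier; 2x average pooling and nearest-neighbour upsampling with
// skip concatenations:
//   conv(3->w)  conv(w->w)[skip1]  pool
//   conv(w->2w) conv(2w->2w)[skip2] pool
//   conv(2w->4w)
//   up + cat skip2 -> conv(6w->2w)
//   up + cat skip1 -> conv(3w->w)  conv1x1(w->K) softmax
// Trained with class-weighted cross-entropy + soft-Dice loss and Adam.
// Single-threaded; all randomness from one std::mt19937 seeded by the caller.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

static const int NLAYER = 8;

// layer channel plan for width w, K classes; kernel 3 except layer 7 (1x1)
static void layer_dims(int w, int K, int in_c[], int out_c[], int ks[]) {
  int ic[NLAYER] = {3, w, w, 2 * w, 2 * w, 6 * w, 3 * w, w};
  int oc[NLAYER] = {w, w, 2 * w, 2 * w, 4 * w, 2 * w, w, K};
  for (int l = 0; l < NLAYER; ++l) {
    in_c[l] = ic[l]; out_c[l] = oc[l]; ks[l] = (l == NLAYER - 1) ? 1 : 3;
  }
}

// dest(i,j) = src(i+dy, j+dx), zero outside
static mat shift_pad(const mat& m, int dy, int dx) {
  int h = m.n_rows, w = m.n_cols;
  mat s(h, w, arma::fill::zeros);
  int r0 = std::max(0, -dy), r1 = std::min(h, h - dy);
  int c0 = std::max(0, -dx), c1 = std::min(w, w - dx);
  if (r1 > r0 && c1 > c0)
    s.submat(r0, c0, r1 - 1, c1 - 1) = m.submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx);
  return s;
}

// im2col for 3x3, zero pad 1: (9*C, h*w); pixel (i,j) -> column j*h+i
static mat im2col3(const cube& x) {
  int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  mat out(9 * c, h * w);
  for (int ch = 0; ch < c; ++ch)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int r = ch * 9 + (dy + 1) * 3 + (dx + 1);
        out.row(r) = arma::vectorise(shift_pad(x.slice(ch), dy, dx)).t();
      }
  return out;
}

// accumulate dX (h,w,C) from dX_col (9*C, h*w)
static cube col2im3(const mat& dcol, int h, int w, int c) {
  cube dx(h, w, c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        int r = ch * 9 + (dy + 1) * 3 + (dx_ + 1);
        mat g = arma::reshape(dcol.row(r).t(), h, w);
        dx.slice(ch) += shift_pad(g, -dy, -dx_);
      }
  return dx;
}

// flatten channels: (C, h*w)
static mat chans(const cube& x) {
  mat out(x.n_slices, x.n_rows * x.n_cols);
  for (uword ch = 0; ch < x.n_slices; ++ch)
    out.row(ch) = arma::vectorise(x.slice(ch)).t();
  return out;
}

static cube unchans(const mat& m, int h, int w) {
  cube out(h, w, m.n_rows);
  for (uword ch = 0; ch < m.n_rows; ++ch)
    out.slice(ch) = arma::reshape(m.row(ch).t(), h, w);
  return out;
}

static cube avgpool2(const cube& x) {
  int h = x.n_rows / 2, w = x.n_cols / 2;
  cube out(h, w, x.n_slices, arma::fill::zeros);
  for (uword ch = 0; ch < x.n_slices; ++ch)
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        out.slice(ch) += 0.25 *
            x.slice(ch).submat(arma::regspace<arma::uvec>(a, 2, 2 * h - 2 + a),
                               arma::regspace<arma::uvec>(b, 2, 2 * w - 2 + b));
  return out;
}

static cube avgpool2_back(const cube& g) {
  int h = g.n_rows * 2, w = g.n_cols * 2;
  cube out(h, w, g.n_slices);
  arma::uvec ri = arma::repelem(arma::regspace<arma::uvec>(0, g.n_rows - 1), 2, 1);
  arma::uvec ci = arma::repelem(arma::regspace<arma::uvec>(0, g.n_cols - 1), 2, 1);
  for (uword ch = 0; ch < g.n_slices; ++ch)
    out.slice(ch) = 0.25 * g.slice(ch).submat(ri, ci);
  return out;
}

static cube up2(const cube& x) {
  int h = x.n_rows * 2, w = x.n_cols * 2;
  cube out(h, w, x.n_slices);
  arma::uvec ri = arma::repelem(arma::regspace<arma::uvec>(0, x.n_rows - 1), 2, 1);
  arma::uvec ci = arma::repelem(arma::regspace<arma::uvec>(0, x.n_cols - 1), 2, 1);
  for (uword ch = 0; ch < x.n_slices; ++ch)
    out.slice(ch) = x.slice(ch).submat(ri, ci);
  return out;
}

static cube up2_back(const cube& g) {
  int h = g.n_rows / 2, w = g.n_cols / 2;
  cube out(h, w, g.n_slices, arma::fill::zeros);
  for (uword ch = 0; ch < g.n_slices; ++ch) {
    const mat& s = g.slice(ch);
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        out.slice(ch) += s.submat(arma::regspace<arma::uvec>(a, 2, 2 * h - 2 + a),
                                  arma::regspace<arma::uvec>(b, 2, 2 * w - 2 + b));
  }
  return out;
}

static cube concat(const cube& a, const cube& b) {
  cube out(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  out.slices(0, a.n_slices - 1) = a;
  out.slices(a.n_slices, a.n_slices + b.n_slices - 1) = b;
  return out;
}

struct Cache {
  std::vector<mat> xcol;   // im2col input of each conv layer
  std::vector<mat> z;      // pre-activation (out_c x N)
  cube a2, a4;             // skip activations
  int h, w;
  mat prob;                // K x N softmax output
};

// conv layer l on input x; relu unless final layer
static cube conv_layer(const std::vector<mat>& W, const std::vector<vec>& b,
                       int l, const cube& x, Cache* cc) {
  mat xc = (W[l].n_cols == x.n_slices) ? chans(x) : im2col3(x);
  mat z = W[l] * xc;
  z.each_col() += b[l];
  if (cc) { cc->xcol[l] = xc; cc->z[l] = z; }
  if (l < NLAYER - 1) z = arma::clamp(z, 0.0, arma::datum::inf);
  return unchans(z, x.n_rows, x.n_cols);
}

static mat softmax_cols(const mat& z) {
  mat p = z.each_row() - arma::max(z, 0);
  p = arma::exp(p);
  p.each_row() /= arma::sum(p, 0);
  return p;
}

// full forward pass; returns prob as K x N (pixel column-major)
static mat forward(const std::vector<mat>& W, const std::vector<vec>& b,
                   const cube& x, Cache* cc) {
  if (cc) { cc->xcol.resize(NLAYER); cc->z.resize(NLAYER); cc->h = x.n_rows; cc->w = x.n_cols; }
  cube a1 = conv_layer(W, b, 0, x, cc);
  cube a2 = conv_layer(W, b, 1, a1, cc);
  cube p1 = avgpool2(a2);
  cube a3 = conv_layer(W, b, 2, p1, cc);
  cube a4 = conv_layer(W, b, 3, a3, cc);
  cube p2 = avgpool2(a4);
  cube a5 = conv_layer(W, b, 4, p2, cc);
  cube c1 = concat(up2(a5), a4);
  cube a6 = conv_layer(W, b, 5, c1, cc);
  cube c2 = concat(up2(a6), a2);
  cube a7 = conv_layer(W, b, 6, c2, cc);
  mat xc7 = chans(a7);
  mat z = W[7] * xc7;
  z.each_col() += b[7];
  if (cc) { cc->xcol[7] = xc7; cc->z[7] = z; cc->a2 = a2; cc->a4 = a4; }
  mat prob = softmax_cols(z);
  if (cc) cc->prob = prob;
  return prob;
}

// backward through a 3x3 conv layer l: dY is the grad at the layer output
// (out_c x N); applies the relu mask, accumulates gW/gb, returns dX cube
static cube conv_back(const std::vector<mat>& W, int l, const Cache& cc,
                      mat dY, int h, int w,
                      std::vector<mat>& gW, std::vector<vec>& gb) {
  dY %= arma::conv_to<mat>::from(cc.z[l] > 0);
  gW[l] += dY * cc.xcol[l].t();
  gb[l] += arma::sum(dY, 1);
  return col2im3(W[l].t() * dY, h, w, W[l].n_cols / 9);
}

// backward from dZ at the logits; returns nothing (grads accumulated)
static void backward(const std::vector<mat>& W, const Cache& cc, const mat& dZ,
                     std::vector<mat>& gW, std::vector<vec>& gb) {
  int h = cc.h, w = cc.w;
  int wd = W[0].n_rows;
  // final 1x1
  gW[7] += dZ * cc.xcol[7].t();
  gb[7] += arma::sum(dZ, 1);
  cube d_a7 = unchans(W[7].t() * dZ, h, w);
  cube d_c2 = conv_back(W, 6, cc, chans(d_a7), h, w, gW, gb);
  cube d_a6 = up2_back(d_c2.slices(0, 2 * wd - 1));
  cube d_a2_skip = d_c2.slices(2 * wd, 3 * wd - 1);
  cube d_c1 = conv_back(W, 5, cc, chans(d_a6), h / 2, w / 2, gW, gb);
  cube d_a5 = up2_back(d_c1.slices(0, 4 * wd - 1));
  cube d_a4_skip = d_c1.slices(4 * wd, 6 * wd - 1);
  cube d_p2 = conv_back(W, 4, cc, chans(d_a5), h / 4, w / 4, gW, gb);
  cube d_a4 = avgpool2_back(d_p2) + d_a4_skip;
  cube d_a3 = conv_back(W, 3, cc, chans(d_a4), h / 2, w / 2, gW, gb);
  cube d_p1 = conv_back(W, 2, cc, chans(d_a3), h / 2, w / 2, gW, gb);
  cube d_a2 = avgpool2_back(d_p1) + d_a2_skip;
  cube d_a1 = conv_back(W, 1, cc, chans(d_a2), h, w, gW, gb);
  conv_back(W, 0, cc, chans(d_a1), h, w, gW, gb);
}

// loss and gradient at the logits for one patch
// y: 0-based labels as uvec (pixel column-major), cw: class weights (K)
static double loss_grad(const mat& prob, const arma::uvec& y, const vec& cw,
                        double dice_weight, mat* dZ) {
  int K = prob.n_rows;
  uword N = prob.n_cols;
  mat g(K, N, arma::fill::zeros);
  vec wpix(N);
  for (uword i = 0; i < N; ++i) { g(y[i], i) = 1.0; wpix[i] = cw[y[i]]; }
  double wsum = arma::accu(wpix);
  // weighted cross-entropy
  double ce = 0.0;
  for (uword i = 0; i < N; ++i) ce -= wpix[i] * std::log(prob(y[i], i) + 1e-12);
  ce /= wsum;
  mat dz = prob - g;
  dz.each_row() %= wpix.t() / wsum;
  // soft Dice over classes present in the ground truth
  const double eps = 1e-6;
  vec G = arma::sum(g, 1), P = arma::sum(prob, 1), I = arma::sum(prob % g, 1);
  arma::uvec present = arma::find(G > 0);
  double dice_loss = 0.0;
  if (dice_weight > 0 && present.n_elem > 0) {
    mat dLdp(K, N, arma::fill::zeros);
    for (uword k = 0; k < present.n_elem; ++k) {
      uword c = present[k];
      double S = P[c] + G[c] + eps;
      dice_loss += 1.0 - (2.0 * I[c] + eps) / S;
      // dD/dp = (2 g S - (2I+eps)) / S^2 ; dL/dp = -dD/dp / |present|
      dLdp.row(c) = -(2.0 * g.row(c) * S - (2.0 * I[c] + eps)) / (S * S) / present.n_elem;
    }
    dice_loss /= present.n_elem;
    // through softmax: dz_k = p_k * (dLdp_k - sum_c dLdp_c p_c)
    arma::rowvec dot = arma::sum(dLdp % prob, 0);
    mat dzd = prob % (dLdp.each_row() - dot);
    dz += dice_weight * dzd;
  }
  if (dZ) *dZ = dz;
  return ce + dice_weight * dice_loss;
}

// dihedral transform k in 0..7: bit0 flip rows, bit1 flip cols, bit2 transpose
static mat dihedral_m(const mat& m, int k) {
  mat r = m;
  if (k & 1) r = arma::flipud(r);
  if (k & 2) r = arma::fliplr(r);
  if (k & 4) r = r.t();
  return r;
}

static cube dihedral_c(const cube& x, int k) {
  if (k == 0) return x;
  mat f = dihedral_m(x.slice(0), k);
  cube out(f.n_rows, f.n_cols, x.n_slices);
  out.slice(0) = f;
  for (uword ch = 1; ch < x.n_slices; ++ch) out.slice(ch) = dihedral_m(x.slice(ch), k);
  return out;
}

static std::vector<mat> as_mats(List l) {
  std::vector<mat> out;
  for (int i = 0; i < l.size(); ++i) out.push_back(as<mat>(l[i]));
  return out;
}
static std::vector<vec> as_vecs(List l) {
  std::vector<vec> out;
  for (int i = 0; i < l.size(); ++i) out.push_back(as<vec>(l[i]));
  return out;
}

// [[Rcpp::export]]
List cpp_unet_init(int width, int n_classes, int seed) {
  int in_c[NLAYER], out_c[NLAYER], ks[NLAYER];
  layer_dims(width, n_classes, in_c, out_c, ks);
  std::mt19937 rng(seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  List W(NLAYER), b(NLAYER);
  for (int l = 0; l < NLAYER; ++l) {
    int fan_in = in_c[l] * ks[l] * ks[l];
    mat w(out_c[l], fan_in);
    double sd = std::sqrt(2.0 / fan_in);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = norm(rng) * sd;
    W[l] = w;
    b[l] = vec(out_c[l], arma::fill::zeros);
  }
  return List::create(_["W"] = W, _["b"] = b, _["width"] = width,
                      _["n_classes"] = n_classes);
}

// [[Rcpp::export]]
NumericVector cpp_unet_forward(List W_, List b_, NumericVector x_) {
  std::vector<mat> W = as_mats(W_);
  std::vector<vec> b = as_vecs(b_);
  IntegerVector dims = x_.attr("dim");
  cube x(x_.begin(), dims[0], dims[1], dims[2]);
  mat prob = forward(W, b, x, nullptr);
  cube out = unchans(prob, dims[0], dims[1]);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(dims[0], dims[1], (int)prob.n_rows);
  return res;
}

// numerical-check helper: loss and analytic logit gradient for one patch
// [[Rcpp::export]]
List cpp_unet_loss(List W_, List b_, NumericVector x_, IntegerMatrix y_,
                   NumericVector class_weights, double dice_weight) {
  std::vector<mat> W = as_mats(W_);
  std::vector<vec> b = as_vecs(b_);
  IntegerVector dims = x_.attr("dim");
  cube x(x_.begin(), dims[0], dims[1], dims[2]);
  Cache cc;
  mat prob = forward(W, b, x, &cc);
  arma::uvec y(prob.n_cols);
  for (int j = 0; j < y_.ncol(); ++j)
    for (int i = 0; i < y_.nrow(); ++i) y[j * y_.nrow() + i] = y_(i, j);
  vec cw = as<vec>(class_weights);
  mat dZ;
  double L = loss_grad(prob, y, cw, dice_weight, &dZ);
  std::vector<mat> gW(NLAYER);
  std::vector<vec> gb(NLAYER);
  for (int l = 0; l < NLAYER; ++l) {
    gW[l].zeros(W[l].n_rows, W[l].n_cols);
    gb[l].zeros(b[l].n_elem);
  }
  backward(W, cc, dZ, gW, gb);
  List gWo(NLAYER), gbo(NLAYER);
  for (int l = 0; l < NLAYER; ++l) { gWo[l] = gW[l]; gbo[l] = gb[l]; }
  return List::create(_["loss"] = L, _["gW"] = gWo, _["gb"] = gbo);
}

// hard per-class Dice of argmax vs labels, mean over classes present anywhere
static double hard_dice(const mat& prob, const arma::uvec& y, int K,
                        vec* per_class) {
  arma::uvec pred = arma::index_max(prob, 0).t();
  vec d(K); d.fill(arma::datum::nan);
  double s = 0; int n = 0;
  for (int c = 0; c < K; ++c) {
    double pc = arma::accu(pred == (uword)c), gc = arma::accu(y == (uword)c);
    if (pc + gc == 0) continue;
    double inter = arma::accu((pred == (uword)c) % (y == (uword)c));
    d[c] = 2.0 * inter / (pc + gc);
    s += d[c]; ++n;
  }
  if (per_class) *per_class = d;
  return n ? s / n : arma::datum::nan;
}

// [[Rcpp::export]]
List cpp_unet_train(List W_, List b_, List X_, List Y_, List Xval_, List Yval_,
                    int epochs, double lr, int batch_size, int seed,
                    NumericVector class_weights, double dice_weight,
                    bool augment) {
  std::vector<mat> W = as_mats(W_);
  std::vector<vec> b = as_vecs(b_);
  vec cw = as<vec>(class_weights);
  int n = X_.size();

  std::vector<cube> X; std::vector<arma::umat> Y;
  for (int i = 0; i < n; ++i) {
    NumericVector xi = X_[i];
    IntegerVector d = xi.attr("dim");
    X.push_back(cube(xi.begin(), d[0], d[1], d[2]));
    Y.push_back(as<arma::umat>(IntegerMatrix(Y_[i])));
  }
  int nval = Xval_.size();
  std::vector<cube> Xv; std::vector<arma::umat> Yv;
  for (int i = 0; i < nval; ++i) {
    NumericVector xi = Xval_[i];
    IntegerVector d = xi.attr("dim");
    Xv.push_back(cube(xi.begin(), d[0], d[1], d[2]));
    Yv.push_back(as<arma::umat>(IntegerMatrix(Yval_[i])));
  }

  // Adam state
  std::vector<mat> mW(NLAYER), vW(NLAYER), gW(NLAYER);
  std::vector<vec> mb(NLAYER), vb(NLAYER), gb(NLAYER);
  for (int l = 0; l < NLAYER; ++l) {
    mW[l].zeros(W[l].n_rows, W[l].n_cols); vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem); vb[l].zeros(b[l].n_elem);
  }
  double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  long t = 0;
  std::mt19937 rng(seed);

  NumericMatrix history(epochs, 2);  // train loss, val mean dice
  colnames(history) = CharacterVector::create("train_loss", "val_dice");

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0; int n_seen = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(n, start + batch_size);
      for (int l = 0; l < NLAYER; ++l) {
        gW[l].zeros(W[l].n_rows, W[l].n_cols);
        gb[l].zeros(b[l].n_elem);
      }
      for (int ii = start; ii < end; ++ii) {
        int k = augment ? (int)(rng() % 8) : 0;
        cube x = dihedral_c(X[idx[ii]], k);
        mat ym = dihedral_m(arma::conv_to<mat>::from(Y[idx[ii]]), k);
        arma::uvec y = arma::conv_to<arma::uvec>::from(arma::vectorise(ym));
        Cache cc;
        mat prob = forward(W, b, x, &cc);
        mat dZ;
        ep_loss += loss_grad(prob, y, cw, dice_weight, &dZ);
        ++n_seen;
        backward(W, cc, dZ, gW, gb);
      }
      double scale = 1.0 / (end - start);
      ++t;
      double bc1 = 1.0 - std::pow(beta1, (double)t);
      double bc2 = 1.0 - std::pow(beta2, (double)t);
      for (int l = 0; l < NLAYER; ++l) {
        mat g = gW[l] * scale;
        mW[l] = beta1 * mW[l] + (1 - beta1) * g;
        vW[l] = beta2 * vW[l] + (1 - beta2) * (g % g);
        W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + adam_eps);
        vec gb_ = gb[l] * scale;
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb_;
        vb[l] = beta2 * vb[l] + (1 - beta2) * (gb_ % gb_);
        b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + adam_eps);
      }
    }
    double vd = arma::datum::nan;
    if (nval > 0) {
      double s = 0; int m = 0;
      for (int i = 0; i < nval; ++i) {
        mat prob = forward(W, b, Xv[i], nullptr);
        arma::uvec y = arma::conv_to<arma::uvec>::from(arma::vectorise(
            arma::conv_to<mat>::from(Yv[i])));
        double d = hard_dice(prob, y, prob.n_rows, nullptr);
        if (arma::is_finite(d)) { s += d; ++m; }
      }
      vd = m ? s / m : arma::datum::nan;
    }
    history(ep, 0) = n_seen ? ep_loss / n_seen : arma::datum::nan;
    history(ep, 1) = vd;
    Rcpp::checkUserInterrupt();
  }

  List Wout(NLAYER), bout(NLAYER);
  for (int l = 0; l < NLAYER; ++l) { Wout[l] = W[l]; bout[l] = b[l]; }
  return List::create(_["W"] = Wout, _["b"] = bout, _["history"] = history);
}
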