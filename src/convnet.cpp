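// Minimal convolutional-network engine (im2col + BLAS matrix products).
//
// Two architectures are supported:
//   * a feed-forward SR network (conv/ReLU chain, same padding, MSE loss);
//   * a residual-network observer (conv stem, average pool, residual blocks,
//     global average pool + linear head, plus a parallel linear-template path
//     on the raw input used for warm starts; BCE-with-logits loss).
//
// Feature maps are stored as (channels x H*W) matrices with position index
// p = x*H + y, matching R's column-major image matrices.  All parameter
// initialisation and optimisation happens on the R side; these routines are
// deterministic given their inputs.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// same-padding im2col: F is (C, H*W), result (C*k*k, H*W), zero fill
void im2col(const arma::mat& F, int H, int W, int k, arma::mat& cols) {
  const int C = F.n_rows, pad = k / 2;
  cols.zeros(C * k * k, H * W);
  for (int dx = -pad; dx <= pad; ++dx) {
    for (int dy = -pad; dy <= pad; ++dy) {
      const int roff = C * ((dy + pad) + k * (dx + pad));
      for (int x = 0; x < W; ++x) {
        const int xs = x + dx;
        if (xs < 0 || xs >= W) continue;
        for (int y = 0; y < H; ++y) {
          const int ys = y + dy;
          if (ys < 0 || ys >= H) continue;
          const int p = x * H + y, ps = xs * H + ys;
          for (int c = 0; c < C; ++c) cols(roff + c, p) = F(c, ps);
        }
      }
    }
  }
}

// adjoint of im2col
void col2im(const arma::mat& cols, int H, int W, int C, int k, arma::mat& dF) {
  const int pad = k / 2;
  dF.zeros(C, H * W);
  for (int dx = -pad; dx <= pad; ++dx) {
    for (int dy = -pad; dy <= pad; ++dy) {
      const int roff = C * ((dy + pad) + k * (dx + pad));
      for (int x = 0; x < W; ++x) {
        const int xs = x + dx;
        if (xs < 0 || xs >= W) continue;
        for (int y = 0; y < H; ++y) {
          const int ys = y + dy;
          if (ys < 0 || ys >= H) continue;
          const int p = x * H + y, ps = xs * H + ys;
          for (int c = 0; c < C; ++c) dF(c, ps) += cols(roff + c, p);
        }
      }
    }
  }
}

arma::mat avgpool2(const arma::mat& F, int H, int W) {
  const int C = F.n_rows, H2 = H / 2, W2 = W / 2;
  arma::mat out(C, H2 * W2);
  for (int x = 0; x < W2; ++x)
    for (int y = 0; y < H2; ++y) {
      const int p = x * H2 + y;
      const int a = (2 * x) * H + 2 * y, b = (2 * x + 1) * H + 2 * y;
      out.col(p) = 0.25 * (F.col(a) + F.col(a + 1) + F.col(b) + F.col(b + 1));
    }
  return out;
}

void avgpool2_back(const arma::mat& dOut, int H, int W, arma::mat& dF) {
  const int C = dOut.n_rows, H2 = H / 2, W2 = W / 2;
  dF.zeros(C, H * W);
  for (int x = 0; x < W2; ++x)
    for (int y = 0; y < H2; ++y) {
      const int p = x * H2 + y;
      const int a = (2 * x) * H + 2 * y, b = (2 * x + 1) * H + 2 * y;
      arma::vec g = 0.25 * dOut.col(p);
      dF.col(a) += g;
      dF.col(a + 1) += g;
      dF.col(b) += g;
      dF.col(b + 1) += g;
    }
}

}  // namespace

// Feed-forward SR chain. X, target: cubes (H, W, N) single channel.
// weights[i]: (out_ch, in_ch*k_i*k_i); biases[i]: out_ch vector.
// [[Rcpp::export(name = ".cnn_sr_batch")]]
List cnn_sr_batch(const arma::cube& X, List weights, List biases,
                  IntegerVector kernels, bool want_grad,
                  Nullable<arma::cube> target_ = R_NilValue) {
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  const int L = weights.size();
  std::vector<arma::mat> Wm(L);
  std::vector<arma::vec> bv(L);
  for (int l = 0; l < L; ++l) {
    Wm[l] = as<arma::mat>(weights[l]);
    bv[l] = as<arma::vec>(biases[l]);
  }
  arma::cube out(H, W, N);
  std::vector<arma::mat> gW(L);
  std::vector<arma::vec> gb(L);
  if (want_grad)
    for (int l = 0; l < L; ++l) {
      gW[l].zeros(Wm[l].n_rows, Wm[l].n_cols);
      gb[l].zeros(bv[l].n_elem);
    }
  arma::cube target;
  bool have_target = target_.isNotNull();
  if (have_target) target = as<arma::cube>(target_.get());
  double loss = 0.0;
  const double denom = (double)H * W * N;
  arma::mat cols;

  for (int i = 0; i < N; ++i) {
    std::vector<arma::mat> acts(L + 1);  // input to each layer
    acts[0] = arma::mat(1, H * W);
    acts[0].row(0) = arma::vectorise(X.slice(i)).t();
    for (int l = 0; l < L; ++l) {
      im2col(acts[l], H, W, kernels[l], cols);
      arma::mat o = Wm[l] * cols;
      o.each_col() += bv[l];
      if (l < L - 1) o.transform([](double v) { return v > 0 ? v : 0.0; });
      acts[l + 1] = std::move(o);
    }
    out.slice(i) = arma::reshape(acts[L].row(0).t(), H, W);
    if (have_target) {
      arma::mat diff = out.slice(i) - target.slice(i);
      loss += arma::accu(diff % diff) / denom;
      if (want_grad) {
        arma::mat dA(1, H * W);
        dA.row(0) = (2.0 / denom) * arma::vectorise(diff).t();
        for (int l = L - 1; l >= 0; --l) {
          if (l < L - 1) dA %= arma::conv_to<arma::mat>::from(acts[l + 1] > 0);
          im2col(acts[l], H, W, kernels[l], cols);
          gW[l] += dA * cols.t();
          gb[l] += arma::sum(dA, 1);
          if (l > 0) {
            arma::mat dcols = Wm[l].t() * dA;
            arma::mat dF;
            col2im(dcols, H, W, acts[l].n_rows, kernels[l], dF);
            dA = std::move(dF);
          }
        }
      }
    }
  }

  List res = List::create(Named("out") = out,
                          Named("loss") = have_target ? loss : NA_REAL);
  if (want_grad) {
    List LgW(L), Lgb(L);
    for (int l = 0; l < L; ++l) {
      LgW[l] = gW[l];
      Lgb[l] = gb[l];
    }
    res["gW"] = LgW;
    res["gb"] = Lgb;
  }
  return res;
}

// Residual-network observer.  params: list(stem_W, stem_b, blocks = list of
// list(W1, b1, W2, b2), head_w, head_b, lin_w).  pool in {1, 2}.
// [[Rcpp::export(name = ".cnn_resnet_batch")]]
List cnn_resnet_batch(const arma::cube& X, List params, int pool,
                      bool want_grad,
                      Nullable<NumericVector> labels_ = R_NilValue) {
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  arma::mat stem_W = as<arma::mat>(params["stem_W"]);
  arma::vec stem_b = as<arma::vec>(params["stem_b"]);
  List blocks = params["blocks"];
  const int nb = blocks.size();
  std::vector<arma::mat> W1(nb), W2(nb);
  std::vector<arma::vec> b1(nb), b2(nb);
  for (int j = 0; j < nb; ++j) {
    List bl = blocks[j];
    W1[j] = as<arma::mat>(bl["W1"]);
    b1[j] = as<arma::vec>(bl["b1"]);
    W2[j] = as<arma::mat>(bl["W2"]);
    b2[j] = as<arma::vec>(bl["b2"]);
  }
  arma::vec head_w = as<arma::vec>(params["head_w"]);
  arma::vec head_wm = as<arma::vec>(params["head_wm"]);
  double head_b = as<double>(params["head_b"]);
  arma::vec lin_w = as<arma::vec>(params["lin_w"]);
  const int C = stem_W.n_rows;
  const int H2 = H / pool, W2s = W / pool;
  const int HW2 = H2 * W2s;

  bool have_labels = labels_.isNotNull();
  arma::vec y;
  if (have_labels) y = as<arma::vec>(NumericVector(labels_.get()));

  arma::vec scores(N);
  double loss = 0.0;
  // gradient accumulators
  arma::mat g_stem_W;
  arma::vec g_stem_b, g_head_w, g_head_wm, g_lin_w;
  double g_head_b = 0.0;
  std::vector<arma::mat> gW1(nb), gW2(nb);
  std::vector<arma::vec> gb1(nb), gb2(nb);
  if (want_grad) {
    g_stem_W.zeros(stem_W.n_rows, stem_W.n_cols);
    g_stem_b.zeros(stem_b.n_elem);
    g_head_w.zeros(head_w.n_elem);
    g_head_wm.zeros(head_wm.n_elem);
    g_lin_w.zeros(lin_w.n_elem);
    for (int j = 0; j < nb; ++j) {
      gW1[j].zeros(W1[j].n_rows, W1[j].n_cols);
      gb1[j].zeros(b1[j].n_elem);
      gW2[j].zeros(W2[j].n_rows, W2[j].n_cols);
      gb2[j].zeros(b2[j].n_elem);
    }
  }
  arma::mat cols;

  for (int i = 0; i < N; ++i) {
    arma::rowvec xv = arma::vectorise(X.slice(i)).t();
    arma::mat F0(1, H * W);
    F0.row(0) = xv;
    im2col(F0, H, W, 3, cols);
    arma::mat stem_pre = stem_W * cols;
    stem_pre.each_col() += stem_b;
    arma::mat stem_act =
        arma::clamp(stem_pre, 0.0, arma::datum::inf);
    arma::mat Fcur = (pool == 2) ? avgpool2(stem_act, H, W) : stem_act;

    std::vector<arma::mat> Fin(nb), pre1(nb), A(nb), sum_pre(nb);
    for (int j = 0; j < nb; ++j) {
      Fin[j] = Fcur;
      im2col(Fcur, H2, W2s, 3, cols);
      pre1[j] = W1[j] * cols;
      pre1[j].each_col() += b1[j];
      A[j] = arma::clamp(pre1[j], 0.0, arma::datum::inf);
      im2col(A[j], H2, W2s, 3, cols);
      arma::mat B = W2[j] * cols;
      B.each_col() += b2[j];
      sum_pre[j] = Fin[j] + B;
      Fcur = arma::clamp(sum_pre[j], 0.0, arma::datum::inf);
    }
    arma::vec gap = arma::mean(Fcur, 1);
    // channelwise max pooling (for localized, signal-known-statistically
    // structure that average pooling cannot express)
    arma::uvec amax(C);
    arma::vec gmax(C);
    for (int c = 0; c < C; ++c) {
      amax(c) = Fcur.row(c).index_max();
      gmax(c) = Fcur(c, amax(c));
    }
    double z = arma::dot(head_w, gap) + arma::dot(head_wm, gmax) + head_b +
               arma::dot(lin_w, xv.t());
    scores(i) = z;

    if (have_labels) {
      // numerically stable softplus
      double sp = (z > 0) ? z + std::log1p(std::exp(-z))
                          : std::log1p(std::exp(z));
      loss += (sp - y(i) * z) / N;
      if (want_grad) {
        double sig = 1.0 / (1.0 + std::exp(-z));
        double dz = (sig - y(i)) / N;
        g_lin_w += dz * xv.t();
        g_head_w += dz * gap;
        g_head_wm += dz * gmax;
        g_head_b += dz;
        arma::mat dF(C, HW2);
        dF.each_col() = (dz / HW2) * head_w;
        for (int c = 0; c < C; ++c) dF(c, amax(c)) += dz * head_wm(c);
        for (int j = nb - 1; j >= 0; --j) {
          dF %= arma::conv_to<arma::mat>::from(sum_pre[j] > 0);
          // branch: B = conv2(A)
          arma::mat dA_cols = W2[j].t() * dF;
          im2col(A[j], H2, W2s, 3, cols);
          gW2[j] += dF * cols.t();
          gb2[j] += arma::sum(dF, 1);
          arma::mat dA;
          col2im(dA_cols, H2, W2s, C, 3, dA);
          dA %= arma::conv_to<arma::mat>::from(pre1[j] > 0);
          im2col(Fin[j], H2, W2s, 3, cols);
          gW1[j] += dA * cols.t();
          gb1[j] += arma::sum(dA, 1);
          arma::mat dcols = W1[j].t() * dA;
          arma::mat dFin;
          col2im(dcols, H2, W2s, C, 3, dFin);
          dF += dFin;  // skip connection
        }
        arma::mat dStemAct;
        if (pool == 2) {
          avgpool2_back(dF, H, W, dStemAct);
        } else {
          dStemAct = dF;
        }
        dStemAct %= arma::conv_to<arma::mat>::from(stem_pre > 0);
        im2col(F0, H, W, 3, cols);
        g_stem_W += dStemAct * cols.t();
        g_stem_b += arma::sum(dStemAct, 1);
      }
    }
  }

  List res = List::create(Named("scores") = scores,
                          Named("loss") = have_labels ? loss : NA_REAL);
  if (want_grad) {
    List gbl(nb);
    for (int j = 0; j < nb; ++j)
      gbl[j] = List::create(Named("W1") = gW1[j], Named("b1") = gb1[j],
                            Named("W2") = gW2[j], Named("b2") = gb2[j]);
    res["grads"] = List::create(
        Named("stem_W") = g_stem_W, Named("stem_b") = g_stem_b,
        Named("blocks") = gbl, Named("head_w") = g_head_w,
        Named("head_wm") = g_head_wm, Named("head_b") = g_head_b,
        Named("lin_w") = g_lin_w);
  }
  return res;
}
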