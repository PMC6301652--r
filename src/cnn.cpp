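// Compact convolutional-network engine: same-padding convolutions (im2col +
// GEMM), max pooling with stride 2, fully connected layers, softmax
// cross-entropy, and mini-batch SGD with momentum.  The whole mini-batch is
// processed as one stacked GEMM per layer (rows of every conv-domain matrix
// are image-major blocks of H*W pixels), which keeps single-core BLAS
// throughput high.  Backpropagation is implemented by hand and verified
// against numerical gradients in the test suite.  Everything is
// deterministic: initial weights and per-epoch shuffle orders are produced
// on the R side from a seeded RNG.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

enum LayerType { CONV = 0, POOL = 1, FC = 2 };

struct Layer {
  int type;
  int k = 0, cin = 0, cout = 0;
  bool relu = false;
  bool trainable = true;
  arma::mat W;
  arma::vec b;
  arma::mat vW;
  arma::vec vb;
};

struct Model {
  int H, Wd, C, classes;
  std::vector<Layer> layers;
  std::vector<int> hs, ws, cs;   // spatial dims entering each layer
  int flat_at = -1;              // index of the first FC layer
};

Model parse_model(const List& rlayers, int H, int Wd, int C, int classes) {
  Model m;
  m.H = H; m.Wd = Wd; m.C = C; m.classes = classes;
  int h = H, w = Wd, c = C;
  bool flat = false;
  for (int l = 0; l < rlayers.size(); ++l) {
    List rl = rlayers[l];
    std::string type = as<std::string>(rl["type"]);
    Layer L;
    m.hs.push_back(h); m.ws.push_back(w); m.cs.push_back(c);
    if (type == "conv") {
      if (flat) stop("conv layer after a fully connected layer");
      L.type = CONV;
      L.k = as<int>(rl["k"]);
      if (L.k % 2 == 0) stop("conv kernel size must be odd");
      L.cin = c;
      L.W = as<arma::mat>(rl["W"]);
      L.b = as<arma::vec>(rl["b"]);
      L.cout = (int)L.b.n_elem;
      if ((int)L.W.n_rows != L.k * L.k * L.cin || (int)L.W.n_cols != L.cout)
        stop("conv weight shape mismatch at layer %d", l + 1);
      L.relu = true;
      c = L.cout;
    } else if (type == "pool") {
      if (flat) stop("pool layer after a fully connected layer");
      L.type = POOL;
      L.k = as<int>(rl["k"]);
      if (h < L.k || w < L.k)
        stop("pooling kernel %d exceeds spatial size %dx%d at layer %d",
             L.k, h, w, l + 1);
      h = (h - L.k) / 2 + 1;
      w = (w - L.k) / 2 + 1;
    } else if (type == "fc") {
      L.type = FC;
      L.W = as<arma::mat>(rl["W"]);
      L.b = as<arma::vec>(rl["b"]);
      L.relu = as<bool>(rl["relu"]);
      if (!flat && (int)L.W.n_rows != h * w * c)
        stop("fully connected input size %d does not match expected %d (input %dx%dx%d)",
             (int)L.W.n_rows, h * w * c, h, w, c);
      if (!flat) { m.flat_at = l; flat = true; }
    } else {
      stop("unknown layer type '%s'", type.c_str());
    }
    if (rl.containsElementNamed("trainable"))
      L.trainable = as<bool>(rl["trainable"]);
    L.vW = arma::zeros<arma::mat>(L.W.n_rows, L.W.n_cols);
    L.vb = arma::zeros<arma::vec>(L.b.n_elem);
    m.layers.push_back(L);
  }
  if (m.layers.empty() || m.layers.back().type != FC)
    stop("network must end in a fully connected layer");
  if ((int)m.layers.back().b.n_elem != classes)
    stop("final layer width %d does not match %d classes",
         (int)m.layers.back().b.n_elem, classes);
  return m;
}

// gather the k x k x cin neighbourhood of every pixel of image block n
// (zero padding); col rows are image-major blocks of H*W
void im2col_block(const arma::mat& A, int n, int H, int W, int C, int k,
                  arma::mat& col) {
  const int pad = k / 2, HW = H * W, base = n * HW;
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int r = dy + k * dx + k * k * c;
        const int oi = dy - pad, oj = dx - pad;
        for (int j = 0; j < W; ++j) {
          const int jj = j + oj;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
          if (i1 <= i0) continue;
          // contiguous run down one column: plain memcpy
          std::memcpy(col.colptr(r) + base + i0 + H * j,
                      A.colptr(c) + base + i0 + oi + H * jj,
                      sizeof(double) * (i1 - i0));
        }
      }
    }
  }
}

void col2im_add_block(const arma::mat& dcol, int n, int H, int W, int C,
                      int k, arma::mat& dA) {
  const int pad = k / 2, HW = H * W, base = n * HW;
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int r = dy + k * dx + k * k * c;
        const int oi = dy - pad, oj = dx - pad;
        for (int j = 0; j < W; ++j) {
          const int jj = j + oj;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
          if (i1 <= i0) continue;
          double* dst = dA.colptr(c) + base + i0 + oi + H * jj;
          const double* src = dcol.colptr(r) + base + i0 + H * j;
          const int len = i1 - i0;
          for (int t = 0; t < len; ++t) dst[t] += src[t];
        }
      }
    }
  }
}

struct Cache {
  std::vector<arma::mat> in;       // activation entering each layer
  std::vector<arma::mat> col;      // stacked im2col (conv layers)
  std::vector<arma::umat> argmax;  // winning input row per output (pool)
  std::vector<arma::mat> pre;      // pre-activation (conv & fc)
};

// forward a batch of bs images; A0 has bs*H*W rows, C columns.
// Returns class probabilities (bs x classes).
arma::mat forward_batch(const Model& m, const arma::mat& A0, int bs,
                        Cache* cache) {
  arma::mat A = A0;
  bool flat = false;
  if (cache) {
    cache->in.assign(m.layers.size(), arma::mat());
    cache->col.assign(m.layers.size(), arma::mat());
    cache->argmax.assign(m.layers.size(), arma::umat());
    cache->pre.assign(m.layers.size(), arma::mat());
  }
  for (size_t l = 0; l < m.layers.size(); ++l) {
    const Layer& L = m.layers[l];
    const int h = m.hs[l], w = m.ws[l], c = m.cs[l];
    if (L.type == CONV) {
      if (cache) cache->in[l] = A;
      arma::mat col(bs * h * w, L.k * L.k * c, arma::fill::zeros);
      for (int n = 0; n < bs; ++n) im2col_block(A, n, h, w, c, L.k, col);
      arma::mat Z = col * L.W;
      Z.each_row() += L.b.t();
      if (cache) { cache->col[l] = std::move(col); cache->pre[l] = Z; }
      A = arma::clamp(Z, 0.0, arma::datum::inf);
    } else if (L.type == POOL) {
      if (cache) cache->in[l] = A;
      const int ho = (h - L.k) / 2 + 1, wo = (w - L.k) / 2 + 1;
      arma::mat O(bs * ho * wo, c);
      arma::umat AM(bs * ho * wo, c);
      for (int n = 0; n < bs; ++n) {
        const int bi = n * h * w, bo = n * ho * wo;
        for (int ch = 0; ch < c; ++ch) {
          for (int jo = 0; jo < wo; ++jo) {
            for (int io = 0; io < ho; ++io) {
              const int i0 = 2 * io, j0 = 2 * jo;
              double best = -arma::datum::inf;
              int bidx = 0;
              for (int dj = 0; dj < L.k; ++dj) {
                for (int di = 0; di < L.k; ++di) {
                  const int p = bi + (i0 + di) + h * (j0 + dj);
                  const double v = A(p, ch);
                  if (v > best) { best = v; bidx = p; }
                }
              }
              O(bo + io + ho * jo, ch) = best;
              AM(bo + io + ho * jo, ch) = (arma::uword)bidx;
            }
          }
        }
      }
      if (cache) cache->argmax[l] = std::move(AM);
      A = std::move(O);
    } else {                       // FC
      if (!flat) {
        // conv-domain (bs*hw x c) -> fc-domain (bs x hw*c)
        const int hw = h * w;
        arma::mat F(bs, hw * c);
        for (int n = 0; n < bs; ++n)
          for (int ch = 0; ch < c; ++ch)
            for (int p = 0; p < hw; ++p)
              F(n, p + hw * ch) = A(n * hw + p, ch);
        A = std::move(F);
        flat = true;
      }
      if (cache) cache->in[l] = A;
      arma::mat Z = A * L.W;
      Z.each_row() += L.b.t();
      if (cache) cache->pre[l] = Z;
      A = L.relu ? arma::clamp(Z, 0.0, arma::datum::inf) : Z;
    }
  }
  // row-wise stable softmax
  arma::vec mx = arma::max(A, 1);
  A.each_col() -= mx;
  A = arma::exp(A);
  arma::vec s = arma::sum(A, 1);
  A.each_col() /= s;
  return A;
}

// backward a batch; accumulates summed gradients into gW/gb and returns the
// summed cross-entropy loss
double backward_batch(const Model& m, const arma::mat& A0, int bs,
                      const std::vector<int>& y,
                      std::vector<arma::mat>& gW, std::vector<arma::vec>& gb) {
  Cache cache;
  arma::mat P = forward_batch(m, A0, bs, &cache);
  double loss = 0.0;
  arma::mat D = P;                // dL/dlogits, summed convention
  for (int n = 0; n < bs; ++n) {
    loss += -std::log(std::max(P(n, y[n]), 1e-300));
    D(n, y[n]) -= 1.0;
  }
  bool in_flat = true;
  for (int l = (int)m.layers.size() - 1; l >= 0; --l) {
    const Layer& L = m.layers[l];
    const int h = m.hs[l], w = m.ws[l], c = m.cs[l];
    if (L.type == FC) {
      if (L.relu) D %= arma::conv_to<arma::mat>::from(cache.pre[l] > 0);
      gW[l] += cache.in[l].t() * D;
      gb[l] += arma::sum(D, 0).t();
      D = D * L.W.t();
      if (l == m.flat_at) {
        // fc-domain (bs x hw*c) -> conv-domain (bs*hw x c)
        const int hw = h * w;
        arma::mat G(bs * hw, c);
        for (int n = 0; n < bs; ++n)
          for (int ch = 0; ch < c; ++ch)
            for (int p = 0; p < hw; ++p)
              G(n * hw + p, ch) = D(n, p + hw * ch);
        D = std::move(G);
        in_flat = false;
      }
    } else if (L.type == POOL) {
      const int ho = (h - L.k) / 2 + 1, wo = (w - L.k) / 2 + 1;
      arma::mat dA(bs * h * w, c, arma::fill::zeros);
      const arma::umat& AM = cache.argmax[l];
      for (int q = 0; q < bs * ho * wo; ++q)
        for (int ch = 0; ch < c; ++ch)
          dA(AM(q, ch), ch) += D(q, ch);
      D = std::move(dA);
    } else {                       // CONV
      arma::mat dZ = D % arma::conv_to<arma::mat>::from(cache.pre[l] > 0);
      gW[l] += cache.col[l].t() * dZ;
      gb[l] += arma::sum(dZ, 0).t();
      arma::mat dcol = dZ * L.W.t();
      arma::mat dA(bs * h * w, c, arma::fill::zeros);
      for (int n = 0; n < bs; ++n)
        col2im_add_block(dcol, n, h, w, c, L.k, dA);
      D = std::move(dA);
    }
  }
  (void)in_flat;
  return loss;
}

// gather images `ids` (0-based) from the R array into a stacked matrix
arma::mat gather_batch(const NumericVector& X, int HW, int C,
                       const std::vector<int>& ids) {
  const int bs = (int)ids.size();
  arma::mat A(bs * HW, C);
  for (int n = 0; n < bs; ++n) {
    const double* ptr = X.begin() + (size_t)ids[n] * HW * C;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < HW; ++p)
        A(n * HW + p, c) = ptr[p + (size_t)HW * c];
  }
  return A;
}

List export_layers(const Model& m, const List& rlayers) {
  List out(rlayers.size());
  for (int l = 0; l < rlayers.size(); ++l) {
    List rl = clone(as<List>(rlayers[l]));
    if (m.layers[l].type != POOL) {
      rl["W"] = wrap(m.layers[l].W);
      rl["b"] = wrap(m.layers[l].b);
    }
    out[l] = rl;
  }
  out.attr("names") = rlayers.attr("names");
  return out;
}

double mean_loss(const Model& m, const NumericVector& X,
                 const IntegerVector& y, int HW, int C) {
  const int N = y.size();
  double tot = 0.0;
  const int chunk = 64;
  for (int start = 0; start < N; start += chunk) {
    const int bs = std::min(chunk, N - start);
    std::vector<int> ids(bs);
    for (int t = 0; t < bs; ++t) ids[t] = start + t;
    arma::mat P = forward_batch(m, gather_batch(X, HW, C, ids), bs, nullptr);
    for (int t = 0; t < bs; ++t)
      tot += -std::log(std::max(P(t, y[start + t]), 1e-300));
  }
  return tot / std::max(1, N);
}

}  // namespace

// Pre-activation response of a single convolution layer on one image,
// exercising exactly the engine's im2col + GEMM path (used by the
// convolution-oracle tests).
// [[Rcpp::export]]
NumericMatrix cpp_cnn_conv_response(NumericVector X, IntegerVector dims,
                                    arma::mat W, arma::vec b, int k) {
  const int H = dims[0], Wd = dims[1], C = dims[2];
  std::vector<int> ids(1, 0);
  arma::mat A = gather_batch(X, H * Wd, C, ids);
  arma::mat col(H * Wd, k * k * C, arma::fill::zeros);
  im2col_block(A, 0, H, Wd, C, k, col);
  arma::mat Z = col * W;
  Z.each_row() += b.t();
  return wrap(Z);
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_forward(NumericVector X, IntegerVector dims, List layers,
                              int classes) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  Model m = parse_model(layers, H, W, C, classes);
  NumericMatrix out(N, classes);
  const int chunk = 64;
  for (int start = 0; start < N; start += chunk) {
    const int bs = std::min(chunk, N - start);
    std::vector<int> ids(bs);
    for (int t = 0; t < bs; ++t) ids[t] = start + t;
    arma::mat P = forward_batch(m, gather_batch(X, H * W, C, ids), bs,
                                nullptr);
    for (int t = 0; t < bs; ++t)
      for (int k = 0; k < classes; ++k) out(start + t, k) = P(t, k);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cnn_loss_grad(NumericVector X, IntegerVector dims, IntegerVector y,
                       List layers, int classes) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  Model m = parse_model(layers, H, W, C, classes);
  std::vector<arma::mat> gW(m.layers.size());
  std::vector<arma::vec> gb(m.layers.size());
  for (size_t l = 0; l < m.layers.size(); ++l) {
    gW[l] = arma::zeros<arma::mat>(m.layers[l].W.n_rows, m.layers[l].W.n_cols);
    gb[l] = arma::zeros<arma::vec>(m.layers[l].b.n_elem);
  }
  std::vector<int> ids(N), yy(N);
  for (int n = 0; n < N; ++n) { ids[n] = n; yy[n] = y[n]; }
  double loss = backward_batch(m, gather_batch(X, H * W, C, ids), N, yy,
                               gW, gb) / N;
  List grads(m.layers.size());
  for (size_t l = 0; l < m.layers.size(); ++l) {
    if (m.layers[l].type == POOL) continue;
    grads[l] = List::create(_["W"] = wrap(gW[l] / N), _["b"] = wrap(gb[l] / N));
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// [[Rcpp::export]]
List cpp_cnn_train(NumericVector X, IntegerVector dims, IntegerVector y,
                   NumericVector Xval, IntegerVector yval, List layers,
                   int classes, int epochs, int batch, double lr,
                   double momentum, IntegerMatrix order) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  Model m = parse_model(layers, H, W, C, classes);
  std::vector<double> loss_hist, val_hist;
  std::vector<arma::mat> gW(m.layers.size());
  std::vector<arma::vec> gb(m.layers.size());
  const bool has_val = yval.size() > 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    int seen = 0;
    for (int start = 0; start < N; start += batch) {
      const int bs = std::min(batch, N - start);
      std::vector<int> ids(bs), yy(bs);
      for (int t = 0; t < bs; ++t) {
        ids[t] = order(start + t, ep) - 1;   // 1-based from R
        yy[t] = y[ids[t]];
      }
      for (size_t l = 0; l < m.layers.size(); ++l) {
        gW[l] = arma::zeros<arma::mat>(m.layers[l].W.n_rows,
                                       m.layers[l].W.n_cols);
        gb[l] = arma::zeros<arma::vec>(m.layers[l].b.n_elem);
      }
      ep_loss += backward_batch(m, gather_batch(X, H * W, C, ids), bs, yy,
                                gW, gb);
      seen += bs;
      for (size_t l = 0; l < m.layers.size(); ++l) {
        Layer& L = m.layers[l];
        if (L.type == POOL || !L.trainable) continue;
        L.vW = momentum * L.vW - lr * (gW[l] / bs);
        L.vb = momentum * L.vb - lr * (gb[l] / bs);
        L.W += L.vW;
        L.b += L.vb;
      }
      Rcpp::checkUserInterrupt();
    }
    loss_hist.push_back(ep_loss / std::max(1, seen));
    if (has_val) val_hist.push_back(mean_loss(m, Xval, yval, H * W, C));
  }
  return List::create(
    _["layers"] = export_layers(m, layers),
    _["loss_history"] = wrap(loss_hist),
    _["val_loss_history"] = wrap(val_hist));
}
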