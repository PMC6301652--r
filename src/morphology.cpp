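// Low-level raster primitives: rank filtering, binary morphology, connected
// components, exact Euclidean distance transform, thinning and
// watershed/Voronoi flooding.  All matrices are column-major (R layout),
// masks are 0/1 integer matrices.

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <functional>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int window) {
  const int h = img.nrow(), w = img.ncol(), r = window / 2;
  NumericMatrix out(h, w);
  std::vector<double> buf;
  buf.reserve(static_cast<size_t>(window) * window);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      buf.clear();
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = clampi(j + dj, 0, w - 1);
        for (int di = -r; di <= r; ++di) {
          buf.push_back(img(clampi(i + di, 0, h - 1), jj));
        }
      }
      std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
      out(i, j) = buf[buf.size() / 2];
    }
  }
  return out;
}

// Binary erosion/dilation with an arbitrary structuring element given as
// offset pairs (rows of `offsets`: drow, dcol).  Out-of-image pixels count
// as background for both operations (scipy binary_* convention).
// [[Rcpp::export]]
IntegerMatrix cpp_binary_morph(const IntegerMatrix& mask,
                               const IntegerMatrix& offsets,
                               bool dilate) {
  const int h = mask.nrow(), w = mask.ncol(), m = offsets.nrow();
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      bool acc = !dilate;  // erosion: AND-accumulator; dilation: OR
      for (int s = 0; s < m; ++s) {
        const int ii = i + offsets(s, 0), jj = j + offsets(s, 1);
        const bool v = (ii >= 0 && ii < h && jj >= 0 && jj < w)
          ? mask(ii, jj) != 0 : false;
        if (dilate) { if (v) { acc = true; break; } }
        else        { if (!v) { acc = false; break; } }
      }
      out(i, j) = acc ? 1 : 0;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      stack.clear();
      stack.push_back(i + h * j);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % h, pj = p / h;
        for (int k = 0; k < nn; ++k) {
          const int ii = pi + dr8[k], jj = pj + dc8[k];
          if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
          if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + h * jj);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform, lower-envelope-of-parabolas method.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k]))
      / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k]))
        / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance of each foreground pixel to the nearest
// background pixel; background pixels carry 0.  Caller guarantees that at
// least one background pixel exists.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const IntegerMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  // large finite sentinel (true infinity breaks the envelope comparisons)
  const double inf = 1e20;
  NumericMatrix g(h, w);
  // column pass
  std::vector<double> f(std::max(h, w)), d(std::max(h, w));
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) f[i] = mask(i, j) != 0 ? inf : 0.0;
    dt1d(f, d, h);
    for (int i = 0; i < h; ++i) g(i, j) = d[i];
  }
  // row pass
  NumericMatrix out(h, w);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) f[j] = g(i, j);
    dt1d(f, d, w);
    for (int j = 0; j < w; ++j) out(i, j) = std::sqrt(d[j]);
  }
  return out;
}

// Zhang-Suen thinning to a 1-pixel-wide, 8-connectivity-preserving
// skeleton.  Candidates are marked from the frozen image per the classic
// two-subiteration rules, but deleted sequentially under a simple-point
// guard (crossing number 1 and at least two neighbours on the *current*
// image): the parallel formulation alone annihilates isolated 2x2 blocks,
// which would change the component count.
// [[Rcpp::export]]
IntegerMatrix cpp_zhang_suen(const IntegerMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix img = clone(mask);
  std::vector<int> cand;
  bool changed = true;
  auto P = [&](int i, int j) -> int {
    if (i < 0 || i >= h || j < 0 || j >= w) return 0;
    return img(i, j) != 0 ? 1 : 0;
  };
  auto neigh = [&](int i, int j, int* p) {
    p[0] = P(i - 1, j);     p[1] = P(i - 1, j + 1);
    p[2] = P(i, j + 1);     p[3] = P(i + 1, j + 1);
    p[4] = P(i + 1, j);     p[5] = P(i + 1, j - 1);
    p[6] = P(i, j - 1);     p[7] = P(i - 1, j - 1);
  };
  auto crossings = [](const int* p) {
    int a = 0;
    for (int k = 0; k < 8; ++k) if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
    return a;
  };
  int p[8];
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      cand.clear();
      for (int j = 0; j < w; ++j) {
        for (int i = 0; i < h; ++i) {
          if (img(i, j) == 0) continue;
          neigh(i, j, p);
          const int b = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (b < 2 || b > 6) continue;
          if (crossings(p) != 1) continue;
          // p2=p[0], p4=p[2], p6=p[4], p8=p[6]
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0 || p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0 || p[0] * p[4] * p[6] != 0) continue;
          }
          cand.push_back(i + h * j);
        }
      }
      for (size_t k = 0; k < cand.size(); ++k) {
        const int i = cand[k] % h, j = cand[k] / h;
        neigh(i, j, p);   // re-check on the current image
        const int b = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
        if (b < 2 || crossings(p) != 1) continue;
        img(i, j) = 0;
        changed = true;
      }
    }
  }
  return img;
}

// Watershed split of touching blobs: flood the distance map downhill from
// its regional maxima; basins whose peak rises less than `tol` above a
// saddle merge into the higher basin, otherwise the saddle pixels become
// ridge (removed from the mask).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed_split(const NumericMatrix& dist, double tol) {
  const int h = dist.nrow(), w = dist.ncol(), n = h * w;
  // order foreground pixels by decreasing distance
  std::vector<int> idx;
  idx.reserve(n);
  for (int p = 0; p < n; ++p) if (dist[p] > 0) idx.push_back(p);
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    return dist[a] > dist[b];
  });
  std::vector<int> parent(n, -1);       // union-find over basin ids = pixels
  std::vector<double> peak(n, 0.0);     // per-root basin peak height
  std::vector<int> state(n, 0);         // 0 unseen, 1 in basin, 2 ridge
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> roots;
  for (size_t t = 0; t < idx.size(); ++t) {
    const int p = idx[t], pi = p % h, pj = p / h;
    roots.clear();
    for (int k = 0; k < 8; ++k) {
      const int ii = pi + dr[k], jj = pj + dc[k];
      if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
      const int q = ii + h * jj;
      if (state[q] == 1) {
        const int r = find(q);
        if (std::find(roots.begin(), roots.end(), r) == roots.end())
          roots.push_back(r);
      }
    }
    if (roots.empty()) {                  // new regional maximum
      parent[p] = p;
      peak[p] = dist[p];
      state[p] = 1;
    } else if (roots.size() == 1) {
      parent[p] = roots[0];
      state[p] = 1;
    } else {
      // merge shallow basins (prominence <= tol) into the highest one
      int best = roots[0];
      for (size_t k = 1; k < roots.size(); ++k)
        if (peak[roots[k]] > peak[best]) best = roots[k];
      bool ridge = false;
      for (size_t k = 0; k < roots.size(); ++k) {
        if (roots[k] == best) continue;
        if (peak[roots[k]] - dist[p] <= tol) {
          parent[roots[k]] = best;
        } else {
          ridge = true;
        }
      }
      if (ridge) {
        state[p] = 2;
      } else {
        parent[p] = best;
        state[p] = 1;
      }
    }
  }
  IntegerMatrix out(h, w);
  for (int p = 0; p < n; ++p) out[p] = (state[p] == 1) ? 1 : 0;
  return out;
}

// Voronoi tessellation lines of labelled particles: flood the background
// outward by increasing distance-to-particle; background pixels reached by
// two different labels become line pixels.
// [[Rcpp::export]]
IntegerMatrix cpp_voronoi_lines(const IntegerMatrix& labels,
                                const NumericMatrix& bgdist) {
  const int h = labels.nrow(), w = labels.ncol(), n = h * w;
  std::vector<int> lab(n, 0);
  std::vector<int> ridge(n, 0);
  typedef std::pair<double, int> QE;   // (distance, pixel)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int p = 0; p < n; ++p) {
    if (labels[p] != 0) { lab[p] = labels[p]; }
  }
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  // seed the queue with background pixels adjacent to particles
  for (int p = 0; p < n; ++p) {
    if (labels[p] == 0) continue;
    const int pi = p % h, pj = p / h;
    for (int k = 0; k < 8; ++k) {
      const int ii = pi + dr[k], jj = pj + dc[k];
      if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
      const int q = ii + h * jj;
      if (labels[q] == 0) pq.push(QE(bgdist[q], q));
    }
  }
  while (!pq.empty()) {
    const int p = pq.top().second;
    pq.pop();
    if (lab[p] != 0 || ridge[p] != 0) continue;
    const int pi = p % h, pj = p / h;
    int owner = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      const int ii = pi + dr[k], jj = pj + dc[k];
      if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
      const int q = ii + h * jj;
      if (lab[q] != 0) {
        if (owner == 0) owner = lab[q];
        else if (lab[q] != owner) conflict = true;
      }
    }
    if (conflict) {
      ridge[p] = 1;
    } else if (owner != 0) {
      lab[p] = owner;
      for (int k = 0; k < 8; ++k) {
        const int ii = pi + dr[k], jj = pj + dc[k];
        if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
        const int q = ii + h * jj;
        if (lab[q] == 0 && ridge[q] == 0) pq.push(QE(bgdist[q], q));
      }
    }
  }
  IntegerMatrix out(h, w);
  for (int p = 0; p < n; ++p) out[p] = ridge[p];
  return out;
}

// 2-D convolution, output same size as input.  border: 0 = zero padding,
// 1 = edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_same(const NumericMatrix& img,
                             const NumericMatrix& kernel, int border) {
  const int h = img.nrow(), w = img.ncol();
  const int kh = kernel.nrow(), kw = kernel.ncol();
  const int rh = kh / 2, rw = kw / 2;
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int b = 0; b < kw; ++b) {
        int jj = j + b - rw;
        for (int a = 0; a < kh; ++a) {
          int ii = i + a - rh;
          double v;
          if (ii >= 0 && ii < h && jj >= 0 && jj < w) {
            v = img(ii, jj);
          } else if (border == 1) {
            v = img(clampi(ii, 0, h - 1), clampi(jj, 0, w - 1));
          } else {
            v = 0.0;
          }
          acc += v * kernel(a, b);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}
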