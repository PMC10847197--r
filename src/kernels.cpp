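#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---- union-find ------------------------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass 8-connected labelling of a binary matrix. Returns integer labels
// 1..k in raster-scan discovery order, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // neighbours already scanned in column-major order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      int nb[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int lmin = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0 && (lmin == 0 || l < lmin)) lmin = l;
      }
      if (lmin == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = lmin;
        for (int k = 0; k < 4; ++k) {
          int rr = nb[k][0], cc = nb[k][1];
          if (rr < 0 || rr >= nr || cc < 0) continue;
          int l = lab(rr, cc);
          if (l > 0) uf_union(parent, l, lmin);
        }
      }
    }
  }

  // flatten and renumber compactly in discovery order of the root
  std::vector<int> newlab(next, 0);
  int k = 0;
  for (int i = 1; i < next; ++i) {
    int root = uf_find(parent, i);
    if (newlab[root] == 0) newlab[root] = ++k;
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = newlab[uf_find(parent, lab(r, c))];
  return lab;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ------

static void dt1d(std::vector<double>& f, std::vector<double>& d, double w2) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Exact anisotropic EDT of a 3D seed mask (H x W x S array, column-major).
// spacing = (row, col, section) physical step sizes. Returns distances in the
// same physical units; Inf where no seed exists anywhere.
// [[Rcpp::export]]
NumericVector cpp_edt3d(const LogicalVector& seed, const IntegerVector& dims,
                        const NumericVector& spacing) {
  const int H = dims[0], W = dims[1], S = dims[2];
  // large finite sentinel: infinity would produce inf-inf = NaN inside the
  // lower-envelope recursion; 1e12 nm^2 dwarfs any squared distance here
  const double INF = 1e12;
  std::vector<double> g((size_t)H * W * S);
  for (R_xlen_t i = 0; i < seed.size(); ++i) g[i] = seed[i] ? 0.0 : INF;

  std::vector<double> f(std::max(H, std::max(W, S))), d(f.size());

  // pass along rows (dimension 1, step spacing[0])
  double w2 = spacing[0] * spacing[0];
  for (int s = 0; s < S; ++s)
    for (int c = 0; c < W; ++c) {
      size_t off = (size_t)s * H * W + (size_t)c * H;
      for (int r = 0; r < H; ++r) f[r] = g[off + r];
      dt1d(f, d, w2);
      for (int r = 0; r < H; ++r) g[off + r] = d[r];
    }

  // pass along columns (dimension 2, step spacing[1])
  w2 = spacing[1] * spacing[1];
  for (int s = 0; s < S; ++s)
    for (int r = 0; r < H; ++r) {
      size_t base = (size_t)s * H * W + r;
      for (int c = 0; c < W; ++c) f[c] = g[base + (size_t)c * H];
      dt1d(f, d, w2);
      for (int c = 0; c < W; ++c) g[base + (size_t)c * H] = d[c];
    }

  // pass along sections (dimension 3, step spacing[2])
  w2 = spacing[2] * spacing[2];
  if (S > 1) {
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        size_t base = (size_t)c * H + r;
        for (int s = 0; s < S; ++s) f[s] = g[base + (size_t)s * H * W];
        dt1d(f, d, w2);
        for (int s = 0; s < S; ++s) g[base + (size_t)s * H * W] = d[s];
      }
  }

  NumericVector out((R_xlen_t)H * W * S);
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = (g[i] >= 0.5 * INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// ---- bilinear affine warp --------------------------------------------------

// Resample img so that output(r, c) = img(Ainv %*% (r, c, 1)), 0-based
// coordinates, bilinear interpolation. Ainv is the output->input mapping,
// a 2x3 matrix in (row, col) convention. Pixels sampled outside the frame
// receive `fill` and valid = FALSE.
// [[Rcpp::export]]
List cpp_warp_affine(const NumericMatrix& img, const NumericMatrix& Ainv,
                     double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  LogicalMatrix valid(nr, nc);
  const double a11 = Ainv(0, 0), a12 = Ainv(0, 1), t1 = Ainv(0, 2);
  const double a21 = Ainv(1, 0), a22 = Ainv(1, 1), t2 = Ainv(1, 2);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double sr = a11 * r + a12 * c + t1;
      double sc = a21 * r + a22 * c + t2;
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      if (r0 < 0 || c0 < 0 || r0 + 1 > nr - 1 || c0 + 1 > nc - 1) {
        // allow exact border hit
        if (sr >= 0 && sc >= 0 && sr <= nr - 1 && sc <= nc - 1) {
          int rr = std::min(r0, nr - 1), cc = std::min(c0, nc - 1);
          double fr = sr - rr, fc = sc - cc;
          int r1 = std::min(rr + 1, nr - 1), c1 = std::min(cc + 1, nc - 1);
          out(r, c) = (1 - fr) * (1 - fc) * img(rr, cc) + fr * (1 - fc) * img(r1, cc) +
                      (1 - fr) * fc * img(rr, c1) + fr * fc * img(r1, c1);
          valid(r, c) = true;
        } else {
          out(r, c) = fill;
          valid(r, c) = false;
        }
      } else {
        double fr = sr - r0, fc = sc - c0;
        out(r, c) = (1 - fr) * (1 - fc) * img(r0, c0) + fr * (1 - fc) * img(r0 + 1, c0) +
                    (1 - fr) * fc * img(r0, c0 + 1) + fr * fc * img(r0 + 1, c0 + 1);
        valid(r, c) = true;
      }
    }
  }
  return List::create(_["image"] = out, _["valid"] = valid);
}
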