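#include <Rcpp.h>
using namespace Rcpp;

// Reflect (symmetric, edge-included) index into [0, n-1]: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int refl(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Pad a column-major h x w matrix by R on all sides with symmetric reflection.
static NumericMatrix pad_reflect(const NumericMatrix& x, int R) {
  const int h = x.nrow(), w = x.ncol();
  NumericMatrix p(h + 2 * R, w + 2 * R);
  for (int j = 0; j < w + 2 * R; ++j) {
    const int sj = refl(j - R, w);
    const double* src = &x(0, sj);
    double* dst = &p(0, j);
    for (int i = 0; i < R; ++i) dst[i] = src[refl(i - R, h)];
    std::copy(src, src + h, dst + R);
    for (int i = 0; i < R; ++i) dst[R + h + i] = src[refl(h + i, h)];
  }
  return p;
}

// Horizontal correlation pass: out(i, j) = sum_k u[k] * p(i, j + k), j = 0..w-1.
// p has hp rows and >= w + len(u) - 1 columns starting at column offset `off`.
static void hpass(const NumericMatrix& p, int off, const NumericVector& u,
                  int w, NumericMatrix& out) {
  const int hp = p.nrow(), ku = u.size();
  std::fill(out.begin(), out.end(), 0.0);
  for (int k = 0; k < ku; ++k) {
    const double uk = u[k];
    if (uk == 0.0) continue;
    for (int j = 0; j < w; ++j) {
      const double* src = &p(0, off + j + k);
      double* dst = &out(0, j);
      for (int i = 0; i < hp; ++i) dst[i] += uk * src[i];
    }
  }
}

// Vertical pass: out(i, j) = sum_k v[k] * t(i + off + k, j), i = 0..h-1; accumulate.
static void vpass_acc(const NumericMatrix& t, int off, const NumericVector& v,
                      int h, double sign, NumericMatrix& out) {
  const int w = out.ncol(), kv = v.size();
  for (int j = 0; j < w; ++j) {
    const double* src = &t(0, j);
    double* dst = &out(0, j);
    for (int k = 0; k < kv; ++k) {
      const double vk = sign * v[k];
      if (vk == 0.0) continue;
      const double* s = src + off + k;
      for (int i = 0; i < h; ++i) dst[i] += vk * s[i];
    }
  }
}

// One filter: resp = corr(x, u1 (x) v1) + corr(x, u2 (x) v2), kernels given by their
// separable 1-D factors (row factor u applied along columns/x, v along rows/y).
static void filter_one(const NumericMatrix& pad, int R, int h, int w,
                       const List& f, NumericMatrix& tmp, NumericMatrix& resp) {
  std::fill(resp.begin(), resp.end(), 0.0);
  NumericVector u1 = f["u1"], v1 = f["v1"];
  const int r = (u1.size() - 1) / 2;
  hpass(pad, R - r, u1, w, tmp);
  vpass_acc(tmp, R - r, v1, h, 1.0, resp);
  if (f.containsElementNamed("u2")) {
    NumericVector u2 = f["u2"], v2 = f["v2"];
    if (u2.size() > 0) {
      hpass(pad, R - r, u2, w, tmp);
      vpass_acc(tmp, R - r, v2, h, 1.0, resp);
    }
  }
}

static int max_radius(const List& filters) {
  int R = 1;
  for (int q = 0; q < filters.size(); ++q) {
    List f = filters[q];
    NumericVector u1 = f["u1"];
    int r = (u1.size() - 1) / 2;
    if (r > R) R = r;
  }
  return R;
}

// [[Rcpp::export]]
List cpp_bank_responses(const NumericMatrix& x, const List& filters) {
  const int h = x.nrow(), w = x.ncol();
  const int R = max_radius(filters);
  NumericMatrix pad = pad_reflect(x, R);
  NumericMatrix tmp(h + 2 * R, w);
  List out(filters.size());
  for (int q = 0; q < filters.size(); ++q) {
    NumericMatrix resp(h, w);
    filter_one(pad, R, h, w, filters[q], tmp, resp);
    out[q] = resp;
  }
  return out;
}

// Per-patch mean and population variance of every filter response over a grid of
// non-overlapping patch_px x patch_px patches anchored at (0, 0). Patches are indexed
// row-major (column index fastest). Returns npatch x nfilter matrices.
// [[Rcpp::export]]
List cpp_bank_patch_moments(const NumericMatrix& x, const List& filters, int patch_px) {
  const int h = x.nrow(), w = x.ncol();
  const int npr = h / patch_px, npc = w / patch_px;
  const int npatch = npr * npc, nf = filters.size();
  const double npix = (double)patch_px * patch_px;
  const int R = max_radius(filters);
  NumericMatrix pad = pad_reflect(x, R);
  NumericMatrix tmp(h + 2 * R, w);
  NumericMatrix resp(h, w);
  NumericMatrix means(npatch, nf), vars(npatch, nf);
  for (int q = 0; q < nf; ++q) {
    filter_one(pad, R, h, w, filters[q], tmp, resp);
    for (int pr = 0; pr < npr; ++pr) {
      for (int pc = 0; pc < npc; ++pc) {
        double s = 0.0, s2 = 0.0;
        for (int j = pc * patch_px; j < (pc + 1) * patch_px; ++j) {
          const double* col = &resp(0, j);
          for (int i = pr * patch_px; i < (pr + 1) * patch_px; ++i) {
            const double z = col[i];
            s += z;
            s2 += z * z;
          }
        }
        const int row = pr * npc + pc;
        const double m = s / npix;
        means(row, q) = m;
        double v = s2 / npix - m * m;
        vars(row, q) = v > 0.0 ? v : 0.0;
      }
    }
  }
  return List::create(_["means"] = means, _["vars"] = vars);
}

// Plain separable correlation with reflect padding (used for Gaussian smoothing in the
// synthetic-texture generator).
// [[Rcpp::export]]
NumericMatrix cpp_separable_corr(const NumericMatrix& x, const NumericVector& u,
                                 const NumericVector& v) {
  const int h = x.nrow(), w = x.ncol();
  const int r = (u.size() - 1) / 2;
  NumericMatrix pad = pad_reflect(x, r);
  NumericMatrix tmp(h + 2 * r, w);
  NumericMatrix resp(h, w);
  hpass(pad, 0, u, w, tmp);
  vpass_acc(tmp, 0, v, h, 1.0, resp);
  return resp;
}
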