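#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// Distances are measured between pixel centres; a foreground pixel whose
// 4-neighbour is background gets distance 1.
// ---------------------------------------------------------------------------

static const double DT_INF = 1e20;

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  NumericMatrix D(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      D(i, j) = fg(i, j) ? DT_INF : 0.0;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // transform down each column
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = D(i, j);
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) D(i, j) = d[i];
  }
  // then across each row
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = D(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) D(i, j) = d[j];
  }
  return D;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (4- or 8-connectivity), iterative DFS.
// Background pixels get label 0; components numbered from 1 in scan order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix m, int connectivity) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  int nn = (connectivity == 8) ? 8 : 4;

  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (m(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Zhang-Suen two-subiteration parallel thinning.
//
// Neighbour order (p2..p9) follows the original paper: N, NE, E, SE, S, SW,
// W, NW of the candidate pixel.  The image is padded with one background ring
// so roots touching the border thin like interior structure.  A sequential
// clean-up pass removes residual 2x2 foreground squares by deleting simple
// pixels (Rutovitz crossing number == 1), which keeps topology intact.
// ---------------------------------------------------------------------------

// crossing number A(p) and neighbour count B(p) on padded buffer
static inline void zs_counts(const std::vector<unsigned char> &img, int NR,
                             int r, int c, int &A, int &B, int p[10]) {
  p[2] = img[(r - 1) + c * NR];
  p[3] = img[(r - 1) + (c + 1) * NR];
  p[4] = img[r + (c + 1) * NR];
  p[5] = img[(r + 1) + (c + 1) * NR];
  p[6] = img[(r + 1) + c * NR];
  p[7] = img[(r + 1) + (c - 1) * NR];
  p[8] = img[r + (c - 1) * NR];
  p[9] = img[(r - 1) + (c - 1) * NR];
  B = p[2] + p[3] + p[4] + p[5] + p[6] + p[7] + p[8] + p[9];
  A = 0;
  for (int k = 2; k <= 9; ++k) {
    int nxt = (k == 9) ? p[2] : p[k + 1];
    if (p[k] == 0 && nxt == 1) ++A;
  }
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin_zs(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  int NR = nr + 2, NC = nc + 2;
  std::vector<unsigned char> img((size_t)NR * NC, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[(i + 1) + (size_t)(j + 1) * NR] = mask(i, j) ? 1 : 0;

  int p[10];
  std::vector<int> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 1; c < NC - 1; ++c) {
        for (int r = 1; r < NR - 1; ++r) {
          if (!img[r + (size_t)c * NR]) continue;
          int A, B;
          zs_counts(img, NR, r, c, A, B, p);
          if (B < 2 || B > 6 || A != 1) continue;
          if (sub == 0) {
            if (p[2] * p[4] * p[6] != 0) continue;
            if (p[4] * p[6] * p[8] != 0) continue;
          } else {
            if (p[2] * p[4] * p[8] != 0) continue;
            if (p[2] * p[6] * p[8] != 0) continue;
          }
          del.push_back(r + c * NR);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k) img[del[k]] = 0;
      }
    }
  }

  // remove any residual 2x2 squares without breaking connectivity
  bool progress = true;
  while (progress) {
    progress = false;
    bool any_block = false;
    for (int c = 1; c < NC - 1; ++c) {
      for (int r = 1; r < NR - 1; ++r) {
        if (!(img[r + (size_t)c * NR] && img[(r + 1) + (size_t)c * NR] &&
              img[r + (size_t)(c + 1) * NR] &&
              img[(r + 1) + (size_t)(c + 1) * NR]))
          continue;
        any_block = true;
        int rs[4] = {r, r + 1, r, r + 1};
        int cs[4] = {c, c, c + 1, c + 1};
        for (int t = 0; t < 4; ++t) {
          int A, B;
          zs_counts(img, NR, rs[t], cs[t], A, B, p);
          if (A == 1 && B >= 2 && B <= 7) {
            img[rs[t] + (size_t)cs[t] * NR] = 0;
            progress = true;
            break;
          }
        }
      }
    }
    if (!any_block) break;
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[(i + 1) + (size_t)(j + 1) * NR] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// k x k median filter with replicated borders (k odd).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int k) {
  int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf((size_t)k * k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      size_t n = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int cj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ci = std::min(std::max(i + di, 0), nr - 1);
          buf[n++] = x(ci, cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local neighbourhood mean (box or Gaussian-weighted), separable passes with
// replicated borders.  sigma <= 0 selects the conventional kernel-size-based
// default sigma = 0.3*((k-1)*0.5 - 1) + 0.8.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_local_mean(NumericMatrix x, int k, bool gaussian,
                             double sigma) {
  int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  std::vector<double> w(k);
  if (gaussian) {
    if (sigma <= 0) sigma = 0.3 * ((k - 1) * 0.5 - 1.0) + 0.8;
    double s = 0;
    for (int t = 0; t < k; ++t) {
      double d = t - h;
      w[t] = std::exp(-(d * d) / (2.0 * sigma * sigma));
      s += w[t];
    }
    for (int t = 0; t < k; ++t) w[t] /= s;
  } else {
    for (int t = 0; t < k; ++t) w[t] = 1.0 / k;
  }

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {           // horizontal pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int t = -h; t <= h; ++t) {
        int cj = std::min(std::max(j + t, 0), nc - 1);
        acc += w[t + h] * x(i, cj);
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < nc; ++j) {           // vertical pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int t = -h; t <= h; ++t) {
        int ci = std::min(std::max(i + t, 0), nr - 1);
        acc += w[t + h] * tmp(ci, j);
      }
      out(i, j) = acc;
    }
  }
  return out;
}
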