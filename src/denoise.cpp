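// Spatial-spectral collaborative denoising by block matching.
//
// For each reference 3D patch (spatial x spatial x spectral), the most
// similar patches inside a spatial search window are stacked into a 4D
// group; a separable orthonormal DCT is applied along all four dimensions
// and the coefficients are hard-thresholded at kappa*sigma (first pass)
// or Wiener-shrunk using a pilot estimate (second pass). Patches return
// to the cube by weighted aggregation. Everything is deterministic:
// patch visitation is raster order and distance ties break by raster
// order of the candidate.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<double> vec;

static void dct_matrix(int n, vec& T) {
  T.assign((size_t)n * n, 0.0);
  for (int k = 0; k < n; ++k) {
    double s = (k == 0) ? std::sqrt(1.0 / n) : std::sqrt(2.0 / n);
    for (int j = 0; j < n; ++j)
      T[(size_t)k * n + j] = s * std::cos(M_PI * (j + 0.5) * k / n);
  }
}

// Apply the n x n orthonormal matrix T (or its transpose) along dimension
// `dim` of the 4D array a with extents d[4], column-major strides.
static void apply_T(vec& a, const int d[4], const vec& T, int dim,
                    bool transpose) {
  int n = d[dim];
  size_t stride = 1;
  for (int m = 0; m < dim; ++m) stride *= d[m];
  size_t outer = 1;
  for (int m = dim + 1; m < 4; ++m) outer *= d[m];
  size_t block = stride * n;
  std::vector<double> x(n), y(n);
  for (size_t o = 0; o < outer; ++o) {
    for (size_t s = 0; s < stride; ++s) {
      size_t base = o * block + s;
      for (int i = 0; i < n; ++i) x[i] = a[base + stride * i];
      for (int k = 0; k < n; ++k) {
        double acc = 0.0;
        if (!transpose) {
          const double* row = &T[(size_t)k * n];
          for (int j = 0; j < n; ++j) acc += row[j] * x[j];
        } else {
          for (int j = 0; j < n; ++j) acc += T[(size_t)j * n + k] * x[j];
        }
        y[k] = acc;
      }
      for (int i = 0; i < n; ++i) a[base + stride * i] = y[i];
    }
  }
}

static std::vector<int> patch_positions(int n, int p, int step) {
  std::vector<int> pos;
  for (int i = 0; i + p <= n; i += step) pos.push_back(i);
  if (pos.empty() || pos.back() != n - p) pos.push_back(n - p);
  return pos;
}

// 3x3x3 box mean with clamped borders; coarse prefilter for matching.
static void box_prefilter(const double* x, int R, int C, int CH, vec& out) {
  out.assign((size_t)R * C * CH, 0.0);
  const size_t npix = (size_t)R * C;
  for (int k = 0; k < CH; ++k) {
    for (int c = 0; c < C; ++c) {
      for (int r = 0; r < R; ++r) {
        double acc = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = k + dk;
          if (kk < 0 || kk >= CH) continue;
          for (int dc = -1; dc <= 1; ++dc) {
            int cc = c + dc;
            if (cc < 0 || cc >= C) continue;
            for (int dr = -1; dr <= 1; ++dr) {
              int rr = r + dr;
              if (rr < 0 || rr >= R) continue;
              acc += x[(size_t)rr + (size_t)R * cc + npix * kk];
              ++cnt;
            }
          }
        }
        out[(size_t)r + (size_t)R * c + npix * k] = acc / cnt;
      }
    }
  }
}

struct Cand {
  double dist;
  int r, c, ord;
};

static void bm_pass(const double* noisy, const double* match,
                    const double* pilot, int R, int C, int CH,
                    int ps, int pw, int search, int K, double kappa,
                    double sigma, bool wiener, int step_s, int step_w,
                    vec& out) {
  const size_t npix = (size_t)R * C;
  vec num(npix * CH, 0.0), den(npix * CH, 0.0);
  vec Ts, Tw;
  dct_matrix(ps, Ts);
  dct_matrix(pw, Tw);
  std::vector<vec> Tk(K + 1);
  for (int k = 1; k <= K; ++k) dct_matrix(k, Tk[k]);

  std::vector<int> rows = patch_positions(R, ps, step_s);
  std::vector<int> cols = patch_positions(C, ps, step_s);
  std::vector<int> slabs = patch_positions(CH, pw, step_w);
  const int dsub = (pw >= 4) ? pw / 4 : 1;  // spectral subsample for distance
  const double thr = kappa * sigma;
  const double s2 = sigma * sigma;
  const size_t patch_elems = (size_t)ps * ps * pw;
  vec G, P;
  std::vector<Cand> cands;

  for (size_t wi = 0; wi < slabs.size(); ++wi) {
    int w0 = slabs[wi];
    for (size_t ci = 0; ci < cols.size(); ++ci) {
      int c0 = cols[ci];
      for (size_t ri = 0; ri < rows.size(); ++ri) {
        int r0 = rows[ri];
        // --- match ---
        cands.clear();
        int rlo = std::max(0, r0 - search), rhi = std::min(R - ps, r0 + search);
        int clo = std::max(0, c0 - search), chi = std::min(C - ps, c0 + search);
        int ord = 0;
        for (int c = clo; c <= chi; ++c) {
          for (int r = rlo; r <= rhi; ++r, ++ord) {
            double dist = 0.0;
            for (int k = 0; k < pw; k += dsub) {
              const double* A =
                match + (size_t)(r0) + (size_t)R * c0 + npix * (w0 + k);
              const double* B =
                match + (size_t)(r) + (size_t)R * c + npix * (w0 + k);
              for (int j = 0; j < ps; ++j) {
                for (int i = 0; i < ps; ++i) {
                  double df = A[i + (size_t)R * j] - B[i + (size_t)R * j];
                  dist += df * df;
                }
              }
            }
            cands.push_back({dist, r, c, ord});
          }
        }
        std::sort(cands.begin(), cands.end(),
                  [](const Cand& a, const Cand& b) {
                    return a.dist < b.dist ||
                           (a.dist == b.dist && a.ord < b.ord);
                  });
        int k = std::min<int>(K, (int)cands.size());
        int d[4] = {ps, ps, pw, k};
        // --- gather ---
        G.assign(patch_elems * k, 0.0);
        if (wiener) P.assign(patch_elems * k, 0.0);
        for (int m = 0; m < k; ++m) {
          for (int kk = 0; kk < pw; ++kk) {
            for (int j = 0; j < ps; ++j) {
              size_t src = (size_t)cands[m].r + (size_t)R * (cands[m].c + j) +
                           npix * (w0 + kk);
              size_t dst = (size_t)ps * j + (size_t)ps * ps * kk +
                           patch_elems * m;
              for (int i = 0; i < ps; ++i) {
                G[dst + i] = noisy[src + i];
                if (wiener) P[dst + i] = pilot[src + i];
              }
            }
          }
        }
        // --- transform ---
        for (int m = 0; m < 4; ++m) {
          const vec& T = (m < 2) ? Ts : (m == 2 ? Tw : Tk[k]);
          apply_T(G, d, T, m, false);
          if (wiener) apply_T(P, d, T, m, false);
        }
        double wgt;
        if (!wiener) {
          size_t kept = 0;
          for (size_t i = 0; i < G.size(); ++i) {
            if (i == 0) { ++kept; continue; }  // DC always kept
            if (std::fabs(G[i]) < thr) G[i] = 0.0;
            else ++kept;
          }
          wgt = 1.0 / (double)std::max<size_t>(kept, 1);
        } else {
          double sw2 = 0.0;
          for (size_t i = 0; i < G.size(); ++i) {
            double w;
            if (i == 0) w = 1.0;  // DC passes through
            else {
              double pp = P[i] * P[i];
              double dd = pp + s2;
              w = (dd > 0) ? pp / dd : 1.0;
            }
            G[i] *= w;
            sw2 += w * w;
          }
          wgt = 1.0 / std::max(sw2, 1e-12);
        }
        // --- inverse ---
        for (int m = 3; m >= 0; --m) {
          const vec& T = (m < 2) ? Ts : (m == 2 ? Tw : Tk[k]);
          apply_T(G, d, T, m, true);
        }
        // --- aggregate ---
        for (int m = 0; m < k; ++m) {
          for (int kk = 0; kk < pw; ++kk) {
            for (int j = 0; j < ps; ++j) {
              size_t dst = (size_t)cands[m].r + (size_t)R * (cands[m].c + j) +
                           npix * (w0 + kk);
              size_t src = (size_t)ps * j + (size_t)ps * ps * kk +
                           patch_elems * m;
              for (int i = 0; i < ps; ++i) {
                num[dst + i] += wgt * G[src + i];
                den[dst + i] += wgt;
              }
            }
          }
        }
      }
    }
  }
  out.assign(npix * CH, 0.0);
  for (size_t i = 0; i < out.size(); ++i)
    out[i] = (den[i] > 0) ? num[i] / den[i] : noisy[i];
}

// [[Rcpp::export]]
NumericVector bm_denoise_cpp(NumericVector cube, IntegerVector dims,
                             int spatial, int spectral, int search,
                             int group, double kappa, double sigma,
                             bool wiener, int step_spatial,
                             int step_spectral) {
  const int R = dims[0], C = dims[1], CH = dims[2];
  vec pre, est1, est2;
  box_prefilter(cube.begin(), R, C, CH, pre);
  bm_pass(cube.begin(), pre.data(), nullptr, R, C, CH, spatial, spectral,
          search, group, kappa, sigma, false, step_spatial, step_spectral,
          est1);
  const vec* fin = &est1;
  if (wiener) {
    bm_pass(cube.begin(), est1.data(), est1.data(), R, C, CH, spatial,
            spectral, search, group, kappa, sigma, true, step_spatial,
            step_spectral, est2);
    fin = &est2;
  }
  NumericVector out(fin->begin(), fin->end());
  out.attr("dim") = dims;
  return out;
}
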