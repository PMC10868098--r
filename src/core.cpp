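#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <functional>
#include <cmath>
using namespace Rcpp;

// ---- PSF rendering -------------------------------------------------------

// Integrated symmetric Gaussian PSF: contribution of one emitter at
// continuous pixel coordinate (x, y) (pixel j spans [j, j+1)) to pixel
// (row i, col j) is photons * dPhi_x * dPhi_y integrated over the pixel.
static inline double phi(double z) { return 0.5 * (1.0 + std::erf(z * M_SQRT1_2)); }

static void add_emitter(NumericMatrix &img, double x, double y,
                        double photons, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  const int r = (int)std::ceil(5.0 * sigma) + 1;
  const int j0 = std::max(0, (int)std::floor(x) - r);
  const int j1 = std::min(W - 1, (int)std::floor(x) + r);
  const int i0 = std::max(0, (int)std::floor(y) - r);
  const int i1 = std::min(H - 1, (int)std::floor(y) + r);
  if (j1 < j0 || i1 < i0) return;
  std::vector<double> wx(j1 - j0 + 1), wy(i1 - i0 + 1);
  for (int j = j0; j <= j1; ++j)
    wx[j - j0] = phi((j + 1 - x) / sigma) - phi((j - x) / sigma);
  for (int i = i0; i <= i1; ++i)
    wy[i - i0] = phi((i + 1 - y) / sigma) - phi((i - y) / sigma);
  for (int j = j0; j <= j1; ++j)
    for (int i = i0; i <= i1; ++i)
      img(i, j) += photons * wx[j - j0] * wy[i - i0];
}

// [[Rcpp::export]]
NumericMatrix cpp_expected_frame(int H, int W, NumericVector x_px,
                                 NumericVector y_px, NumericVector photons,
                                 double sigma_px) {
  NumericMatrix img(H, W);
  for (int k = 0; k < x_px.size(); ++k)
    add_emitter(img, x_px[k], y_px[k], photons[k], sigma_px);
  return img;
}

// Synthesize a whole blinking-acquisition stack. Events must be sorted by
// frame (0-based). Per frame: lambda = base + active emitter PSFs, then
// Poisson shot noise plus Gaussian read noise, rounded and clamped to
// [0, 65535] (16-bit camera ADU).
// [[Rcpp::export]]
NumericVector cpp_synth_stack(NumericMatrix base_lambda, IntegerVector ev_frame,
                              NumericVector ev_x, NumericVector ev_y,
                              NumericVector ev_photons, double sigma_px,
                              int n_frames, double read_noise_sd) {
  const int H = base_lambda.nrow(), W = base_lambda.ncol();
  NumericVector out((R_xlen_t)H * W * n_frames);
  out.attr("dim") = IntegerVector::create(H, W, n_frames);
  NumericMatrix lam(H, W);
  int e = 0;
  const int n_ev = ev_frame.size();
  for (int t = 0; t < n_frames; ++t) {
    std::copy(base_lambda.begin(), base_lambda.end(), lam.begin());
    while (e < n_ev && ev_frame[e] == t) {
      add_emitter(lam, ev_x[e], ev_y[e], ev_photons[e], sigma_px);
      ++e;
    }
    double *dst = &out[(R_xlen_t)t * H * W];
    for (int p = 0; p < H * W; ++p) {
      double v = R::rpois(lam[p]);
      if (read_noise_sd > 0) v += R::rnorm(0.0, read_noise_sd);
      v = std::nearbyint(v);
      if (v < 0) v = 0; else if (v > 65535) v = 65535;
      dst[p] = v;
    }
  }
  return out;
}

// ---- detection -----------------------------------------------------------

// Local maxima (8-connectivity, value >= every in-bounds neighbour and
// value > tau[t]); per frame, maxima closer than min_sep px are merged
// into the brighter one. Returns columns: frame0, row0, col0, value.
// [[Rcpp::export]]
NumericMatrix cpp_detect_stack(NumericVector stack, NumericVector tau,
                               double min_sep) {
  IntegerVector dim = stack.attr("dim");
  const int H = dim[0], W = dim[1], T = dim.size() > 2 ? dim[2] : 1;
  std::vector<double> out;
  const double sep2 = min_sep * min_sep;
  std::vector<int> prow, pcol;
  std::vector<double> pval;
  for (int t = 0; t < T; ++t) {
    const double *f = &stack[(R_xlen_t)t * H * W];
    const double th = tau[tau.size() == 1 ? 0 : t];
    prow.clear(); pcol.clear(); pval.clear();
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = f[i + (R_xlen_t)j * H];
        if (!(v > th)) continue;
        bool is_max = true;
        for (int dj = -1; dj <= 1 && is_max; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (f[ii + (R_xlen_t)jj * H] > v) { is_max = false; break; }
          }
        }
        if (is_max) { prow.push_back(i); pcol.push_back(j); pval.push_back(v); }
      }
    }
    // brighter-first greedy suppression; ties resolved by scan order
    std::vector<int> ord(prow.size());
    for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return pval[a] > pval[b]; });
    std::vector<int> kept;
    for (int k : ord) {
      bool ok = true;
      for (int q : kept) {
        const double dr = prow[k] - prow[q], dc = pcol[k] - pcol[q];
        if (dr * dr + dc * dc < sep2) { ok = false; break; }
      }
      if (ok) {
        kept.push_back(k);
        out.push_back(t); out.push_back(prow[k]); out.push_back(pcol[k]);
        out.push_back(pval[k]);
      }
    }
  }
  NumericMatrix res(4, out.size() / 4);
  std::copy(out.begin(), out.end(), res.begin());
  return transpose(res);
}

// ---- Gaussian fitting ----------------------------------------------------

static bool solve5(double A[5][5], double b[5], double x[5]) {
  int idx[5] = {0, 1, 2, 3, 4};
  for (int c = 0; c < 5; ++c) {
    int piv = c;
    for (int r = c + 1; r < 5; ++r)
      if (std::fabs(A[idx[r]][c]) > std::fabs(A[idx[piv]][c])) piv = r;
    std::swap(idx[c], idx[piv]);
    const double d = A[idx[c]][c];
    if (std::fabs(d) < 1e-300) return false;
    for (int r = c + 1; r < 5; ++r) {
      const double m = A[idx[r]][c] / d;
      for (int k = c; k < 5; ++k) A[idx[r]][k] -= m * A[idx[c]][k];
      b[idx[r]] -= m * b[idx[c]];
    }
  }
  for (int c = 4; c >= 0; --c) {
    double s = b[idx[c]];
    for (int k = c + 1; k < 5; ++k) s -= A[idx[c]][k] * x[k];
    x[c] = s / A[idx[c]][c];
  }
  return true;
}

// theta = (A, x0, y0, sigma, b); model at pixel centres (col+0.5, row+0.5).
static double gauss_cost(const double *w, int n, const double *cx,
                         const double *cy, const double th[5]) {
  double c = 0;
  for (int p = 0; p < n; ++p) {
    const double dx = cx[p] - th[1], dy = cy[p] - th[2];
    const double m = th[4] + th[0] * std::exp(-(dx * dx + dy * dy) /
                                              (2 * th[3] * th[3]));
    const double r = w[p] - m;
    c += r * r;
  }
  return c;
}

// Levenberg-Marquardt fit of a symmetric 2-D Gaussian over one window.
// Returns (A, x0, y0, sigma, b, converged, iters).
static void fit_window(const double *w, int win, const double *cx,
                       const double *cy, double init_sigma, int max_iter,
                       double tol, double outp[7]) {
  const int n = win * win;
  double wmin = w[0], wmax = w[0];
  double sx = 0, sy = 0, sw = 0;
  for (int p = 0; p < n; ++p) { wmin = std::min(wmin, w[p]); wmax = std::max(wmax, w[p]); }
  for (int p = 0; p < n; ++p) {
    const double v = w[p] - wmin;
    sx += v * cx[p]; sy += v * cy[p]; sw += v;
  }
  double th[5];
  th[0] = wmax - wmin;
  th[1] = sw > 0 ? sx / sw : cx[n / 2];
  th[2] = sw > 0 ? sy / sw : cy[n / 2];
  th[3] = init_sigma;
  th[4] = wmin;
  double cost = gauss_cost(w, n, cx, cy, th);
  double lambda = 1e-3;
  bool converged = false;
  int it = 0;
  if (th[0] <= 0) { // flat window: nothing to fit
    for (int k = 0; k < 5; ++k) outp[k] = th[k];
    outp[5] = 0; outp[6] = 0;
    return;
  }
  for (it = 0; it < max_iter && !converged; ++it) {
    double JtJ[5][5] = {{0}}, Jtr[5] = {0};
    for (int p = 0; p < n; ++p) {
      const double dx = cx[p] - th[1], dy = cy[p] - th[2];
      const double s2 = th[3] * th[3];
      const double E = std::exp(-(dx * dx + dy * dy) / (2 * s2));
      const double m = th[4] + th[0] * E;
      const double r = w[p] - m;
      double J[5];
      J[0] = E;
      J[1] = th[0] * E * dx / s2;
      J[2] = th[0] * E * dy / s2;
      J[3] = th[0] * E * (dx * dx + dy * dy) / (s2 * th[3]);
      J[4] = 1.0;
      for (int a = 0; a < 5; ++a) {
        Jtr[a] += J[a] * r;
        for (int b = a; b < 5; ++b) JtJ[a][b] += J[a] * J[b];
      }
    }
    for (int a = 0; a < 5; ++a)
      for (int b = 0; b < a; ++b) JtJ[a][b] = JtJ[b][a];
    bool stepped = false;
    for (int inner = 0; inner < 30; ++inner) {
      double M[5][5], rhs[5], delta[5];
      for (int a = 0; a < 5; ++a) {
        for (int b = 0; b < 5; ++b) M[a][b] = JtJ[a][b];
        M[a][a] += lambda * std::max(JtJ[a][a], 1e-12);
        rhs[a] = Jtr[a];
      }
      if (!solve5(M, rhs, delta)) { lambda *= 10; continue; }
      double cand[5];
      for (int a = 0; a < 5; ++a) cand[a] = th[a] + delta[a];
      if (cand[3] < 0.05 || !std::isfinite(cand[3])) { lambda *= 10; continue; }
      const double cc = gauss_cost(w, n, cx, cy, cand);
      if (std::isfinite(cc) && cc <= cost) {
        double maxstep = 0;
        for (int a = 0; a < 5; ++a)
          maxstep = std::max(maxstep, std::fabs(delta[a]));
        if (cost - cc <= tol * std::max(cost, 1e-12) || maxstep < 1e-10 ||
            cc < 1e-20)
          converged = true;
        for (int a = 0; a < 5; ++a) th[a] = cand[a];
        cost = cc;
        lambda = std::max(lambda * 0.4, 1e-12);
        stepped = true;
        break;
      }
      lambda *= 10;
    }
    if (!stepped) { converged = cost < 1e-18 || it > 0; break; }
  }
  for (int k = 0; k < 5; ++k) outp[k] = th[k];
  outp[5] = converged ? 1 : 0;
  outp[6] = it;
}

// Fit every detected peak. peaks columns: frame0, row0, col0.
// Returns columns: frame0, x_px, y_px, sigma_px, amplitude, offset, status
// (0 ok, 1 window outside frame, 2 no convergence, 3 sigma out of range,
// 4 amplitude <= 0, 5 centre left window).
// [[Rcpp::export]]
NumericMatrix cpp_fit_spots(NumericVector stack, NumericMatrix peaks,
                            int window_half, double init_sigma,
                            double sigma_min_fac, double sigma_max_fac,
                            int max_iter, double tol) {
  IntegerVector dim = stack.attr("dim");
  const int H = dim[0], W = dim[1];
  const int win = 2 * window_half + 1, n = win * win;
  std::vector<double> cx(n), cy(n), w(n);
  const int np = peaks.nrow();
  NumericMatrix res(np, 7);
  for (int k = 0; k < np; ++k) {
    const int t = (int)peaks(k, 0), pi = (int)peaks(k, 1), pj = (int)peaks(k, 2);
    res(k, 0) = t;
    if (pi < window_half || pi >= H - window_half || pj < window_half ||
        pj >= W - window_half) {
      res(k, 6) = 1;
      continue;
    }
    const double *f = &stack[(R_xlen_t)t * H * W];
    int p = 0;
    for (int dj = -window_half; dj <= window_half; ++dj) {
      for (int di = -window_half; di <= window_half; ++di, ++p) {
        w[p] = f[(pi + di) + (R_xlen_t)(pj + dj) * H];
        cx[p] = pj + dj + 0.5;
        cy[p] = pi + di + 0.5;
      }
    }
    double out[7];
    fit_window(w.data(), win, cx.data(), cy.data(), init_sigma, max_iter,
               tol, out);
    res(k, 1) = out[1]; res(k, 2) = out[2]; res(k, 3) = out[3];
    res(k, 4) = out[0]; res(k, 5) = out[4];
    int status = 0;
    if (out[5] == 0) status = 2;
    else if (out[3] < sigma_min_fac * init_sigma ||
             out[3] > sigma_max_fac * init_sigma) status = 3;
    else if (out[0] <= 0) status = 4;
    else if (out[1] < pj - window_half || out[1] > pj + window_half + 1 ||
             out[2] < pi - window_half || out[2] > pi + window_half + 1)
      status = 5;
    res(k, 6) = status;
  }
  return res;
}

// ---- grayscale morphology ------------------------------------------------

// min or max filter with a disk neighbourhood {(di,dj): di^2+dj^2 <= r^2};
// out-of-bounds neighbours are ignored. Offset-outer loops keep the inner
// loop contiguous down columns so the compiler can vectorize it.
static void disk_filter(const double *src, double *dst, int H, int W,
                        int radius, bool take_min) {
  const double init = take_min ? R_PosInf : R_NegInf;
  std::fill(dst, dst + (R_xlen_t)H * W, init);
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di) {
      if (di * di + dj * dj > radius * radius) continue;
      const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      for (int j = j0; j < j1; ++j) {
        const double *s = src + (R_xlen_t)(j + dj) * H + di;
        double *d = dst + (R_xlen_t)j * H;
        if (take_min) {
          for (int i = i0; i < i1; ++i) d[i] = std::min(d[i], s[i]);
        } else {
          for (int i = i0; i < i1; ++i) d[i] = std::max(d[i], s[i]);
        }
      }
    }
}

// Grayscale opening with a disk structuring element: erosion (min) then
// dilation (max).
// [[Rcpp::export]]
NumericMatrix cpp_disk_opening(NumericMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix ero(H, W), out(H, W);
  disk_filter(img.begin(), ero.begin(), H, W, radius, true);
  disk_filter(ero.begin(), out.begin(), H, W, radius, false);
  return out;
}

// Frame-wise rolling-ball (disk opening) background subtraction over a
// stack, clipped at zero.
// [[Rcpp::export]]
NumericVector cpp_subtract_opening_stack(NumericVector stack, int radius) {
  IntegerVector dim = stack.attr("dim");
  const int H = dim[0], W = dim[1], T = dim.size() > 2 ? dim[2] : 1;
  NumericVector out((R_xlen_t)H * W * T);
  out.attr("dim") = dim;
  NumericMatrix frame(H, W);
  for (int t = 0; t < T; ++t) {
    const double *src = &stack[(R_xlen_t)t * H * W];
    std::copy(src, src + (R_xlen_t)H * W, frame.begin());
    NumericMatrix bg = cpp_disk_opening(frame, radius);
    double *dst = &out[(R_xlen_t)t * H * W];
    for (int p = 0; p < H * W; ++p) dst[p] = std::max(src[p] - bg[p], 0.0);
  }
  return out;
}

// ---- blind-spot median ---------------------------------------------------

static inline int mirror_idx(int q, int n) {
  if (q < 0) q = -q;
  if (q >= n) q = 2 * n - 2 - q;
  return q;
}

// Median of the square (2r+1)^2 neighbourhood excluding the centre pixel,
// mirror padding at the borders. Applied frame-wise to a (H, W, T) stack.
// [[Rcpp::export]]
NumericVector cpp_blindspot_median(NumericVector stack, int radius) {
  IntegerVector dim = stack.attr("dim");
  const int H = dim[0], W = dim[1], T = dim.size() > 2 ? dim[2] : 1;
  NumericVector out((R_xlen_t)H * W * T);
  out.attr("dim") = dim;
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1) - 1);
  for (int t = 0; t < T; ++t) {
    const double *f = &stack[(R_xlen_t)t * H * W];
    double *g = &out[(R_xlen_t)t * H * W];
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        buf.clear();
        for (int dj = -radius; dj <= radius; ++dj)
          for (int di = -radius; di <= radius; ++di) {
            if (di == 0 && dj == 0) continue;
            buf.push_back(f[mirror_idx(i + di, H) +
                            (R_xlen_t)mirror_idx(j + dj, W) * H]);
          }
        const size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        g[i + (R_xlen_t)j * H] = med;
      }
  }
  return out;
}

// ---- localization clustering --------------------------------------------

// Single-linkage connected components: points linked when within eps.
// Grid-hashed union-find; labels are 1-based component ids.
// [[Rcpp::export]]
IntegerVector cpp_cluster_points(NumericVector x, NumericVector y, double eps) {
  const int n = x.size();
  IntegerVector lab(n);
  if (n == 0) return lab;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [&](long long cx, long long cy) { return cx * 2000003LL + cy; };
  for (int i = 0; i < n; ++i)
    grid[key((long long)std::floor(x[i] / eps),
             (long long)std::floor(y[i] / eps))].push_back(i);
  const double eps2 = eps * eps;
  for (int i = 0; i < n; ++i) {
    const long long cx = (long long)std::floor(x[i] / eps);
    const long long cy = (long long)std::floor(y[i] / eps);
    for (long long a = cx - 1; a <= cx + 1; ++a)
      for (long long b = cy - 1; b <= cy + 1; ++b) {
        auto it = grid.find(key(a, b));
        if (it == grid.end()) continue;
        for (int q : it->second) {
          if (q <= i) continue;
          const double dx = x[i] - x[q], dy = y[i] - y[q];
          if (dx * dx + dy * dy <= eps2) unite(i, q);
        }
      }
  }
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    const int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
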