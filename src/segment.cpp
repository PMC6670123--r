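#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ----- morphological curvature smoothing operators (SI / IS) ---------------
// Four 3-pixel line segments through the center; SI = max over segments of
// the segment minimum, IS = min over segments of the segment maximum.
static void si_op(const std::vector<char> &u, std::vector<char> &out,
                  int ny, int nx) {
  static const int seg[4][2] = {{0, 1}, {1, 0}, {1, 1}, {1, -1}};
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      char best = 0;
      for (int s = 0; s < 4 && !best; ++s) {
        char mn = 1;
        for (int k = -1; k <= 1; ++k) {
          int rr = r + k * seg[s][0], cc = c + k * seg[s][1];
          if (rr < 0) rr = 0; if (rr >= ny) rr = ny - 1;
          if (cc < 0) cc = 0; if (cc >= nx) cc = nx - 1;
          if (!u[rr + (size_t)cc * ny]) { mn = 0; break; }
        }
        if (mn) best = 1;
      }
      out[r + (size_t)c * ny] = best;
    }
}

static void is_op(const std::vector<char> &u, std::vector<char> &out,
                  int ny, int nx) {
  static const int seg[4][2] = {{0, 1}, {1, 0}, {1, 1}, {1, -1}};
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      char best = 1;
      for (int s = 0; s < 4 && best; ++s) {
        char mx = 0;
        for (int k = -1; k <= 1; ++k) {
          int rr = r + k * seg[s][0], cc = c + k * seg[s][1];
          if (rr < 0) rr = 0; if (rr >= ny) rr = ny - 1;
          if (cc < 0) cc = 0; if (cc >= nx) cc = nx - 1;
          if (u[rr + (size_t)cc * ny]) { mx = 1; break; }
        }
        if (!mx) best = 0;
      }
      out[r + (size_t)c * ny] = best;
    }
}

// Morphological Chan-Vese (two-phase, region-based) with a hard edge
// barrier: pixels flagged in `barrier` never change state, so detected
// edges stop the evolving front. Converges when no pixel changes.
// [[Rcpp::export]]
List morph_acwe_cpp(NumericMatrix img, LogicalMatrix init,
                    LogicalMatrix barrier, int max_iter, int smoothing) {
  int ny = img.nrow(), nx = img.ncol();
  size_t N = (size_t)ny * nx;
  std::vector<char> u(N), frozen(N), tmp(N), prev1, prev2;
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      u[r + (size_t)c * ny] = init(r, c) ? 1 : 0;
      frozen[r + (size_t)c * ny] = barrier(r, c) ? 1 : 0;
    }
  bool converged = false, border_touch = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // region means
    double s1 = 0, s0 = 0; size_t n1 = 0, n0 = 0;
    for (int c = 0; c < nx; ++c)
      for (int r = 0; r < ny; ++r) {
        double v = img(r, c);
        if (u[r + (size_t)c * ny]) { s1 += v; ++n1; } else { s0 += v; ++n0; }
      }
    if (n1 == 0 || n0 == 0) break;
    double c1 = s1 / n1, c0 = s0 / n0;
    // ACWE step on the boundary zone (8-neighborhood of sign change)
    size_t changed = 0;
    std::copy(u.begin(), u.end(), tmp.begin());
    for (int c = 0; c < nx; ++c)
      for (int r = 0; r < ny; ++r) {
        size_t idx = r + (size_t)c * ny;
        if (frozen[idx]) continue;
        char uc = u[idx];
        bool boundary = false;
        for (int dc = -1; dc <= 1 && !boundary; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= ny || cc < 0 || cc >= nx) continue;
            if (u[rr + (size_t)cc * ny] != uc) { boundary = true; break; }
          }
        if (!boundary) continue;
        double v = img(r, c);
        double d1 = (v - c1) * (v - c1), d0 = (v - c0) * (v - c0);
        char nu = (d1 < d0) ? 1 : 0;
        if (nu != uc) { tmp[idx] = nu; ++changed; }
      }
    std::swap(u, tmp);
    // curvature smoothing, alternating composition per pass
    for (int s = 0; s < smoothing; ++s) {
      if ((iter + s) % 2 == 0) { si_op(u, tmp, ny, nx); is_op(tmp, u, ny, nx); }
      else                     { is_op(u, tmp, ny, nx); si_op(tmp, u, ny, nx); }
    }
    // frozen (edge-barrier) pixels keep their initial state throughout
    if (smoothing > 0)
      for (int c = 0; c < nx; ++c)
        for (int r = 0; r < ny; ++r) {
          size_t idx = r + (size_t)c * ny;
          if (frozen[idx]) u[idx] = init(r, c) ? 1 : 0;
        }
    // converged when the (possibly oscillating) front revisits a state
    if (!prev1.empty() && (u == prev1 || (!prev2.empty() && u == prev2))) {
      converged = true;
      break;
    }
    prev2 = prev1;
    prev1 = u;
    if (changed == 0 && iter > 1) { converged = true; break; }
    if (iter % 8 == 0) {
      size_t area = 0;
      bool touch = false;
      for (int c = 0; c < nx; ++c) {
        if (u[0 + (size_t)c * ny] || u[(ny - 1) + (size_t)c * ny]) touch = true;
      }
      for (int r = 0; r < ny && !touch; ++r)
        if (u[r] || u[r + (size_t)(nx - 1) * ny]) touch = true;
      for (size_t i = 0; i < N; ++i) area += u[i];
      if (touch || area > 0.35 * N) { border_touch = touch; break; }
    }
  }
  LogicalMatrix out(ny, nx);
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) out(r, c) = u[r + (size_t)c * ny] != 0;
  return List::create(_["mask"] = out,
                      _["iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged,
                      _["border_touch"] = border_touch);
}

// connected-component labelling, 8- or 4-connectivity; 0 = background
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * ny);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % ny, cc = idx / ny;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (connectivity == 4 && dr != 0 && dc != 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= ny || c2 < 0 || c2 >= nx) continue;
            if (mask(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * ny);
            }
          }
      }
    }
  return lab;
}

// two-pass chamfer distance transform (1, sqrt2 weights); distance of a
// foreground pixel to the nearest background pixel, border counts as
// background-adjacent only through real background pixels
// [[Rcpp::export]]
NumericMatrix chamfer_dt_cpp(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  const double INF = std::numeric_limits<double>::max() / 4;
  const double W1 = 1.0, W2 = std::sqrt(2.0);
  NumericMatrix d(ny, nx);
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) d(r, c) = mask(r, c) ? INF : 0.0;
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      if (d(r, c) == 0) continue;
      double v = d(r, c);
      if (r > 0) v = std::min(v, d(r - 1, c) + W1);
      if (c > 0) v = std::min(v, d(r, c - 1) + W1);
      if (r > 0 && c > 0) v = std::min(v, d(r - 1, c - 1) + W2);
      if (r > 0 && c < nx - 1) v = std::min(v, d(r - 1, c + 1) + W2);
      d(r, c) = v;
    }
  for (int c = nx - 1; c >= 0; --c)
    for (int r = ny - 1; r >= 0; --r) {
      if (d(r, c) == 0) continue;
      double v = d(r, c);
      if (r < ny - 1) v = std::min(v, d(r + 1, c) + W1);
      if (c < nx - 1) v = std::min(v, d(r, c + 1) + W1);
      if (r < ny - 1 && c < nx - 1) v = std::min(v, d(r + 1, c + 1) + W2);
      if (r < ny - 1 && c > 0) v = std::min(v, d(r + 1, c - 1) + W2);
      d(r, c) = v;
    }
  return d;
}

// binary 3x3 dilation, iterated
// [[Rcpp::export]]
LogicalMatrix dilate_cpp(LogicalMatrix mask, int iter) {
  int ny = mask.nrow(), nx = mask.ncol();
  LogicalMatrix cur = clone(mask);
  for (int it = 0; it < iter; ++it) {
    LogicalMatrix nxt(ny, nx);
    for (int c = 0; c < nx; ++c)
      for (int r = 0; r < ny; ++r) {
        bool v = false;
        for (int dc = -1; dc <= 1 && !v; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= ny || cc < 0 || cc >= nx) continue;
            if (cur(rr, cc)) { v = true; break; }
          }
        nxt(r, c) = v;
      }
    cur = nxt;
  }
  return cur;
}

// ridge pixels: distance-transform local maxima within the mask
// [[Rcpp::export]]
LogicalMatrix ridge_cpp(NumericMatrix dist, LogicalMatrix mask) {
  int ny = dist.nrow(), nx = dist.ncol();
  LogicalMatrix out(ny, nx);
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      if (!mask(r, c)) continue;
      double v = dist(r, c);
      bool mx = true;
      for (int dc = -1; dc <= 1 && mx; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= ny || cc < 0 || cc >= nx) continue;
          if (dist(rr, cc) > v) { mx = false; break; }
        }
      out(r, c) = mx;
    }
  return out;
}

// stamp discs of radius `rad` (px) at the given (row, col) centers (1-based
// R indices); modifies `canvas` in place and returns the number of newly
// set pixels that fall inside `region` (the phantom's density bookkeeping)
// [[Rcpp::export]]
int stamp_discs_cpp(LogicalMatrix canvas, NumericVector rows,
                    NumericVector cols, double rad, LogicalMatrix region) {
  int ny = canvas.nrow(), nx = canvas.ncol();
  int R = (int)std::ceil(rad);
  double r2 = rad * rad;
  int newly = 0;
  for (int i = 0; i < rows.size(); ++i) {
    int cr = (int)std::lround(rows[i]) - 1, cc = (int)std::lround(cols[i]) - 1;
    for (int dc = -R; dc <= R; ++dc)
      for (int dr = -R; dr <= R; ++dr) {
        if (dr * dr + dc * dc > r2) continue;
        int rr = cr + dr, c2 = cc + dc;
        if (rr < 0 || rr >= ny || c2 < 0 || c2 >= nx) continue;
        if (!canvas(rr, c2)) {
          canvas(rr, c2) = true;
          if (region(rr, c2)) ++newly;
        }
      }
  }
  return newly;
}
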