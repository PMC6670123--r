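#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cubic convolution kernel (Keys, a = -0.5), the conventional "bicubic"
static inline double cubic_kernel(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
  if (t < 2.0)  return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericMatrix bicubic_resize_cpp(NumericMatrix src, int out_ny, int out_nx) {
  int ny = src.nrow(), nx = src.ncol();
  NumericMatrix out(out_ny, out_nx);
  double sy = (double)ny / out_ny, sx = (double)nx / out_nx;
  std::vector<double> wx(4), wy(4);
  for (int r = 0; r < out_ny; ++r) {
    double y = (r + 0.5) * sy - 0.5;
    int iy = (int)std::floor(y);
    double fy = y - iy;
    for (int j = 0; j < 4; ++j) wy[j] = cubic_kernel(j - 1 - fy);
    for (int c = 0; c < out_nx; ++c) {
      double x = (c + 0.5) * sx - 0.5;
      int ix = (int)std::floor(x);
      double fx = x - ix;
      for (int i = 0; i < 4; ++i) wx[i] = cubic_kernel(i - 1 - fx);
      double acc = 0.0;
      for (int j = 0; j < 4; ++j) {
        int yy = clampi(iy - 1 + j, 0, ny - 1);
        double row = 0.0;
        for (int i = 0; i < 4; ++i) {
          int xx = clampi(ix - 1 + i, 0, nx - 1);
          row += src(yy, xx) * wx[i];
        }
        acc += row * wy[j];
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// separable Gaussian, edge-replicated borders
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  int ny = img.nrow(), nx = img.ncol();
  if (sigma <= 0) return clone(img);
  int R = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * R + 1);
  double s = 0.0;
  for (int i = -R; i <= R; ++i) {
    k[i + R] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + R];
  }
  for (auto &v : k) v /= s;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int r = 0; r < ny; ++r)
    for (int c = 0; c < nx; ++c) {
      double acc = 0.0;
      for (int i = -R; i <= R; ++i)
        acc += img(r, clampi(c + i, 0, nx - 1)) * k[i + R];
      tmp(r, c) = acc;
    }
  for (int r = 0; r < ny; ++r)
    for (int c = 0; c < nx; ++c) {
      double acc = 0.0;
      for (int i = -R; i <= R; ++i)
        acc += tmp(clampi(r + i, 0, ny - 1), c) * k[i + R];
      out(r, c) = acc;
    }
  return out;
}

// local mean over a w x w window (w odd), window clipped at the borders
// [[Rcpp::export]]
NumericMatrix box_mean_cpp(NumericMatrix img, int w) {
  int ny = img.nrow(), nx = img.ncol();
  int R = w / 2;
  // integral image with a zero first row/col
  std::vector<double> ii((ny + 1) * (nx + 1), 0.0);
  for (int r = 0; r < ny; ++r)
    for (int c = 0; c < nx; ++c)
      ii[(r + 1) * (nx + 1) + (c + 1)] =
        img(r, c) + ii[r * (nx + 1) + (c + 1)] +
        ii[(r + 1) * (nx + 1) + c] - ii[r * (nx + 1) + c];
  NumericMatrix out(ny, nx);
  for (int r = 0; r < ny; ++r) {
    int r0 = std::max(0, r - R), r1 = std::min(ny - 1, r + R);
    for (int c = 0; c < nx; ++c) {
      int c0 = std::max(0, c - R), c1 = std::min(nx - 1, c + R);
      double sum = ii[(r1 + 1) * (nx + 1) + (c1 + 1)] -
                   ii[r0 * (nx + 1) + (c1 + 1)] -
                   ii[(r1 + 1) * (nx + 1) + c0] + ii[r0 * (nx + 1) + c0];
      out(r, c) = sum / ((r1 - r0 + 1) * (c1 - c0 + 1));
    }
  }
  return out;
}

// Canny: Gaussian blur, Sobel, non-maximum suppression, hysteresis.
// low/high are fractions of the maximum gradient magnitude.
// [[Rcpp::export]]
LogicalMatrix canny_cpp(NumericMatrix img, double sigma, double low, double high) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix sm = gaussian_blur_cpp(img, sigma);
  NumericMatrix gx(ny, nx), gy(ny, nx), mag(ny, nx);
  double mmax = 0.0;
  for (int r = 1; r < ny - 1; ++r)
    for (int c = 1; c < nx - 1; ++c) {
      double sx = (sm(r - 1, c + 1) + 2 * sm(r, c + 1) + sm(r + 1, c + 1)) -
                  (sm(r - 1, c - 1) + 2 * sm(r, c - 1) + sm(r + 1, c - 1));
      double sy = (sm(r + 1, c - 1) + 2 * sm(r + 1, c) + sm(r + 1, c + 1)) -
                  (sm(r - 1, c - 1) + 2 * sm(r - 1, c) + sm(r - 1, c + 1));
      gx(r, c) = sx; gy(r, c) = sy;
      double m = std::sqrt(sx * sx + sy * sy);
      mag(r, c) = m;
      if (m > mmax) mmax = m;
    }
  LogicalMatrix edges(ny, nx);
  if (mmax <= 0) return edges;
  double tl = low * mmax, th = high * mmax;
  // NMS: keep local maxima along the quantized gradient direction
  std::vector<char> cand(ny * nx, 0); // 0 none, 1 weak, 2 strong
  for (int r = 1; r < ny - 1; ++r)
    for (int c = 1; c < nx - 1; ++c) {
      double m = mag(r, c);
      if (m < tl) continue;
      double ang = std::atan2(gy(r, c), gx(r, c));
      if (ang < 0) ang += M_PI;
      double n1, n2;
      if (ang < M_PI / 8 || ang >= 7 * M_PI / 8) {        // horizontal gradient
        n1 = mag(r, c - 1); n2 = mag(r, c + 1);
      } else if (ang < 3 * M_PI / 8) {                    // 45 deg
        n1 = mag(r - 1, c + 1); n2 = mag(r + 1, c - 1);
      } else if (ang < 5 * M_PI / 8) {                    // vertical gradient
        n1 = mag(r - 1, c); n2 = mag(r + 1, c);
      } else {                                            // 135 deg
        n1 = mag(r - 1, c - 1); n2 = mag(r + 1, c + 1);
      }
      if (m >= n1 && m >= n2) cand[r + (size_t)c * ny] = (m >= th) ? 2 : 1;
    }
  // hysteresis: grow strong edges through weak candidates (8-connected)
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r)
      if (cand[r + (size_t)c * ny] == 2) {
        edges(r, c) = true;
        stack.push_back(r + c * ny);
      }
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int r = idx % ny, c = idx / ny;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= ny || cc < 0 || cc >= nx) continue;
        if (cand[rr + (size_t)cc * ny] == 1 && !edges(rr, cc)) {
          edges(rr, cc) = true;
          stack.push_back(rr + cc * ny);
        }
      }
  }
  return edges;
}

// local mean over a w x w window ignoring excluded pixels (e.g. large
// vessels, whose brightness would mask adjacent capillaries); windows
// that are entirely excluded fall back to the global non-excluded mean
// [[Rcpp::export]]
NumericMatrix masked_box_mean_cpp(NumericMatrix img, int w,
                                  LogicalMatrix exclude) {
  int ny = img.nrow(), nx = img.ncol();
  int R = w / 2;
  std::vector<double> ii((ny + 1) * (nx + 1), 0.0);
  std::vector<double> ic((ny + 1) * (nx + 1), 0.0);
  double gsum = 0.0; long gcnt = 0;
  for (int r = 0; r < ny; ++r)
    for (int c = 0; c < nx; ++c) {
      double keep = exclude(r, c) ? 0.0 : 1.0;
      if (keep > 0) { gsum += img(r, c); ++gcnt; }
      ii[(r + 1) * (nx + 1) + (c + 1)] =
        img(r, c) * keep + ii[r * (nx + 1) + (c + 1)] +
        ii[(r + 1) * (nx + 1) + c] - ii[r * (nx + 1) + c];
      ic[(r + 1) * (nx + 1) + (c + 1)] =
        keep + ic[r * (nx + 1) + (c + 1)] +
        ic[(r + 1) * (nx + 1) + c] - ic[r * (nx + 1) + c];
    }
  double gmean = gcnt > 0 ? gsum / gcnt : 0.0;
  NumericMatrix out(ny, nx);
  for (int r = 0; r < ny; ++r) {
    int r0 = std::max(0, r - R), r1 = std::min(ny - 1, r + R);
    for (int c = 0; c < nx; ++c) {
      int c0 = std::max(0, c - R), c1 = std::min(nx - 1, c + R);
      double sum = ii[(r1 + 1) * (nx + 1) + (c1 + 1)] -
                   ii[r0 * (nx + 1) + (c1 + 1)] -
                   ii[(r1 + 1) * (nx + 1) + c0] + ii[r0 * (nx + 1) + c0];
      double cnt = ic[(r1 + 1) * (nx + 1) + (c1 + 1)] -
                   ic[r0 * (nx + 1) + (c1 + 1)] -
                   ic[(r1 + 1) * (nx + 1) + c0] + ic[r0 * (nx + 1) + c0];
      out(r, c) = cnt > 0 ? sum / cnt : gmean;
    }
  }
  return out;
}
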