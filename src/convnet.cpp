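// Low-level numeric kernels: im2col convolution (forward/backward),
// star-convex distance targets, polygon rasterisation IoU and greedy NMS.
// Tensors are arma::cube in (H, W, C) layout, matching R's column-major
// array(dim = c(H, W, C)). Weight matrices are (kh*kw*Cin) x Cout with
// row index c*kh*kw + a*kw + b (b fastest), as produced by R-side helpers.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int stride, int dil,
                  int pad, int& Ho, int& Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  Ho = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  Wo = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  mat out(Ho * Wo, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int a = 0; a < kh; ++a)
      for (int b = 0; b < kw; ++b) {
        const int col = c * kh * kw + a * kw + b;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride + b * dil - pad;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int hi = i * stride + a * dil - pad;
            if (hi < 0 || hi >= H) continue;
            out(j * Ho + i, col) = x(hi, wj, c);
          }
        }
      }
  return out;
}

static cube col2im(const mat& cols, int H, int W, int C, int kh, int kw,
                   int stride, int dil, int pad, int Ho, int Wo) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int a = 0; a < kh; ++a)
      for (int b = 0; b < kw; ++b) {
        const int col = c * kh * kw + a * kw + b;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride + b * dil - pad;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int hi = i * stride + a * dil - pad;
            if (hi < 0 || hi >= H) continue;
            dx(hi, wj, c) += cols(j * Ho + i, col);
          }
        }
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& Wm,
                        const arma::vec& b, int kh, int kw, int stride,
                        int dil, int pad) {
  int Ho, Wo;
  mat xc = im2col(x, kh, kw, stride, dil, pad, Ho, Wo);
  mat y = xc * Wm;
  y.each_row() += b.t();
  return cube(y.memptr(), Ho, Wo, Wm.n_cols);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::cube& x, const arma::mat& Wm,
                        const arma::cube& dy, int kh, int kw, int stride,
                        int dil, int pad) {
  int Ho, Wo;
  mat xc = im2col(x, kh, kw, stride, dil, pad, Ho, Wo);
  const mat dym(const_cast<double*>(dy.memptr()), Ho * Wo, dy.n_slices, false);
  mat dW = xc.t() * dym;
  vec db = sum(dym, 0).t();
  mat dxc = dym * Wm.t();
  cube dx = col2im(dxc, x.n_rows, x.n_cols, x.n_slices, kh, kw, stride, dil,
                   pad, Ho, Wo);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Star-convex radial distance targets. For every foreground pixel, march
// in unit steps along each ray (integer rounding of the sampled point) and
// record the step count at which the ray first leaves the pixel's own
// object (by label change, background, or image border). Background = 0.
// [[Rcpp::export]]
arma::cube cpp_star_dist(const arma::imat& lab, const arma::vec& angles,
                         int max_steps) {
  const int H = lab.n_rows, W = lab.n_cols, R = angles.n_elem;
  cube out(H, W, R, fill::zeros);
  for (int r = 0; r < R; ++r) {
    const double dr = std::sin(angles[r]), dc = std::cos(angles[r]);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const long L = lab(i, j);
        if (L == 0) continue;
        int t = 1;
        for (; t < max_steps; ++t) {
          const int ii = (int)std::lround(i + t * dr);
          const int jj = (int)std::lround(j + t * dc);
          if (ii < 0 || ii >= H || jj < 0 || jj >= W || lab(ii, jj) != L)
            break;
        }
        out(i, j, r) = t;
      }
  }
  return out;
}

static bool point_in_poly(double py, double px, const std::vector<double>& vy,
                          const std::vector<double>& vx) {
  bool inside = false;
  const int n = vy.size();
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside = !inside;
  }
  return inside;
}

static void poly_vertices(double cy, double cx, const vec& radii,
                          const vec& angles, std::vector<double>& vy,
                          std::vector<double>& vx) {
  const int n = radii.n_elem;
  vy.resize(n);
  vx.resize(n);
  for (int k = 0; k < n; ++k) {
    vy[k] = cy + radii[k] * std::sin(angles[k]);
    vx[k] = cx + radii[k] * std::cos(angles[k]);
  }
}

static double poly_iou_impl(double cy1, double cx1, const vec& r1, double cy2,
                            double cx2, const vec& r2, const vec& angles) {
  if (r1.max() <= 0.0 || r2.max() <= 0.0) return 0.0;  // zero-area convention
  std::vector<double> ay, ax, by, bx;
  poly_vertices(cy1, cx1, r1, angles, ay, ax);
  poly_vertices(cy2, cx2, r2, angles, by, bx);
  const double aymin = *std::min_element(ay.begin(), ay.end());
  const double aymax = *std::max_element(ay.begin(), ay.end());
  const double axmin = *std::min_element(ax.begin(), ax.end());
  const double axmax = *std::max_element(ax.begin(), ax.end());
  const double bymin = *std::min_element(by.begin(), by.end());
  const double bymax = *std::max_element(by.begin(), by.end());
  const double bxmin = *std::min_element(bx.begin(), bx.end());
  const double bxmax = *std::max_element(bx.begin(), bx.end());
  if (aymax < bymin || bymax < aymin || axmax < bxmin || bxmax < axmin)
    return 0.0;
  const double y0 = std::floor(std::min(aymin, bymin));
  const double y1 = std::ceil(std::max(aymax, bymax));
  const double x0 = std::floor(std::min(axmin, bxmin));
  const double x1 = std::ceil(std::max(axmax, bxmax));
  // adaptive raster: sub-pixel sampling for small polygons so the IoU
  // stays accurate down to unit radii, unit step for large ones
  double step = std::max(r1.max(), r2.max()) / 8.0;
  if (step > 1.0) step = 1.0;
  if (step < 0.05) step = 0.05;
  long nA = 0, nB = 0, nAB = 0;
  for (double y = y0; y <= y1; y += step)
    for (double x = x0; x <= x1; x += step) {
      const bool inA = point_in_poly(y, x, ay, ax);
      const bool inB = point_in_poly(y, x, by, bx);
      if (inA) ++nA;
      if (inB) ++nB;
      if (inA && inB) ++nAB;
    }
  const long uni = nA + nB - nAB;
  if (uni <= 0) return 0.0;
  return (double)nAB / (double)uni;
}

// [[Rcpp::export]]
double cpp_poly_iou(const arma::vec& c1, const arma::vec& r1,
                    const arma::vec& c2, const arma::vec& r2,
                    const arma::vec& angles) {
  return poly_iou_impl(c1[0], c1[1], r1, c2[0], c2[1], r2, angles);
}

// Greedy NMS over candidates already sorted by descending probability
// (ties broken upstream). Returns a keep flag per candidate.
// [[Rcpp::export]]
LogicalVector cpp_nms(const arma::mat& centers, const arma::mat& radii,
                      const arma::vec& angles, double iou_thresh) {
  const int n = centers.n_rows;
  LogicalVector keep(n);
  std::vector<int> acc;
  std::vector<double> rmax(n);
  for (int i = 0; i < n; ++i) rmax[i] = radii.row(i).max();
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    const vec ri = radii.row(i).t();
    for (size_t k = 0; k < acc.size() && ok; ++k) {
      const int j = acc[k];
      // bounding-circle prefilter
      const double dy = centers(i, 0) - centers(j, 0);
      const double dx = centers(i, 1) - centers(j, 1);
      if (std::sqrt(dy * dy + dx * dx) > rmax[i] + rmax[j] + 1.0) continue;
      const vec rj = radii.row(j).t();
      if (poly_iou_impl(centers(i, 0), centers(i, 1), ri, centers(j, 0),
                        centers(j, 1), rj, angles) > iou_thresh)
        ok = false;
    }
    keep[i] = ok;
    if (ok) acc.push_back(i);
  }
  return keep;
}
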