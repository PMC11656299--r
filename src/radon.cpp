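#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel-driven forward projector with linear splatting onto the detector.
// The image is square (n x n), pixel (ix, iy) has centre
//   x = (ix - (n-1)/2) * dx,  y = (iy - (n-1)/2) * dx   (0-based, mm).
// Detector bin j has centre s_j = (j - (nd-1)/2) * dd.  Each pixel value is
// splatted onto the two bins bracketing t = x cos(theta) + y sin(theta) with
// linear weights and the area factor dx*dx/dd, so entries approximate
// mm-weighted line integrals.  backproject_cpp below is the exact transpose
// of this operator (up to the area factor, applied in R).
//
// Sinograms cross the C++ boundary in detector-major layout
// [detector x angle]; the R wrappers transpose to the user-facing
// [angle x detector] convention.

// [[Rcpp::export(name = ".forward_project_cpp")]]
NumericMatrix forward_project_cpp(NumericMatrix img, NumericVector angles,
                                  int n_det, double det_spacing,
                                  double voxel_spacing) {
  const int n = img.nrow();
  const int na = angles.size();
  NumericMatrix sino(n_det, na);
  const double c0 = (n - 1) / 2.0;
  const double d0 = (n_det - 1) / 2.0;
  const double area = voxel_spacing * voxel_spacing / det_spacing;

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    const double du = voxel_spacing * ct / det_spacing;
    double* col = &sino(0, a);
    for (int iy = 0; iy < n; ++iy) {
      const double ty = (iy - c0) * voxel_spacing * st;
      const double* ic = &img(0, iy);
      double u = ((0 - c0) * voxel_spacing * ct + ty) / det_spacing + d0;
      for (int ix = 0; ix < n; ++ix, u += du) {
        const double v = ic[ix];
        if (v == 0.0) continue;
        const int j0 = (int)std::floor(u);
        const double w = u - j0;
        if (j0 >= 0 && j0 < n_det)         col[j0]     += v * (1.0 - w) * area;
        if (j0 + 1 >= 0 && j0 + 1 < n_det) col[j0 + 1] += v * w * area;
      }
    }
  }
  return sino;
}

// Interpolating backprojector: out(ix,iy) = sum_a q_a(t(ix,iy,a)) with
// linear interpolation between detector bins.  Multiplied by dx^2/dd this
// is the exact adjoint of forward_project_cpp; multiplied by pi/n_angles it
// is the backprojection step of filtered back projection.

// [[Rcpp::export(name = ".backproject_cpp")]]
NumericMatrix backproject_cpp(NumericMatrix sino, NumericVector angles,
                              int n, double det_spacing,
                              double voxel_spacing) {
  const int na = angles.size();
  const int n_det = sino.nrow();
  NumericMatrix img(n, n);
  const double c0 = (n - 1) / 2.0;
  const double d0 = (n_det - 1) / 2.0;

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    const double du = voxel_spacing * ct / det_spacing;
    const double* col = &sino(0, a);
    for (int iy = 0; iy < n; ++iy) {
      const double ty = (iy - c0) * voxel_spacing * st;
      double* ic = &img(0, iy);
      double u = ((0 - c0) * voxel_spacing * ct + ty) / det_spacing + d0;
      for (int ix = 0; ix < n; ++ix, u += du) {
        const int j0 = (int)std::floor(u);
        const double w = u - j0;
        double val = 0.0;
        if (j0 >= 0 && j0 < n_det)         val += col[j0] * (1.0 - w);
        if (j0 + 1 >= 0 && j0 + 1 < n_det) val += col[j0 + 1] * w;
        ic[ix] += val;
      }
    }
  }
  return img;
}

// Brute-force bilateral filter: spatial Gaussian x range Gaussian weights,
// normalised per pixel.  Window radius = ceil(3 * sigma_spatial) pixels.

// [[Rcpp::export(name = ".bilateral_cpp")]]
NumericMatrix bilateral_cpp(NumericMatrix img, double sigma_spatial,
                            double sigma_range) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::ceil(3.0 * sigma_spatial);
  NumericMatrix out(nr, nc);
  const double si2 = 2.0 * sigma_spatial * sigma_spatial;
  const double sr2 = 2.0 * sigma_range * sigma_range;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double v0 = img(i, j);
      double wsum = 0.0, vsum = 0.0;
      const int i0 = std::max(0, i - r), i1 = std::min(nr - 1, i + r);
      const int j0 = std::max(0, j - r), j1 = std::min(nc - 1, j + r);
      for (int jj = j0; jj <= j1; ++jj) {
        for (int ii = i0; ii <= i1; ++ii) {
          const double ds = (double)((ii - i) * (ii - i) + (jj - j) * (jj - j));
          const double dv = img(ii, jj) - v0;
          const double w = std::exp(-ds / si2 - dv * dv / sr2);
          wsum += w;
          vsum += w * img(ii, jj);
        }
      }
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}
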