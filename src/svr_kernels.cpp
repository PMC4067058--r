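#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Triplets of the discretized oriented Gaussian PSF rows.
//
// P:      n x 3 world positions of slice-voxel centers (kernel centers)
// axes:   3x3 matrix, columns = PSF axis directions in world space
// sigma:  per-axis Gaussian sigma (mm) in the PSF frame
// tau:    truncation radius in sigma units (per axis, box in PSF frame)
// origin, spacing, dir, shape: target volume grid (dir orthonormal,
//         index = dir^T (p - origin) / spacing, zero-based centers)
//
// Rows with no voxel inside the truncation box fall back to the nearest
// in-grid voxel with weight 1 (delta-function limit); rows whose support
// lies entirely outside the grid stay empty.  Row normalization is done
// by the caller.
// [[Rcpp::export]]
List psf_rows_cpp(NumericMatrix P, NumericMatrix axes, NumericVector sigma,
                  double tau, NumericVector origin, NumericVector spacing,
                  NumericMatrix dir, IntegerVector shape) {
  const int n = P.nrow();
  const int n1 = shape[0], n2 = shape[1], n3 = shape[2];

  // B = dir^T * axes maps PSF-frame displacements to index-frame (pre-spacing)
  double B[3][3];
  for (int a = 0; a < 3; ++a)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int w = 0; w < 3; ++w) s += dir(w, a) * axes(w, j);
      B[a][j] = s;
    }
  // index-space half widths of the truncation box
  double half[3];
  for (int a = 0; a < 3; ++a) {
    double s = 0.0;
    for (int j = 0; j < 3; ++j) s += std::abs(B[a][j]) * tau * sigma[j];
    half[a] = s / spacing[a];
  }

  std::vector<int> ri, ci;
  std::vector<double> wv;
  ri.reserve(n * 32); ci.reserve(n * 32); wv.reserve(n * 32);

  for (int r = 0; r < n; ++r) {
    // center in continuous index coordinates
    double c[3];
    for (int a = 0; a < 3; ++a) {
      double s = 0.0;
      for (int w = 0; w < 3; ++w) s += dir(w, a) * (P(r, w) - origin[w]);
      c[a] = s / spacing[a];
    }
    int lo[3], hi[3];
    bool any_box = true;
    for (int a = 0; a < 3; ++a) {
      lo[a] = (int)std::ceil(c[a] - half[a]);
      hi[a] = (int)std::floor(c[a] + half[a]);
      if (lo[a] < 0) lo[a] = 0;
      int mx = (a == 0 ? n1 : (a == 1 ? n2 : n3)) - 1;
      if (hi[a] > mx) hi[a] = mx;
      if (lo[a] > hi[a]) any_box = false;
    }
    size_t row_start = wv.size();
    if (any_box) {
      for (int ic = lo[2]; ic <= hi[2]; ++ic)
        for (int ib = lo[1]; ib <= hi[1]; ++ib)
          for (int ia = lo[0]; ia <= hi[0]; ++ia) {
            // displacement voxel-center minus kernel center, world frame,
            // expressed directly in PSF frame: u = axes^T dir S (idx - c)
            double d[3] = { (ia - c[0]) * spacing[0],
                            (ib - c[1]) * spacing[1],
                            (ic - c[2]) * spacing[2] };
            // world displacement dw = dir * d; u_j = axes(:,j) . dw
            double dw[3];
            for (int w = 0; w < 3; ++w)
              dw[w] = dir(w, 0) * d[0] + dir(w, 1) * d[1] + dir(w, 2) * d[2];
            double q = 0.0;
            bool inside = true;
            for (int j = 0; j < 3; ++j) {
              double u = axes(0, j) * dw[0] + axes(1, j) * dw[1] +
                         axes(2, j) * dw[2];
              if (std::abs(u) > tau * sigma[j]) { inside = false; break; }
              double z = u / sigma[j];
              q += z * z;
            }
            if (!inside) continue;
            ri.push_back(r + 1);
            ci.push_back(1 + ia + n1 * (ib + n2 * ic));
            wv.push_back(std::exp(-0.5 * q));
          }
    }
    if (wv.size() == row_start) {
      // delta-function fallback: nearest in-grid voxel, weight 1
      int ia = (int)std::lround(c[0]);
      int ib = (int)std::lround(c[1]);
      int ic = (int)std::lround(c[2]);
      if (ia >= 0 && ia < n1 && ib >= 0 && ib < n2 && ic >= 0 && ic < n3) {
        ri.push_back(r + 1);
        ci.push_back(1 + ia + n1 * (ib + n2 * ic));
        wv.push_back(1.0);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["x"] = wrap(wv));
}

// Trilinear interpolation of a 3D array at continuous zero-based voxel
// indices; points outside the grid return `outside`.
// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector values, NumericMatrix idx,
                            double outside) {
  IntegerVector dm = values.attr("dim");
  const int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  const int n = idx.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double x = idx(r, 0), y = idx(r, 1), z = idx(r, 2);
    if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
      out[r] = outside;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 == n1 - 1) --i0;
    if (j0 == n2 - 1) --j0;
    if (k0 == n3 - 1) --k0;
    if (n1 == 1) i0 = 0;
    if (n2 == 1) j0 = 0;
    if (n3 == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, n1 - 1), j1 = std::min(j0 + 1, n2 - 1),
        k1 = std::min(k0 + 1, n3 - 1);
    double v = 0.0;
    double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    int ii[2] = {i0, i1}, jj[2] = {j0, j1}, kk[2] = {k0, k1};
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int cq = 0; cq < 2; ++cq) {
          double w = wx[a] * wy[b] * wz[cq];
          if (w > 0)
            v += w * values[ii[a] + n1 * (jj[b] + n2 * kk[cq])];
        }
    out[r] = v;
  }
  return out;
}
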