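#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Iso-surface area by marching tetrahedra on a scalar field sampled at voxel
// centers with anisotropic physical spacing. Each cell is split into six
// tetrahedra around the main diagonal; linear interpolation on edges. The
// caller pads the field so surfaces close at the array border.

static inline void interp(const double *pa, const double *pb, double va,
                          double vb, double level, double *out) {
  double t = (level - va) / (vb - va);
  for (int d = 0; d < 3; ++d) out[d] = pa[d] + t * (pb[d] - pa[d]);
}

static inline double tri_area(const double *a, const double *b, const double *c) {
  double u[3], v[3];
  for (int d = 0; d < 3; ++d) { u[d] = b[d] - a[d]; v[d] = c[d] - a[d]; }
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double marching_tetra_area_cpp(NumericVector field, IntegerVector dim,
                               NumericVector spacing, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  // vertex bit order: bit0 = x, bit1 = y, bit2 = z
  static const int tets[6][4] = {
    {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
    {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};
  double area = 0.0;
  double v[8], p[8][3];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          v[c] = field[ii + nx * (jj + (long) ny * kk)];
          p[c][0] = ii * dx; p[c][1] = jj * dy; p[c][2] = kk * dz;
          (v[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], out[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            int vi = tets[t][c];
            if (v[vi] > level) in[ni++] = vi; else out[no++] = vi;
          }
          if (ni == 0 || ni == 4) continue;
          double q[4][3];
          if (ni == 1 || ni == 3) {
            int a = (ni == 1) ? in[0] : out[0];
            int *rest = (ni == 1) ? out : in;
            for (int c = 0; c < 3; ++c)
              interp(p[a], p[rest[c]], v[a], v[rest[c]], level, q[c]);
            area += tri_area(q[0], q[1], q[2]);
          } else { // 2 in, 2 out: quad cycle (a,c)(a,d)(b,d)(b,c)
            interp(p[in[0]], p[out[0]], v[in[0]], v[out[0]], level, q[0]);
            interp(p[in[0]], p[out[1]], v[in[0]], v[out[1]], level, q[1]);
            interp(p[in[1]], p[out[1]], v[in[1]], v[out[1]], level, q[2]);
            interp(p[in[1]], p[out[0]], v[in[1]], v[out[0]], level, q[3]);
            area += tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
          }
        }
      }
  return area;
}
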