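#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long) ny * k);
}

// 3D median filter with a cubic (2r+1)^3 window, window clipped at borders.
// [[Rcpp::export]]
NumericVector median_filter3d_cpp(NumericVector img, IntegerVector dim, int r) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(img.size());
  std::vector<double> buf((2 * r + 1) * (2 * r + 1) * (2 * r + 1));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int m = 0;
        for (int dk = std::max(0, k - r); dk <= std::min(nz - 1, k + r); ++dk)
          for (int dj = std::max(0, j - r); dj <= std::min(ny - 1, j + r); ++dj)
            for (int di = std::max(0, i - r); di <= std::min(nx - 1, i + r); ++di)
              buf[m++] = img[idx3(di, dj, dk, nx, ny)];
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        double med = buf[m / 2];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
          med = 0.5 * (med + lo);
        }
        out[idx3(i, j, k, nx, ny)] = med;
      }
  return out;
}

// Label 26-connected foreground components; background = 0.
// [[Rcpp::export]]
IntegerVector label_components26_cpp(LogicalVector fg, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long) nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<long> stack;
  int next = 0;
  for (long s = 0; s < n; ++s) {
    if (!fg[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((long) nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            long w = idx3(ii, jj, kk, nx, ny);
            if (fg[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  return lab;
}

// Fill holes slice-by-slice along z: background 4-connected to the slice
// border stays background, enclosed background becomes foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_slices_cpp(LogicalVector fg, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(fg);
  std::vector<char> open((long) nx * ny);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k) {
    std::fill(open.begin(), open.end(), 0);
    stack.clear();
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if ((i == 0 || j == 0 || i == nx - 1 || j == ny - 1) &&
            !fg[idx3(i, j, k, nx, ny)] && !open[i + nx * j]) {
          open[i + nx * j] = 1;
          stack.push_back(i + nx * j);
        }
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int i = v % nx, j = v / nx;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int d = 0; d < 4; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        int w = ii + nx * jj;
        if (!open[w] && !fg[idx3(ii, jj, k, nx, ny)]) { open[w] = 1; stack.push_back(w); }
      }
    }
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (!fg[idx3(i, j, k, nx, ny)] && !open[i + nx * j])
          out[idx3(i, j, k, nx, ny)] = true;
  }
  return out;
}
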