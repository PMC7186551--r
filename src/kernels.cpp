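#include <Rcpp.h>
using namespace Rcpp;

// 3D arrays are column-major with dim = (nz, ny, nx): linear index
// i = z + nz * (y + ny * x).

// 1D convolution of every line along one axis with an odd kernel,
// renormalizing the kernel where its support is cut by the array edge
// (so a constant input maps to the same constant, exactly).
// Tap-outer accumulation over contiguous blocks keeps the memory access
// sequential for every axis.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nz, int ny, int nx, int axis,
                      const NumericVector& k) {
  const int h = (k.size() - 1) / 2;
  const int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  std::fill(out.begin(), out.end(), 0.0);
  for (int j = -h; j <= h; ++j) {
    const double kv = k[j + h];
    const int lo = std::max(0, -j);
    const int hi = n - 1 - std::max(0, j);
    if (hi < lo) continue;
    if (axis == 2) {  // whole (z, y) planes are contiguous
      const R_xlen_t cnt = (R_xlen_t)nz * ny * (hi - lo + 1);
      const double* src = in.data() + (R_xlen_t)(lo + j) * nz * ny;
      double* dst = out.data() + (R_xlen_t)lo * nz * ny;
      for (R_xlen_t t = 0; t < cnt; ++t) dst[t] += kv * src[t];
    } else if (axis == 1) {  // per x-slab, (z, y) block is contiguous
      const R_xlen_t cnt = (R_xlen_t)nz * (hi - lo + 1);
      for (int x = 0; x < nx; ++x) {
        const double* src =
            in.data() + (R_xlen_t)x * nz * ny + (R_xlen_t)(lo + j) * nz;
        double* dst =
            out.data() + (R_xlen_t)x * nz * ny + (R_xlen_t)lo * nz;
        for (R_xlen_t t = 0; t < cnt; ++t) dst[t] += kv * src[t];
      }
    } else {  // along z: per (y, x) column, stride 1
      const R_xlen_t ncol = (R_xlen_t)ny * nx;
      const int cnt = hi - lo + 1;
      for (R_xlen_t c = 0; c < ncol; ++c) {
        const double* src = in.data() + c * nz + lo + j;
        double* dst = out.data() + c * nz + lo;
        for (int t = 0; t < cnt; ++t) dst[t] += kv * src[t];
      }
    }
  }
  // edge renormalization: divide by the in-range kernel mass per position
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = std::max(-h, -i); j <= std::min(h, n - 1 - i); ++j)
      acc += k[j + h];
    w[i] = acc;
  }
  bool needs = false;
  for (int i = 0; i < n; ++i)
    if (std::abs(w[i] - 1.0) > 1e-14) { needs = true; break; }
  if (!needs) return;
  if (axis == 2) {
    for (int x = 0; x < nx; ++x) {
      if (std::abs(w[x] - 1.0) <= 1e-14) continue;
      const double inv = 1.0 / w[x];
      double* dst = out.data() + (R_xlen_t)x * nz * ny;
      for (R_xlen_t t = 0; t < (R_xlen_t)nz * ny; ++t) dst[t] *= inv;
    }
  } else if (axis == 1) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        if (std::abs(w[y] - 1.0) <= 1e-14) continue;
        const double inv = 1.0 / w[y];
        double* dst = out.data() + (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz;
        for (int t = 0; t < nz; ++t) dst[t] *= inv;
      }
  } else {
    const R_xlen_t ncol = (R_xlen_t)ny * nx;
    for (R_xlen_t c = 0; c < ncol; ++c) {
      double* dst = out.data() + c * nz;
      for (int i = 0; i < nz; ++i)
        if (std::abs(w[i] - 1.0) > 1e-14) dst[i] /= w[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector a, IntegerVector dim,
                               NumericVector kz, NumericVector ky,
                               NumericVector kx) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> buf1(a.begin(), a.end()), buf2(n);
  conv_axis(buf1, buf2, nz, ny, nx, 0, kz);
  conv_axis(buf2, buf1, nz, ny, nx, 1, ky);
  conv_axis(buf1, buf2, nz, ny, nx, 2, kx);
  NumericVector out(n);
  std::copy(buf2.begin(), buf2.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// 26-connectivity local maxima above `thr`. Plateaus are broken by the
// (z, y, x) lexicographic rule: on equal values the voxel with the smaller
// (z, y, x) tuple wins, so each flat plateau yields exactly one candidate.
// Returns a matrix of 1-based (z, y, x) indices plus the voxel value.
// [[Rcpp::export]]
NumericMatrix cpp_local_max3d(NumericVector a, IntegerVector dim, double thr) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> zz, yy, xx;
  std::vector<double> vv;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const double v = a[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
        if (!(v > thr)) continue;
        bool is_max = true;
        for (int dx = -1; dx <= 1 && is_max; ++dx) {
          const int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          for (int dy = -1; dy <= 1 && is_max; ++dy) {
            const int y2 = y + dy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int dz = -1; dz <= 1 && is_max; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int z2 = z + dz;
              if (z2 < 0 || z2 >= nz) continue;
              const double w =
                  a[z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2)];
              if (w > v) {
                is_max = false;
              } else if (w == v) {
                // lexicographic (z, y, x) tie-break
                if (z2 < z || (z2 == z && (y2 < y || (y2 == y && x2 < x))))
                  is_max = false;
              }
            }
          }
        }
        if (is_max) {
          zz.push_back(z + 1); yy.push_back(y + 1); xx.push_back(x + 1);
          vv.push_back(v);
        }
      }
    }
  }
  NumericMatrix out(zz.size(), 4);
  for (size_t i = 0; i < zz.size(); ++i) {
    out(i, 0) = zz[i]; out(i, 1) = yy[i]; out(i, 2) = xx[i]; out(i, 3) = vv[i];
  }
  colnames(out) = CharacterVector::create("z", "y", "x", "value");
  return out;
}
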