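#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Same-padded 3D sliding-window convolution (CNN convention: inner product
// of the kernel with the window, no kernel flip).  Out-of-volume positions
// are treated as zero.  Kernel dims must be odd.
// [[Rcpp::export(name = ".conv3d_same_cpp")]]
NumericVector conv3d_same_cpp(NumericVector x, NumericVector k) {
  IntegerVector xd = x.attr("dim");
  IntegerVector kd = k.attr("dim");
  if (xd.size() != 3 || kd.size() != 3)
    stop("conv3d: both arguments must be 3D arrays");
  const int nx = xd[0], ny = xd[1], nz = xd[2];
  const int ka = kd[0], kb = kd[1], kc = kd[2];
  if (ka % 2 == 0 || kb % 2 == 0 || kc % 2 == 0)
    stop("conv3d: kernel dims must be odd");
  const int ha = ka / 2, hb = kb / 2, hc = kc / 2;

  NumericVector out(nx * ny * nz);
  out.attr("dim") = xd;
  const double *px = x.begin(), *pk = k.begin();
  double *po = out.begin();

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int xi = 0; xi < nx; ++xi) {
        double acc = 0.0;
        for (int c = 0; c < kc; ++c) {
          const int zz = z + c - hc;
          if (zz < 0 || zz >= nz) continue;
          for (int b = 0; b < kb; ++b) {
            const int yy = y + b - hb;
            if (yy < 0 || yy >= ny) continue;
            const double *xrow = px + (size_t)zz * nx * ny + (size_t)yy * nx;
            const double *krow = pk + (size_t)c * ka * kb + (size_t)b * ka;
            for (int a = 0; a < ka; ++a) {
              const int xx = xi + a - ha;
              if (xx < 0 || xx >= nx) continue;
              acc += xrow[xx] * krow[a];
            }
          }
        }
        po[(size_t)z * nx * ny + (size_t)y * nx + xi] = acc;
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary 3D array; connectivity 6 or 26.
// Labels are 1..n_components in first-encounter order, background 0.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(IntegerVector mask, int connectivity) {
  IntegerVector md = mask.attr("dim");
  if (md.size() != 3) stop("label3d: mask must be a 3D array");
  if (connectivity != 6 && connectivity != 26)
    stop("label3d: connectivity must be 6 or 26");
  const int nx = md[0], ny = md[1], nz = md[2];
  const size_t n = (size_t)nx * ny * nz;

  IntegerVector lab(n);
  lab.attr("dim") = md;
  const int *pm = mask.begin();
  int *pl = lab.begin();

  std::vector<int> offs;  // neighbour offsets as (dx,dy,dz) triples
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }

  int next_label = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (pm[s] == 0 || pl[s] != 0) continue;
    ++next_label;
    pl[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int z = cur / ((size_t)nx * ny);
      const int rem = cur % ((size_t)nx * ny);
      const int y = rem / nx, x = rem % nx;
      for (size_t o = 0; o < offs.size(); o += 3) {
        const int xx = x + offs[o], yy = y + offs[o + 1], zz = z + offs[o + 2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const size_t t = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (pm[t] != 0 && pl[t] == 0) {
          pl[t] = next_label;
          stack.push_back(t);
        }
      }
    }
  }
  return lab;
}
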