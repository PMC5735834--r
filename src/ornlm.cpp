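#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Optimized Rician non-local means core.
//
// Patch similarities are computed on the magnitude image (whose noise SD is
// sigma, making h = sigma a natural scale); the averaging itself runs on the
// squared image, and the Rician bias 2*sigma^2 is subtracted before the
// square root. Patch distances use a
// separable Gaussian weighting over patch offsets (1D taps normalized to sum
// 1, so the 3D weights sum to 1 and the distance is a weighted mean squared
// difference). Patch reads outside the volume use edge replication; the
// search window is clipped at the volume border. The offset loop exploits the
// symmetry d_t(x) = d_{-t}(x + t) to halve the work.

static inline int iclamp(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".ornlm_core")]]
NumericVector ornlm_core(NumericVector vol, IntegerVector dims,
                         int search_radius, int patch_radius,
                         double h, double sigma, double patch_sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int pr = patch_radius, sr = search_radius;
  const int npx = nx + 2 * pr, npy = ny + 2 * pr, npz = nz + 2 * pr;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t np = (R_xlen_t)npx * npy * npz;
  const double inv_h2 = 1.0 / (h * h);

  // normalized 1D Gaussian taps over patch offsets
  std::vector<double> tap(2 * pr + 1);
  double tsum = 0.0;
  for (int k = -pr; k <= pr; ++k) {
    tap[k + pr] = std::exp(-0.5 * (double)(k * k) / (patch_sigma * patch_sigma));
    tsum += tap[k + pr];
  }
  for (auto &t : tap) t /= tsum;

  std::vector<double> u2(n);
  for (R_xlen_t i = 0; i < n; ++i) u2[i] = vol[i] * vol[i];

  // edge-replicated padded copy of the magnitude image (patch distances)
  std::vector<double> up(np);
  for (int z = 0; z < npz; ++z) {
    int zz = iclamp(z - pr, 0, nz - 1);
    for (int y = 0; y < npy; ++y) {
      int yy = iclamp(y - pr, 0, ny - 1);
      const double *src = &vol[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx];
      double *dst = &up[(R_xlen_t)z * npx * npy + (R_xlen_t)y * npx];
      for (int x = 0; x < npx; ++x) dst[x] = src[iclamp(x - pr, 0, nx - 1)];
    }
  }

  // self weight
  std::vector<double> num(u2), den(n, 1.0);

  std::vector<double> A(np), B(np), C(np), E(n);

  for (int tz = -sr; tz <= sr; ++tz) {
    for (int ty = -sr; ty <= sr; ++ty) {
      for (int tx = -sr; tx <= sr; ++tx) {
        // positive lexicographic half; the mirror offset is handled by symmetry
        if (tz < 0 || (tz == 0 && (ty < 0 || (ty == 0 && tx <= 0)))) continue;

        // squared differences on the padded grid (clamped reads for x + t)
        for (int z = 0; z < npz; ++z) {
          int zs = iclamp(z + tz, 0, npz - 1);
          for (int y = 0; y < npy; ++y) {
            int ys = iclamp(y + ty, 0, npy - 1);
            const double *r0 = &up[(R_xlen_t)z * npx * npy + (R_xlen_t)y * npx];
            const double *r1 = &up[(R_xlen_t)zs * npx * npy + (R_xlen_t)ys * npx];
            double *a = &A[(R_xlen_t)z * npx * npy + (R_xlen_t)y * npx];
            for (int x = 0; x < npx; ++x) {
              double d = r0[x] - r1[iclamp(x + tx, 0, npx - 1)];
              a[x] = d * d;
            }
          }
        }
        // NOTE on clamping: for voxels x in the valid accumulation box,
        // x + t is inside the volume, so clamped reads only ever replicate
        // edges of the *patch*, matching the brute-force definition.

        // separable Gaussian patch filtering: x, then y, then z
        for (int z = 0; z < npz; ++z)
          for (int y = 0; y < npy; ++y) {
            const double *a = &A[(R_xlen_t)z * npx * npy + (R_xlen_t)y * npx];
            double *b = &B[(R_xlen_t)z * npx * npy + (R_xlen_t)y * npx];
            for (int x = pr; x < npx - pr; ++x) {
              double s = 0.0;
              for (int k = -pr; k <= pr; ++k) s += tap[k + pr] * a[x + k];
              b[x] = s;
            }
          }
        for (int z = 0; z < npz; ++z)
          for (int y = pr; y < npy - pr; ++y) {
            double *c = &C[(R_xlen_t)z * npx * npy + (R_xlen_t)y * npx];
            for (int x = pr; x < npx - pr; ++x) {
              double s = 0.0;
              for (int k = -pr; k <= pr; ++k)
                s += tap[k + pr] * B[(R_xlen_t)z * npx * npy +
                                     (R_xlen_t)(y + k) * npx + x];
              c[x] = s;
            }
          }
        for (int z = 0; z < nz; ++z)
          for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
              double s = 0.0;
              for (int k = -pr; k <= pr; ++k)
                s += tap[k + pr] * C[(R_xlen_t)(z + pr + k) * npx * npy +
                                     (R_xlen_t)(y + pr) * npx + (x + pr)];
              E[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = s;
            }

        // accumulate over the box where both x and x + t are in the volume
        const int x0 = std::max(0, -tx), x1 = nx - std::max(0, tx);
        const int y0 = std::max(0, -ty), y1 = ny - std::max(0, ty);
        const int z0 = std::max(0, -tz), z1 = nz - std::max(0, tz);
        const R_xlen_t toff = (R_xlen_t)tz * nx * ny + (R_xlen_t)ty * nx + tx;
        for (int z = z0; z < z1; ++z)
          for (int y = y0; y < y1; ++y) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
            for (int x = x0; x < x1; ++x) {
              R_xlen_t i = base + x, j = i + toff;
              double w = std::exp(-E[i] * inv_h2);
              num[i] += w * u2[j];
              den[i] += w;
              num[j] += w * u2[i];
              den[j] += w;
            }
          }
      }
    }
  }

  const double bias = 2.0 * sigma * sigma;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = num[i] / den[i] - bias;
    out[i] = v > 0.0 ? std::sqrt(v) : 0.0;
  }
  out.attr("dim") = dims;
  return out;
}
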