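#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multispectral non-local-means core.
//
// Operates on reflect-padded channel and sigma arrays prepared in R, with
// the search-offset table (sorted by distance, grouped into shells of
// equal distance) and the separable 1D patch kernels shared with the pure
// R reference implementation, so both paths use the same discretization.
//
// Offset-major evaluation: for each search offset delta, the Gaussian
// patch distance d2(x, x+delta) is computed for every core voxel at once
// as a separable convolution of the squared difference image, then the
// per-channel weights are accumulated for voxels whose weight budget is
// not yet met. Stopping is checked after each complete shell; the loop
// over shells terminates early once every voxel has met its budget.
//
// [[Rcpp::export]]
List mnlm_core(List Xp, List Sp, NumericVector qn, double sc2,
               double target, IntegerMatrix soff, NumericVector sdist,
               IntegerVector shell, List k1d, IntegerVector kext,
               IntegerVector core_dim, IntegerVector pad,
               LogicalVector mask, LogicalVector finite) {
  const int M = Xp.size();
  const int nx = core_dim[0], ny = core_dim[1], nz = core_dim[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int npx = nx + 2 * px, npy = ny + 2 * py, npz = nz + 2 * pz;
  const R_xlen_t npvox = (R_xlen_t)npx * npy * npz;
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const int ex = kext[0], ey = kext[1], ez = kext[2];
  const int noff = soff.nrow();

  std::vector<const double*> X(M), S(M);
  for (int m = 0; m < M; ++m) {
    NumericVector xm = Xp[m], sm = Sp[m];
    X[m] = REAL(xm);
    S[m] = REAL(sm);
  }
  NumericVector kx = k1d[0], ky = k1d[1], kz = k1d[2];

  NumericMatrix num(nv, M), den(nv, M), radius(nv, M);
  LogicalMatrix capped(nv, M);
  std::vector<char> stopped((size_t)nv * M, 0);
  std::vector<char> active(nv, 0);
  R_xlen_t n_active = 0;

  // padded linear index of each core voxel, and per-voxel sigma^2 at x
  std::vector<R_xlen_t> cidx(nv);
  NumericMatrix sig2x(nv, M);
  {
    R_xlen_t vi = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++vi) {
          cidx[vi] = (R_xlen_t)(x + px) +
                     (R_xlen_t)npx * ((y + py) + (R_xlen_t)npy * (z + pz));
          for (int m = 0; m < M; ++m) {
            double s = S[m][cidx[vi]];
            sig2x(vi, m) = s * s;
          }
          if (mask[vi]) { active[vi] = 1; ++n_active; }
        }
  }

  // convolution work buffers (padded size) and per-offset distance image
  std::vector<double> D(npvox), T1(npvox), d2(nv);

  // shells are contiguous in the sorted offset table
  int nshell = 0;
  for (int i = 0; i < noff; ++i) if (shell[i] + 1 > nshell) nshell = shell[i] + 1;
  std::vector<int> sh_start(nshell + 1, noff);
  for (int i = noff - 1; i >= 0; --i) sh_start[shell[i]] = i;
  sh_start[nshell] = noff;

  for (int s = 0; s < nshell && n_active > 0; ++s) {
    for (int io = sh_start[s]; io < sh_start[s + 1]; ++io) {
      const int dx = soff(io, 0), dy = soff(io, 1), dz = soff(io, 2);
      const R_xlen_t dlin = (R_xlen_t)dx + (R_xlen_t)npx *
                            ((R_xlen_t)dy + (R_xlen_t)npy * dz);
      std::fill(d2.begin(), d2.end(), 0.0);

      for (int m = 0; m < M; ++m) {
        const double* Xm = X[m];
        // squared difference image on the core box expanded by the kernel
        for (int z = pz - ez; z < pz + nz + ez; ++z)
          for (int y = py - ey; y < py + ny + ey; ++y) {
            R_xlen_t base = (R_xlen_t)npx * (y + (R_xlen_t)npy * z);
            for (int x = px - ex; x < px + nx + ex; ++x) {
              R_xlen_t u = base + x;
              double d = Xm[u] - Xm[u + dlin];
              D[u] = d * d;
            }
          }
        // x pass
        for (int z = pz - ez; z < pz + nz + ez; ++z)
          for (int y = py - ey; y < py + ny + ey; ++y) {
            R_xlen_t base = (R_xlen_t)npx * (y + (R_xlen_t)npy * z);
            for (int x = px; x < px + nx; ++x) {
              double acc = 0.0;
              for (int i = -ex; i <= ex; ++i)
                acc += kx[i + ex] * D[base + x + i];
              T1[base + x] = acc;
            }
          }
        // y pass (write back into D)
        for (int z = pz - ez; z < pz + nz + ez; ++z)
          for (int y = py; y < py + ny; ++y)
            for (int x = px; x < px + nx; ++x) {
              R_xlen_t u = (R_xlen_t)x + (R_xlen_t)npx *
                           (y + (R_xlen_t)npy * z);
              double acc = 0.0;
              for (int j = -ey; j <= ey; ++j)
                acc += ky[j + ey] * T1[u + (R_xlen_t)j * npx];
              D[u] = acc;
            }
        // z pass, normalized by the center sigmas, accumulated into d2
        const R_xlen_t zstep = (R_xlen_t)npx * npy;
        R_xlen_t vi = 0;
        for (int z = pz; z < pz + nz; ++z)
          for (int y = py; y < py + ny; ++y)
            for (int x = px; x < px + nx; ++x, ++vi) {
              R_xlen_t u = (R_xlen_t)x + (R_xlen_t)npx *
                           (y + (R_xlen_t)npy * z);
              double acc = 0.0;
              for (int k = -ez; k <= ez; ++k)
                acc += kz[k + ez] * D[u + (R_xlen_t)k * zstep];
              double sy = S[m][u + dlin];
              d2[vi] += acc / (sig2x(vi, m) + sy * sy);
            }
      }

      // weight accumulation at active voxels
      for (R_xlen_t vi = 0; vi < nv; ++vi) {
        if (!active[vi]) continue;
        R_xlen_t yidx = cidx[vi] + dlin;
        if (!finite[yidx]) continue;
        double dd = d2[vi];
        if (!std::isfinite(dd)) continue;
        for (int m = 0; m < M; ++m) {
          if (stopped[(size_t)vi * M + m]) continue;
          double w = std::exp(-dd * qn[m] / sc2);
          num(vi, m) += w * X[m][yidx];
          den(vi, m) += w;
        }
      }
    }
    // end-of-shell stopping check
    const double rs = sdist[sh_start[s]];
    for (R_xlen_t vi = 0; vi < nv; ++vi) {
      if (!active[vi]) continue;
      bool any_open = false;
      for (int m = 0; m < M; ++m) {
        size_t k = (size_t)vi * M + m;
        if (!stopped[k]) {
          if (den(vi, m) >= target) {
            stopped[k] = 1;
            radius(vi, m) = rs;
          } else any_open = true;
        }
      }
      if (!any_open) { active[vi] = 0; --n_active; }
    }
  }

  NumericMatrix out(nv, M);
  const double rmax = noff > 0 ? sdist[noff - 1] : 0.0;
  for (R_xlen_t vi = 0; vi < nv; ++vi) {
    if (!mask[vi]) {
      for (int m = 0; m < M; ++m) out(vi, m) = NA_REAL;
      continue;
    }
    for (int m = 0; m < M; ++m) {
      if (!stopped[(size_t)vi * M + m]) {
        capped(vi, m) = true;
        radius(vi, m) = rmax;
      }
      out(vi, m) = num(vi, m) / den(vi, m);
    }
  }
  return List::create(_["out"] = out, _["radius"] = radius,
                      _["capped"] = capped);
}
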