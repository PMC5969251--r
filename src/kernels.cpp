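#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

inline int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

// Sample a 3D volume (column-major, dims nx,ny,nz) at continuous 0-based
// voxel coordinates. interp: 0 = nearest, 1 = trilinear. Samples outside the
// grid return `outside` (may be NA_REAL so callers can build an overlap mask).
// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector data, IntegerVector dim,
                         NumericMatrix xyz, int interp, double outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xyz.nrow();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    double x = xyz(k, 0), y = xyz(k, 1), z = xyz(k, 2);
    if (interp == 0) {
      int ix = (int)std::floor(x + 0.5), iy = (int)std::floor(y + 0.5),
          iz = (int)std::floor(z + 0.5);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
        out[k] = outside;
      } else {
        out[k] = data[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      }
    } else {
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
        out[k] = outside;
        continue;
      }
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
      int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
          z1 = std::min(z0 + 1, nz - 1);
      double fx = x - x0, fy = y - y0, fz = z - z0;
      double c000 = data[x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0)];
      double c100 = data[x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0)];
      double c010 = data[x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0)];
      double c110 = data[x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0)];
      double c001 = data[x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1)];
      double c101 = data[x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1)];
      double c011 = data[x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1)];
      double c111 = data[x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1)];
      double c00 = c000 * (1 - fx) + c100 * fx;
      double c10 = c010 * (1 - fx) + c110 * fx;
      double c01 = c001 * (1 - fx) + c101 * fx;
      double c11 = c011 * (1 - fx) + c111 * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[k] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// Separable 1D convolution along `axis` (0,1,2) with boundary renormalisation:
// at the edges the kernel is re-normalised over in-bounds taps, so constant
// images are preserved exactly.
// [[Rcpp::export]]
NumericVector cpp_conv1d(NumericVector data, IntegerVector dim,
                         NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size();
  const int hw = klen / 2; // kernel assumed odd length, centred
  NumericVector out(data.size());
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];
  // iterate over all lines along `axis`
  int o1 = (axis == 0) ? 1 : 0;
  int o2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[o2]; ++j2) {
    for (int j1 = 0; j1 < n[o1]; ++j1) {
      R_xlen_t base = (R_xlen_t)j1 * stride[o1] + (R_xlen_t)j2 * stride[o2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0, wsum = 0.0;
        for (int t = -hw; t <= hw; ++t) {
          int ii = i + t;
          if (ii < 0 || ii >= na) continue;
          double w = kernel[t + hw];
          acc += w * data[base + (R_xlen_t)ii * sa];
          wsum += w;
        }
        out[base + (R_xlen_t)i * sa] = (wsum > 0) ? acc / wsum : 0.0;
      }
    }
  }
  return out;
}

// Weighted 2D Parzen joint histogram. `pi`, `pj` are continuous bin positions
// in [0, bins-1]. kernel: 0 = box (nearest-bin assignment), 1 = Gaussian with
// sigma of one bin truncated at +-3 bins (weights renormalised per sample).
// [[Rcpp::export]]
NumericMatrix cpp_parzen_hist2(NumericVector pi, NumericVector pj,
                               NumericVector w, int bins, int kernel) {
  NumericMatrix H(bins, bins);
  const R_xlen_t n = pi.size();
  if (kernel == 0) {
    for (R_xlen_t k = 0; k < n; ++k) {
      int bi = clampi((int)std::floor(pi[k] + 0.5), 0, bins - 1);
      int bj = clampi((int)std::floor(pj[k] + 0.5), 0, bins - 1);
      H(bi, bj) += w[k];
    }
  } else {
    for (R_xlen_t k = 0; k < n; ++k) {
      int ci = clampi((int)std::floor(pi[k] + 0.5), 0, bins - 1);
      int cj = clampi((int)std::floor(pj[k] + 0.5), 0, bins - 1);
      double wtot = 0.0;
      double wij[7][7];
      for (int a = -3; a <= 3; ++a) {
        for (int b = -3; b <= 3; ++b) {
          int bi = ci + a, bj = cj + b;
          if (bi < 0 || bj < 0 || bi >= bins || bj >= bins) { wij[a + 3][b + 3] = 0; continue; }
          double di = pi[k] - bi, dj = pj[k] - bj;
          double ww = std::exp(-0.5 * (di * di + dj * dj));
          wij[a + 3][b + 3] = ww;
          wtot += ww;
        }
      }
      if (wtot <= 0) continue;
      for (int a = -3; a <= 3; ++a)
        for (int b = -3; b <= 3; ++b)
          if (wij[a + 3][b + 3] > 0)
            H(ci + a, cj + b) += w[k] * wij[a + 3][b + 3] / wtot;
    }
  }
  return H;
}

// Patch-based conditional-probability similarity. For each candidate voxel x
// (0-based linear index) and each scale s, a joint histogram of the binned
// target/atlas scale-space images is accumulated over the cubic patch of
// radius `radius` around x, and p(i_x | j_x) = H[i_x, j_x] / sum_i H[i, j_x]
// is returned. Bins are 0-based integers in [0, bins-1]; out-of-grid patch
// voxels are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_patch_cond_prob(IntegerMatrix tgtBins, IntegerMatrix atlBins,
                                  IntegerVector dim, IntegerVector cand,
                                  int radius, int bins) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ns = tgtBins.ncol();
  const R_xlen_t nc = cand.size();
  NumericMatrix out(nc, ns);
  std::vector<double> H((size_t)bins * bins);
  for (R_xlen_t c = 0; c < nc; ++c) {
    R_xlen_t idx = cand[c];
    int z = (int)(idx / ((R_xlen_t)nx * ny));
    int rem = (int)(idx - (R_xlen_t)z * nx * ny);
    int y = rem / nx, x = rem % nx;
    for (int s = 0; s < ns; ++s) {
      std::fill(H.begin(), H.end(), 0.0);
      for (int dz = -radius; dz <= radius; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -radius; dy <= radius; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -radius; dx <= radius; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            R_xlen_t ii = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            int bi = tgtBins(ii, s), bj = atlBins(ii, s);
            H[(size_t)bi + (size_t)bins * bj] += 1.0;
          }
        }
      }
      int i0 = tgtBins(idx, s), j0 = atlBins(idx, s);
      double colsum = 0.0;
      for (int i = 0; i < bins; ++i) colsum += H[(size_t)i + (size_t)bins * j0];
      out(c, s) = (colsum > 0) ? H[(size_t)i0 + (size_t)bins * j0] / colsum : 0.0;
    }
  }
  return out;
}

// SLIC super-pixels on one 2D slice (column-major nr x nc image).
// Returns 1-based labels, per-iteration energies (sum of squared proximity D^2
// in the scaled feature space), and final centers. Search window is
// 2S x 2S around each center; the previous assignment is always kept as a
// candidate so the assignment step never increases any pixel's proximity.
// [[Rcpp::export]]
List cpp_slic(NumericMatrix img, int S, double m, int maxIter,
              bool perturb) {
  const int nr = img.nrow(), nc = img.ncol();
  const int gr = (nr + S - 1) / S, gc = (nc + S - 1) / S;
  const int K = gr * gc;
  std::vector<double> cr(K), cc(K), ci(K);
  int k = 0;
  for (int a = 0; a < gr; ++a) {
    for (int b = 0; b < gc; ++b) {
      double r = std::min((double)nr - 1.0, a * (double)S + S / 2.0 - 0.5);
      double c = std::min((double)nc - 1.0, b * (double)S + S / 2.0 - 0.5);
      if (perturb) {
        // move to lowest-gradient position in 3x3 neighbourhood
        int r0 = (int)std::floor(r + 0.5), c0 = (int)std::floor(c + 0.5);
        double best = R_PosInf; int br = r0, bc = c0;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = clampi(r0 + dr, 1, nr - 2), cc2 = clampi(c0 + dc, 1, nc - 2);
            double gx = img(rr + 1, cc2) - img(rr - 1, cc2);
            double gy = img(rr, cc2 + 1) - img(rr, cc2 - 1);
            double g = gx * gx + gy * gy;
            if (g < best) { best = g; br = rr; bc = cc2; }
          }
        }
        r = br; c = bc;
      }
      cr[k] = r; cc[k] = c;
      ci[k] = img(clampi((int)std::floor(r + 0.5), 0, nr - 1),
                  clampi((int)std::floor(c + 0.5), 0, nc - 1));
      ++k;
    }
  }
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), NA_INTEGER);
  NumericVector energies(maxIter);
  const double mS = m / (double)S;
  int used = 0;
  for (int it = 0; it < maxIter; ++it) {
    // assignment
    NumericMatrix bestD(nr, nc);
    std::fill(bestD.begin(), bestD.end(), R_PosInf);
    // previous assignment stays candidate
    for (int c2 = 0; c2 < nc; ++c2) {
      for (int r2 = 0; r2 < nr; ++r2) {
        int pk = lab(r2, c2);
        if (pk != NA_INTEGER) {
          int kk = pk - 1;
          double dc2 = img(r2, c2) - ci[kk];
          double dsr = r2 - cr[kk], dsc = c2 - cc[kk];
          bestD(r2, c2) = dc2 * dc2 + (dsr * dsr + dsc * dsc) * mS * mS;
        }
      }
    }
    for (int kk = 0; kk < K; ++kk) {
      int rlo = std::max(0, (int)std::floor(cr[kk]) - S);
      int rhi = std::min(nr - 1, (int)std::floor(cr[kk]) + S);
      int clo = std::max(0, (int)std::floor(cc[kk]) - S);
      int chi = std::min(nc - 1, (int)std::floor(cc[kk]) + S);
      for (int c2 = clo; c2 <= chi; ++c2) {
        for (int r2 = rlo; r2 <= rhi; ++r2) {
          double dc2 = img(r2, c2) - ci[kk];
          double dsr = r2 - cr[kk], dsc = c2 - cc[kk];
          double D2 = dc2 * dc2 + (dsr * dsr + dsc * dsc) * mS * mS;
          if (D2 < bestD(r2, c2)) { bestD(r2, c2) = D2; lab(r2, c2) = kk + 1; }
        }
      }
    }
    // orphan pixels (no center within 2S): assign to nearest center globally
    for (int c2 = 0; c2 < nc; ++c2) {
      for (int r2 = 0; r2 < nr; ++r2) {
        if (lab(r2, c2) == NA_INTEGER) {
          double best = R_PosInf; int bk = 1;
          for (int kk = 0; kk < K; ++kk) {
            double dc2 = img(r2, c2) - ci[kk];
            double dsr = r2 - cr[kk], dsc = c2 - cc[kk];
            double D2 = dc2 * dc2 + (dsr * dsr + dsc * dsc) * mS * mS;
            if (D2 < best) { best = D2; bk = kk + 1; }
          }
          lab(r2, c2) = bk; bestD(r2, c2) = best;
        }
      }
    }
    double E = 0.0;
    for (int i = 0; i < nr * nc; ++i) E += bestD[i];
    energies[it] = E;
    used = it + 1;
    // center update (means minimise the energy given the assignment)
    std::vector<double> sr(K, 0), sc(K, 0), si(K, 0), cnt(K, 0);
    double maxShift = 0.0;
    for (int c2 = 0; c2 < nc; ++c2) {
      for (int r2 = 0; r2 < nr; ++r2) {
        int kk = lab(r2, c2) - 1;
        sr[kk] += r2; sc[kk] += c2; si[kk] += img(r2, c2); cnt[kk] += 1;
      }
    }
    for (int kk = 0; kk < K; ++kk) {
      if (cnt[kk] == 0) continue;
      double nr2 = sr[kk] / cnt[kk], nc2 = sc[kk] / cnt[kk];
      double sh = std::sqrt((nr2 - cr[kk]) * (nr2 - cr[kk]) +
                            (nc2 - cc[kk]) * (nc2 - cc[kk]));
      if (sh > maxShift) maxShift = sh;
      cr[kk] = nr2; cc[kk] = nc2; ci[kk] = si[kk] / cnt[kk];
    }
    if (maxShift < 0.5) break;
  }
  return List::create(_["labels"] = lab,
                      _["energy"] = energies[Range(0, used - 1)],
                      _["n_centers"] = K);
}

// Enforce super-pixel connectivity: fragments of a super-pixel that are not
// its largest 4-connected component are merged into the dominant touching
// neighbour super-pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_slic_connectivity(IntegerMatrix lab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix comp(nr, nc); // component id per pixel, 0 = unvisited
  std::vector<int> compLab, compSize;
  int ncomp = 0;
  const int dr[4] = {1, -1, 0, 0}, dcn[4] = {0, 0, 1, -1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (comp(r, c) != 0) continue;
      ++ncomp;
      int L = lab(r, c);
      compLab.push_back(L);
      int size = 0;
      std::queue<std::pair<int,int> > q;
      q.push(std::make_pair(r, c)); comp(r, c) = ncomp;
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop(); ++size;
        for (int d = 0; d < 4; ++d) {
          int rr = p.first + dr[d], cc = p.second + dcn[d];
          if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
          if (comp(rr, cc) == 0 && lab(rr, cc) == L) {
            comp(rr, cc) = ncomp; q.push(std::make_pair(rr, cc));
          }
        }
      }
      compSize.push_back(size);
    }
  }
  // largest component per label keeps the label
  std::map<int, int> keep; // label -> component id of its largest fragment
  for (int i = 0; i < ncomp; ++i) {
    int L = compLab[i];
    if (keep.find(L) == keep.end() || compSize[i] > compSize[keep[L] - 1])
      keep[L] = i + 1;
  }
  IntegerMatrix out = clone(lab);
  // iteratively merge non-dominant fragments into touching kept regions
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 100) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        int ci = comp(r, c);
        if (keep[compLab[ci - 1]] == ci) continue; // dominant fragment
        // vote among 4-neighbours that are in dominant fragments
        std::map<int, int> votes;
        for (int d = 0; d < 4; ++d) {
          int rr = r + dr[d], cc = c + dcn[d];
          if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
          int cj = comp(rr, cc);
          if (keep[compLab[cj - 1]] == cj) votes[out(rr, cc)]++;
        }
        if (!votes.empty()) {
          int bestL = votes.begin()->first, bestV = votes.begin()->second;
          for (std::map<int,int>::iterator it = votes.begin(); it != votes.end(); ++it)
            if (it->second > bestV) { bestV = it->second; bestL = it->first; }
          out(r, c) = bestL;
          // absorb into the dominant fragment of bestL
          comp(r, c) = keep[bestL];
          compLab[comp(r, c) - 1] = bestL;
          changed = true;
        }
      }
    }
  }
  return out;
}

// Dense displacement field from cubic B-spline control coefficients.
// coef: (ncx*ncy*ncz) x 3, control point (a,b,c) sits at voxel
// ((a-1)*delta, ...), i.e. one layer of phantom control points precedes the
// grid. dim: target dims; delta: control spacing in voxels.
static inline double bspl(double t, int i) {
  // cubic B-spline basis functions B0..B3 evaluated at fractional t in [0,1)
  double t2 = t * t, t3 = t2 * t;
  switch (i) {
    case 0: return (1 - 3 * t + 3 * t2 - t3) / 6.0;
    case 1: return (3 * t3 - 6 * t2 + 4) / 6.0;
    case 2: return (-3 * t3 + 3 * t2 + 3 * t + 1) / 6.0;
    default: return t3 / 6.0;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_bspline_field(NumericMatrix coef, IntegerVector ncp,
                                IntegerVector dim, double delta) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ncx = ncp[0], ncy = ncp[1], ncz = ncp[2];
  NumericMatrix out((R_xlen_t)nx * ny * nz, 3);
  for (int z = 0; z < nz; ++z) {
    double uz = z / delta; int kz = (int)std::floor(uz); double tz = uz - kz;
    for (int y = 0; y < ny; ++y) {
      double uy = y / delta; int ky = (int)std::floor(uy); double ty = uy - ky;
      for (int x = 0; x < nx; ++x) {
        double ux = x / delta; int kx = (int)std::floor(ux); double tx = ux - kx;
        double acc0 = 0, acc1 = 0, acc2 = 0;
        for (int c = 0; c < 4; ++c) {
          int icz = kz + c; if (icz >= ncz) continue;
          double wz = bspl(tz, c);
          for (int b = 0; b < 4; ++b) {
            int icy = ky + b; if (icy >= ncy) continue;
            double wy = bspl(ty, b) * wz;
            for (int a = 0; a < 4; ++a) {
              int icx = kx + a; if (icx >= ncx) continue;
              double w = bspl(tx, a) * wy;
              R_xlen_t ic = icx + (R_xlen_t)ncx * (icy + (R_xlen_t)ncy * icz);
              acc0 += w * coef(ic, 0);
              acc1 += w * coef(ic, 1);
              acc2 += w * coef(ic, 2);
            }
          }
        }
        R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        out(idx, 0) = acc0; out(idx, 1) = acc1; out(idx, 2) = acc2;
      }
    }
  }
  return out;
}

// Transpose of cpp_bspline_field: project a dense force field onto the
// control grid (normalised by accumulated basis weight).
// [[Rcpp::export]]
NumericMatrix cpp_bspline_project(NumericMatrix force, IntegerVector dim,
                                  IntegerVector ncp, double delta) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ncx = ncp[0], ncy = ncp[1], ncz = ncp[2];
  NumericMatrix acc((R_xlen_t)ncx * ncy * ncz, 3);
  std::vector<double> wacc((size_t)ncx * ncy * ncz, 0.0);
  for (int z = 0; z < nz; ++z) {
    double uz = z / delta; int kz = (int)std::floor(uz); double tz = uz - kz;
    for (int y = 0; y < ny; ++y) {
      double uy = y / delta; int ky = (int)std::floor(uy); double ty = uy - ky;
      for (int x = 0; x < nx; ++x) {
        double ux = x / delta; int kx = (int)std::floor(ux); double tx = ux - kx;
        R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double f0 = force(idx, 0), f1 = force(idx, 1), f2 = force(idx, 2);
        for (int c = 0; c < 4; ++c) {
          int icz = kz + c; if (icz >= ncz) continue;
          double wz = bspl(tz, c);
          for (int b = 0; b < 4; ++b) {
            int icy = ky + b; if (icy >= ncy) continue;
            double wy = bspl(ty, b) * wz;
            for (int a = 0; a < 4; ++a) {
              int icx = kx + a; if (icx >= ncx) continue;
              double w = bspl(tx, a) * wy;
              R_xlen_t ic = icx + (R_xlen_t)ncx * (icy + (R_xlen_t)ncy * icz);
              acc(ic, 0) += w * f0; acc(ic, 1) += w * f1; acc(ic, 2) += w * f2;
              wacc[ic] += w;
            }
          }
        }
      }
    }
  }
  for (R_xlen_t ic = 0; ic < acc.nrow(); ++ic) {
    if (wacc[ic] > 0) {
      acc(ic, 0) /= wacc[ic]; acc(ic, 1) /= wacc[ic]; acc(ic, 2) /= wacc[ic];
    }
  }
  return acc;
}

// For each row of P, the minimum Euclidean distance to any row of Q.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix P, NumericMatrix Q) {
  const R_xlen_t n = P.nrow(), m = Q.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    for (R_xlen_t j = 0; j < m; ++j) {
      double dx = px - Q(j, 0), dy = py - Q(j, 1), dz = pz - Q(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Binary dilation by an arbitrary offset list (voxel offsets, n x 3).
// [[Rcpp::export]]
LogicalVector cpp_dilate_offsets(LogicalVector mask, IntegerVector dim,
                                 IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int no = offsets.nrow();
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[idx]) continue;
        for (int o = 0; o < no; ++o) {
          int xx = x + offsets(o, 0), yy = y + offsets(o, 1), zz = z + offsets(o, 2);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
          out[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] = true;
        }
      }
    }
  }
  return out;
}
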