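// Numeric core: Gaussian map simulation, trilinear interpolation,
// rigid-body coordinate-ascent optimization, Chamfer nearest neighbours,
// clash fractions and Shrake-Rupley SASA.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Voxel (i,j,k) (0-based) has its centre at origin + (i,j,k) * voxel.
// Arrays are stored column-major with x fastest, i.e. dim = (nx, ny, nz).

// [[Rcpp::export]]
NumericVector cpp_splat_gaussian(const NumericMatrix& atoms,
                                 const NumericVector& weights,
                                 const IntegerVector& dim,
                                 const NumericVector& origin,
                                 const NumericVector& voxel,
                                 double sigma, double cutoff) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double rad = cutoff * sigma;
  for (int a = 0; a < atoms.nrow(); ++a) {
    const double px = atoms(a, 0), py = atoms(a, 1), pz = atoms(a, 2);
    const double w = weights[a];
    int i0 = (int)std::ceil((px - rad - origin[0]) / voxel[0]);
    int i1 = (int)std::floor((px + rad - origin[0]) / voxel[0]);
    int j0 = (int)std::ceil((py - rad - origin[1]) / voxel[1]);
    int j1 = (int)std::floor((py + rad - origin[1]) / voxel[1]);
    int k0 = (int)std::ceil((pz - rad - origin[2]) / voxel[2]);
    int k1 = (int)std::floor((pz + rad - origin[2]) / voxel[2]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel[2] - pz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel[1] - py;
        const double d2yz = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel[0] - px;
          out[base + i] += w * std::exp(-(dx * dx + d2yz) * inv2s2);
        }
      }
    }
  }
  return out;
}

static inline double trilinear_one(const double* v, int nx, int ny, int nz,
                                   const double* origin, const double* voxel,
                                   double px, double py, double pz) {
  const double gx = (px - origin[0]) / voxel[0];
  const double gy = (py - origin[1]) / voxel[1];
  const double gz = (pz - origin[2]) / voxel[2];
  const int ix = (int)std::floor(gx);
  const int iy = (int)std::floor(gy);
  const int iz = (int)std::floor(gz);
  const double fx = gx - ix, fy = gy - iy, fz = gz - iz;
  double val = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    const int z = iz + dz;
    if (z < 0 || z >= nz) continue;
    const double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy < 2; ++dy) {
      const int y = iy + dy;
      if (y < 0 || y >= ny) continue;
      const double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx < 2; ++dx) {
        const int x = ix + dx;
        if (x < 0 || x >= nx) continue;
        const double wx = dx ? fx : 1.0 - fx;
        val += wx * wy * wz * v[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
      }
    }
  }
  return val;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector& values,
                            const IntegerVector& dim,
                            const NumericVector& origin,
                            const NumericVector& voxel,
                            const NumericMatrix& points) {
  const int n = points.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilinear_one(REAL(values), dim[0], dim[1], dim[2],
                           REAL(origin), REAL(voxel),
                           points(i, 0), points(i, 1), points(i, 2));
  return out;
}

static double objective(const double* v, const int* dim,
                        const double* origin, const double* voxel,
                        const NumericMatrix& atoms, const NumericVector& w,
                        const double R[9], const double t[3]) {
  double s = 0.0;
  for (int a = 0; a < atoms.nrow(); ++a) {
    const double x = atoms(a, 0), y = atoms(a, 1), z = atoms(a, 2);
    const double px = R[0] * x + R[1] * y + R[2] * z + t[0];
    const double py = R[3] * x + R[4] * y + R[5] * z + t[1];
    const double pz = R[6] * x + R[7] * y + R[8] * z + t[2];
    s += w[a] * trilinear_one(v, dim[0], dim[1], dim[2], origin, voxel,
                              px, py, pz);
  }
  return s;
}

static void axis_rot(int axis, double ang, double A[9]) {
  const double c = std::cos(ang), s = std::sin(ang);
  for (int i = 0; i < 9; ++i) A[i] = 0.0;
  if (axis == 0) { A[0] = 1; A[4] = c; A[5] = -s; A[7] = s; A[8] = c; }
  else if (axis == 1) { A[4] = 1; A[0] = c; A[2] = s; A[6] = -s; A[8] = c; }
  else { A[8] = 1; A[0] = c; A[1] = -s; A[3] = s; A[4] = c; }
}

static void matmul3(const double A[9], const double B[9], double C[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}

// Greedy coordinate ascent over 6 rigid parameters (3 rotations about the
// placed centroid, 3 translations) with backtracking step sizes.  `steps`
// caps the number of full sweeps.  Returns the improved transform, its
// objective value and the per-sweep score trace (non-decreasing).
// [[Rcpp::export]]
List cpp_local_optimize(const NumericVector& values,
                        const IntegerVector& dim,
                        const NumericVector& origin,
                        const NumericVector& voxel,
                        const NumericMatrix& atoms,
                        const NumericVector& weights,
                        const NumericMatrix& R0,
                        const NumericVector& t0,
                        int steps,
                        double step_rot, double step_trans,
                        double min_trans) {
  const double* v = REAL(values);
  double R[9], t[3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[3 * i + j] = R0(i, j);
  for (int i = 0; i < 3; ++i) t[i] = t0[i];
  // model centroid (weighted)
  double c0[3] = {0, 0, 0}, wsum = 0.0;
  for (int a = 0; a < atoms.nrow(); ++a) {
    for (int d = 0; d < 3; ++d) c0[d] += weights[a] * atoms(a, d);
    wsum += weights[a];
  }
  for (int d = 0; d < 3; ++d) c0[d] /= wsum;

  int dims[3] = {dim[0], dim[1], dim[2]};
  double score = objective(v, dims, REAL(origin), REAL(voxel),
                           atoms, weights, R, t);
  std::vector<double> trace;
  trace.push_back(score);
  double dr = step_rot, dt = step_trans;
  int sweeps = 0;
  while (sweeps < steps) {
    bool improved = false;
    // translations
    for (int d = 0; d < 3; ++d) {
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double t2[3] = {t[0], t[1], t[2]};
        t2[d] += sgn * dt;
        double s2 = objective(v, dims, REAL(origin), REAL(voxel),
                              atoms, weights, R, t2);
        if (s2 > score) { score = s2; t[d] = t2[d]; improved = true; break; }
      }
    }
    // rotations about the placed centroid
    double cplaced[3];
    for (int i = 0; i < 3; ++i)
      cplaced[i] = R[3 * i] * c0[0] + R[3 * i + 1] * c0[1] +
                   R[3 * i + 2] * c0[2] + t[i];
    for (int ax = 0; ax < 3; ++ax) {
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double A[9], R2[9], t2[3];
        axis_rot(ax, sgn * dr, A);
        matmul3(A, R, R2);
        for (int i = 0; i < 3; ++i)
          t2[i] = cplaced[i] - (R2[3 * i] * c0[0] + R2[3 * i + 1] * c0[1] +
                                R2[3 * i + 2] * c0[2]);
        double s2 = objective(v, dims, REAL(origin), REAL(voxel),
                              atoms, weights, R2, t2);
        if (s2 > score) {
          score = s2;
          for (int i = 0; i < 9; ++i) R[i] = R2[i];
          for (int i = 0; i < 3; ++i) t[i] = t2[i];
          improved = true;
          break;
        }
      }
    }
    ++sweeps;
    trace.push_back(score);
    if (!improved) {
      dr *= 0.5;
      dt *= 0.5;
      if (dt < min_trans) break;
    }
  }
  NumericMatrix Rout(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Rout(i, j) = R[3 * i + j];
  return List::create(_["rotation"] = Rout,
                      _["translation"] = NumericVector::create(t[0], t[1], t[2]),
                      _["score"] = score,
                      _["trace"] = wrap(trace),
                      _["sweeps"] = sweeps);
}

// [[Rcpp::export]]
double cpp_objective(const NumericVector& values, const IntegerVector& dim,
                     const NumericVector& origin, const NumericVector& voxel,
                     const NumericMatrix& atoms, const NumericVector& weights,
                     const NumericMatrix& R0, const NumericVector& t0) {
  double R[9], t[3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[3 * i + j] = R0(i, j);
  for (int i = 0; i < 3; ++i) t[i] = t0[i];
  int dims[3] = {dim[0], dim[1], dim[2]};
  return objective(REAL(values), dims, REAL(origin), REAL(voxel),
                   atoms, weights, R, t);
}

// One-directional mean nearest-neighbour distance from A to B using a
// projection search on x (sorted B, prune by |dx|).
static double mean_nn(const NumericMatrix& A, const NumericMatrix& B,
                      const std::vector<int>& ord) {
  const int n = A.nrow(), m = B.nrow();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    // binary search for ax in sorted B x-coordinates
    int lo = 0, hi = m;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (B(ord[mid], 0) < ax) lo = mid + 1; else hi = mid;
    }
    double best = R_PosInf;
    int l = lo - 1, r = lo;
    while (l >= 0 || r < m) {
      bool goLeft = false;
      if (l >= 0 && r < m)
        goLeft = (ax - B(ord[l], 0)) <= (B(ord[r], 0) - ax);
      else goLeft = (l >= 0);
      int idx = goLeft ? ord[l] : ord[r];
      double dx = B(idx, 0) - ax;
      if (dx * dx > best) {
        if (goLeft) { l = -1; } else { r = m; }
        continue;
      }
      double dy = B(idx, 1) - ay, dz = B(idx, 2) - az;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
      if (goLeft) --l; else ++r;
    }
    total += std::sqrt(best);
  }
  return total / n;
}

// [[Rcpp::export]]
double cpp_chamfer(const NumericMatrix& A, const NumericMatrix& B) {
  std::vector<int> ordA(A.nrow()), ordB(B.nrow());
  for (size_t i = 0; i < ordA.size(); ++i) ordA[i] = (int)i;
  for (size_t i = 0; i < ordB.size(); ++i) ordB[i] = (int)i;
  std::sort(ordA.begin(), ordA.end(),
            [&](int a, int b) { return A(a, 0) < A(b, 0); });
  std::sort(ordB.begin(), ordB.end(),
            [&](int a, int b) { return B(a, 0) < B(b, 0); });
  return 0.5 * (mean_nn(A, B, ordB) + mean_nn(B, A, ordA));
}

// Fraction of rows of A lying within `radius` of any row of B.
// [[Rcpp::export]]
double cpp_clash_fraction(const NumericMatrix& A, const NumericMatrix& B,
                          double radius) {
  const double r2 = radius * radius;
  int nclash = 0;
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      const double dx = A(i, 0) - B(j, 0);
      const double dy = A(i, 1) - B(j, 1);
      const double dz = A(i, 2) - B(j, 2);
      if (dx * dx + dy * dy + dz * dz < r2) { ++nclash; break; }
    }
  }
  return (double)nclash / A.nrow();
}

// Shrake-Rupley SASA with a golden-spiral quadrature of n_points per atom.
// [[Rcpp::export]]
NumericVector cpp_sasa(const NumericMatrix& coords,
                       const NumericVector& radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  // golden spiral points on the unit sphere
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double th = golden * k;
    sx[k] = rho * std::cos(th);
    sy[k] = rho * std::sin(th);
    sz[k] = z;
  }
  NumericVector area(n);
  std::vector<double> Ri(n);
  for (int i = 0; i < n; ++i) Ri[i] = radii[i] + probe;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - coords(i, 0);
      const double dy = coords(j, 1) - coords(i, 1);
      const double dz = coords(j, 2) - coords(i, 2);
      const double lim = Ri[i] + Ri[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double px = coords(i, 0) + Ri[i] * sx[k];
      const double py = coords(i, 1) + Ri[i] * sy[k];
      const double pz = coords(i, 2) + Ri[i] * sz[k];
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px - coords(j, 0);
        const double dy = py - coords(j, 1);
        const double dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < Ri[j] * Ri[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri[i] * Ri[i] * (double)acc / n_points;
  }
  return area;
}

// Largest 6-connected component of a boolean grid (dust removal for
// envelopes of noisy maps).
// [[Rcpp::export]]
LogicalVector cpp_largest_component(const LogicalVector& mask,
                                    const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  int best_label = 0, best_size = 0, cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++cur;
    int size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && !label[w]) { label[w] = cur; stack.push_back(w); }
      }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (label[s] == best_label);
  return out;
}
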