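#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Uniform-lattice kernels backing the octree-discretized Poisson solve.
// The lattice is the complete depth-D level of the octree: g = 2^D nodes per
// axis spanning the padded root cube; index = x + g*(y + g*z). All solver
// arithmetic is done in grid units (spacing 1), which makes the solve exactly
// similarity-equivariant.

namespace {

// Quadratic B-spline (3-fold box convolution), support (-1.5, 1.5).
inline double bspline2(double t) {
  double a = std::fabs(t);
  if (a <= 0.5) return 0.75 - t * t;
  if (a < 1.5) {
    double s = 1.5 - a;
    return 0.5 * s * s;
  }
  return 0.0;
}

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

}  // namespace

// Distribute per-sample values (columns of `vals`) to lattice nodes with
// tensor-product quadratic B-spline partition-of-unity weights.
// [[Rcpp::export]]
NumericMatrix splat_grid_cpp(NumericMatrix P, NumericVector origin, double h,
                             int g, NumericMatrix vals) {
  const int n = P.nrow();
  const int m = vals.ncol();
  const R_xlen_t g3 = (R_xlen_t)g * g * g;
  NumericMatrix out(g3, m);
  double wbuf[3][3];
  int ibuf[3][3];
  for (int p = 0; p < n; ++p) {
    for (int d = 0; d < 3; ++d) {
      double u = (P(p, d) - origin[d]) / h;
      int j0 = (int)std::ceil(u - 1.5);
      for (int o = 0; o < 3; ++o) {
        int j = j0 + o;
        wbuf[d][o] = bspline2(u - j);
        ibuf[d][o] = clampi(j, 0, g - 1);
      }
    }
    for (int oz = 0; oz < 3; ++oz) {
      double wz = wbuf[2][oz];
      if (wz == 0) continue;
      R_xlen_t bz = (R_xlen_t)ibuf[2][oz] * g * g;
      for (int oy = 0; oy < 3; ++oy) {
        double wyz = wz * wbuf[1][oy];
        if (wyz == 0) continue;
        R_xlen_t byz = bz + (R_xlen_t)ibuf[1][oy] * g;
        for (int ox = 0; ox < 3; ++ox) {
          double w = wyz * wbuf[0][ox];
          if (w == 0) continue;
          R_xlen_t idx = byz + ibuf[0][ox];
          for (int c = 0; c < m; ++c) out(idx, c) += w * vals(p, c);
        }
      }
    }
  }
  return out;
}

// Evaluate a lattice field at arbitrary points through the same B-spline
// basis (normalized by the local weight sum so clamping at the boundary and
// the partition of unity stay consistent).
// [[Rcpp::export]]
NumericVector eval_grid_cpp(NumericVector field, NumericVector origin, double h,
                            int g, NumericMatrix Q) {
  const int n = Q.nrow();
  NumericVector out(n);
  double wbuf[3][3];
  int ibuf[3][3];
  for (int p = 0; p < n; ++p) {
    for (int d = 0; d < 3; ++d) {
      double u = (Q(p, d) - origin[d]) / h;
      int j0 = (int)std::ceil(u - 1.5);
      for (int o = 0; o < 3; ++o) {
        int j = j0 + o;
        wbuf[d][o] = bspline2(u - j);
        ibuf[d][o] = clampi(j, 0, g - 1);
      }
    }
    double acc = 0.0, wsum = 0.0;
    for (int oz = 0; oz < 3; ++oz) {
      double wz = wbuf[2][oz];
      if (wz == 0) continue;
      R_xlen_t bz = (R_xlen_t)ibuf[2][oz] * g * g;
      for (int oy = 0; oy < 3; ++oy) {
        double wyz = wz * wbuf[1][oy];
        if (wyz == 0) continue;
        R_xlen_t byz = bz + (R_xlen_t)ibuf[1][oy] * g;
        for (int ox = 0; ox < 3; ++ox) {
          double w = wyz * wbuf[0][ox];
          if (w == 0) continue;
          acc += w * field[byz + ibuf[0][ox]];
          wsum += w;
        }
      }
    }
    out[p] = wsum > 0 ? acc / wsum : 0.0;
  }
  return out;
}

// Central-difference divergence in grid units (one-sided contributions vanish
// at the boundary where the splatted field is identically zero anyway).
// [[Rcpp::export]]
NumericVector divergence_cpp(NumericVector Vx, NumericVector Vy,
                             NumericVector Vz, int g) {
  const R_xlen_t g3 = (R_xlen_t)g * g * g;
  NumericVector out(g3);
  const R_xlen_t sx = 1, sy = g, sz = (R_xlen_t)g * g;
  for (int z = 0; z < g; ++z) {
    for (int y = 0; y < g; ++y) {
      R_xlen_t base = (R_xlen_t)z * sz + (R_xlen_t)y * sy;
      for (int x = 0; x < g; ++x) {
        R_xlen_t i = base + x;
        double d = 0.0;
        if (x > 0 && x < g - 1) d += 0.5 * (Vx[i + sx] - Vx[i - sx]);
        if (y > 0 && y < g - 1) d += 0.5 * (Vy[i + sy] - Vy[i - sy]);
        if (z > 0 && z < g - 1) d += 0.5 * (Vz[i + sz] - Vz[i - sz]);
        out[i] = d;
      }
    }
  }
  return out;
}

namespace {

// out = (L + diag(alpha * W)) v, L the Neumann graph Laplacian of the lattice.
void apply_op(const double* v, double* out, int g, const double* W,
              double alpha) {
  const R_xlen_t sx = 1, sy = g, sz = (R_xlen_t)g * g;
  for (int iz = 0; iz < g; ++iz) {
    for (int iy = 0; iy < g; ++iy) {
      R_xlen_t base = (R_xlen_t)iz * sz + (R_xlen_t)iy * sy;
      if (iy > 0 && iy < g - 1 && iz > 0 && iz < g - 1) {
        R_xlen_t i = base + 1;
        for (int ix = 1; ix < g - 1; ++ix, ++i) {
          double a = 6.0 * v[i] - v[i - sx] - v[i + sx] - v[i - sy] -
                     v[i + sy] - v[i - sz] - v[i + sz];
          if (W) a += alpha * W[i] * v[i];
          out[i] = a;
        }
        for (int ix = 0; ix < g; ix += g - 1) {
          R_xlen_t i = base + ix;
          double a = 4.0 * v[i] - v[i - sy] - v[i + sy] - v[i - sz] - v[i + sz];
          if (ix > 0) a += v[i] - v[i - sx];
          if (ix < g - 1) a += v[i] - v[i + sx];
          if (W) a += alpha * W[i] * v[i];
          out[i] = a;
        }
      } else {
        for (int ix = 0; ix < g; ++ix) {
          R_xlen_t i = base + ix;
          double a = 0.0;
          if (ix > 0) a += v[i] - v[i - sx];
          if (ix < g - 1) a += v[i] - v[i + sx];
          if (iy > 0) a += v[i] - v[i - sy];
          if (iy < g - 1) a += v[i] - v[i + sy];
          if (iz > 0) a += v[i] - v[i - sz];
          if (iz < g - 1) a += v[i] - v[i + sz];
          if (W) a += alpha * W[i] * v[i];
          out[i] = a;
        }
      }
    }
  }
}

inline double dot_vec(const std::vector<double>& a,
                      const std::vector<double>& b) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}

}  // namespace

// Jacobi-preconditioned conjugate gradients for
// (L + alpha*diag(W)) chi = b on the g^3 lattice.
// With alpha = 0 the system is singular (constant nullspace); b is projected
// to zero mean by the caller and the nullspace component of the iterates is
// irrelevant to the residual, so plain CG applies unchanged.
// [[Rcpp::export]]
List pcg_solve_cpp(NumericVector b, Nullable<NumericVector> W_, double alpha,
                   int g, double tol, int maxit) {
  const R_xlen_t g3 = (R_xlen_t)g * g * g;
  const double* W = nullptr;
  NumericVector Wv;
  if (W_.isNotNull()) {
    Wv = W_.get();
    W = REAL(Wv);
  }
  std::vector<double> x(g3, 0.0), r(g3), p(g3), Ap(g3), z(g3), dinv(g3);
  const R_xlen_t sxy = (R_xlen_t)g * g;
  for (R_xlen_t i = 0; i < g3; ++i) {
    int ix = (int)(i % g), iy = (int)((i / g) % g), iz = (int)(i / sxy);
    double d = (double)((ix > 0) + (ix < g - 1) + (iy > 0) + (iy < g - 1) +
                        (iz > 0) + (iz < g - 1));
    if (W) d += alpha * W[i];
    dinv[i] = 1.0 / d;
  }
  double bnorm = 0.0;
  for (R_xlen_t i = 0; i < g3; ++i) {
    r[i] = b[i];
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["x"] = NumericVector(g3), _["iterations"] = 0,
                        _["relres"] = 0.0);
  }
  for (R_xlen_t i = 0; i < g3; ++i) {
    z[i] = dinv[i] * r[i];
    p[i] = z[i];
  }
  double rz = dot_vec(r, z);
  double relres = 1.0;
  int it = 0;
  for (; it < maxit; ++it) {
    apply_op(p.data(), Ap.data(), g, W, alpha);
    double pAp = dot_vec(p, Ap);
    if (pAp <= 0) break;
    double a = rz / pAp;
    double rn2 = 0.0;
    for (R_xlen_t i = 0; i < g3; ++i) {
      x[i] += a * p[i];
      r[i] -= a * Ap[i];
      rn2 += r[i] * r[i];
    }
    relres = std::sqrt(rn2) / bnorm;
    if (relres <= tol) {
      ++it;
      break;
    }
    double rz_new = 0.0;
    for (R_xlen_t i = 0; i < g3; ++i) {
      z[i] = dinv[i] * r[i];
      rz_new += r[i] * z[i];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t i = 0; i < g3; ++i) p[i] = z[i] + beta * p[i];
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector xr(g3);
  for (R_xlen_t i = 0; i < g3; ++i) xr[i] = x[i];
  return List::create(_["x"] = xr, _["iterations"] = it,
                      _["relres"] = relres);
}

// ---------------------------------------------------------------------------
// Geometric multigrid preconditioner (lumped-Galerkin hierarchy).
//
// Level operator: A_l = s_l * L(graph Laplacian) + diag(dw_l), with
// s_{l+1} = 2 s_l and dw aggregated with separable (1/2, 1, 1/2) weights --
// the mass-lumped Galerkin coarse operator for trilinear prolongation.
// Residuals restrict with the same (aggregation) kernel; corrections
// prolong by its transpose (linear interpolation). Smoother: damped Jacobi
// (symmetric, so one V-cycle is a valid SPD preconditioner for CG).

namespace {

struct MgLevel {
  int g;
  double s;                  // Laplacian scale
  std::vector<double> dw;    // screening diagonal (already alpha-scaled)
  std::vector<double> dinv;  // 1 / operator diagonal
  std::vector<double> x, b, r;
};

inline R_xlen_t gidx(int x, int y, int z, int g) {
  return (R_xlen_t)x + (R_xlen_t)g * ((R_xlen_t)y + (R_xlen_t)g * z);
}

// out = s*L(v) + dw*v
void level_apply_scaled(const MgLevel& L, const std::vector<double>& v,
                        std::vector<double>& out) {
  apply_op(v.data(), out.data(), L.g, nullptr, 0.0);
  const R_xlen_t n = (R_xlen_t)L.g * L.g * L.g;
  if (L.dw.empty()) {
    for (R_xlen_t i = 0; i < n; ++i) out[i] *= L.s;
  } else {
    for (R_xlen_t i = 0; i < n; ++i) out[i] = L.s * out[i] + L.dw[i] * v[i];
  }
}

void jacobi_sweep(MgLevel& L, const std::vector<double>& b,
                  std::vector<double>& x, std::vector<double>& tmp,
                  double omega) {
  level_apply_scaled(L, x, tmp);
  const R_xlen_t n = (R_xlen_t)L.g * L.g * L.g;
  for (R_xlen_t i = 0; i < n; ++i) {
    x[i] += omega * L.dinv[i] * (b[i] - tmp[i]);
  }
}

// separable aggregation with per-axis weights (1/2, 1, 1/2), downsampled at
// even fine nodes
void restrict_field(const std::vector<double>& fine, int gf,
                    std::vector<double>& coarse, int gc) {
  auto wsum = [&](const std::vector<double>& v, R_xlen_t i, R_xlen_t stride,
                  int pos, int gmax) {
    double s = v[i];
    if (pos > 0) s += 0.5 * v[i - stride];
    if (pos < gmax - 1) s += 0.5 * v[i + stride];
    return s;
  };
  // pass 1: x-axis aggregate at even x
  std::vector<double> t1((R_xlen_t)gc * gf * gf);
  for (int z = 0; z < gf; ++z)
    for (int y = 0; y < gf; ++y)
      for (int X = 0; X < gc; ++X) {
        R_xlen_t i = gidx(2 * X, y, z, gf);
        t1[(R_xlen_t)X + (R_xlen_t)gc * (y + (R_xlen_t)gf * z)] =
            wsum(fine, i, 1, 2 * X, gf);
      }
  // pass 2: y-axis
  std::vector<double> t2((R_xlen_t)gc * gc * gf);
  for (int z = 0; z < gf; ++z)
    for (int Y = 0; Y < gc; ++Y)
      for (int X = 0; X < gc; ++X) {
        R_xlen_t i = (R_xlen_t)X + (R_xlen_t)gc * (2 * Y + (R_xlen_t)gf * z);
        t2[(R_xlen_t)X + (R_xlen_t)gc * (Y + (R_xlen_t)gc * z)] =
            wsum(t1, i, gc, 2 * Y, gf);
      }
  // pass 3: z-axis
  for (int Z = 0; Z < gc; ++Z)
    for (int Y = 0; Y < gc; ++Y)
      for (int X = 0; X < gc; ++X) {
        R_xlen_t i = (R_xlen_t)X + (R_xlen_t)gc * (Y + (R_xlen_t)gc * 2 * Z);
        coarse[gidx(X, Y, Z, gc)] = wsum(t2, i, (R_xlen_t)gc * gc, 2 * Z, gf);
      }
}

// transpose of restrict_field: trilinear interpolation, accumulated into fine
void prolong_add(const std::vector<double>& coarse, int gc,
                 std::vector<double>& fine, int gf) {
  for (int z = 0; z < gf; ++z) {
    int Z0 = z / 2;
    bool zodd = z & 1;
    for (int y = 0; y < gf; ++y) {
      int Y0 = y / 2;
      bool yodd = y & 1;
      for (int x = 0; x < gf; ++x) {
        int X0 = x / 2;
        bool xodd = x & 1;
        double acc = 0.0;
        for (int dz = 0; dz <= (zodd ? 1 : 0); ++dz) {
          int Z = Z0 + dz;
          if (Z >= gc) continue;
          double wz = zodd ? 0.5 : 1.0;
          for (int dy = 0; dy <= (yodd ? 1 : 0); ++dy) {
            int Y = Y0 + dy;
            if (Y >= gc) continue;
            double wy = yodd ? 0.5 : 1.0;
            for (int dx = 0; dx <= (xodd ? 1 : 0); ++dx) {
              int X = X0 + dx;
              if (X >= gc) continue;
              double wx = xodd ? 0.5 : 1.0;
              acc += wz * wy * wx * coarse[gidx(X, Y, Z, gc)];
            }
          }
        }
        fine[gidx(x, y, z, gf)] += acc;
      }
    }
  }
}

void build_dinv(MgLevel& L) {
  const int g = L.g;
  const R_xlen_t n = (R_xlen_t)g * g * g;
  L.dinv.resize(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int ix = (int)(i % g), iy = (int)((i / g) % g),
        iz = (int)(i / ((R_xlen_t)g * g));
    double d = L.s * (double)((ix > 0) + (ix < g - 1) + (iy > 0) +
                              (iy < g - 1) + (iz > 0) + (iz < g - 1));
    if (!L.dw.empty()) d += L.dw[i];
    if (d <= 0) d = 1.0;
    L.dinv[i] = 1.0 / d;
  }
}

void vcycle(std::vector<MgLevel>& levels, size_t l,
            std::vector<std::vector<double>>& tmps) {
  MgLevel& L = levels[l];
  const R_xlen_t n = (R_xlen_t)L.g * L.g * L.g;
  std::fill(L.x.begin(), L.x.end(), 0.0);
  const double omega = 2.0 / 3.0;
  if (l == levels.size() - 1) {
    for (int s = 0; s < 80; ++s) jacobi_sweep(L, L.b, L.x, tmps[l], omega);
    return;
  }
  for (int s = 0; s < 2; ++s) jacobi_sweep(L, L.b, L.x, tmps[l], omega);
  level_apply_scaled(L, L.x, L.r);
  for (R_xlen_t i = 0; i < n; ++i) L.r[i] = L.b[i] - L.r[i];
  MgLevel& C = levels[l + 1];
  restrict_field(L.r, L.g, C.b, C.g);
  vcycle(levels, l + 1, tmps);
  prolong_add(C.x, C.g, L.x, L.g);
  for (int s = 0; s < 2; ++s) jacobi_sweep(L, L.b, L.x, tmps[l], omega);
}

}  // namespace

// Multigrid-preconditioned conjugate gradients for
// (L + alpha*diag(W)) chi = b.
// [[Rcpp::export]]
List mg_pcg_solve_cpp(NumericVector b, Nullable<NumericVector> W_,
                      double alpha, int g, double tol, int maxit) {
  const R_xlen_t g3 = (R_xlen_t)g * g * g;
  // build hierarchy
  std::vector<MgLevel> levels;
  {
    MgLevel L0;
    L0.g = g;
    L0.s = 1.0;
    if (W_.isNotNull()) {
      NumericVector Wv = W_.get();
      L0.dw.resize(g3);
      for (R_xlen_t i = 0; i < g3; ++i) L0.dw[i] = alpha * Wv[i];
    }
    levels.push_back(std::move(L0));
    while (levels.back().g >= 8 && levels.back().g % 2 == 0) {
      MgLevel C;
      C.g = levels.back().g / 2;
      C.s = 2.0 * levels.back().s;
      if (!levels.back().dw.empty()) {
        C.dw.assign((R_xlen_t)C.g * C.g * C.g, 0.0);
        restrict_field(levels.back().dw, levels.back().g, C.dw, C.g);
      }
      levels.push_back(std::move(C));
    }
    for (auto& L : levels) {
      R_xlen_t n = (R_xlen_t)L.g * L.g * L.g;
      L.x.assign(n, 0.0);
      L.b.assign(n, 0.0);
      L.r.assign(n, 0.0);
      build_dinv(L);
    }
  }
  std::vector<std::vector<double>> tmps(levels.size());
  for (size_t l = 0; l < levels.size(); ++l) {
    tmps[l].assign((R_xlen_t)levels[l].g * levels[l].g * levels[l].g, 0.0);
  }
  const bool singular = levels[0].dw.empty();

  std::vector<double> x(g3, 0.0), r(g3), p(g3), Ap(g3), z(g3);
  double bnorm = 0.0;
  for (R_xlen_t i = 0; i < g3; ++i) {
    r[i] = b[i];
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["x"] = NumericVector(g3), _["iterations"] = 0,
                        _["relres"] = 0.0);
  }
  auto precond = [&](const std::vector<double>& rin, std::vector<double>& zout) {
    std::copy(rin.begin(), rin.end(), levels[0].b.begin());
    vcycle(levels, 0, tmps);
    std::copy(levels[0].x.begin(), levels[0].x.end(), zout.begin());
    if (singular) {
      double m = 0.0;
      for (R_xlen_t i = 0; i < g3; ++i) m += zout[i];
      m /= (double)g3;
      for (R_xlen_t i = 0; i < g3; ++i) zout[i] -= m;
    }
  };
  precond(r, z);
  std::copy(z.begin(), z.end(), p.begin());
  double rz = dot_vec(r, z);
  double relres = 1.0;
  int it = 0;
  for (; it < maxit; ++it) {
    level_apply_scaled(levels[0], p, Ap);
    double pAp = dot_vec(p, Ap);
    if (pAp <= 0) break;
    double a = rz / pAp;
    double rn2 = 0.0;
    for (R_xlen_t i = 0; i < g3; ++i) {
      x[i] += a * p[i];
      r[i] -= a * Ap[i];
      rn2 += r[i] * r[i];
    }
    relres = std::sqrt(rn2) / bnorm;
    if (relres <= tol) {
      ++it;
      break;
    }
    precond(r, z);
    double rz_new = dot_vec(r, z);
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t i = 0; i < g3; ++i) p[i] = z[i] + beta * p[i];
    Rcpp::checkUserInterrupt();
  }
  NumericVector xr(g3);
  for (R_xlen_t i = 0; i < g3; ++i) xr[i] = x[i];
  return List::create(_["x"] = xr, _["iterations"] = it,
                      _["relres"] = relres);
}
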