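// Voxel-grid kernels for the coupled electro-thermal weld simulator.
//
// Discretisation: conservative finite volumes on a regular grid with
// harmonic-mean face conductivities across material interfaces.  The
// electric potential is quasi-static (div(sigma grad V) = 0) with the
// electrodes acting as Dirichlet plates; the temperature advances by a
// backward-Euler step with property lagging.  Both linear systems are
// SPD and solved by SSOR-preconditioned conjugate gradients on a
// structured 7-point stencil (padded arrays, branch-free sweeps).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// region labels (must match R side)
static const int AIR = 0, TISSUE = 1, UPPER = 2, LOWER = 3;

struct Grid {
  int nx, ny, nz;
  double dx, dy, dz;
  int n() const { return nx * ny * nz; }
  int nxy() const { return nx * ny; }
  int idx(int i, int j, int k) const { return i + nx * (j + (long)ny * k); }
};

static inline double harm(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

// ---------------------------------------------------------------------------
// Structured 7-point SPD system.  All arrays are padded by nxy ghost cells
// on both ends (index with +pad) so stencil reads never leave the buffer;
// couplings to ghost or non-unknown cells are zero.  Non-unknown cells are
// identity rows (diag 1, b = imposed value) and never change during CG.
struct Stencil {
  int nx, ny, nz, n, pad;
  std::vector<double> gx, gy, gz;   // face couplings (cell i <-> i+stride)
  std::vector<double> diag, b;
  std::vector<char> unknown;
  std::vector<double> x, r, z, p, Ap, u;  // CG workspace (padded)
  // contiguous active spans (one per grid row that holds active cells),
  // unpadded cell indices [lo, hi]; rows are in increasing-index order
  std::vector<int> seg_lo, seg_hi;
  void alloc(const Grid& G) {
    nx = G.nx; ny = G.ny; nz = G.nz; n = G.n(); pad = G.nxy();
    size_t tot = (size_t)n + 2 * pad;
    gx.assign(tot, 0.0); gy.assign(tot, 0.0); gz.assign(tot, 0.0);
    diag.assign(tot, 1.0); b.assign(tot, 0.0);
    unknown.assign(tot, 0);
    x.assign(tot, 0.0); r.assign(tot, 0.0); z.assign(tot, 0.0);
    p.assign(tot, 0.0); Ap.assign(tot, 0.0); u.assign(tot, 0.0);
  }
  void set_segments(const Grid& G, const int* label) {
    seg_lo.clear(); seg_hi.clear();
    for (int k = 0; k < G.nz; ++k)
      for (int j = 0; j < G.ny; ++j) {
        int lo = -1, hi = -1;
        for (int i = 0; i < G.nx; ++i)
          if (label[G.idx(i, j, k)] != AIR) {
            if (lo < 0) lo = i;
            hi = i;
          }
        if (lo >= 0) {
          seg_lo.push_back(G.idx(lo, j, k));
          seg_hi.push_back(G.idx(hi, j, k));
        }
      }
  }
  void reset() {
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    std::fill(gz.begin(), gz.end(), 0.0);
    std::fill(diag.begin(), diag.end(), 1.0);
    std::fill(b.begin(), b.end(), 0.0);
    std::fill(unknown.begin(), unknown.end(), 0);
  }
};

#define SEG_LOOP(S, body)                                        \
  for (size_t s_ = 0; s_ < (S).seg_lo.size(); ++s_)              \
    for (int i = (S).seg_lo[s_]; i <= (S).seg_hi[s_]; ++i) { body }

// y = A x restricted to active rows; returns dot(w, y) fused
static double st_matvec_dot(Stencil& S, const std::vector<double>& xv,
                            std::vector<double>& yv,
                            const std::vector<double>& wv) {
  const int pad = S.pad, sx = 1, sy = S.nx, sz = S.pad;
  const double *gx = S.gx.data() + pad, *gy = S.gy.data() + pad,
               *gz = S.gz.data() + pad, *d = S.diag.data() + pad;
  const double* xp = xv.data() + pad;
  const double* wp = wv.data() + pad;
  double* yp = yv.data() + pad;
  double acc = 0.0;
  SEG_LOOP(S, {
    double v = d[i] * xp[i]
        - gx[i] * xp[i + sx] - gx[i - sx] * xp[i - sx]
        - gy[i] * xp[i + sy] - gy[i - sy] * xp[i - sy]
        - gz[i] * xp[i + sz] - gz[i - sz] * xp[i - sz];
    yp[i] = v;
    acc += wp[i] * v;
  })
  return acc;
}

// z = (D+U)^-1 D (D+L)^-1 r (symmetric Gauss-Seidel); returns dot(r, z)
static double st_ssor_dot(Stencil& S, const std::vector<double>& rv,
                          std::vector<double>& zv, std::vector<double>& uv) {
  const int pad = S.pad, sx = 1, sy = S.nx, sz = S.pad;
  const double *gx = S.gx.data() + pad, *gy = S.gy.data() + pad,
               *gz = S.gz.data() + pad, *d = S.diag.data() + pad;
  const double* rp = rv.data() + pad;
  double* up = uv.data() + pad;
  double* zp = zv.data() + pad;
  SEG_LOOP(S, {
    up[i] = (rp[i] + gx[i - sx] * up[i - sx] + gy[i - sy] * up[i - sy] +
             gz[i - sz] * up[i - sz]) / d[i];
  })
  double acc = 0.0;
  for (size_t s_ = S.seg_lo.size(); s_-- > 0;)
    for (int i = S.seg_hi[s_]; i >= S.seg_lo[s_]; --i) {
      zp[i] = (up[i] * d[i] + gx[i] * zp[i + sx] + gy[i] * zp[i + sy] +
               gz[i] * zp[i + sz]) / d[i];
      acc += rp[i] * zp[i];
    }
  return acc;
}

// SSOR-preconditioned CG; x must hold imposed values on non-unknown rows.
static int st_cg(Stencil& S, double tol, int maxit, double* rel) {
  const int pad = S.pad;
  double* x = S.x.data() + pad;
  const double* b = S.b.data() + pad;
  const char* unk = S.unknown.data() + pad;
  SEG_LOOP(S, { if (!unk[i]) x[i] = b[i]; })
  double bnorm = 0.0;
  SEG_LOOP(S, { if (unk[i]) bnorm += b[i] * b[i]; })
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    SEG_LOOP(S, { if (unk[i]) x[i] = 0.0; })
    *rel = 0.0;
    return 0;
  }
  st_matvec_dot(S, S.x, S.Ap, S.x);
  double* r = S.r.data() + pad;
  const double* Ap = S.Ap.data() + pad;
  double rnorm = 0.0;
  SEG_LOOP(S, { r[i] = b[i] - Ap[i]; rnorm += r[i] * r[i]; })
  // identity rows are consistent by construction: r = 0 there
  double rz = st_ssor_dot(S, S.r, S.z, S.u);
  double* z = S.z.data() + pad;
  double* pv = S.p.data() + pad;
  SEG_LOOP(S, { pv[i] = z[i]; })
  rnorm = std::sqrt(rnorm);
  int it = 0;
  while (rnorm > tol * bnorm && it < maxit) {
    double pAp = st_matvec_dot(S, S.p, S.Ap, S.p);
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    rnorm = 0.0;
    SEG_LOOP(S, {
      x[i] += alpha * pv[i];
      r[i] -= alpha * Ap[i];
      rnorm += r[i] * r[i];
    })
    rnorm = std::sqrt(rnorm);
    double rz_new = st_ssor_dot(S, S.r, S.z, S.u);
    double beta = rz_new / rz;
    rz = rz_new;
    SEG_LOOP(S, { pv[i] = z[i] + beta * pv[i]; })
    ++it;
  }
  *rel = rnorm / bnorm;
  return it;
}

static void face_geom(const Grid& G, double A[3], double d[3]) {
  A[0] = G.dy * G.dz; A[1] = G.dx * G.dz; A[2] = G.dx * G.dy;
  d[0] = G.dx; d[1] = G.dy; d[2] = G.dz;
}

// ---------------------------------------------------------------------------
// Electric potential: unknowns = tissue cells with sigma > 0; Dirichlet on
// electrode cells (upper = v_applied, lower = 0); air faces insulating.
static void build_potential(const Grid& G, const double* sigma,
                            const int* label, double v_applied, Stencil& S) {
  S.reset();
  double A[3], d[3];
  face_geom(G, A, d);
  const int pad = S.pad;
  auto conducting = [&](int c) { return label[c] != AIR && sigma[c] > 0.0; };
  for (int k = 0; k < G.nz; ++k)
    for (int j = 0; j < G.ny; ++j)
      for (int i = 0; i < G.nx; ++i) {
        int c = G.idx(i, j, k);
        if (label[c] == TISSUE && sigma[c] > 0.0) {
          S.unknown[pad + c] = 1;
          S.diag[pad + c] = 0.0;
        } else if (label[c] == UPPER) {
          S.b[pad + c] = v_applied;
        }
      }
  // faces: accumulate couplings / Dirichlet contributions
  const int st[3] = { 1, G.nx, G.nxy() };
  for (int k = 0; k < G.nz; ++k)
    for (int j = 0; j < G.ny; ++j)
      for (int i = 0; i < G.nx; ++i) {
        int c = G.idx(i, j, k);
        if (!conducting(c)) continue;
        const int lim[3] = { i, j, k };
        const int top[3] = { G.nx, G.ny, G.nz };
        for (int ax = 0; ax < 3; ++ax) {
          if (lim[ax] + 1 >= top[ax]) continue;
          int c2 = c + st[ax];
          if (!conducting(c2)) continue;
          double gf = A[ax] / d[ax] * harm(sigma[c], sigma[c2]);
          bool u1 = S.unknown[pad + c], u2 = S.unknown[pad + c2];
          if (u1 && u2) {
            (ax == 0 ? S.gx : ax == 1 ? S.gy : S.gz)[pad + c] = gf;
            S.diag[pad + c] += gf;
            S.diag[pad + c2] += gf;
          } else if (u1) {  // c2 is a Dirichlet electrode cell
            S.diag[pad + c] += gf;
            S.b[pad + c] += gf * S.b[pad + c2];
          } else if (u2) {
            S.diag[pad + c2] += gf;
            S.b[pad + c2] += gf * S.b[pad + c];
          }
        }
      }
  // isolated unknowns (no conducting neighbours) would leave diag = 0
  for (int c = 0; c < G.n(); ++c)
    if (S.unknown[pad + c] && S.diag[pad + c] <= 0.0) {
      S.unknown[pad + c] = 0;
      S.diag[pad + c] = 1.0;
      S.b[pad + c] = 0.0;
    }
}

// [[Rcpp::export]]
List cpp_solve_potential(IntegerVector dims, NumericVector spac,
                         NumericVector sigma, IntegerVector label,
                         double v_applied, double tol, int maxit,
                         Nullable<NumericVector> warm = R_NilValue) {
  Grid G{dims[0], dims[1], dims[2], spac[0], spac[1], spac[2]};
  Stencil S;
  S.alloc(G);
  S.set_segments(G, INTEGER(label));
  build_potential(G, REAL(sigma), INTEGER(label), v_applied, S);
  const int pad = S.pad;
  if (warm.isNotNull()) {
    NumericVector w(warm);
    if (w.size() == G.n())
      for (int c = 0; c < G.n(); ++c)
        if (S.unknown[pad + c] && R_finite(w[c])) S.x[pad + c] = w[c];
  }
  double rel = 0.0;
  int it = st_cg(S, tol, maxit, &rel);
  if (rel > tol)
    stop("potential solver did not converge (relative residual %.3e after %d iterations)",
         rel, it);
  NumericVector V(G.n());
  const int* lab = INTEGER(label);
  for (int c = 0; c < G.n(); ++c) {
    if (lab[c] == UPPER) V[c] = v_applied;
    else if (lab[c] == LOWER) V[c] = 0.0;
    else if (S.unknown[pad + c]) V[c] = S.x[pad + c];
    else V[c] = NA_REAL;
  }
  return List::create(_["V"] = V, _["iterations"] = it, _["residual"] = rel);
}

// ---------------------------------------------------------------------------
// Joule heating q = sigma |grad V|^2 in conservative face form: each face
// dissipates g (dV)^2; split between the two tissue cells, or assigned to
// the tissue cell when the other side is an electrode (Dirichlet) cell.
static void joule_core(const Grid& G, const double* sg, const int* lab,
                       const double* v, double* q, double* ptot,
                       double* isrc) {
  double A[3], d[3];
  face_geom(G, A, d);
  const double vol = G.dx * G.dy * G.dz;
  const int st[3] = { 1, G.nx, G.nxy() };
  *ptot = 0.0; *isrc = 0.0;
  std::memset(q, 0, sizeof(double) * G.n());
  for (int k = 0; k < G.nz; ++k)
    for (int j = 0; j < G.ny; ++j)
      for (int i = 0; i < G.nx; ++i) {
        int c = G.idx(i, j, k);
        if (lab[c] == AIR || sg[c] <= 0.0) continue;
        const int lim[3] = { i, j, k };
        const int top[3] = { G.nx, G.ny, G.nz };
        for (int ax = 0; ax < 3; ++ax) {
          if (lim[ax] + 1 >= top[ax]) continue;
          int c2 = c + st[ax];
          if (lab[c2] == AIR || sg[c2] <= 0.0) continue;
          double gf = A[ax] / d[ax] * harm(sg[c], sg[c2]);
          double dv = v[c] - v[c2];
          double P = gf * dv * dv;
          *ptot += P;
          bool t1 = lab[c] == TISSUE, t2 = lab[c2] == TISSUE;
          if (t1 && t2) { q[c] += 0.5 * P / vol; q[c2] += 0.5 * P / vol; }
          else if (t1) q[c] += P / vol;
          else if (t2) q[c2] += P / vol;
          if (lab[c] == UPPER && t2) *isrc += gf * (v[c] - v[c2]);
          else if (lab[c2] == UPPER && t1) *isrc += gf * (v[c2] - v[c]);
        }
      }
}

// [[Rcpp::export]]
List cpp_joule(IntegerVector dims, NumericVector spac, NumericVector sigma,
               IntegerVector label, NumericVector V, double v_applied) {
  Grid G{dims[0], dims[1], dims[2], spac[0], spac[1], spac[2]};
  NumericVector q(G.n());
  double ptot, isrc;
  joule_core(G, REAL(sigma), INTEGER(label), REAL(V), REAL(q), &ptot, &isrc);
  (void)v_applied;
  return List::create(_["q"] = q, _["total_power"] = ptot,
                      _["source_current"] = isrc);
}

// ---------------------------------------------------------------------------
// Backward-Euler heat step.  Exposed faces (air neighbour or domain
// boundary) lose heat by convection: electrode outer z-faces couple to the
// sink, everything else to ambient air.  Perfusion (if enabled) adds a
// linear sink on tissue cells, treated implicitly.
struct ThermalBC {
  double h_air, t_amb, h_sink, t_sink;
  double perf_coef, perf_tb, perf_qmet;  // coef = rho_b c_b omega_b
};

static void build_thermal(const Grid& G, const double* T, const double* q,
                          const double* kc, const double* rhoc,
                          const int* label, double dt, const ThermalBC& bc,
                          Stencil& S, std::vector<double>& hA,
                          std::vector<double>& hAenv) {
  S.reset();
  double A[3], d[3];
  face_geom(G, A, d);
  const double vol = G.dx * G.dy * G.dz;
  const int pad = S.pad;
  const int n = G.n();
  hA.assign(n, 0.0);
  hAenv.assign(n, 0.0);
  const int st[3] = { 1, G.nx, G.nxy() };
  for (int k = 0; k < G.nz; ++k)
    for (int j = 0; j < G.ny; ++j)
      for (int i = 0; i < G.nx; ++i) {
        int c = G.idx(i, j, k);
        if (label[c] == AIR) continue;
        S.unknown[pad + c] = 1;
        double cap = rhoc[c] * vol / dt;
        S.diag[pad + c] = cap;
        S.b[pad + c] = cap * T[c] + q[c] * vol;
        if (label[c] == TISSUE) {
          if (bc.perf_coef > 0.0) {
            S.diag[pad + c] += bc.perf_coef * vol;
            S.b[pad + c] += vol * (bc.perf_coef * bc.perf_tb + bc.perf_qmet);
          } else if (bc.perf_qmet != 0.0) {
            S.b[pad + c] += vol * bc.perf_qmet;
          }
        }
        // exposed faces (all 6 directions)
        const int pos[3] = { i, j, k };
        const int top[3] = { G.nx, G.ny, G.nz };
        for (int f = 0; f < 6; ++f) {
          int ax = f / 2, dir = (f % 2 == 0) ? 1 : -1;
          int pp = pos[ax] + dir;
          bool outside = pp < 0 || pp >= top[ax];
          int c2 = outside ? -1 : c + dir * st[ax];
          if (!outside && label[c2] != AIR) continue;
          double h, env;
          if ((label[c] == UPPER && ax == 2 && dir == 1) ||
              (label[c] == LOWER && ax == 2 && dir == -1)) {
            h = bc.h_sink; env = bc.t_sink;
          } else {
            h = bc.h_air; env = bc.t_amb;
          }
          if (h > 0.0) {
            double ha = h * A[ax];
            S.diag[pad + c] += ha;
            S.b[pad + c] += ha * env;
            hA[c] += ha;
            hAenv[c] += ha * env;
          }
        }
      }
  // conduction faces
  for (int k = 0; k < G.nz; ++k)
    for (int j = 0; j < G.ny; ++j)
      for (int i = 0; i < G.nx; ++i) {
        int c = G.idx(i, j, k);
        if (label[c] == AIR) continue;
        const int lim[3] = { i, j, k };
        const int top[3] = { G.nx, G.ny, G.nz };
        for (int ax = 0; ax < 3; ++ax) {
          if (lim[ax] + 1 >= top[ax]) continue;
          int c2 = c + st[ax];
          if (label[c2] == AIR) continue;
          double gf = A[ax] / d[ax] * harm(kc[c], kc[c2]);
          (ax == 0 ? S.gx : ax == 1 ? S.gy : S.gz)[pad + c] = gf;
          S.diag[pad + c] += gf;
          S.diag[pad + c2] += gf;
        }
      }
}

// [[Rcpp::export]]
List cpp_advance_temperature(IntegerVector dims, NumericVector spac,
                             NumericVector T, NumericVector q,
                             NumericVector kcell, NumericVector rhoc,
                             IntegerVector label, double dt,
                             double h_air, double t_amb,
                             double h_sink, double t_sink,
                             double perf_coef, double perf_tb,
                             double perf_qmet, double tol, int maxit) {
  Grid G{dims[0], dims[1], dims[2], spac[0], spac[1], spac[2]};
  ThermalBC bc{h_air, t_amb, h_sink, t_sink, perf_coef, perf_tb, perf_qmet};
  Stencil S;
  S.alloc(G);
  S.set_segments(G, INTEGER(label));
  std::vector<double> hA, hAenv;
  // treat NA temperatures on air cells as zero internally
  std::vector<double> Tin(G.n(), 0.0);
  const int* lab = INTEGER(label);
  for (int c = 0; c < G.n(); ++c)
    if (lab[c] != AIR) {
      if (!R_finite(T[c]))
        stop("non-finite temperature entering the step (dt = %g)", dt);
      Tin[c] = T[c];
    }
  build_thermal(G, Tin.data(), REAL(q), REAL(kcell), REAL(rhoc), lab, dt,
                bc, S, hA, hAenv);
  for (int c = 0; c < G.n(); ++c)
    if (S.unknown[S.pad + c]) S.x[S.pad + c] = Tin[c];
  double rel = 0.0;
  int it = st_cg(S, tol, maxit, &rel);
  if (rel > tol)
    stop("thermal step did not converge (dt = %g, relative residual %.3e)",
         dt, rel);
  NumericVector Tn(G.n(), NA_REAL);
  double loss = 0.0;
  for (int c = 0; c < G.n(); ++c)
    if (lab[c] != AIR) {
      double v = S.x[S.pad + c];
      if (!R_finite(v))
        stop("thermal step produced a non-finite temperature (dt = %g)", dt);
      Tn[c] = v;
      loss += hA[c] * v - hAenv[c];
    }
  return List::create(_["T"] = Tn, _["iterations"] = it, _["residual"] = rel,
                      _["boundary_loss_power"] = loss);
}

// ---------------------------------------------------------------------------
// Full coupled run.  mat: 7 x 3 matrix of region parameters, columns
// tissue/upper/lower, rows rho_c, k0, k_coef, sigma0, sigma_frac, Tref,
// tdep(0/1).
// [[Rcpp::export]]
List cpp_run_simulation(IntegerVector dims, NumericVector spac,
                        IntegerVector label, NumericMatrix mat,
                        NumericVector T0, double v_eff, double dt,
                        double t_end, NumericVector checkpoint_times,
                        double h_air, double t_amb, double h_sink,
                        double t_sink, double perf_coef, double perf_tb,
                        double perf_qmet, double tol, int maxit,
                        IntegerVector central, double stop_when_above = -1.0) {
  Grid G{dims[0], dims[1], dims[2], spac[0], spac[1], spac[2]};
  const int n = G.n();
  const int* lab = INTEGER(label);
  ThermalBC bc{h_air, t_amb, h_sink, t_sink, perf_coef, perf_tb, perf_qmet};
  int nsteps = (int)std::lround(t_end / dt);
  if (nsteps < 1) stop("end time shorter than one time step");

  std::vector<double> T(n, 0.0), kc(n, 0.0), sg(n, 0.0), qv(n, 0.0),
      Vf(n, NA_REAL), rhoc(n, 0.0);
  double matloc[21];
  for (int r = 0; r < 3; ++r)
    for (int s = 0; s < 7; ++s) matloc[7 * r + s] = mat(s, r);
  for (int c = 0; c < n; ++c)
    if (lab[c] != AIR) {
      T[c] = T0[c];
      rhoc[c] = matloc[7 * (lab[c] - 1)];
    }

  std::vector<int> tissue_cells;
  for (int c = 0; c < n; ++c)
    if (lab[c] == TISSUE) tissue_cells.push_back(c);
  std::vector<int> central_cells(central.begin(), central.end());

  NumericVector times(nsteps + 1), tmax(nsteps + 1), cmax(nsteps + 1),
      cmean(nsteps + 1);
  std::vector<int> cp_step;
  for (int s = 0; s < checkpoint_times.size(); ++s) {
    int stp = (int)std::lround(checkpoint_times[s] / dt);
    if (stp >= 0 && stp <= nsteps) cp_step.push_back(stp);
  }

  auto tissue_max = [&](const std::vector<double>& Tv) {
    double m = R_NegInf;
    for (size_t s = 0; s < tissue_cells.size(); ++s)
      if (Tv[tissue_cells[s]] > m) m = Tv[tissue_cells[s]];
    return m;
  };
  auto central_stats = [&](const std::vector<double>& Tv, double* mx,
                           double* mn) {
    if (central_cells.empty()) { *mx = NA_REAL; *mn = NA_REAL; return; }
    double m = R_NegInf, acc = 0.0;
    for (size_t s = 0; s < central_cells.size(); ++s) {
      double v = Tv[central_cells[s]];
      if (v > m) m = v;
      acc += v;
    }
    *mx = m;
    *mn = acc / (double)central_cells.size();
  };
  auto snapshot = [&]() {
    NumericVector snap(n);
    for (int c = 0; c < n; ++c) snap[c] = lab[c] == AIR ? NA_REAL : T[c];
    return snap;
  };

  times[0] = 0.0;
  tmax[0] = tissue_max(T);
  central_stats(T, &cmax[0], &cmean[0]);
  std::vector<std::pair<int, NumericVector> > stored;
  for (size_t s = 0; s < cp_step.size(); ++s)
    if (cp_step[s] == 0) stored.push_back(std::make_pair(0, snapshot()));

  Stencil SP, ST;
  SP.alloc(G);
  SP.set_segments(G, lab);
  ST.alloc(G);
  ST.set_segments(G, lab);
  std::vector<double> hA, hAenv;
  long pot_iters = 0, temp_iters = 0;
  double joule_energy = 0.0, loss_energy = 0.0;
  int last_step = nsteps;
  bool have_warm = false;

  for (int step = 1; step <= nsteps; ++step) {
    // material laws at lagged temperature
    for (int c = 0; c < n; ++c) {
      if (lab[c] == AIR) continue;
      int r = lab[c] - 1;
      double Tc = T[c];
      if (!R_finite(Tc)) stop("non-finite temperature entering step %d", step);
      bool tdep = matloc[7 * r + 6] != 0.0;
      double kk = tdep ? matloc[7 * r + 1] + matloc[7 * r + 2] *
                             (Tc - matloc[7 * r + 5])
                       : matloc[7 * r + 1];
      double ss = tdep ? matloc[7 * r + 3] *
                             (1.0 + matloc[7 * r + 4] * (Tc - matloc[7 * r + 5]))
                       : matloc[7 * r + 3];
      if (kk <= 0.0)
        stop("degenerate thermal conductivity (%.4g) at T = %.2f", kk, Tc);
      if (ss < 0.0)
        stop("degenerate electrical conductivity (%.4g) at T = %.2f", ss, Tc);
      kc[c] = kk;
      sg[c] = ss;
    }
    // potential + Joule source
    double ptot = 0.0;
    if (v_eff > 0.0) {
      std::vector<double> warm_save;
      if (have_warm) warm_save = SP.x;  // keep previous solution across reset
      build_potential(G, sg.data(), lab, v_eff, SP);
      if (have_warm) SP.x = warm_save;
      double rel = 0.0;
      int it = st_cg(SP, tol, maxit, &rel);
      if (rel > tol)
        stop("potential solver did not converge at t = %g", step * dt);
      pot_iters += it;
      have_warm = true;
      for (int c = 0; c < n; ++c) {
        if (lab[c] == UPPER) Vf[c] = v_eff;
        else if (lab[c] == LOWER) Vf[c] = 0.0;
        else if (SP.unknown[SP.pad + c]) Vf[c] = SP.x[SP.pad + c];
        else Vf[c] = 0.0;
      }
      double isrc = 0.0;
      joule_core(G, sg.data(), lab, Vf.data(), qv.data(), &ptot, &isrc);
    } else {
      std::fill(qv.begin(), qv.end(), 0.0);
    }
    // implicit heat step
    build_thermal(G, T.data(), qv.data(), kc.data(), rhoc.data(), lab, dt,
                  bc, ST, hA, hAenv);
    for (int c = 0; c < n; ++c)
      if (ST.unknown[ST.pad + c]) ST.x[ST.pad + c] = T[c];
    double rel = 0.0;
    int it = st_cg(ST, tol, maxit, &rel);
    if (rel > tol)
      stop("thermal step did not converge at t = %g (dt = %g)", step * dt, dt);
    temp_iters += it;
    double loss = 0.0;
    for (int c = 0; c < n; ++c)
      if (lab[c] != AIR) {
        double v = ST.x[ST.pad + c];
        if (!R_finite(v))
          stop("non-finite temperature at t = %g (dt = %g)", step * dt, dt);
        T[c] = v;
        loss += hA[c] * v - hAenv[c];
      }
    joule_energy += ptot * dt;
    loss_energy += loss * dt;
    times[step] = step * dt;
    tmax[step] = tissue_max(T);
    central_stats(T, &cmax[step], &cmean[step]);
    for (size_t s = 0; s < cp_step.size(); ++s)
      if (cp_step[s] == step)
        stored.push_back(std::make_pair(step, snapshot()));
    if (stop_when_above > 0.0 && tmax[step] >= stop_when_above) {
      last_step = step;
      break;
    }
  }

  int nrec = last_step + 1;
  NumericVector times_out(nrec), tmax_out(nrec), cmax_out(nrec),
      cmean_out(nrec);
  for (int s = 0; s < nrec; ++s) {
    times_out[s] = times[s]; tmax_out[s] = tmax[s];
    cmax_out[s] = cmax[s]; cmean_out[s] = cmean[s];
  }
  List cp_list(stored.size());
  NumericVector cp_t(stored.size());
  for (size_t s = 0; s < stored.size(); ++s) {
    cp_t[s] = stored[s].first * dt;
    cp_list[s] = stored[s].second;
  }
  NumericVector Tfinal(n, NA_REAL), Vfinal(n, NA_REAL);
  for (int c = 0; c < n; ++c) {
    if (lab[c] != AIR) Tfinal[c] = T[c];
    Vfinal[c] = Vf[c];
  }
  return List::create(
      _["time"] = times_out, _["tissue_max"] = tmax_out,
      _["central_max"] = cmax_out, _["central_mean"] = cmean_out,
      _["checkpoint_times"] = cp_t, _["checkpoints"] = cp_list,
      _["T_final"] = Tfinal, _["V_final"] = Vfinal,
      _["potential_iterations"] = (double)pot_iters,
      _["thermal_iterations"] = (double)temp_iters,
      _["joule_energy"] = joule_energy, _["loss_energy"] = loss_energy,
      _["completed_steps"] = last_step);
}
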