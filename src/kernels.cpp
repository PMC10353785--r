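// Compiled cores of the simulator: Morton keys and voxel ranges, the 27-voxel
// force gather, LOD diffusion-decay sweeps with cached Thomas factorizations,
// the implicit supply/uptake update, and the per-cell phase / volume steps.
// Stochastic kernels draw from R's RNG so a single seed fixes the whole run.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- Morton keys

// Bit b of i lands at position 3b, of j at 3b+1, of k at 3b+2.
// Keys are returned as doubles; 17 bits per axis keeps them exact (< 2^51).
// [[Rcpp::export]]
NumericVector morton_encode_cpp(IntegerVector i, IntegerVector j,
                                IntegerVector k) {
  const int n = i.size();
  if (j.size() != n || k.size() != n)
    stop("index vectors must have equal length");
  NumericVector key(n);
  const int max_index = 1 << 17;
  for (int c = 0; c < n; ++c) {
    int ii = i[c], jj = j[c], kk = k[c];
    if (ii == NA_INTEGER || jj == NA_INTEGER || kk == NA_INTEGER)
      stop("voxel index is NA");
    if (ii < 0 || jj < 0 || kk < 0)
      stop("voxel index out of domain (negative)");
    if (ii >= max_index || jj >= max_index || kk >= max_index)
      stop("voxel index exceeds 17 bits per axis");
    uint64_t key64 = 0;
    for (int b = 0; b < 17; ++b) {
      key64 |= ((uint64_t)((ii >> b) & 1)) << (3 * b);
      key64 |= ((uint64_t)((jj >> b) & 1)) << (3 * b + 1);
      key64 |= ((uint64_t)((kk >> b) & 1)) << (3 * b + 2);
    }
    key[c] = (double)key64;
  }
  return key;
}

// Contiguous index range per linear voxel id. `vox` must be grouped (cells of
// one voxel adjacent), which Morton-sorting guarantees. 0-based half-open.
// [[Rcpp::export]]
List voxel_ranges_cpp(IntegerVector vox, int nvox) {
  const int n = vox.size();
  IntegerVector start(nvox, 0), end(nvox, 0);
  int c = 0;
  while (c < n) {
    const int v = vox[c];
    if (v < 0 || v >= nvox) stop("voxel id out of range");
    int c2 = c;
    while (c2 < n && vox[c2] == v) ++c2;
    start[v] = c;
    end[v] = c2;
    c = c2;
  }
  return List::create(_["start"] = start, _["end"] = end);
}

// ------------------------------------------------------------------ mechanics

// Total short-range force on every cell: adhesion Ccca*(1-d/RA)^2 toward the
// neighbour, repulsion Cccr*(1-d/RR)^2 away, summed over the 27-voxel
// neighbourhood (clipped at domain faces), plus the per-cell motile force.
// Requires the population sorted by Morton key with voxel ranges current.
// [[Rcpp::export]]
NumericMatrix aggregate_forces_cpp(NumericMatrix pos, NumericVector radius,
                                   IntegerVector vi, IntegerVector vj,
                                   IntegerVector vk, IntegerVector start,
                                   IntegerVector end, int nx, int ny, int nz,
                                   double ccr, double cca, double adh_factor,
                                   NumericMatrix fmot) {
  const int n = pos.nrow();
  NumericMatrix F(n, 3);
  int n_coincident = 0;
  for (int c = 0; c < n; ++c) {
    const double xi = pos(c, 0), yi = pos(c, 1), zi = pos(c, 2);
    const double Ri = radius[c];
    double fx = fmot(c, 0), fy = fmot(c, 1), fz = fmot(c, 2);
    for (int di = -1; di <= 1; ++di) {
      const int ii = vi[c] + di;
      if (ii < 0 || ii >= nx) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        const int jj = vj[c] + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int dk = -1; dk <= 1; ++dk) {
          const int kk = vk[c] + dk;
          if (kk < 0 || kk >= nz) continue;
          const int v = ii + nx * (jj + ny * kk);
          for (int o = start[v]; o < end[v]; ++o) {
            if (o == c) continue;
            const double rx = pos(o, 0) - xi;
            const double ry = pos(o, 1) - yi;
            const double rz = pos(o, 2) - zi;
            const double d2 = rx * rx + ry * ry + rz * rz;
            const double RR = Ri + radius[o];
            const double RA = adh_factor * RR;
            if (d2 > RA * RA) continue;
            const double d = std::sqrt(d2);
            if (d == 0.0) {
              // coincident centers: deterministic fallback axis, the
              // lower-index cell is pushed toward -x, the other toward +x
              fx += (c < o) ? -ccr : ccr;
              ++n_coincident;
              continue;
            }
            double m = 0.0;
            {
              const double t = 1.0 - d / RA;
              m += cca * t * t;
            }
            if (d <= RR) {
              const double t = 1.0 - d / RR;
              m -= ccr * t * t;
            }
            const double inv = m / d;
            fx += inv * rx;
            fy += inv * ry;
            fz += inv * rz;
          }
        }
      }
    }
    F(c, 0) = fx;
    F(c, 1) = fy;
    F(c, 2) = fz;
  }
  if (n_coincident > 0)
    warning("%d coincident cell-center pair evaluations; fallback axis "
            "repulsion applied", n_coincident);
  return F;
}

// ------------------------------------------------------------- tridiag / LOD

// General Thomas solve; sub/super have length n-1.
// [[Rcpp::export]]
NumericVector thomas_solve_cpp(NumericVector sub, NumericVector diag,
                               NumericVector super, NumericVector rhs) {
  const int n = diag.size();
  if (n < 1) stop("empty system");
  if (sub.size() != n - 1 || super.size() != n - 1 || rhs.size() != n)
    stop("inconsistent tridiagonal system dimensions");
  std::vector<double> cp(n), dp(n);
  double beta = diag[0];
  if (beta == 0.0) stop("zero pivot in Thomas algorithm");
  cp[0] = (n > 1) ? super[0] / beta : 0.0;
  dp[0] = rhs[0] / beta;
  for (int i = 1; i < n; ++i) {
    beta = diag[i] - sub[i - 1] * cp[i - 1];
    if (beta == 0.0) stop("zero pivot in Thomas algorithm");
    cp[i] = (i < n - 1) ? super[i] / beta : 0.0;
    dp[i] = (rhs[i] - sub[i - 1] * dp[i - 1]) / beta;
  }
  NumericVector x(n);
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}

// One implicit 1-D diffusion-decay solve along an axis for every strip.
// Zero-flux closure: end rows carry a single flux term (none for n == 1).
// The factorization is identical for all strips and cached once. For the y
// and z axes the elimination runs across whole contiguous lines/planes so
// memory access stays sequential.
static void lod_factor(int n, double q, double lam_term, std::vector<double> &beta,
                       std::vector<double> &cp) {
  const double off = -q;
  beta.resize(n);
  cp.resize(n);
  for (int i = 0; i < n; ++i) {
    double d;
    if (n == 1)
      d = 1.0 + lam_term;
    else if (i == 0 || i == n - 1)
      d = 1.0 + lam_term + q;
    else
      d = 1.0 + lam_term + 2.0 * q;
    beta[i] = (i == 0) ? d : d - off * cp[i - 1];
    cp[i] = (i < n - 1) ? off / beta[i] : 0.0;
  }
}

static void lod_sweep(std::vector<double> &rho, int nx, int ny, int nz,
                      int axis, double q, double lam_term) {
  const int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const double off = -q;
  std::vector<double> beta, cp;
  lod_factor(n, q, lam_term, beta, cp);
  std::vector<double> ibeta(n);
  for (int i = 0; i < n; ++i) ibeta[i] = 1.0 / beta[i];
  if (axis == 0) {
    std::vector<double> dp(n);
    const long nstrip = (long)ny * nz;
    for (long s = 0; s < nstrip; ++s) {
      double *r = &rho[s * nx];
      dp[0] = r[0] * ibeta[0];
      for (int i = 1; i < n; ++i)
        dp[i] = (r[i] - off * dp[i - 1]) * ibeta[i];
      r[n - 1] = dp[n - 1];
      for (int i = n - 2; i >= 0; --i) r[i] = dp[i] - cp[i] * r[i + 1];
    }
  } else if (axis == 1) {
    // per z-plane, eliminate across rows of length nx (contiguous)
    for (int k = 0; k < nz; ++k) {
      double *p = &rho[(long)k * nx * ny];
      double *r0 = p;
      for (int i = 0; i < nx; ++i) r0[i] *= ibeta[0];
      for (int j = 1; j < n; ++j) {
        double *r = p + (long)j * nx;
        const double *rp = r - nx;
        const double ib = ibeta[j];
        for (int i = 0; i < nx; ++i) r[i] = (r[i] - off * rp[i]) * ib;
      }
      for (int j = n - 2; j >= 0; --j) {
        double *r = p + (long)j * nx;
        const double *rn = r + nx;
        const double c = cp[j];
        for (int i = 0; i < nx; ++i) r[i] -= c * rn[i];
      }
    }
  } else {
    // eliminate across whole xy planes (contiguous)
    const long np = (long)nx * ny;
    double *p0 = &rho[0];
    for (long i = 0; i < np; ++i) p0[i] *= ibeta[0];
    for (int k = 1; k < n; ++k) {
      double *p = &rho[(long)k * np];
      const double *pp = p - np;
      const double ib = ibeta[k];
      for (long i = 0; i < np; ++i) p[i] = (p[i] - off * pp[i]) * ib;
    }
    for (int k = n - 2; k >= 0; --k) {
      double *p = &rho[(long)k * np];
      const double *pn = p + np;
      const double c = cp[k];
      for (long i = 0; i < np; ++i) p[i] -= c * pn[i];
    }
  }
}

static void repin(std::vector<double> &rho, IntegerVector pinned,
                  NumericVector pinned_val) {
  const int m = pinned.size();
  for (int p = 0; p < m; ++p) rho[pinned[p]] = pinned_val[p];
}

// Full LOD step: sweeps x, then y, then z (reversed if `reverse`); decay is
// distributed as lambda/3 per sweep; Dirichlet voxels re-pinned after every
// sweep. `pinned` holds 0-based linear voxel ids.
// [[Rcpp::export]]
NumericVector lod_step_cpp(NumericVector rho_in, int nx, int ny, int nz,
                           double D, double lam, double dt, double dx,
                           IntegerVector pinned, NumericVector pinned_val,
                           bool reverse = false) {
  const long nvox = (long)nx * ny * nz;
  if (rho_in.size() != nvox) stop("rho length does not match grid");
  std::vector<double> rho(rho_in.begin(), rho_in.end());
  const double q = dt * D / (dx * dx);
  const double lam_term = dt * lam / 3.0;
  repin(rho, pinned, pinned_val);
  for (int s = 0; s < 3; ++s) {
    const int axis = reverse ? 2 - s : s;
    lod_sweep(rho, nx, ny, nz, axis, q, lam_term);
    repin(rho, pinned, pinned_val);
  }
  NumericVector out(rho.begin(), rho.end());
  return out;
}

// Implicit supply/uptake update: rho <- (rho + dt*S*rho_star)/(1 + dt*(S+U)).
// S may have length 1 (uniform) or nvox.
// [[Rcpp::export]]
NumericVector supply_uptake_cpp(NumericVector rho_in, NumericVector U,
                                NumericVector S, double rho_star, double dt,
                                IntegerVector pinned,
                                NumericVector pinned_val) {
  const long nvox = rho_in.size();
  if (U.size() != nvox) stop("U length does not match rho");
  const bool s_uniform = (S.size() == 1);
  if (!s_uniform && S.size() != nvox) stop("S length does not match rho");
  NumericVector rho = clone(rho_in);
  for (long v = 0; v < nvox; ++v) {
    const double s = s_uniform ? S[0] : S[v];
    rho[v] = (rho[v] + dt * s * rho_star) / (1.0 + dt * (s + U[v]));
  }
  const int m = pinned.size();
  for (int p = 0; p < m; ++p) rho[pinned[p]] = pinned_val[p];
  return rho;
}

// Per-voxel uptake map: U_v = sum over living cells in v of (V_cell/V_voxel)*Uo.
// [[Rcpp::export]]
NumericVector compute_uptake_cpp(IntegerVector vox, NumericVector V,
                                 LogicalVector living, int nvox, double Vvox,
                                 double Uo) {
  NumericVector U(nvox, 0.0);
  const int n = vox.size();
  const double f = Uo / Vvox;
  for (int c = 0; c < n; ++c) {
    if (!living[c]) continue;
    const int v = vox[c];
    if (v < 0 || v >= nvox) stop("cell voxel id out of range");
    U[v] += V[c] * f;
  }
  return U;
}

// ----------------------------------------------------------------- cell cycle

static inline double prolif_rate(double p, double rmax, double sa, double th) {
  if (p >= sa) return rmax;
  if (p <= th) return 0.0;
  return rmax * (p - th) / (sa - th);
}

static inline double necro_rate(double p, double rmax, double sa, double th) {
  if (p >= th) return 0.0;
  if (p <= sa) return rmax;
  return rmax * (th - p) / (th - sa);
}

// Phase codes: 1 premitotic, 2 postmitotic, 3 quiescent, 4 apoptotic,
// 5 early necrotic, 6 late necrotic. All times/rates here are in minutes.
// Per-cell order within one step: death tests, division marking, postmitotic
// maturation, quiescent activation, rupture, clock advance. RNG draws happen
// only when the corresponding rate is positive, in fixed cell order.
// [[Rcpp::export]]
List update_phases_cpp(IntegerVector phase_in, NumericVector clock_in,
                       NumericVector V, NumericVector p_oxy, double dt,
                       double T_prem, double T_postm, double r_apop,
                       double r_pro_max, double Sa_pro, double Th_pro,
                       double r_nec_max, double Sa_nec, double Th_nec,
                       double V_std, double rupture_ratio,
                       double removal_fraction) {
  const int n = phase_in.size();
  IntegerVector phase = clone(phase_in);
  NumericVector clock = clone(clock_in);
  LogicalVector divide(n, false), remove(n, false);
  const double removal_V = removal_fraction * V_std;
  const double rupture_V = rupture_ratio * V_std;
  RNGScope scope;
  for (int c = 0; c < n; ++c) {
    int p = phase[c];
    if (p >= 1 && p <= 3) {
      if (r_apop > 0.0 && unif_rand() < r_apop * dt) {
        p = 4;
        clock[c] = 0.0;
      } else {
        const double rn = necro_rate(p_oxy[c], r_nec_max, Sa_nec, Th_nec);
        if (rn > 0.0 && unif_rand() < rn * dt) {
          p = 5;
          clock[c] = 0.0;
        }
      }
    }
    if (p == 1 && clock[c] >= T_prem) {
      divide[c] = true;
    } else if (p == 2 && clock[c] >= T_postm) {
      p = 3;
      clock[c] = 0.0;
    } else if (p == 3) {
      const double rp = prolif_rate(p_oxy[c], r_pro_max, Sa_pro, Th_pro);
      if (rp > 0.0 && unif_rand() < rp * dt) {
        p = 1;
        clock[c] = 0.0;
      }
    }
    if (p == 5 && V[c] >= rupture_V) {
      p = 6;
      clock[c] = 0.0;
    }
    if (p >= 4 && V[c] < removal_V) remove[c] = true;
    phase[c] = p;
    clock[c] += dt;
  }
  return List::create(_["phase"] = phase, _["clock"] = clock,
                      _["divide"] = divide, _["remove"] = remove);
}

// Explicit relaxation step V_i <- V_i - dt*r*(V_i - V_i^p) for each component.
// fluid_mode per phase: 0 target = fF*V, 1 target = current V, 2 target = 0.
// Negative results are clamped to zero and counted.
// [[Rcpp::export]]
List update_volumes_cpp(IntegerVector phase, NumericVector VF_in,
                        NumericVector VNS_in, NumericVector VCS_in, double dt,
                        double fF, IntegerVector fluid_mode, NumericVector rF,
                        NumericVector VNS_target, NumericVector rNS,
                        NumericVector VCS_target, NumericVector rCS) {
  const int n = phase.size();
  NumericVector VF = clone(VF_in), VNS = clone(VNS_in), VCS = clone(VCS_in);
  NumericVector V(n);
  int n_clamped = 0;
  for (int c = 0; c < n; ++c) {
    const int p = phase[c] - 1;
    if (p < 0 || p > 5) stop("invalid phase code");
    const double Vtot = VF[c] + VNS[c] + VCS[c];
    double tF;
    if (fluid_mode[p] == 0)
      tF = fF * Vtot;
    else if (fluid_mode[p] == 1)
      tF = Vtot;
    else
      tF = 0.0;
    VF[c] -= dt * rF[p] * (VF[c] - tF);
    VNS[c] -= dt * rNS[p] * (VNS[c] - VNS_target[p]);
    VCS[c] -= dt * rCS[p] * (VCS[c] - VCS_target[p]);
    if (VF[c] < 0.0) { VF[c] = 0.0; ++n_clamped; }
    if (VNS[c] < 0.0) { VNS[c] = 0.0; ++n_clamped; }
    if (VCS[c] < 0.0) { VCS[c] = 0.0; ++n_clamped; }
    V[c] = VF[c] + VNS[c] + VCS[c];
  }
  return List::create(_["V"] = V, _["V_F"] = VF, _["V_NS"] = VNS,
                      _["V_CS"] = VCS, _["n_clamped"] = n_clamped);
}
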