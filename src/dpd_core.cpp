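// Core DPD kernels: pair/bond/angle forces with cell lists, the
// Groot-Warren modified velocity-Verlet loop (NVT / weak-coupling NPT),
// spherically binned Irving-Kirkwood stress, and single-linkage clustering.
// All randomness flows through one xoshiro256+ stream seeded per call.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
#include <functional>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // zero-mean, unit-variance symmetric uniform noise (standard DPD choice)
  inline double noise() { return (2.0 * unif() - 1.0) * 1.7320508075688772; }
};

inline double min_image(double dx, double L) {
  if (dx >  0.5 * L) dx -= L;
  else if (dx < -0.5 * L) dx += L;
  return dx;
}

struct CellList {
  int nc[3];
  double inv_cw[3];
  std::vector<int> head;   // first bead in cell, -1 if empty
  std::vector<int> nxt;    // next bead in same cell
  bool ok;

  void build(const std::vector<double>& x, int n, const double* box,
             double rc) {
    ok = true;
    for (int d = 0; d < 3; ++d) {
      nc[d] = (int)std::floor(box[d] / rc);
      if (nc[d] < 3) { ok = false; return; }
      inv_cw[d] = nc[d] / box[d];
    }
    head.assign((size_t)nc[0] * nc[1] * nc[2], -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(x[3 * i + 0] * inv_cw[0]); if (cx >= nc[0]) cx = nc[0] - 1; if (cx < 0) cx = 0;
      int cy = (int)(x[3 * i + 1] * inv_cw[1]); if (cy >= nc[1]) cy = nc[1] - 1; if (cy < 0) cy = 0;
      int cz = (int)(x[3 * i + 2] * inv_cw[2]); if (cz >= nc[2]) cz = nc[2] - 1; if (cz < 0) cz = 0;
      int c = (cz * nc[1] + cy) * nc[0] + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// half-space cell offsets (13) + self handled separately
static const int HALF_OFF[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
  {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

struct Params {
  std::vector<double> fmat;  // 4x4 column-major
  double rc, inv_rc;
  double bond_k, bond_l0, bend_k;
  double gamma, sigma, dt, inv_sqrt_dt;
};

class DpdSystem {
public:
  int n;
  std::vector<double> x, v, f;
  std::vector<int> type;                   // 0..3
  double box[3];
  std::vector<int> bond_i, bond_j;
  std::vector<int> ang_a, ang_b, ang_c;
  Params p;
  CellList cl;
  double virial;                           // conservative + bonded only

  void wrap() {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double& xi = x[3 * i + d];
        xi -= box[d] * std::floor(xi / box[d]);
        if (xi >= box[d]) xi = 0.0;  // guard against rounding
      }
  }

  inline void pair_interaction(int i, int j, bool thermo, Rng* rng) {
    double dx = min_image(x[3*i] - x[3*j], box[0]);
    double dy = min_image(x[3*i+1] - x[3*j+1], box[1]);
    double dz = min_image(x[3*i+2] - x[3*j+2], box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= p.rc * p.rc || r2 < 1e-14) return;
    double r = std::sqrt(r2);
    double inv_r = 1.0 / r;
    double w = 1.0 - r * p.inv_rc;         // omega_R; omega_D = w^2
    double fij = p.fmat[type[i] + 4 * type[j]];
    double fc = fij * w;                   // conservative magnitude
    double ex = dx * inv_r, ey = dy * inv_r, ez = dz * inv_r;
    virial += fc * r;
    double fmag = fc;
    if (thermo) {
      double vdotr = (v[3*i] - v[3*j]) * ex + (v[3*i+1] - v[3*j+1]) * ey +
                     (v[3*i+2] - v[3*j+2]) * ez;
      double fd = -p.gamma * w * w * vdotr;
      double fr = p.sigma * w * rng->noise() * p.inv_sqrt_dt;
      fmag += fd + fr;
    }
    f[3*i]   += fmag * ex; f[3*j]   -= fmag * ex;
    f[3*i+1] += fmag * ey; f[3*j+1] -= fmag * ey;
    f[3*i+2] += fmag * ez; f[3*j+2] -= fmag * ez;
  }

  void bonded_forces() {
    // harmonic bonds
    for (size_t b = 0; b < bond_i.size(); ++b) {
      int i = bond_i[b], j = bond_j[b];
      double dx = min_image(x[3*i] - x[3*j], box[0]);
      double dy = min_image(x[3*i+1] - x[3*j+1], box[1]);
      double dz = min_image(x[3*i+2] - x[3*j+2], box[2]);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < 1e-12) continue;
      double fmag = -p.bond_k * (r - p.bond_l0);  // along +rhat on i
      virial += fmag * r;
      double s = fmag / r;
      f[3*i]   += s * dx; f[3*j]   -= s * dx;
      f[3*i+1] += s * dy; f[3*j+1] -= s * dy;
      f[3*i+2] += s * dz; f[3*j+2] -= s * dz;
    }
    // chain stiffness k*(1 - cos phi), phi between consecutive bond vectors
    for (size_t a = 0; a < ang_a.size(); ++a) {
      int ia = ang_a[a], ib = ang_b[a], ic = ang_c[a];
      double ux = min_image(x[3*ib] - x[3*ia], box[0]);
      double uy = min_image(x[3*ib+1] - x[3*ia+1], box[1]);
      double uz = min_image(x[3*ib+2] - x[3*ia+2], box[2]);
      double vx = min_image(x[3*ic] - x[3*ib], box[0]);
      double vy = min_image(x[3*ic+1] - x[3*ib+1], box[1]);
      double vz = min_image(x[3*ic+2] - x[3*ib+2], box[2]);
      double lu = std::sqrt(ux*ux + uy*uy + uz*uz);
      double lv = std::sqrt(vx*vx + vy*vy + vz*vz);
      if (lu < 1e-12 || lv < 1e-12) continue;
      double inv = 1.0 / (lu * lv);
      double c = (ux*vx + uy*vy + uz*vz) * inv;
      // dc/du, dc/dv
      double dcux = vx * inv - c * ux / (lu * lu);
      double dcuy = vy * inv - c * uy / (lu * lu);
      double dcuz = vz * inv - c * uz / (lu * lu);
      double dcvx = ux * inv - c * vx / (lv * lv);
      double dcvy = uy * inv - c * vy / (lv * lv);
      double dcvz = uz * inv - c * vz / (lv * lv);
      double k = p.bend_k;
      // F_a = -k dc/du ; F_c = k dc/dv ; F_b = -(F_a + F_c)
      f[3*ia]   += -k * dcux; f[3*ia+1] += -k * dcuy; f[3*ia+2] += -k * dcuz;
      f[3*ic]   +=  k * dcvx; f[3*ic+1] +=  k * dcvy; f[3*ic+2] +=  k * dcvz;
      f[3*ib]   +=  k * (dcux - dcvx);
      f[3*ib+1] +=  k * (dcuy - dcvy);
      f[3*ib+2] +=  k * (dcuz - dcvz);
      // scale-invariant potential: zero virial contribution
    }
  }

  // full force evaluation; thermo = include dissipative + random pair forces
  void forces(bool thermo, Rng* rng, int use_cells) {
    std::fill(f.begin(), f.end(), 0.0);
    virial = 0.0;
    bool cells = false;
    if (use_cells != 0) {
      cl.build(x, n, box, p.rc);
      cells = cl.ok;
      if (use_cells == 1 && !cells)
        stop("box too small for cell list (need >= 3 cells per edge)");
    }
    if (cells) {
      for (int cz = 0; cz < cl.nc[2]; ++cz)
        for (int cy = 0; cy < cl.nc[1]; ++cy)
          for (int cx = 0; cx < cl.nc[0]; ++cx) {
            int c = (cz * cl.nc[1] + cy) * cl.nc[0] + cx;
            // within-cell pairs
            for (int i = cl.head[c]; i != -1; i = cl.nxt[i])
              for (int j = cl.nxt[i]; j != -1; j = cl.nxt[j])
                pair_interaction(i, j, thermo, rng);
            // half-space neighbor cells
            for (int o = 0; o < 13; ++o) {
              int ox = (cx + HALF_OFF[o][0] + cl.nc[0]) % cl.nc[0];
              int oy = (cy + HALF_OFF[o][1] + cl.nc[1]) % cl.nc[1];
              int oz = (cz + HALF_OFF[o][2] + cl.nc[2]) % cl.nc[2];
              int c2 = (oz * cl.nc[1] + oy) * cl.nc[0] + ox;
              if (c2 == c) continue;  // degenerate when nc == small
              for (int i = cl.head[c]; i != -1; i = cl.nxt[i])
                for (int j = cl.head[c2]; j != -1; j = cl.nxt[j])
                  pair_interaction(i, j, thermo, rng);
            }
          }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          pair_interaction(i, j, thermo, rng);
    }
    bonded_forces();
  }
};

DpdSystem make_system(const NumericMatrix& pos, const NumericMatrix& vel,
                      const IntegerVector& type, const NumericVector& box,
                      const NumericMatrix& fmat, const IntegerMatrix& bonds,
                      const IntegerMatrix& angles, const List& par) {
  DpdSystem S;
  S.n = pos.nrow();
  S.x.resize(3 * S.n); S.v.resize(3 * S.n); S.f.assign(3 * S.n, 0.0);
  S.type.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    for (int d = 0; d < 3; ++d) {
      S.x[3*i+d] = pos(i, d);
      S.v[3*i+d] = vel(i, d);
    }
    S.type[i] = type[i] - 1;
    if (S.type[i] < 0 || S.type[i] > 3) stop("bead type out of range 1..4");
  }
  for (int d = 0; d < 3; ++d) S.box[d] = box[d];
  S.p.fmat.resize(16);
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) S.p.fmat[a + 4*b] = fmat(a, b);
  S.p.rc = as<double>(par["cutoff"]);
  S.p.inv_rc = 1.0 / S.p.rc;
  S.p.bond_k = as<double>(par["bond_k"]);
  S.p.bond_l0 = as<double>(par["bond_l0"]);
  S.p.bend_k = as<double>(par["bend_k"]);
  S.p.gamma = as<double>(par["gamma"]);
  S.p.sigma = as<double>(par["sigma"]);
  S.p.dt = as<double>(par["dt"]);
  S.p.inv_sqrt_dt = 1.0 / std::sqrt(S.p.dt);
  int nb = bonds.nrow();
  S.bond_i.resize(nb); S.bond_j.resize(nb);
  for (int b = 0; b < nb; ++b) {
    S.bond_i[b] = bonds(b, 0) - 1;
    S.bond_j[b] = bonds(b, 1) - 1;
  }
  int na = angles.nrow();
  S.ang_a.resize(na); S.ang_b.resize(na); S.ang_c.resize(na);
  for (int a = 0; a < na; ++a) {
    S.ang_a[a] = angles(a, 0) - 1;
    S.ang_b[a] = angles(a, 1) - 1;
    S.ang_c[a] = angles(a, 2) - 1;
  }
  S.wrap();
  return S;
}

} // namespace

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericMatrix vel,
                        IntegerVector type, NumericVector box,
                        NumericMatrix fmat, IntegerMatrix bonds,
                        IntegerMatrix angles, List par, bool thermo,
                        int use_cells, int seed) {
  DpdSystem S = make_system(pos, vel, type, box, fmat, bonds, angles, par);
  Rng rng((uint64_t)seed);
  S.forces(thermo, &rng, use_cells);
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = S.f[3*i+d];
  return List::create(_["forces"] = F, _["virial"] = S.virial);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
             NumericVector box, NumericMatrix fmat, IntegerMatrix bonds,
             IntegerMatrix angles, List par, double lambda, int n_steps,
             int frame_stride, int obs_stride, int ensemble,
             double p_target, double tau_p, int seed, int step0,
             bool thermo) {
  DpdSystem S = make_system(pos, vel, type, box, fmat, bonds, angles, par);
  Rng rng((uint64_t)seed);
  const double dt = S.p.dt;
  const int n = S.n;

  std::vector<double> v_old(3 * n), f_old(3 * n);
  S.forces(thermo, &rng, 2);

  int n_frames = frame_stride > 0 ? n_steps / frame_stride : 0;
  List frames(n_frames);
  NumericMatrix frame_boxes(n_frames, 3);
  IntegerVector frame_steps(n_frames);
  int fi = 0;

  int n_obs = obs_stride > 0 ? n_steps / obs_stride : 0;
  NumericMatrix obs(n_obs, 7);  // step, time, T, Pex, Ptot, L, px-sum
  int oi = 0;

  for (int s = 1; s <= n_steps; ++s) {
    // Groot-Warren modified velocity-Verlet
    std::copy(S.v.begin(), S.v.end(), v_old.begin());
    std::copy(S.f.begin(), S.f.end(), f_old.begin());
    for (int i = 0; i < 3 * n; ++i) {
      S.x[i] += dt * S.v[i] + 0.5 * dt * dt * S.f[i];
      S.v[i] = v_old[i] + lambda * dt * S.f[i];  // prediction
    }
    S.wrap();
    S.forces(thermo, &rng, 2);
    for (int i = 0; i < 3 * n; ++i)
      S.v[i] = v_old[i] + 0.5 * dt * (f_old[i] + S.f[i]);

    double V = S.box[0] * S.box[1] * S.box[2];
    double p_ex = S.virial / (3.0 * V);

    if (ensemble == 1) {  // weak-coupling isotropic NPT on P_total
      double ke2 = 0.0;
      for (int i = 0; i < 3 * n; ++i) ke2 += S.v[i] * S.v[i];
      double p_tot = p_ex + ke2 / (3.0 * V);
      double mu3 = 1.0 - (dt / tau_p) * (p_target - p_tot);
      if (mu3 < 0.97) mu3 = 0.97;
      if (mu3 > 1.03) mu3 = 1.03;
      double mu = std::cbrt(mu3);
      for (int d = 0; d < 3; ++d) S.box[d] *= mu;
      for (int i = 0; i < 3 * n; ++i) S.x[i] *= mu;
    }

    if (obs_stride > 0 && s % obs_stride == 0) {
      double ke2 = 0.0, px = 0.0, py = 0.0, pz = 0.0;
      bool finite = true;
      for (int i = 0; i < n; ++i) {
        for (int d = 0; d < 3; ++d) {
          double vv = S.v[3*i+d];
          ke2 += vv * vv;
          if (!std::isfinite(S.x[3*i+d]) || !std::isfinite(vv)) finite = false;
        }
        px += S.v[3*i]; py += S.v[3*i+1]; pz += S.v[3*i+2];
      }
      if (!finite)
        stop("simulation diverged (non-finite coordinates) at step %d",
             step0 + s);
      double Vn = S.box[0] * S.box[1] * S.box[2];
      double T = ke2 / (3.0 * n - 3.0);
      double pex_n = S.virial / (3.0 * Vn);
      obs(oi, 0) = step0 + s;
      obs(oi, 1) = (step0 + s) * dt;
      obs(oi, 2) = T;
      obs(oi, 3) = pex_n;
      obs(oi, 4) = pex_n + ke2 / (3.0 * Vn);
      obs(oi, 5) = S.box[0];
      obs(oi, 6) = std::sqrt(px * px + py * py + pz * pz);
      ++oi;
    }
    if (frame_stride > 0 && s % frame_stride == 0) {
      NumericMatrix P(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) P(i, d) = S.x[3*i+d];
      frames[fi] = P;
      for (int d = 0; d < 3; ++d) frame_boxes(fi, d) = S.box[d];
      frame_steps[fi] = step0 + s;
      ++fi;
    }
  }

  NumericMatrix Pn(n, 3), Vn(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      Pn(i, d) = S.x[3*i+d];
      Vn(i, d) = S.v[3*i+d];
    }
  return List::create(
    _["pos"] = Pn, _["vel"] = Vn,
    _["box"] = NumericVector::create(S.box[0], S.box[1], S.box[2]),
    _["frames"] = frames, _["frame_boxes"] = frame_boxes,
    _["frame_steps"] = frame_steps, _["obs"] = obs,
    _["virial"] = S.virial);
}

// Spherically binned Irving-Kirkwood stress for one frame. Pair (and
// pairwise-decomposed angle) force segments are subdivided and each
// piece assigned to the radial shell of its midpoint.
// [[Rcpp::export]]
List cpp_stress_bin(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                    NumericVector box, NumericMatrix fmat,
                    IntegerMatrix bonds, IntegerMatrix angles, List par,
                    NumericVector center, double bin_width, int nbins) {
  DpdSystem S = make_system(pos, vel, type, box, fmat, bonds, angles, par);
  const int n = S.n;
  std::vector<double> PN(nbins, 0.0), PT(nbins, 0.0);
  double cx = center[0], cy = center[1], cz = center[2];
  double virial = 0.0;

  // coordinates relative to center, minimum image
  std::vector<double> rx(n), ry(n), rz(n);
  for (int i = 0; i < n; ++i) {
    rx[i] = min_image(S.x[3*i]   - cx, S.box[0]);
    ry[i] = min_image(S.x[3*i+1] - cy, S.box[1]);
    rz[i] = min_image(S.x[3*i+2] - cz, S.box[2]);
  }

  // deposit one force segment: force (fx,fy,fz) acting across separation
  // (sx,sy,sz) (= r_i - r_j), segment from bead j endpoint to bead i endpoint
  auto deposit = [&](double fx, double fy, double fz,
                     double sx, double sy, double sz,
                     double xi, double yi, double zi) {
    double len = std::sqrt(sx*sx + sy*sy + sz*sz);
    int m = (int)std::ceil(len / (0.25 * bin_width));
    if (m < 1) m = 1;
    double wseg = 1.0 / m;
    for (int k = 0; k < m; ++k) {
      double lam = (k + 0.5) / m;           // along j -> i
      double px = xi - (1.0 - lam) * sx;
      double py = yi - (1.0 - lam) * sy;
      double pz = zi - (1.0 - lam) * sz;
      double r = std::sqrt(px*px + py*py + pz*pz);
      int bin = (int)(r / bin_width);
      if (bin >= nbins || r < 1e-12) continue;
      double ex = px / r, ey = py / r, ez = pz / r;
      double f_r = fx*ex + fy*ey + fz*ez;
      double s_r = sx*ex + sy*ey + sz*ez;
      double fdots = fx*sx + fy*sy + fz*sz;
      PN[bin] += wseg * f_r * s_r;
      PT[bin] += wseg * 0.5 * (fdots - f_r * s_r);
    }
  };

  // non-bonded conservative pairs (all-pairs or cells)
  CellList cl;
  cl.build(S.x, n, S.box, S.p.rc);
  auto do_pair = [&](int i, int j) {
    double dx = min_image(S.x[3*i] - S.x[3*j], S.box[0]);
    double dy = min_image(S.x[3*i+1] - S.x[3*j+1], S.box[1]);
    double dz = min_image(S.x[3*i+2] - S.x[3*j+2], S.box[2]);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= S.p.rc * S.p.rc || r2 < 1e-14) return;
    double r = std::sqrt(r2);
    double fc = S.p.fmat[S.type[i] + 4 * S.type[j]] * (1.0 - r / S.p.rc) / r;
    virial += fc * r2;
    deposit(fc * dx, fc * dy, fc * dz, dx, dy, dz, rx[i], ry[i], rz[i]);
  };
  if (cl.ok) {
    for (int czi = 0; czi < cl.nc[2]; ++czi)
      for (int cyi = 0; cyi < cl.nc[1]; ++cyi)
        for (int cxi = 0; cxi < cl.nc[0]; ++cxi) {
          int c = (czi * cl.nc[1] + cyi) * cl.nc[0] + cxi;
          for (int i = cl.head[c]; i != -1; i = cl.nxt[i])
            for (int j = cl.nxt[i]; j != -1; j = cl.nxt[j]) do_pair(i, j);
          for (int o = 0; o < 13; ++o) {
            int ox = (cxi + HALF_OFF[o][0] + cl.nc[0]) % cl.nc[0];
            int oy = (cyi + HALF_OFF[o][1] + cl.nc[1]) % cl.nc[1];
            int oz = (czi + HALF_OFF[o][2] + cl.nc[2]) % cl.nc[2];
            int c2 = (oz * cl.nc[1] + oy) * cl.nc[0] + ox;
            if (c2 == c) continue;
            for (int i = cl.head[c]; i != -1; i = cl.nxt[i])
              for (int j = cl.head[c2]; j != -1; j = cl.nxt[j]) do_pair(i, j);
          }
        }
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) do_pair(i, j);
  }

  // bonds
  for (size_t b = 0; b < S.bond_i.size(); ++b) {
    int i = S.bond_i[b], j = S.bond_j[b];
    double dx = min_image(S.x[3*i] - S.x[3*j], S.box[0]);
    double dy = min_image(S.x[3*i+1] - S.x[3*j+1], S.box[1]);
    double dz = min_image(S.x[3*i+2] - S.x[3*j+2], S.box[2]);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-12) continue;
    double s = -S.p.bond_k * (r - S.p.bond_l0) / r;
    virial += s * r * r;
    deposit(s * dx, s * dy, s * dz, dx, dy, dz, rx[i], ry[i], rz[i]);
  }

  // angles, decomposed into two bond-segment pair forces
  for (size_t a = 0; a < S.ang_a.size(); ++a) {
    int ia = S.ang_a[a], ib = S.ang_b[a], ic = S.ang_c[a];
    double ux = min_image(S.x[3*ib] - S.x[3*ia], S.box[0]);
    double uy = min_image(S.x[3*ib+1] - S.x[3*ia+1], S.box[1]);
    double uz = min_image(S.x[3*ib+2] - S.x[3*ia+2], S.box[2]);
    double vx = min_image(S.x[3*ic] - S.x[3*ib], S.box[0]);
    double vy = min_image(S.x[3*ic+1] - S.x[3*ib+1], S.box[1]);
    double vz = min_image(S.x[3*ic+2] - S.x[3*ib+2], S.box[2]);
    double lu = std::sqrt(ux*ux + uy*uy + uz*uz);
    double lv = std::sqrt(vx*vx + vy*vy + vz*vz);
    if (lu < 1e-12 || lv < 1e-12) continue;
    double inv = 1.0 / (lu * lv);
    double c = (ux*vx + uy*vy + uz*vz) * inv;
    double k = S.p.bend_k;
    double fax = -k * (vx * inv - c * ux / (lu * lu));
    double fay = -k * (vy * inv - c * uy / (lu * lu));
    double faz = -k * (vz * inv - c * uz / (lu * lu));
    double fcx =  k * (ux * inv - c * vx / (lv * lv));
    double fcy =  k * (uy * inv - c * vy / (lv * lv));
    double fcz =  k * (uz * inv - c * vz / (lv * lv));
    // force fa acts on a across separation r_a - r_b = -u
    deposit(fax, fay, faz, -ux, -uy, -uz, rx[ia], ry[ia], rz[ia]);
    // force fc acts on c across separation r_c - r_b = v
    deposit(fcx, fcy, fcz, vx, vy, vz, rx[ic], ry[ic], rz[ic]);
  }

  // kinetic part per bead shell
  std::vector<double> KN(nbins, 0.0), KT(nbins, 0.0);
  for (int i = 0; i < n; ++i) {
    double r = std::sqrt(rx[i]*rx[i] + ry[i]*ry[i] + rz[i]*rz[i]);
    int bin = (int)(r / bin_width);
    if (bin >= nbins || r < 1e-12) continue;
    double ex = rx[i]/r, ey = ry[i]/r, ez = rz[i]/r;
    double vr = S.v[3*i]*ex + S.v[3*i+1]*ey + S.v[3*i+2]*ez;
    double v2 = S.v[3*i]*S.v[3*i] + S.v[3*i+1]*S.v[3*i+1] +
                S.v[3*i+2]*S.v[3*i+2];
    KN[bin] += vr * vr;
    KT[bin] += 0.5 * (v2 - vr * vr);
  }

  NumericVector outN(nbins), outT(nbins), outKN(nbins), outKT(nbins);
  const double four_thirds_pi = 4.0 * M_PI / 3.0;
  for (int b = 0; b < nbins; ++b) {
    double r0 = b * bin_width, r1 = (b + 1) * bin_width;
    double vol = four_thirds_pi * (r1*r1*r1 - r0*r0*r0);
    outN[b] = PN[b] / vol;
    outT[b] = PT[b] / vol;
    outKN[b] = KN[b] / vol;
    outKT[b] = KT[b] / vol;
  }
  return List::create(_["P_N_conf"] = outN, _["P_T_conf"] = outT,
                      _["P_N_kin"] = outKN, _["P_T_kin"] = outKT,
                      _["virial"] = virial);
}

// single-linkage clustering with distance cutoff (union-find over cell list)
// [[Rcpp::export]]
IntegerVector cpp_cluster(NumericMatrix pos, NumericVector box,
                          double cutoff) {
  int n = pos.nrow();
  std::vector<double> x(3 * n);
  double bx[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double xi = pos(i, d);
      xi -= bx[d] * std::floor(xi / bx[d]);
      x[3*i+d] = xi;
    }
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  auto unite = [&](int i, int j) {
    int ri = find(i), rj = find(j);
    if (ri != rj) parent[ri] = rj;
  };
  auto near = [&](int i, int j) {
    double dx = min_image(x[3*i] - x[3*j], bx[0]);
    double dy = min_image(x[3*i+1] - x[3*j+1], bx[1]);
    double dz = min_image(x[3*i+2] - x[3*j+2], bx[2]);
    return dx*dx + dy*dy + dz*dz <= cutoff * cutoff;
  };
  CellList cl;
  cl.build(x, n, bx, cutoff);
  if (cl.ok) {
    for (int cz = 0; cz < cl.nc[2]; ++cz)
      for (int cy = 0; cy < cl.nc[1]; ++cy)
        for (int cx = 0; cx < cl.nc[0]; ++cx) {
          int c = (cz * cl.nc[1] + cy) * cl.nc[0] + cx;
          for (int i = cl.head[c]; i != -1; i = cl.nxt[i])
            for (int j = cl.nxt[i]; j != -1; j = cl.nxt[j])
              if (near(i, j)) unite(i, j);
          for (int o = 0; o < 13; ++o) {
            int ox = (cx + HALF_OFF[o][0] + cl.nc[0]) % cl.nc[0];
            int oy = (cy + HALF_OFF[o][1] + cl.nc[1]) % cl.nc[1];
            int oz = (cz + HALF_OFF[o][2] + cl.nc[2]) % cl.nc[2];
            int c2 = (oz * cl.nc[1] + oy) * cl.nc[0] + ox;
            if (c2 == c) continue;
            for (int i = cl.head[c]; i != -1; i = cl.nxt[i])
              for (int j = cl.head[c2]; j != -1; j = cl.nxt[j])
                if (near(i, j)) unite(i, j);
          }
        }
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (near(i, j)) unite(i, j);
  }
  // relabel components 1..k in order of first appearance
  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next_lab = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (remap[r] == 0) remap[r] = ++next_lab;
    lab[i] = remap[r];
  }
  return lab;
}
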