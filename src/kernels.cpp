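// Monte Carlo and scattering kernels.
//
// Both pair potentials used by the package are affine in the attraction
// strength eps_ij:  beta*U = U_elec + eps_ij * W,  where W collects the
// Lennard-Jones (amino-acid model) or -(sigma/r)^6 (bead model) terms with
// unit eps.  All kernels therefore track (U_elec, W) separately, which lets
// the R side evaluate a configuration's energy under any eps without
// re-summing pairs (used by Hamiltonian replica exchange).
//
// Units: lengths in Angstrom, energies in kBT, charges in units of e.
// The bead-model Debye-Hueckel size factor exp(s/2lD)/(1+s/2lD) is folded
// into the effective charges passed from R, so the electrostatic term is
// always lB * q_i * q_j * exp(-r/lD) / r.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// xoshiro256** seeded with splitmix64: deterministic across platforms,
// independent of R's global RNG state.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
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
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  inline int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

struct Model {
  int type;       // 0 = amino-acid (full LJ), 1 = bead (hard core + attractive r^-6)
  double lB, lD, L;
  double rc_e2, rc_v2;  // squared cutoffs for electrostatic / short-range terms
  // optional lookup table for exp(-r/lD)/r on [0, rc_e] (sampling kernels
  // only; the exact path is kept for the user-facing pair-energy functions)
  const double* ytab = nullptr;
  double inv_h = 0.0;
  int ntab = 0;

  inline double yukawa(double r) const {
    if (ytab) {
      const double u = r * inv_h;
      const int i = (int)u;
      if (i + 1 < ntab && i >= 1) {
        const double f = u - i;
        return ytab[i] + f * (ytab[i + 1] - ytab[i]);
      }
    }
    return std::exp(-r / lD) / r;
  }
};

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Accumulate inter-molecular pair energy components between bead sets A and B.
// Returns false on hard-core overlap (bead model only).
// `shift` is an optional precomputed periodic image offset applied to B
// (valid whenever all interacting pairs share one image, i.e. cutoffs <= L/2
// and the shift comes from the molecule-com separation); when absent the
// minimum image is taken per bead pair.
inline bool pair_accum(const double* A, int na, const double* B, int nb,
                       const double* qA, const double* qB,
                       const double* sA, const double* sB,
                       const Model& m, double& elec, double& w,
                       const double* shift = nullptr) {
  for (int i = 0; i < na; ++i) {
    const double ax = A[3 * i], ay = A[3 * i + 1], az = A[3 * i + 2];
    const double qi = qA[i], si = sA[i];
    for (int j = 0; j < nb; ++j) {
      double dx, dy, dz;
      if (shift) {
        dx = ax - B[3 * j] - shift[0];
        dy = ay - B[3 * j + 1] - shift[1];
        dz = az - B[3 * j + 2] - shift[2];
      } else {
        dx = min_image(ax - B[3 * j], m.L);
        dy = min_image(ay - B[3 * j + 1], m.L);
        dz = min_image(az - B[3 * j + 2], m.L);
      }
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double s = 0.5 * (si + sB[j]);
      if (m.type == 1 && r2 < s * s) return false;
      if (r2 < m.rc_e2) {
        const double qq = qi * qB[j];
        if (qq != 0.0) {
          const double r = std::sqrt(r2);
          elec += m.lB * qq * m.yukawa(r);
        }
      }
      if (r2 < m.rc_v2) {
        const double sr2 = s * s / r2;
        const double sr6 = sr2 * sr2 * sr2;
        if (m.type == 0)
          w += 4.0 * (sr6 * sr6 - sr6);
        else
          w += -sr6;
      }
    }
  }
  return true;
}

// quaternion (w,x,y,z) to rotation matrix, row-major
inline void quat_to_rot(const double* q, double* R) {
  const double wq = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z);
  R[1] = 2 * (x * y - wq * z);
  R[2] = 2 * (x * z + wq * y);
  R[3] = 2 * (x * y + wq * z);
  R[4] = 1 - 2 * (x * x + z * z);
  R[5] = 2 * (y * z - wq * x);
  R[6] = 2 * (x * z - wq * y);
  R[7] = 2 * (y * z + wq * x);
  R[8] = 1 - 2 * (x * x + y * y);
}

inline void quat_mult(const double* a, const double* b, double* out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

inline void quat_normalize(double* q) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= n;
}

// world coordinates of one molecule: R(quat) * tmpl' + com
inline void place(const double* tmpl, int nb, const double* com,
                  const double* q, double* out) {
  double R[9];
  quat_to_rot(q, R);
  for (int i = 0; i < nb; ++i) {
    const double x = tmpl[3 * i], y = tmpl[3 * i + 1], z = tmpl[3 * i + 2];
    out[3 * i] = R[0] * x + R[1] * y + R[2] * z + com[0];
    out[3 * i + 1] = R[3] * x + R[4] * y + R[5] * z + com[1];
    out[3 * i + 2] = R[6] * x + R[7] * y + R[8] * z + com[2];
  }
}

struct System {
  int np, nb;
  std::vector<double> ytab_store;
  std::vector<double> world;  // np*nb*3
  std::vector<double> com;    // np*3
  std::vector<double> quat;   // np*4
  std::vector<double> tmpl;   // nb*3 (com-centred)
  std::vector<double> sigma, qeff;
  Model m;
  double rmax;   // max bead distance from com in template
  double skip2;  // squared com-distance beyond which molecule pairs cannot interact
  bool use_shift;  // one image per molecule pair is exact when rc + 2*rmax <= L/2

  // energy of molecule i against all others; false on overlap
  bool mol_energy(int i, const double* coords_i, const double* com_i,
                  double& elec, double& w) const {
    elec = 0.0;
    w = 0.0;
    for (int j = 0; j < np; ++j) {
      if (j == i) continue;
      const double rx = com_i[0] - com[3 * j];
      const double ry = com_i[1] - com[3 * j + 1];
      const double rz = com_i[2] - com[3 * j + 2];
      double sh[3] = {m.L * std::nearbyint(rx / m.L),
                      m.L * std::nearbyint(ry / m.L),
                      m.L * std::nearbyint(rz / m.L)};
      const double dx = rx - sh[0], dy = ry - sh[1], dz = rz - sh[2];
      if (dx * dx + dy * dy + dz * dz > skip2) continue;
      if (!pair_accum(coords_i, nb, &world[3 * nb * j], nb, qeff.data(),
                      qeff.data(), sigma.data(), sigma.data(), m, elec, w,
                      use_shift ? sh : nullptr))
        return false;
    }
    return true;
  }

  bool total_energy(double& elec, double& w) const {
    elec = 0.0;
    w = 0.0;
    for (int i = 0; i < np; ++i)
      for (int j = i + 1; j < np; ++j) {
        const double rx = com[3 * i] - com[3 * j];
        const double ry = com[3 * i + 1] - com[3 * j + 1];
        const double rz = com[3 * i + 2] - com[3 * j + 2];
        double sh[3] = {m.L * std::nearbyint(rx / m.L),
                        m.L * std::nearbyint(ry / m.L),
                        m.L * std::nearbyint(rz / m.L)};
        const double dx = rx - sh[0], dy = ry - sh[1], dz = rz - sh[2];
        if (dx * dx + dy * dy + dz * dz > skip2) continue;
        if (!pair_accum(&world[3 * nb * i], nb, &world[3 * nb * j], nb,
                        qeff.data(), qeff.data(), sigma.data(), sigma.data(),
                        m, elec, w, use_shift ? sh : nullptr))
          return false;
      }
    return true;
  }
};

System make_system(NumericMatrix tmpl, NumericVector sigma, NumericVector qeff,
                   NumericMatrix com, NumericMatrix quat, double L, double lB,
                   double lD, int model, double rc_e, double rc_v) {
  System s;
  s.np = com.nrow();
  s.nb = tmpl.nrow();
  s.m.type = model;
  s.m.L = L;
  s.m.lB = lB;
  s.m.lD = lD;
  s.m.rc_e2 = rc_e * rc_e;
  s.m.rc_v2 = rc_v * rc_v;
  s.tmpl.resize(3 * s.nb);
  for (int i = 0; i < s.nb; ++i)
    for (int k = 0; k < 3; ++k) s.tmpl[3 * i + k] = tmpl(i, k);
  s.sigma.assign(sigma.begin(), sigma.end());
  s.qeff.assign(qeff.begin(), qeff.end());
  s.com.resize(3 * s.np);
  s.quat.resize(4 * s.np);
  for (int i = 0; i < s.np; ++i) {
    for (int k = 0; k < 3; ++k) s.com[3 * i + k] = com(i, k);
    for (int k = 0; k < 4; ++k) s.quat[4 * i + k] = quat(i, k);
  }
  s.rmax = 0.0;
  double smax = 0.0;
  for (int i = 0; i < s.nb; ++i) {
    double r = std::sqrt(s.tmpl[3 * i] * s.tmpl[3 * i] +
                         s.tmpl[3 * i + 1] * s.tmpl[3 * i + 1] +
                         s.tmpl[3 * i + 2] * s.tmpl[3 * i + 2]);
    if (r > s.rmax) s.rmax = r;
    if (sigma[i] > smax) smax = sigma[i];
  }
  double rc = std::max(rc_e, rc_v);
  rc = std::max(rc, smax);  // hard core must never be skipped
  double skip = rc + 2.0 * s.rmax;
  s.skip2 = skip * skip;
  s.use_shift = (rc + 2.0 * s.rmax) <= 0.5 * L + 1e-9;
  // lookup table for the screened-Coulomb radial factor (piecewise linear,
  // 0.005 A step: interpolation error ~1e-8 of the local value)
  const double h = 0.005;
  int ntab = (int)(rc_e / h) + 3;
  if (ntab > 3) {
    s.ytab_store.resize(ntab);
    s.ytab_store[0] = 0.0;
    for (int i = 1; i < ntab; ++i) {
      const double r = i * h;
      s.ytab_store[i] = std::exp(-r / lD) / r;
    }
    s.m.ytab = s.ytab_store.data();
    s.m.inv_h = 1.0 / h;
    s.m.ntab = ntab;
  }
  s.world.resize(3 * s.nb * s.np);
  for (int i = 0; i < s.np; ++i)
    place(s.tmpl.data(), s.nb, &s.com[3 * i], &s.quat[4 * i],
          &s.world[3 * s.nb * i]);
  return s;
}

}  // namespace

// [[Rcpp::export]]
List cpp_box_energy(NumericMatrix tmpl, NumericVector sigma, NumericVector qeff,
                    NumericMatrix com, NumericMatrix quat, double L, double lB,
                    double lD, int model, double rc_e, double rc_v) {
  System s = make_system(tmpl, sigma, qeff, com, quat, L, lB, lD, model, rc_e, rc_v);
  double elec, w;
  bool ok = s.total_energy(elec, w);
  return List::create(_["elec"] = elec, _["w"] = w, _["overlap"] = !ok);
}

// [[Rcpp::export]]
List cpp_mol_pair_energy(NumericMatrix a, NumericMatrix b, NumericVector qa,
                         NumericVector qb, NumericVector sa, NumericVector sb,
                         double L, double lB, double lD, int model, double rc_e,
                         double rc_v) {
  Model m;
  m.type = model;
  m.L = L;
  m.lB = lB;
  m.lD = lD;
  m.rc_e2 = rc_e * rc_e;
  m.rc_v2 = rc_v * rc_v;
  std::vector<double> A(3 * a.nrow()), B(3 * b.nrow());
  for (int i = 0; i < a.nrow(); ++i)
    for (int k = 0; k < 3; ++k) A[3 * i + k] = a(i, k);
  for (int i = 0; i < b.nrow(); ++i)
    for (int k = 0; k < 3; ++k) B[3 * i + k] = b(i, k);
  double elec = 0.0, w = 0.0;
  bool ok = pair_accum(A.data(), a.nrow(), B.data(), b.nrow(), &qa[0], &qb[0],
                       &sa[0], &sb[0], m, elec, w);
  return List::create(_["elec"] = elec, _["w"] = w, _["overlap"] = !ok);
}

// Rigid-body Metropolis MC.  One sweep = np single-molecule moves in random
// permutation order, each a combined translation + rotation about the com.
// Move sizes are tuned toward target_acc during burn-in only.
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix tmpl, NumericVector sigma, NumericVector qeff,
                NumericMatrix com, NumericMatrix quat, double L, double lB,
                double lD, double eps, int model, double rc_e, double rc_v,
                int n_sweeps, int burn_in, int sample_stride, double max_trans,
                double max_rot, bool tune, double target_acc, double seed,
                bool record_frames, NumericMatrix base_qvecs,
                IntegerMatrix shell_map, int n_shells, int intensity_stride) {
  System s = make_system(tmpl, sigma, qeff, com, quat, L, lB, lD, model, rc_e, rc_v);
  Xoshiro rng((uint64_t)seed);
  const int np = s.np, nb = s.nb;

  double E_elec, E_w;
  if (!s.total_energy(E_elec, E_w))
    stop("initial configuration contains hard-core overlaps");

  int n_samples = 0;
  if (n_sweeps > burn_in) n_samples = (n_sweeps - burn_in) / std::max(1, sample_stride);
  NumericMatrix frames(record_frames ? n_samples : 0, record_frames ? 3 * np * nb : 0);
  NumericMatrix com_trace(n_samples, 3 * np);
  NumericMatrix quat_trace(n_samples, 4 * np);
  NumericVector e_elec(n_samples), e_w(n_samples);

  // optional streamed scattering: per-shell intensity every intensity_stride
  // sweeps after burn-in (avoids storing bead coordinates).  The lattice
  // q-vectors are harmonics p of a few base directions, so phases recur:
  // one sincos per bead per direction, then complex multiplication over p.
  const int ndir = base_qvecs.nrow();
  const int pmax = shell_map.nrow();
  int n_imeas = 0;
  if (ndir > 0 && n_sweeps > burn_in && intensity_stride > 0)
    n_imeas = (n_sweeps - burn_in) / intensity_stride;
  NumericMatrix inten(n_imeas, ndir > 0 ? n_shells : 0);
  std::vector<double> shell_count(n_shells > 0 ? n_shells : 1, 0.0);
  for (int d = 0; d < ndir; ++d)
    for (int p = 0; p < pmax; ++p) shell_count[shell_map(p, d)] += 1.0;
  std::vector<double> Ap(pmax), Bp(pmax);
  int imeas = 0;

  std::vector<double> cand(3 * nb);
  std::vector<int> order(np);
  long acc_prod = 0, att_prod = 0;  // post burn-in
  long acc_win = 0, att_win = 0;    // tuning window
  int isample = 0;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int i = 0; i < np; ++i) order[i] = i;
    for (int i = np - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);

    for (int t = 0; t < np; ++t) {
      const int k = order[t];
      double e0, w0;
      s.mol_energy(k, &s.world[3 * nb * k], &s.com[3 * k], e0, w0);

      double ncom[3];
      for (int d = 0; d < 3; ++d) {
        ncom[d] = s.com[3 * k + d] + (2.0 * rng.unif() - 1.0) * max_trans;
        ncom[d] -= L * std::floor(ncom[d] / L);
      }
      // rotation: uniform axis, angle uniform in (0, max_rot]
      const double z = 2.0 * rng.unif() - 1.0;
      const double phi = 2.0 * M_PI * rng.unif();
      const double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
      const double ang = (1.0 - rng.unif()) * max_rot;
      const double sh = std::sin(0.5 * ang);
      double dq[4] = {std::cos(0.5 * ang), rxy * std::cos(phi) * sh,
                      rxy * std::sin(phi) * sh, z * sh};
      double nq[4];
      quat_mult(dq, &s.quat[4 * k], nq);
      quat_normalize(nq);
      place(s.tmpl.data(), nb, ncom, nq, cand.data());

      bool in_prod = sweep > burn_in;
      if (in_prod) ++att_prod; else ++att_win;

      double e1, w1;
      bool ok = s.mol_energy(k, cand.data(), ncom, e1, w1);
      bool accept = false;
      if (ok) {
        const double dU = (e1 - e0) + eps * (w1 - w0);
        accept = dU <= 0.0 || rng.unif() < std::exp(-dU);
      }
      if (accept) {
        std::copy(cand.begin(), cand.end(), s.world.begin() + 3 * nb * k);
        for (int d = 0; d < 3; ++d) s.com[3 * k + d] = ncom[d];
        for (int d = 0; d < 4; ++d) s.quat[4 * k + d] = nq[d];
        E_elec += e1 - e0;
        E_w += w1 - w0;
        if (in_prod) ++acc_prod; else ++acc_win;
      }
    }

    if (tune && sweep <= burn_in && sweep % 50 == 0 && att_win > 0) {
      const double r = (double)acc_win / att_win;
      const double f = r > target_acc ? 1.15 : 0.85;
      max_trans = std::min(0.5 * L, std::max(0.01, max_trans * f));
      max_rot = std::min(M_PI, std::max(0.005, max_rot * f));
      acc_win = att_win = 0;
    }

    if (ndir > 0 && sweep > burn_in && intensity_stride > 0 &&
        (sweep - burn_in) % intensity_stride == 0 && imeas < n_imeas) {
      const int ntot = np * nb;
      const double* W = s.world.data();
      for (int d = 0; d < ndir; ++d) {
        const double qx = base_qvecs(d, 0), qy = base_qvecs(d, 1),
                     qz = base_qvecs(d, 2);
        std::fill(Ap.begin(), Ap.end(), 0.0);
        std::fill(Bp.begin(), Bp.end(), 0.0);
        for (int i = 0; i < ntot; ++i) {
          const double th =
              qx * W[3 * i] + qy * W[3 * i + 1] + qz * W[3 * i + 2];
          const double c0 = std::cos(th), s0 = std::sin(th);
          double c = c0, sn = s0;
          for (int p = 0; p < pmax; ++p) {
            Ap[p] += sn;
            Bp[p] += c;
            const double cn = c * c0 - sn * s0;
            sn = c * s0 + sn * c0;
            c = cn;
          }
        }
        for (int p = 0; p < pmax; ++p)
          inten(imeas, shell_map(p, d)) += (Ap[p] * Ap[p] + Bp[p] * Bp[p]) / ntot;
      }
      for (int sdx = 0; sdx < n_shells; ++sdx)
        inten(imeas, sdx) /= shell_count[sdx];
      ++imeas;
    }

    if (sweep > burn_in && (sweep - burn_in) % std::max(1, sample_stride) == 0 &&
        isample < n_samples) {
      if (record_frames)
        for (int i = 0; i < 3 * np * nb; ++i) frames(isample, i) = s.world[i];
      for (int i = 0; i < 3 * np; ++i) com_trace(isample, i) = s.com[i];
      for (int i = 0; i < 4 * np; ++i) quat_trace(isample, i) = s.quat[i];
      e_elec[isample] = E_elec;
      e_w[isample] = E_w;
      ++isample;
    }
  }

  NumericMatrix fcom(np, 3), fquat(np, 4);
  for (int i = 0; i < np; ++i) {
    for (int k = 0; k < 3; ++k) fcom(i, k) = s.com[3 * i + k];
    for (int k = 0; k < 4; ++k) fquat(i, k) = s.quat[4 * i + k];
  }
  return List::create(
      _["frames"] = frames, _["com_trace"] = com_trace,
      _["quat_trace"] = quat_trace, _["e_elec"] = e_elec, _["e_w"] = e_w,
      _["E_elec"] = E_elec, _["E_w"] = E_w,
      _["acceptance"] = att_prod > 0 ? (double)acc_prod / att_prod : NA_REAL,
      _["max_trans"] = max_trans, _["max_rot"] = max_rot,
      _["final_com"] = fcom, _["final_quat"] = fquat,
      _["n_samples"] = isample, _["intensity"] = inten,
      _["n_intensity"] = imeas);
}

// Lattice sums for the scattering intensity: per q-vector,
// [ (sum_i sin q.r_i)^2 + (sum_i cos q.r_i)^2 ] / N.
// [[Rcpp::export]]
NumericVector cpp_intensity(NumericMatrix coords, NumericMatrix qvecs) {
  const int n = coords.nrow(), m = qvecs.nrow();
  NumericVector out(m);
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0);
    y[i] = coords(i, 1);
    z[i] = coords(i, 2);
  }
  for (int k = 0; k < m; ++k) {
    const double qx = qvecs(k, 0), qy = qvecs(k, 1), qz = qvecs(k, 2);
    double A = 0.0, B = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = qx * x[i] + qy * y[i] + qz * z[i];
      A += std::sin(d);
      B += std::cos(d);
    }
    out[k] = (A * A + B * B) / n;
  }
  return out;
}

// Constant-pH titration MC on a fixed geometry.  J is the n_sites x n_charged
// Yukawa coupling matrix lB*exp(-r/lD)/r between titratable sites and all
// potentially charged beads (sites plus fixed charges); site_index maps each
// site to its column in J (self-interaction excluded via that column).
// dq_deprot[i] = charge change on deprotonation; dmu_deprot[i] =
// ln(10)*(pKa_i - pH).  Returns per-sweep net charge trace and final state.
// [[Rcpp::export]]
List cpp_titrate(NumericMatrix J, IntegerVector site_col, NumericVector q_fixed,
                 NumericVector q_prot, NumericVector q_deprot,
                 LogicalVector protonated0, NumericVector dmu_deprot,
                 double fixed_net, int n_sweeps, int moves_per_sweep,
                 double seed) {
  const int ns = site_col.size();
  const int ncol = J.ncol();
  Xoshiro rng((uint64_t)seed);
  std::vector<int> prot(ns);
  std::vector<double> qcol(ncol);  // current charge per J column
  for (int c = 0; c < ncol; ++c) qcol[c] = q_fixed[c];
  double net = fixed_net;
  for (int i = 0; i < ns; ++i) {
    prot[i] = protonated0[i] ? 1 : 0;
    const double qi = prot[i] ? q_prot[i] : q_deprot[i];
    qcol[site_col[i]] = qi;
    net += qi;
  }
  NumericMatrix trace(n_sweeps, 1);
  NumericMatrix site_trace(n_sweeps, ns);
  long acc = 0, att = 0;

  // the per-sweep trace is the time average over the sweep's moves (an
  // isolated site at pH = pKa flips deterministically, so end-of-sweep
  // snapshots would alias with even move counts)
  std::vector<double> site_acc(ns);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    double net_acc = 0.0;
    std::fill(site_acc.begin(), site_acc.end(), 0.0);
    for (int mv = 0; mv < moves_per_sweep; ++mv) {
      const int i = rng.below(ns);
      const int ci = site_col[i];
      const double q_old = prot[i] ? q_prot[i] : q_deprot[i];
      const double q_new = prot[i] ? q_deprot[i] : q_prot[i];
      const double dq = q_new - q_old;
      double sumJq = 0.0;
      for (int c = 0; c < ncol; ++c)
        if (c != ci) sumJq += J(i, c) * qcol[c];
      double dU = dq * sumJq;
      dU += prot[i] ? dmu_deprot[i] : -dmu_deprot[i];
      ++att;
      if (dU <= 0.0 || rng.unif() < std::exp(-dU)) {
        prot[i] = 1 - prot[i];
        qcol[ci] = q_new;
        net += dq;
        ++acc;
      }
      net_acc += net;
      for (int k = 0; k < ns; ++k)
        site_acc[k] += prot[k] ? q_prot[k] : q_deprot[k];
    }
    trace(sweep, 0) = net_acc / moves_per_sweep;
    for (int i = 0; i < ns; ++i)
      site_trace(sweep, i) = site_acc[i] / moves_per_sweep;
  }
  LogicalVector pfin(ns);
  for (int i = 0; i < ns; ++i) pfin[i] = prot[i] == 1;
  return List::create(_["trace"] = trace, _["site_trace"] = site_trace,
                      _["protonated"] = pfin,
                      _["acceptance"] = att > 0 ? (double)acc / att : NA_REAL);
}
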