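#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Internal-coordinate chain builder (NeRF placement) and constant-force
// torsional energy used by both the Metropolis sampler and the quadrature
// grid. Atom seeding: atom 0 at the origin, atom 1 on +x, atom 2 in the
// xy-plane with positive y. All angles arrive in radians here.

static const double PN_ANGSTROM_TO_KJMOL = 0.06022; // 1 pN*A in kJ/mol
static const double KB_KJMOL = 0.0083145;           // kJ/(mol*K)

struct ModelC {
  int n_atoms;
  std::vector<int> ref1, ref2, ref3;   // 0-based; -1 where unused (seed atoms)
  std::vector<double> blen;            // Angstrom
  std::vector<double> bang;            // radians, angle ref1-..-self at ref1? stored per atom
  std::vector<int> dih_idx;            // 0-based index into conformation, or -1
  std::vector<double> dih_fixed;       // radians, used when dih_idx < 0
  int n_dih;
  std::vector<double> V1, V2, V3, g1, g2, g3; // Fourier params per rotatable dihedral
  int pull_i, pull_j, ca_i, ca_j;      // 0-based
};

static ModelC unpack_model(const List& m) {
  ModelC mc;
  IntegerMatrix refs = m["refs"];             // n_atoms x 3, 0-based, -1 = unused
  NumericVector blen = m["bond_length"];
  NumericVector bang = m["bond_angle_rad"];
  IntegerVector didx = m["dih_idx0"];
  NumericVector dfix = m["dih_fixed_rad"];
  NumericMatrix V = m["fourier_v"];           // n_dih x 3 (kJ/mol)
  NumericMatrix G = m["fourier_gamma_rad"];   // n_dih x 3
  IntegerVector pp = m["pull_pair0"];
  IntegerVector cp = m["calpha_pair0"];
  mc.n_atoms = blen.size();
  mc.ref1.resize(mc.n_atoms); mc.ref2.resize(mc.n_atoms); mc.ref3.resize(mc.n_atoms);
  mc.blen.resize(mc.n_atoms); mc.bang.resize(mc.n_atoms);
  mc.dih_idx.resize(mc.n_atoms); mc.dih_fixed.resize(mc.n_atoms);
  for (int i = 0; i < mc.n_atoms; ++i) {
    mc.ref1[i] = refs(i, 0); mc.ref2[i] = refs(i, 1); mc.ref3[i] = refs(i, 2);
    mc.blen[i] = blen[i]; mc.bang[i] = bang[i];
    mc.dih_idx[i] = didx[i]; mc.dih_fixed[i] = dfix[i];
  }
  mc.n_dih = V.nrow();
  mc.V1.resize(mc.n_dih); mc.V2.resize(mc.n_dih); mc.V3.resize(mc.n_dih);
  mc.g1.resize(mc.n_dih); mc.g2.resize(mc.n_dih); mc.g3.resize(mc.n_dih);
  for (int k = 0; k < mc.n_dih; ++k) {
    mc.V1[k] = V(k, 0); mc.V2[k] = V(k, 1); mc.V3[k] = V(k, 2);
    mc.g1[k] = G(k, 0); mc.g2[k] = G(k, 1); mc.g3[k] = G(k, 2);
  }
  mc.pull_i = pp[0]; mc.pull_j = pp[1];
  mc.ca_i = cp[0]; mc.ca_j = cp[1];
  return mc;
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double norm3(const double* a) {
  return std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
}

// Build Cartesian coordinates for one conformation (radians). coords is
// pre-allocated n_atoms*3 (row-major per atom).
static void build_chain(const ModelC& m, const double* conf, double* coords) {
  // seed atoms
  coords[0] = 0.0; coords[1] = 0.0; coords[2] = 0.0;
  if (m.n_atoms > 1) {
    coords[3] = m.blen[1]; coords[4] = 0.0; coords[5] = 0.0;
  }
  if (m.n_atoms > 2) {
    const double* p = coords + 3 * m.ref1[2];
    double th = m.bang[2];
    coords[6] = p[0] - m.blen[2] * std::cos(th);
    coords[7] = p[1] + m.blen[2] * std::sin(th);
    coords[8] = p[2];
  }
  for (int i = 3; i < m.n_atoms; ++i) {
    const double* C = coords + 3 * m.ref1[i]; // parent
    const double* B = coords + 3 * m.ref2[i]; // grandparent
    const double* A = coords + 3 * m.ref3[i]; // great-grandparent
    double phi = (m.dih_idx[i] >= 0) ? conf[m.dih_idx[i]] : m.dih_fixed[i];
    double th = m.bang[i], r = m.blen[i];
    double ab[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double bc[3] = {C[0] - B[0], C[1] - B[1], C[2] - B[2]};
    double nbc = norm3(bc);
    bc[0] /= nbc; bc[1] /= nbc; bc[2] /= nbc;
    double n[3];
    cross3(ab, bc, n);
    double nn = norm3(n);
    if (nn < 1e-8) stop("ill-conditioned internal reference frame (collinear) at atom %d", i + 1);
    n[0] /= nn; n[1] /= nn; n[2] /= nn;
    double mvec[3];
    cross3(n, bc, mvec);
    double dl0 = -r * std::cos(th);
    double dl1 = r * std::sin(th) * std::cos(phi);
    double dl2 = r * std::sin(th) * std::sin(phi);
    double* D = coords + 3 * i;
    D[0] = C[0] + bc[0] * dl0 + mvec[0] * dl1 + n[0] * dl2;
    D[1] = C[1] + bc[1] * dl0 + mvec[1] * dl1 + n[1] * dl2;
    D[2] = C[2] + bc[2] * dl0 + mvec[2] * dl1 + n[2] * dl2;
  }
}

static inline double dist3(const double* a, const double* b) {
  double d0 = a[0] - b[0], d1 = a[1] - b[1], d2 = a[2] - b[2];
  return std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
}

// torsional Fourier energy, conformation in radians
static double torsion_energy(const ModelC& m, const double* conf) {
  double e = 0.0;
  for (int k = 0; k < m.n_dih; ++k) {
    double p = conf[k];
    e += 0.5 * (m.V1[k] * (1.0 + std::cos(p - m.g1[k])) +
                m.V2[k] * (1.0 + std::cos(2.0 * p - m.g2[k])) +
                m.V3[k] * (1.0 + std::cos(3.0 * p - m.g3[k])));
  }
  return e;
}

// [[Rcpp::export(name = ".nerfBuild")]]
NumericMatrix nerf_build(List model_cpp, NumericVector conf_deg) {
  ModelC m = unpack_model(model_cpp);
  if ((int)conf_deg.size() != m.n_dih)
    stop("conformation has %d dihedrals; model declares %d", (int)conf_deg.size(), m.n_dih);
  std::vector<double> conf(m.n_dih);
  for (int k = 0; k < m.n_dih; ++k) conf[k] = conf_deg[k] * M_PI / 180.0;
  std::vector<double> coords(3 * m.n_atoms);
  build_chain(m, conf.data(), coords.data());
  NumericMatrix out(m.n_atoms, 3);
  for (int i = 0; i < m.n_atoms; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = coords[3 * i + j];
  return out;
}

// [[Rcpp::export(name = ".energyBatch")]]
List energy_batch(List model_cpp, NumericMatrix confs_deg, double force_pN) {
  ModelC m = unpack_model(model_cpp);
  int n = confs_deg.nrow();
  if (confs_deg.ncol() != m.n_dih) stop("conformation matrix has wrong width");
  NumericVector energy(n), R(n), dca(n);
  std::vector<double> conf(m.n_dih), coords(3 * m.n_atoms);
  for (int s = 0; s < n; ++s) {
    for (int k = 0; k < m.n_dih; ++k) conf[k] = confs_deg(s, k) * M_PI / 180.0;
    build_chain(m, conf.data(), coords.data());
    double r = dist3(&coords[3 * m.pull_i], &coords[3 * m.pull_j]);
    R[s] = r;
    dca[s] = dist3(&coords[3 * m.ca_i], &coords[3 * m.ca_j]);
    energy[s] = torsion_energy(m, conf.data()) - force_pN * r * PN_ANGSTROM_TO_KJMOL;
  }
  return List::create(_["energy"] = energy, _["R"] = R, _["d_calpha"] = dca);
}

// Single-dihedral Gaussian-step Metropolis sampler in the isotensional
// ensemble E(phi) - F*R(phi). Uses R's RNG: deterministic under set.seed().
// [[Rcpp::export(name = ".mcRun")]]
List mc_run(List model_cpp, double force_pN, double temp_K,
            double n_steps_d, double n_burnin_d, int thin,
            double step_deg, NumericVector init_deg) {
  ModelC m = unpack_model(model_cpp);
  long n_steps = (long)n_steps_d, n_burnin = (long)n_burnin_d;
  if (temp_K <= 0) stop("temperature must be positive");
  if (step_deg <= 0 || step_deg > 180) stop("step width must lie in (0, 180] degrees");
  if (n_steps <= n_burnin) stop("n_steps must exceed burn-in");
  double beta = 1.0 / (KB_KJMOL * temp_K);
  double step_rad = step_deg * M_PI / 180.0;
  const double TWO_PI = 2.0 * M_PI;

  std::vector<double> conf(m.n_dih), coords(3 * m.n_atoms);
  for (int k = 0; k < m.n_dih; ++k) conf[k] = init_deg[k] * M_PI / 180.0;
  build_chain(m, conf.data(), coords.data());
  double R = dist3(&coords[3 * m.pull_i], &coords[3 * m.pull_j]);
  double E = torsion_energy(m, conf.data()) - force_pN * R * PN_ANGSTROM_TO_KJMOL;

  long n_keep = (n_steps - n_burnin) / thin;
  NumericMatrix dih_out(n_keep, m.n_dih);
  NumericVector R_out(n_keep), dca_out(n_keep), E_out(n_keep);
  long kept = 0, accepted = 0;
  RNGScope scope;

  for (long s = 0; s < n_steps; ++s) {
    int k = (int)(unif_rand() * m.n_dih);
    if (k == m.n_dih) k = m.n_dih - 1;
    double old_phi = conf[k];
    double prop = old_phi + norm_rand() * step_rad;
    prop -= TWO_PI * std::floor(prop / TWO_PI);   // periodic wrap to [0, 2pi)
    conf[k] = prop;
    build_chain(m, conf.data(), coords.data());
    double Rn = dist3(&coords[3 * m.pull_i], &coords[3 * m.pull_j]);
    double En = torsion_energy(m, conf.data()) - force_pN * Rn * PN_ANGSTROM_TO_KJMOL;
    double dE = En - E;
    if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
      E = En; R = Rn; ++accepted;
    } else {
      conf[k] = old_phi;
    }
    if (s >= n_burnin && ((s - n_burnin) % thin == 0) && kept < n_keep) {
      // rebuild for the current (possibly reverted) conformation
      build_chain(m, conf.data(), coords.data());
      for (int j = 0; j < m.n_dih; ++j) {
        double deg = conf[j] * 180.0 / M_PI;
        deg -= 360.0 * std::floor(deg / 360.0);
        dih_out(kept, j) = deg;
      }
      R_out[kept] = dist3(&coords[3 * m.pull_i], &coords[3 * m.pull_j]);
      dca_out[kept] = dist3(&coords[3 * m.ca_i], &coords[3 * m.ca_j]);
      E_out[kept] = torsion_energy(m, conf.data()) -
        force_pN * R_out[kept] * PN_ANGSTROM_TO_KJMOL;
      ++kept;
    }
  }
  return List::create(_["dihedrals"] = dih_out, _["R"] = R_out,
                      _["d_calpha"] = dca_out, _["energy"] = E_out,
                      _["accept_rate"] = (double)accepted / (double)n_steps);
}
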