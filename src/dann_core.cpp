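// Numerical core: internal coordinates with analytic Cartesian Jacobians,
// the analytic 3-state diabatic oracle potential, symmetric 3x3
// adiabatization with a fixed sign convention, exact two-level amplitude
// propagation for fewest-switches hopping, and an ensemble trajectory
// runner specialised to the oracle (used for brute-force reference yields).
//
// Units: kcal/mol, Angstrom, fs, amu, radians internally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static const double HBAR_KCAL_FS = 15.178729;     // hbar in kcal/mol * fs
static const double ACC_CONV = 4.184e-4;          // (kcal/mol/A)/amu -> A/fs^2
static const double KIN_CONV = 1.0 / 4.184e-4;    // amu*A^2/fs^2 -> kcal/mol

// ---------------------------------------------------------------------------
// internal coordinates
// ---------------------------------------------------------------------------

// bond length and gradient w.r.t. the two atoms
static double bond_val(const mat& pos, int i, int j, mat* grad = nullptr) {
  arma::rowvec d = pos.row(i) - pos.row(j);
  double r = arma::norm(d);
  if (grad) {
    grad->zeros();
    grad->row(i) = d / r;
    grad->row(j) = -d / r;
  }
  return r;
}

// angle i-j-k (at j), radians
static double angle_val(const mat& pos, int i, int j, int k, mat* grad = nullptr) {
  arma::rowvec u = pos.row(i) - pos.row(j);
  arma::rowvec v = pos.row(k) - pos.row(j);
  double nu = arma::norm(u), nv = arma::norm(v);
  arma::rowvec uh = u / nu, vh = v / nv;
  double c = arma::dot(uh, vh);
  c = std::max(-1.0, std::min(1.0, c));
  double th = std::acos(c);
  if (grad) {
    double s = std::sqrt(std::max(1.0 - c * c, 1e-14));
    arma::rowvec gi = -(vh - c * uh) / (nu * s);
    arma::rowvec gk = -(uh - c * vh) / (nv * s);
    grad->zeros();
    grad->row(i) = gi;
    grad->row(k) = gk;
    grad->row(j) = -(gi + gk);
  }
  return th;
}

// signed dihedral i-j-k-l in (-pi, pi], IUPAC sign convention
static double dihedral_val(const mat& pos, int i, int j, int k, int l,
                           mat* grad = nullptr) {
  arma::rowvec b1 = pos.row(j) - pos.row(i);
  arma::rowvec b2 = pos.row(k) - pos.row(j);
  arma::rowvec b3 = pos.row(l) - pos.row(k);
  arma::rowvec n1 = arma::cross(b1, b2);
  arma::rowvec n2 = arma::cross(b2, b3);
  double nb2 = arma::norm(b2);
  double x = arma::dot(n1, n2);
  double y = arma::dot(arma::cross(n1, n2), b2 / nb2);
  double phi = std::atan2(y, x);
  if (grad) {
    // Blondel & Karplus formulas
    double n1sq = arma::dot(n1, n1), n2sq = arma::dot(n2, n2);
    arma::rowvec F = -(nb2 / n1sq) * n1;
    arma::rowvec L = (nb2 / n2sq) * n2;
    double p = arma::dot(b1, b2) / (nb2 * nb2);
    double q = arma::dot(b3, b2) / (nb2 * nb2);
    grad->zeros();
    grad->row(i) = F;
    grad->row(l) = L;
    grad->row(j) = -(1.0 + p) * F + q * L;
    grad->row(k) = p * F - (1.0 + q) * L;
  }
  return phi;
}

// [[Rcpp::export]]
double dihedral_cpp(const arma::mat& pos, const IntegerVector& idx) {
  return dihedral_val(pos, idx[0] - 1, idx[1] - 1, idx[2] - 1, idx[3] - 1);
}

// Values and Jacobians for descriptor construction.  bonds: m x 2,
// angles: m x 3, torsions: m x 4 (1-based).  Jacobians are m x 3N
// (atom-major: columns x1 y1 z1 x2 ...).
// [[Rcpp::export]]
List internal_coords_cpp(const arma::mat& pos, const IntegerMatrix& bonds,
                         const IntegerMatrix& angles, const IntegerMatrix& torsions,
                         bool jacobian = true) {
  int n = pos.n_rows;
  mat g(n, 3);
  auto flat = [&](const mat& gm) {
    arma::rowvec out = arma::vectorise(gm.t()).t();
    return out;
  };

  int nb = bonds.nrow(), na = angles.nrow(), nt = torsions.nrow();
  vec bv(nb), av(na), tv(nt);
  mat Jb(nb, 3 * n, arma::fill::zeros), Ja(na, 3 * n, arma::fill::zeros),
      Jt(nt, 3 * n, arma::fill::zeros);
  for (int m = 0; m < nb; ++m) {
    bv[m] = bond_val(pos, bonds(m, 0) - 1, bonds(m, 1) - 1, jacobian ? &g : nullptr);
    if (jacobian) Jb.row(m) = flat(g);
  }
  for (int m = 0; m < na; ++m) {
    av[m] = angle_val(pos, angles(m, 0) - 1, angles(m, 1) - 1, angles(m, 2) - 1,
                      jacobian ? &g : nullptr);
    if (jacobian) Ja.row(m) = flat(g);
  }
  for (int m = 0; m < nt; ++m) {
    tv[m] = dihedral_val(pos, torsions(m, 0) - 1, torsions(m, 1) - 1,
                         torsions(m, 2) - 1, torsions(m, 3) - 1,
                         jacobian ? &g : nullptr);
    if (jacobian) Jt.row(m) = flat(g);
  }
  return List::create(_["bonds"] = bv, _["angles"] = av, _["torsions"] = tv,
                      _["J_bonds"] = Jb, _["J_angles"] = Ja, _["J_torsions"] = Jt);
}

// ---------------------------------------------------------------------------
// oracle diabatic potential
// ---------------------------------------------------------------------------

struct Oracle {
  arma::ivec core;          // 4 atoms (0-based): C N N C
  mat diag_cos;             // 3 x K: d_ss torsional profile sum_k C(s,k) cos(k phi)
  vec dip_amp;              // per-state planar dip amplitude, * ((1-cos phi)/2)^p
  int dip_pow;
  vec bend_k, bend_c;       // per-state bend stiffness / center (both core angles)
  mat coup_cos;             // 3 x K rows (01, 02, 12)
  arma::imat bond_idx; vec bond_r0, bond_k;
  arma::imat ang_idx;  vec ang_t0, ang_k;
  arma::imat tor_idx;  vec tor_k, tor_d; arma::ivec tor_n;
};

static Oracle parse_oracle(const List& spec) {
  Oracle o;
  o.core = arma::conv_to<arma::ivec>::from(as<arma::vec>(spec["core"])) - 1;
  o.diag_cos = as<mat>(spec["diag_cos"]);
  o.dip_amp = as<vec>(spec["dip_amp"]);
  o.dip_pow = as<int>(spec["dip_pow"]);
  o.bend_k = as<vec>(spec["bend_k"]);
  o.bend_c = as<vec>(spec["bend_c"]);
  o.coup_cos = as<mat>(spec["coup_cos"]);
  List bath = spec["bath"];
  o.bond_idx = arma::conv_to<arma::imat>::from(as<arma::mat>(bath["bond_idx"]));
  o.bond_r0 = as<vec>(bath["bond_r0"]);
  o.bond_k = as<vec>(bath["bond_k"]);
  o.ang_idx = arma::conv_to<arma::imat>::from(as<arma::mat>(bath["ang_idx"]));
  o.ang_t0 = as<vec>(bath["ang_t0"]);
  o.ang_k = as<vec>(bath["ang_k"]);
  o.tor_idx = arma::conv_to<arma::imat>::from(as<arma::mat>(bath["tor_idx"]));
  o.tor_k = as<vec>(bath["tor_k"]);
  o.tor_n = arma::conv_to<arma::ivec>::from(as<arma::vec>(bath["tor_n"]));
  o.tor_d = as<vec>(bath["tor_d"]);
  return o;
}

// evaluate d (3x3) and, if grad != nullptr, gradients of the six independent
// elements in order 00,11,22,01,02,12 (each N x 3)
static void oracle_eval(const Oracle& o, const mat& pos, mat& d,
                        std::vector<mat>* grad) {
  int n = pos.n_rows;
  int K = o.diag_cos.n_cols;
  mat gphi(n, 3), ga1(n, 3), ga2(n, 3), gtmp(n, 3);
  bool want = grad != nullptr;

  double phi = dihedral_val(pos, o.core[0], o.core[1], o.core[2], o.core[3],
                            want ? &gphi : nullptr);
  double a1 = angle_val(pos, o.core[0], o.core[1], o.core[2], want ? &ga1 : nullptr);
  double a2 = angle_val(pos, o.core[1], o.core[2], o.core[3], want ? &ga2 : nullptr);

  // shared harmonic bath on the diagonal
  double ebath = 0.0;
  mat gbath(n, 3, arma::fill::zeros);
  for (uword m = 0; m < o.bond_idx.n_rows; ++m) {
    double r = bond_val(pos, o.bond_idx(m, 0) - 1, o.bond_idx(m, 1) - 1,
                        want ? &gtmp : nullptr);
    double dr = r - o.bond_r0[m];
    ebath += 0.5 * o.bond_k[m] * dr * dr;
    if (want) gbath += o.bond_k[m] * dr * gtmp;
  }
  for (uword m = 0; m < o.ang_idx.n_rows; ++m) {
    double th = angle_val(pos, o.ang_idx(m, 0) - 1, o.ang_idx(m, 1) - 1,
                          o.ang_idx(m, 2) - 1, want ? &gtmp : nullptr);
    double dt_ = th - o.ang_t0[m];
    ebath += 0.5 * o.ang_k[m] * dt_ * dt_;
    if (want) gbath += o.ang_k[m] * dt_ * gtmp;
  }
  for (uword m = 0; m < o.tor_idx.n_rows; ++m) {
    double ph = dihedral_val(pos, o.tor_idx(m, 0) - 1, o.tor_idx(m, 1) - 1,
                             o.tor_idx(m, 2) - 1, o.tor_idx(m, 3) - 1,
                             want ? &gtmp : nullptr);
    int nn = o.tor_n[m];
    ebath += o.tor_k[m] * (1.0 + std::cos(nn * ph - o.tor_d[m]));
    if (want) gbath += -o.tor_k[m] * nn * std::sin(nn * ph - o.tor_d[m]) * gtmp;
  }

  d.zeros(3, 3);
  if (want) {
    grad->assign(6, mat(n, 3, arma::fill::zeros));
  }
  // diagonals
  for (int s = 0; s < 3; ++s) {
    double val = 0.0, dval = 0.0;  // torsional part and d/dphi
    for (int k = 0; k < K; ++k) {
      val += o.diag_cos(s, k) * std::cos(k * phi);
      dval += -o.diag_cos(s, k) * k * std::sin(k * phi);
    }
    if (o.dip_amp[s] != 0.0) {
      double u = 0.5 * (1.0 - std::cos(phi));
      val += -o.dip_amp[s] * std::pow(u, o.dip_pow);
      dval += -o.dip_amp[s] * o.dip_pow * std::pow(u, o.dip_pow - 1) *
              0.5 * std::sin(phi);
    }
    double k_s = o.bend_k[s], c_s = o.bend_c[s];
    double bend = 0.5 * k_s * ((a1 - c_s) * (a1 - c_s) + (a2 - c_s) * (a2 - c_s));
    d(s, s) = val + bend + ebath;
    if (want) {
      (*grad)[s] = dval * gphi + k_s * (a1 - c_s) * ga1 + k_s * (a2 - c_s) * ga2 +
                   gbath;
    }
  }
  // couplings (01, 02, 12)
  int pr[3][2] = {{0, 1}, {0, 2}, {1, 2}};
  for (int p = 0; p < 3; ++p) {
    double val = 0.0, dval = 0.0;
    for (int k = 0; k < K; ++k) {
      val += o.coup_cos(p, k) * std::cos(k * phi);
      dval += -o.coup_cos(p, k) * k * std::sin(k * phi);
    }
    d(pr[p][0], pr[p][1]) = d(pr[p][1], pr[p][0]) = val;
    if (want) (*grad)[3 + p] = dval * gphi;
  }
}

// [[Rcpp::export]]
List oracle_eval_cpp(const List& spec, const arma::mat& pos, bool gradient = true) {
  Oracle o = parse_oracle(spec);
  mat d;
  if (!gradient) {
    oracle_eval(o, pos, d, nullptr);
    return List::create(_["d"] = d);
  }
  std::vector<mat> g;
  oracle_eval(o, pos, d, &g);
  int n = pos.n_rows;
  NumericVector arr(3 * 3 * n * 3);
  arr.attr("dim") = IntegerVector::create(3, 3, n, 3);
  int pairs[6][2] = {{0, 0}, {1, 1}, {2, 2}, {0, 1}, {0, 2}, {1, 2}};
  for (int p = 0; p < 6; ++p) {
    int a = pairs[p][0], b = pairs[p][1];
    for (int i = 0; i < n; ++i)
      for (int x = 0; x < 3; ++x) {
        double v = g[p](i, x);
        arr[a + 3 * b + 9 * i + 9 * n * x] = v;
        arr[b + 3 * a + 9 * i + 9 * n * x] = v;
      }
  }
  return List::create(_["d"] = d, _["grad"] = arr);
}

// ---------------------------------------------------------------------------
// adiabatization
// ---------------------------------------------------------------------------

// ascending eigenvalues; per-column sign so largest-|.| entry is positive,
// or continuity against a previous rotation if given
static void adiab3(const mat& d, vec& E, mat& U, const mat* Uprev) {
  arma::eig_sym(E, U, d);  // ascending
  for (int c = 0; c < 3; ++c) {
    double s;
    if (Uprev) {
      s = arma::dot(Uprev->col(c), U.col(c)) >= 0 ? 1.0 : -1.0;
    } else {
      arma::uword imax = arma::abs(U.col(c)).index_max();
      s = U(imax, c) >= 0 ? 1.0 : -1.0;
    }
    U.col(c) *= s;
  }
}

// [[Rcpp::export]]
List adiab3_cpp(const arma::mat& d) {
  vec E; mat U;
  adiab3(d, E, U, nullptr);
  return List::create(_["energies"] = E, _["u"] = U);
}

// ---------------------------------------------------------------------------
// two-level amplitude propagation (exact piecewise-constant exponential)
// ---------------------------------------------------------------------------

// Propagates c = (c0, c1) across one nuclear step split into nsub substeps,
// linearly interpolating E0, E1 and the scalar coupling v.k01 between the
// step endpoints.  Accumulates the fewest-switches hop probability out of
// `active` as one minus the product of substep survival probabilities
// (the correct composition of independent substep decisions; a plain sum
// over-counts hops whenever the per-step population transfer is large).
static double propagate_tdse(arma::cx_vec& c, double E0a, double E0b, double E1a,
                             double E1b, double vka, double vkb, double dt,
                             int nsub, int active) {
  double survival = 1.0;
  double dts = dt / nsub;
  const std::complex<double> I(0.0, 1.0);
  for (int s = 0; s < nsub; ++s) {
    double f = (s + 0.5) / nsub;
    double E0 = E0a + f * (E0b - E0a);
    double E1 = E1a + f * (E1b - E1a);
    double vk = vka + f * (vkb - vka);
    // hop probability with current amplitudes (d_ab = v.k_ab, k_10 = -k_01)
    double dab = (active == 0) ? vk : -vk;
    int b = 1 - active;
    double pa = std::norm(c[active]);
    if (pa > 1e-12) {
      double flux = 2.0 * dab * std::real(std::conj(c[active]) * c[b]);
      if (flux > 0) {
        double gs = std::min(flux * dts / pa, 1.0);
        survival *= (1.0 - gs);
      }
    }
    // exact exponential of M*dts, M = [[-iE0/h, -vk], [vk, -iE1/h]]
    std::complex<double> m = -I * (E0 + E1) / (2.0 * HBAR_KCAL_FS);
    double w = std::sqrt(std::pow((E1 - E0) / (2.0 * HBAR_KCAL_FS), 2) + vk * vk);
    std::complex<double> e = std::exp(m * dts);
    double cw = std::cos(w * dts);
    double sw = (w > 1e-14) ? std::sin(w * dts) / w : dts;
    std::complex<double> M00 = -I * E0 / HBAR_KCAL_FS - m;
    std::complex<double> M11 = -I * E1 / HBAR_KCAL_FS - m;
    std::complex<double> n0 = e * (cw * c[0] + sw * (M00 * c[0] - vk * c[1]));
    std::complex<double> n1 = e * (cw * c[1] + sw * (vk * c[0] + M11 * c[1]));
    c[0] = n0; c[1] = n1;
  }
  return 1.0 - survival;
}

// [[Rcpp::export]]
List propagate_tdse_cpp(const arma::cx_vec& c, double E0a, double E0b, double E1a,
                        double E1b, double vka, double vkb, double dt, int nsub,
                        int active) {
  arma::cx_vec cc = c;
  double g = propagate_tdse(cc, E0a, E0b, E1a, E1b, vka, vkb, dt, nsub, active);
  return List::create(_["c"] = cc, _["g_hop"] = g);
}

// ---------------------------------------------------------------------------
// oracle trajectory runner (velocity Verlet + FSSH or ZN gap-minimum hopping)
// ---------------------------------------------------------------------------

struct EvalOut {
  vec E;        // 3 adiabatic energies
  mat U;        // 3x3
  mat f_active; // N x 3 force on active surface
  mat h01;      // N x 3
  double gap;
};

static void full_eval(const Oracle& o, const mat& pos, int active, const mat* Uprev,
                      EvalOut& out, std::vector<mat>& gbuf, bool need_h) {
  mat d;
  oracle_eval(o, pos, d, &gbuf);
  adiab3(d, out.E, out.U, Uprev);
  out.gap = out.E[1] - out.E[0];
  int n = pos.n_rows;
  // rotated gradients: (U^T grad U)_nm = sum over independent elements
  // weights for element p=(a,b): U(a,n)U(b,m) + (a!=b) U(b,n)U(a,m)
  int pairs[6][2] = {{0, 0}, {1, 1}, {2, 2}, {0, 1}, {0, 2}, {1, 2}};
  out.f_active.zeros(n, 3);
  if (need_h) out.h01.zeros(n, 3);
  for (int p = 0; p < 6; ++p) {
    int a = pairs[p][0], b = pairs[p][1];
    double wf = out.U(a, active) * out.U(b, active);
    if (a != b) wf += out.U(b, active) * out.U(a, active);
    out.f_active -= wf * gbuf[p];
    if (need_h) {
      double wh = out.U(a, 0) * out.U(b, 1);
      if (a != b) wh += out.U(b, 0) * out.U(a, 1);
      out.h01 += wh * gbuf[p];
    }
  }
}

static double kinetic(const mat& vel, const vec& mass) {
  double ke = 0.0;
  for (uword i = 0; i < vel.n_rows; ++i)
    ke += 0.5 * mass[i] * arma::dot(vel.row(i), vel.row(i));
  return ke * KIN_CONV;
}

// single oracle trajectory; returns summary fields
// scheme: 0 = fewest switches, 1 = ZN gap-minimum
static List oracle_traj_one(const Oracle& o, mat pos, mat vel, const vec& mass,
                            double dt, int nsub, double horizon, double relax,
                            int scheme, double deg_tol, std::mt19937_64& rng,
                            std::vector<double>* hop_t, std::vector<double>* hop_phi,
                            std::vector<int>* hop_acc) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  int n = pos.n_rows;
  int active = 1;
  double phi0 = dihedral_val(pos, o.core[0], o.core[1], o.core[2], o.core[3]);
  int start_cis = std::abs(phi0) < M_PI / 2 ? 1 : 0;
  arma::cx_vec c(2, arma::fill::zeros);
  c[1] = 1.0;  // vertical excitation to S1
  EvalOut ev, ev2;
  std::vector<mat> gbuf;
  bool fs = (scheme == 0);
  full_eval(o, pos, active, nullptr, ev, gbuf, fs);
  double t = 0.0;
  bool reached_ground = false, aborted = false;
  double s1_exit = NA_REAL;
  int n_frust = 0;
  double g2prev = NA_REAL, g1prev = NA_REAL;  // gap history for ZN
  mat accel(n, 3);

  auto calc_accel = [&](const mat& f, mat& a) {
    for (int i = 0; i < n; ++i) a.row(i) = f.row(i) * (ACC_CONV / mass[i]);
  };

  int max_steps = (int)std::ceil(horizon / dt);
  for (int step = 0; step < max_steps; ++step) {
    calc_accel(ev.f_active, accel);
    vel += 0.5 * dt * accel;
    pos += dt * vel;
    mat Uprev = ev.U;
    double E0a = ev.E[0], E1a = ev.E[1];
    double vka = 0.0;
    mat k01a;
    if (fs && ev.gap > deg_tol) {
      k01a = ev.h01 / ev.gap;
      vka = arma::accu(vel % k01a);
    }
    full_eval(o, pos, active, &Uprev, ev2, gbuf, fs);
    if (!ev2.E.is_finite() || !pos.is_finite()) { aborted = true; break; }
    calc_accel(ev2.f_active, accel);
    vel += 0.5 * dt * accel;
    t += dt;

    bool attempt = false;
    double p_hop = 0.0;
    mat dir;  // rescaling direction (FSSH: k01), empty for uniform
    if (fs) {
      double vkb = 0.0;
      mat k01b;
      if (ev2.gap > deg_tol) {
        k01b = ev2.h01 / ev2.gap;
        vkb = arma::accu(vel % k01b);
        dir = k01b / arma::norm(arma::vectorise(k01b));
      }
      p_hop = propagate_tdse(c, E0a, ev2.E[0], E1a, ev2.E[1], vka, vkb, dt, nsub,
                             active);
      attempt = (p_hop > 0) && (unif(rng) < p_hop) && dir.n_rows > 0;
    } else {
      // ZN: local gap minimum over three consecutive steps
      double g0 = ev2.gap;
      if (std::isfinite(g2prev) && g1prev < g2prev && g1prev < g0) {
        double curv = (g0 - 2.0 * g1prev + g2prev) / (dt * dt);
        if (curv > 1e-12) {
          p_hop = std::exp(-(M_PI / (2.0 * HBAR_KCAL_FS)) *
                           std::sqrt(std::pow(std::max(g1prev, 0.0), 3) / curv));
          attempt = unif(rng) < p_hop;
        }
      }
      g2prev = g1prev; g1prev = g0;
    }

    if (attempt) {
      int target = 1 - active;
      double dE = ev2.E[target] - ev2.E[active];
      bool ok = false;
      if (fs) {
        // rescale along the coupling direction: v_i -> v_i + gamma dir_i / m_i,
        // gamma solving KIN_CONV*(Ap g^2 + Bp g) = -dE
        double Ap = 0.0, Bp = 0.0;
        for (int i = 0; i < n; ++i) {
          Ap += 0.5 * arma::dot(dir.row(i), dir.row(i)) / mass[i];
          Bp += arma::dot(vel.row(i), dir.row(i));
        }
        Ap *= KIN_CONV; Bp *= KIN_CONV;
        double disc = Bp * Bp - 4.0 * Ap * dE;
        if (disc >= 0) {
          double r1 = (-Bp + std::sqrt(disc)) / (2.0 * Ap);
          double r2 = (-Bp - std::sqrt(disc)) / (2.0 * Ap);
          double gam = std::abs(r1) < std::abs(r2) ? r1 : r2;
          for (int i = 0; i < n; ++i) vel.row(i) += gam * dir.row(i) / mass[i];
          ok = true;
        }
      } else {
        double ke = kinetic(vel, mass);
        if (ke > dE) {
          vel *= std::sqrt(1.0 - dE / ke);
          ok = true;
        }
      }
      double phi_hop = dihedral_val(pos, o.core[0], o.core[1], o.core[2], o.core[3]);
      if (hop_t) {
        hop_t->push_back(t);
        hop_phi->push_back(phi_hop * 180.0 / M_PI);
        hop_acc->push_back(ok ? 1 : 0);
      }
      if (ok) {
        active = target;
        // recompute forces on the new surface
        full_eval(o, pos, active, &ev2.U, ev, gbuf, fs);
        if (active == 0) {
          reached_ground = true;
          s1_exit = t;
          break;  // relaxation handled below
        }
        continue;
      } else {
        ++n_frust;
      }
    }
    ev = ev2;
  }

  if (reached_ground && !aborted) {
    // ground-state relaxation window, no further hopping
    int nrel = (int)std::ceil(relax / dt);
    full_eval(o, pos, 0, nullptr, ev, gbuf, false);
    for (int s = 0; s < nrel; ++s) {
      calc_accel(ev.f_active, accel);
      vel += 0.5 * dt * accel;
      pos += dt * vel;
      mat Uprev = ev.U;
      full_eval(o, pos, 0, &Uprev, ev, gbuf, false);
      if (!ev.E.is_finite()) { aborted = true; break; }
      calc_accel(ev.f_active, accel);
      vel += 0.5 * dt * accel;
    }
  }

  double phi_end = dihedral_val(pos, o.core[0], o.core[1], o.core[2], o.core[3]);
  // the final isomer is only defined after relaxing on the ground state;
  // trajectories still excited at the horizon keep their initial isomer
  int final_cis = (reached_ground && !aborted)
                      ? (std::abs(phi_end) < M_PI / 2 ? 1 : 0)
                      : start_cis;
  return List::create(_["final_cis"] = final_cis,
                      _["reached_ground"] = reached_ground,
                      _["s1_exit"] = s1_exit, _["aborted"] = aborted,
                      _["n_frustrated"] = n_frust,
                      _["cnnc_end"] = phi_end * 180.0 / M_PI);
}

// Ensemble runner.  init_pos/init_vel: n_traj x (N*3) matrices (atom-major
// rows: x1 y1 z1 x2 ...).  Returns per-trajectory summaries plus flat hop
// records.
// [[Rcpp::export]]
List oracle_ensemble_cpp(const List& spec, const arma::mat& init_pos,
                         const arma::mat& init_vel, const arma::vec& masses,
                         double dt, int nsub, double horizon, double relax,
                         int scheme, double deg_tol, int seed,
                         bool record_hops = false) {
  Oracle o = parse_oracle(spec);
  int ntraj = init_pos.n_rows;
  int natom = masses.n_elem;
  IntegerVector final_cis(ntraj), reached(ntraj), nfrust(ntraj), aborted(ntraj);
  NumericVector s1_exit(ntraj), cnnc_end(ntraj);
  std::vector<double> all_hop_t, all_hop_phi;
  std::vector<int> all_hop_acc, all_hop_traj;
  std::mt19937_64 seeder((uint64_t)seed);
  for (int k = 0; k < ntraj; ++k) {
    mat pos(natom, 3), vel(natom, 3);
    for (int i = 0; i < natom; ++i)
      for (int x = 0; x < 3; ++x) {
        pos(i, x) = init_pos(k, 3 * i + x);
        vel(i, x) = init_vel(k, 3 * i + x);
      }
    std::mt19937_64 rng(seeder());
    std::vector<double> ht, hp;
    std::vector<int> ha;
    List res = oracle_traj_one(o, pos, vel, masses, dt, nsub, horizon, relax,
                               scheme, deg_tol, rng,
                               record_hops ? &ht : nullptr,
                               record_hops ? &hp : nullptr,
                               record_hops ? &ha : nullptr);
    final_cis[k] = as<int>(res["final_cis"]);
    reached[k] = as<bool>(res["reached_ground"]);
    s1_exit[k] = as<double>(res["s1_exit"]);
    aborted[k] = as<bool>(res["aborted"]);
    nfrust[k] = as<int>(res["n_frustrated"]);
    cnnc_end[k] = as<double>(res["cnnc_end"]);
    if (record_hops) {
      for (size_t m = 0; m < ht.size(); ++m) {
        all_hop_t.push_back(ht[m]);
        all_hop_phi.push_back(hp[m]);
        all_hop_acc.push_back(ha[m]);
        all_hop_traj.push_back(k + 1);
      }
    }
  }
  List out = List::create(_["final_cis"] = final_cis, _["reached_ground"] = reached,
                          _["s1_exit"] = s1_exit, _["aborted"] = aborted,
                          _["n_frustrated"] = nfrust, _["cnnc_end"] = cnnc_end);
  if (record_hops) {
    out["hop_traj"] = wrap(all_hop_traj);
    out["hop_time"] = wrap(all_hop_t);
    out["hop_cnnc"] = wrap(all_hop_phi);
    out["hop_accepted"] = wrap(all_hop_acc);
  }
  return out;
}
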