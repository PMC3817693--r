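// Numerical core: backbone torsions, smooth low-resolution energy terms with
// analytic Cartesian gradients, Gaussian map simulation, masked per-residue
// real-space correlation, and tricubic (prefiltered cubic B-spline)
// interpolation of FFT-convolved density score fields.
//
// Coordinate layout shared with R: a numeric array dim c(nres, 5, 3) with
// atom slots 1..5 = N, CA, C, O, CB (CB is the side-chain centroid; glycine
// carries a pseudo-CB). Column-major: idx = i + n*(a + 5*x).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double DEG = 180.0 / M_PI;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
static inline V3 operator+(const V3 &a, const V3 &b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3 &a, const V3 &b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3 &a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3 &a) { double n = norm(a); return (1.0 / n) * a; }

// 3x3 matrix (row-major) for the H-placement Jacobians
struct M3 {
  double m[9];
  M3() { for (int i = 0; i < 9; ++i) m[i] = 0; }
};
static inline M3 outer(const V3 &a, const V3 &b) {
  M3 r;
  r.m[0] = a.x * b.x; r.m[1] = a.x * b.y; r.m[2] = a.x * b.z;
  r.m[3] = a.y * b.x; r.m[4] = a.y * b.y; r.m[5] = a.y * b.z;
  r.m[6] = a.z * b.x; r.m[7] = a.z * b.y; r.m[8] = a.z * b.z;
  return r;
}
static inline M3 eye(double s) { M3 r; r.m[0] = r.m[4] = r.m[8] = s; return r; }
static inline M3 add(const M3 &a, const M3 &b) { M3 r; for (int i = 0; i < 9; ++i) r.m[i] = a.m[i] + b.m[i]; return r; }
static inline M3 scale(double s, const M3 &a) { M3 r; for (int i = 0; i < 9; ++i) r.m[i] = s * a.m[i]; return r; }
static inline M3 mul(const M3 &a, const M3 &b) {
  M3 r;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += a.m[3 * i + k] * b.m[3 * k + j];
      r.m[3 * i + j] = s;
    }
  return r;
}
static inline V3 tmulv(const M3 &a, const V3 &v) { // a^T v
  return V3(a.m[0] * v.x + a.m[3] * v.y + a.m[6] * v.z,
            a.m[1] * v.x + a.m[4] * v.y + a.m[7] * v.z,
            a.m[2] * v.x + a.m[5] * v.y + a.m[8] * v.z);
}

class Coords {
public:
  const double *p;
  int n;
  Coords(const NumericVector &c, int n_) : p(c.begin()), n(n_) {}
  inline V3 at(int i, int a) const {
    return V3(p[i + n * (a + 5 * 0)], p[i + n * (a + 5 * 1)], p[i + n * (a + 5 * 2)]);
  }
};
class Grad {
public:
  double *p;
  int n;
  Grad(NumericVector &g, int n_) : p(g.begin()), n(n_) {}
  inline void add(int i, int a, const V3 &v) {
    p[i + n * (a + 5 * 0)] += v.x;
    p[i + n * (a + 5 * 1)] += v.y;
    p[i + n * (a + 5 * 2)] += v.z;
  }
};

// dihedral in radians, range (-pi, pi]
static double dihedral(const V3 &p1, const V3 &p2, const V3 &p3, const V3 &p4) {
  V3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  V3 m = cross(n1, unit(b2));
  double x = dot(n1, n2), y = dot(m, n2);
  return std::atan2(y, x);
}

// analytic dihedral gradients (radians per Angstrom)
static void dihedral_grad(const V3 &p1, const V3 &p2, const V3 &p3, const V3 &p4,
                          V3 &g1, V3 &g2, V3 &g3, V3 &g4) {
  V3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  double lb2 = norm(b2);
  double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
  g1 = (lb2 / n1sq) * n1;
  g4 = (-lb2 / n2sq) * n2;
  double c1 = -dot(b1, b2) / (lb2 * lb2);
  double c2 = -dot(b3, b2) / (lb2 * lb2);
  g2 = (c1 - 1.0) * g1 - c2 * g4;
  g3 = (c2 - 1.0) * g4 - c1 * g1;
}

// angle at p2 in radians plus gradients
static double angle_grad(const V3 &p1, const V3 &p2, const V3 &p3,
                         V3 &g1, V3 &g2, V3 &g3) {
  V3 a = p1 - p2, b = p3 - p2;
  double la = norm(a), lb = norm(b);
  V3 ua = (1.0 / la) * a, ub = (1.0 / lb) * b;
  double c = dot(ua, ub);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  double th = std::acos(c);
  double s = std::sqrt(1.0 - c * c);
  if (s < 1e-10) s = 1e-10;
  g1 = (-1.0 / (s * la)) * (ub - c * ua);
  g3 = (-1.0 / (s * lb)) * (ua - c * ub);
  g2 = (-1.0) * (g1 + g3);
  return th;
}

static inline double wrap_deg(double d) {
  while (d <= -180.0) d += 360.0;
  while (d > 180.0) d -= 360.0;
  return d;
}
static inline double wrap_rad(double d) {
  while (d <= -M_PI) d += 2 * M_PI;
  while (d > M_PI) d -= 2 * M_PI;
  return d;
}

// ---------------------------------------------------------------- torsions

// [[Rcpp::export]]
NumericMatrix cpp_backbone_torsions(NumericVector coords, LogicalVector break_after) {
  IntegerVector dim = coords.attr("dim");
  int n = dim[0];
  Coords C(coords, n);
  NumericMatrix tor(n, 3);
  std::fill(tor.begin(), tor.end(), NA_REAL);
  for (int i = 0; i < n; ++i) {
    bool okprev = (i > 0) && !break_after[i - 1];
    bool oknext = (i < n - 1) && !break_after[i];
    if (okprev)
      tor(i, 0) = DEG * dihedral(C.at(i - 1, 2), C.at(i, 0), C.at(i, 1), C.at(i, 2));
    if (oknext) {
      tor(i, 1) = DEG * dihedral(C.at(i, 0), C.at(i, 1), C.at(i, 2), C.at(i + 1, 0));
      tor(i, 2) = DEG * dihedral(C.at(i, 1), C.at(i, 2), C.at(i + 1, 0), C.at(i + 1, 1));
    }
  }
  return tor;
}

// ------------------------------------------------------------------- rama

// mixture of periodic anisotropic Gaussian basins over (phi, psi), degrees
// [[Rcpp::export]]
List cpp_rama(NumericVector coords, LogicalVector break_after, List params) {
  IntegerVector dim = coords.attr("dim");
  int n = dim[0];
  Coords C(coords, n);
  NumericMatrix centers = params["centers"]; // nb x 2
  NumericMatrix sigmas = params["sigmas"];   // nb x 2
  NumericVector wts = params["weights"];
  double floorp = params["floor"];
  int nb = centers.nrow();

  NumericVector grad(n * 5 * 3);
  grad.attr("dim") = IntegerVector::create(n, 5, 3);
  Grad G(grad, n);
  NumericVector per_res(n);
  double E = 0;

  for (int i = 0; i < n; ++i) {
    bool okprev = (i > 0) && !break_after[i - 1];
    bool oknext = (i < n - 1) && !break_after[i];
    if (!okprev || !oknext) continue;
    V3 pA = C.at(i - 1, 2), pB = C.at(i, 0), pC = C.at(i, 1), pD = C.at(i, 2);
    V3 qA = C.at(i, 0), qB = C.at(i, 1), qC = C.at(i, 2), qD = C.at(i + 1, 0);
    double phi = DEG * dihedral(pA, pB, pC, pD);
    double psi = DEG * dihedral(qA, qB, qC, qD);
    double P = floorp, dPdphi = 0, dPdpsi = 0;
    for (int b = 0; b < nb; ++b) {
      double dphi = wrap_deg(phi - centers(b, 0));
      double dpsi = wrap_deg(psi - centers(b, 1));
      double sp = sigmas(b, 0), ss = sigmas(b, 1);
      double g = wts[b] * std::exp(-0.5 * (dphi * dphi / (sp * sp) + dpsi * dpsi / (ss * ss)));
      P += g;
      dPdphi += g * (-dphi / (sp * sp));
      dPdpsi += g * (-dpsi / (ss * ss));
    }
    double e = -std::log(P);
    E += e;
    per_res[i] = e;
    double dEdphi = -dPdphi / P; // per degree
    double dEdpsi = -dPdpsi / P;
    V3 g1, g2, g3, g4;
    dihedral_grad(pA, pB, pC, pD, g1, g2, g3, g4);
    double s = dEdphi * DEG; // per-radian
    G.add(i - 1, 2, s * g1); G.add(i, 0, s * g2); G.add(i, 1, s * g3); G.add(i, 2, s * g4);
    dihedral_grad(qA, qB, qC, qD, g1, g2, g3, g4);
    s = dEdpsi * DEG;
    G.add(i, 0, s * g1); G.add(i, 1, s * g2); G.add(i, 2, s * g3); G.add(i + 1, 0, s * g4);
  }
  return List::create(_["energy"] = E, _["grad"] = grad, _["per_residue"] = per_res);
}

// -------------------------------------------------------------------- vdw

// purely repulsive soft sphere: k*(r0-d)^2 for d < r0, pairs separated by
// >= 2 residues in sequence numbering
// [[Rcpp::export]]
List cpp_vdw(NumericVector coords, IntegerVector resno, NumericVector radii, double k) {
  IntegerVector dim = coords.attr("dim");
  int n = dim[0];
  Coords C(coords, n);
  NumericVector grad(n * 5 * 3);
  grad.attr("dim") = IntegerVector::create(n, 5, 3);
  Grad G(grad, n);
  double E = 0;
  double rmax = 0;
  for (int a = 0; a < 5; ++a) rmax = std::max(rmax, radii[a]);
  double cut = 2 * rmax;

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (std::abs(resno[i] - resno[j]) < 2) continue;
      // cheap CA-CA prefilter: atoms lie within ~2.5 A of their CA
      V3 ci = C.at(i, 1), cj = C.at(j, 1);
      V3 dca = ci - cj;
      if (dot(dca, dca) > (cut + 6.0) * (cut + 6.0)) continue;
      for (int a = 0; a < 5; ++a) {
        V3 pa = C.at(i, a);
        for (int b = 0; b < 5; ++b) {
          double r0 = radii[a] + radii[b];
          V3 d = pa - C.at(j, b);
          double d2 = dot(d, d);
          if (d2 >= r0 * r0 || d2 < 1e-12) continue;
          double dist = std::sqrt(d2);
          double diff = r0 - dist;
          E += k * diff * diff;
          double dEdd = -2.0 * k * diff; // dE/d(dist)
          V3 g = (dEdd / dist) * d;
          G.add(i, a, g);
          G.add(j, b, (-1.0) * g);
        }
      }
    }
  }
  return List::create(_["energy"] = E, _["grad"] = grad);
}

// ------------------------------------------------------------------ hbond

// backbone H-bond: donor N-H (H built on the fly from N, CA and the
// preceding C), acceptor carbonyl O. E = -depth * f(d_HO) * g(angle NHO).
// [[Rcpp::export]]
List cpp_hbond(NumericVector coords, IntegerVector resno, LogicalVector break_after,
               double depth, double d0, double sigma_d, double LH) {
  IntegerVector dim = coords.attr("dim");
  int n = dim[0];
  Coords C(coords, n);
  NumericVector grad(n * 5 * 3);
  grad.attr("dim") = IntegerVector::create(n, 5, 3);
  Grad G(grad, n);
  NumericMatrix pair_e(n, n); // donor i, acceptor j (sparse in practice)
  std::fill(pair_e.begin(), pair_e.end(), 0.0);
  double E = 0;
  double cut = d0 + 6.0 * sigma_d;

  for (int i = 1; i < n; ++i) {
    if (break_after[i - 1]) continue; // need C of i-1 bonded to N of i
    V3 N = C.at(i, 0), CA = C.at(i, 1), Cp = C.at(i - 1, 2);
    V3 a = CA - N, b = Cp - N;
    double la = norm(a), lb = norm(b);
    V3 ua = (1.0 / la) * a, ub = (1.0 / lb) * b;
    V3 s = ua + ub;
    double ls = norm(s);
    V3 u = (-1.0 / ls) * s;
    V3 H = N + LH * u;
    // Jacobians of u wrt N, CA, Cp
    M3 duds = scale(-1.0 / ls, add(eye(1.0), scale(-1.0, outer(u, u))));
    M3 Pa = scale(1.0 / la, add(eye(1.0), scale(-1.0, outer(ua, ua))));
    M3 Pb = scale(1.0 / lb, add(eye(1.0), scale(-1.0, outer(ub, ub))));
    M3 JuCA = mul(duds, Pa);
    M3 JuCp = mul(duds, Pb);
    M3 JuN = scale(-1.0, add(JuCA, JuCp));

    for (int j = 0; j < n; ++j) {
      if (std::abs(resno[i] - resno[j]) < 2) continue;
      V3 O = C.at(j, 3);
      V3 w = O - H;
      double d = norm(w);
      if (d > cut || d < 1e-8) continue;
      V3 wh = (1.0 / d) * w;
      double c = dot(u, wh); // = -cos(angle N-H-O); 1 at ideal
      if (c <= 0) continue;
      double f = std::exp(-0.5 * (d - d0) * (d - d0) / (sigma_d * sigma_d));
      double Sc = c * c;
      double e = -depth * f * Sc;
      E += e;
      pair_e(i, j) = e;
      double dEdd = -depth * Sc * f * (-(d - d0) / (sigma_d * sigma_d));
      double dEdc = -depth * f * 2.0 * c;
      // d wrt H: -(wh); wrt O: wh.  c wrt u: wh; wrt O: (u - c*wh)/d; wrt H: -(u - c*wh)/d
      V3 dcdO = (1.0 / d) * (u - c * wh);
      V3 gH = dEdd * (-1.0 * wh) + dEdc * (-1.0 * dcdO);
      V3 gO = dEdd * wh + dEdc * dcdO;
      V3 gu = dEdc * wh;
      V3 back = LH * gH + gu;
      G.add(j, 3, gO);
      G.add(i, 0, gH + tmulv(JuN, back));
      G.add(i, 1, tmulv(JuCA, back));
      G.add(i - 1, 2, tmulv(JuCp, back));
    }
  }
  return List::create(_["energy"] = E, _["grad"] = grad, _["pair_energies"] = pair_e);
}

// ------------------------------------------------------------ cart_bonded

struct GeomPar {
  double b_n_ca, b_ca_c, b_c_n, b_c_o, b_ca_cb;
  double a_n_ca_c, a_ca_c_n, a_c_n_ca, a_ca_c_o, a_o_c_n, a_n_ca_cb;
  double t_cb; // improper dihedral C-N-CA-CB, radians
};

// [[Rcpp::export]]
List cpp_cart_bonded(NumericVector coords, LogicalVector break_after, List geom,
                     double k_len, double k_ang, double k_omega) {
  IntegerVector dim = coords.attr("dim");
  int n = dim[0];
  Coords C(coords, n);
  GeomPar g;
  g.b_n_ca = geom["b_n_ca"]; g.b_ca_c = geom["b_ca_c"]; g.b_c_n = geom["b_c_n"];
  g.b_c_o = geom["b_c_o"]; g.b_ca_cb = geom["b_ca_cb"];
  g.a_n_ca_c = as<double>(geom["a_n_ca_c"]) / DEG;
  g.a_ca_c_n = as<double>(geom["a_ca_c_n"]) / DEG;
  g.a_c_n_ca = as<double>(geom["a_c_n_ca"]) / DEG;
  g.a_ca_c_o = as<double>(geom["a_ca_c_o"]) / DEG;
  g.a_o_c_n = as<double>(geom["a_o_c_n"]) / DEG;
  g.a_n_ca_cb = as<double>(geom["a_n_ca_cb"]) / DEG;
  g.t_cb = as<double>(geom["t_cb"]) / DEG;

  NumericVector grad(n * 5 * 3);
  grad.attr("dim") = IntegerVector::create(n, 5, 3);
  Grad G(grad, n);
  double E = 0;
  double max_bond_dev = 0;

  // accumulate one harmonic bond
  auto bond = [&](int i1, int a1, int i2, int a2, double b0) {
    V3 p = C.at(i1, a1), q = C.at(i2, a2);
    V3 d = p - q;
    double dist = norm(d);
    double diff = dist - b0;
    if (std::abs(diff) > max_bond_dev) max_bond_dev = std::abs(diff);
    E += k_len * diff * diff;
    V3 gg = (2.0 * k_len * diff / dist) * d;
    G.add(i1, a1, gg);
    G.add(i2, a2, (-1.0) * gg);
  };
  auto ang = [&](int i1, int a1, int i2, int a2, int i3, int a3, double th0) {
    V3 g1, g2, g3;
    double th = angle_grad(C.at(i1, a1), C.at(i2, a2), C.at(i3, a3), g1, g2, g3);
    double diff = th - th0;
    E += k_ang * diff * diff;
    double s = 2.0 * k_ang * diff;
    G.add(i1, a1, s * g1); G.add(i2, a2, s * g2); G.add(i3, a3, s * g3);
  };
  auto dih = [&](int i1, int a1, int i2, int a2, int i3, int a3, int i4, int a4,
                 double t0, double kk) {
    V3 p1 = C.at(i1, a1), p2 = C.at(i2, a2), p3 = C.at(i3, a3), p4 = C.at(i4, a4);
    double t = dihedral(p1, p2, p3, p4);
    double diff = wrap_rad(t - t0);
    E += kk * diff * diff;
    V3 g1, g2, g3, g4;
    dihedral_grad(p1, p2, p3, p4, g1, g2, g3, g4);
    double s = 2.0 * kk * diff;
    G.add(i1, a1, s * g1); G.add(i2, a2, s * g2); G.add(i3, a3, s * g3); G.add(i4, a4, s * g4);
  };

  for (int i = 0; i < n; ++i) {
    bond(i, 0, i, 1, g.b_n_ca);
    bond(i, 1, i, 2, g.b_ca_c);
    bond(i, 2, i, 3, g.b_c_o);
    bond(i, 1, i, 4, g.b_ca_cb);
    ang(i, 0, i, 1, i, 2, g.a_n_ca_c);
    ang(i, 1, i, 2, i, 3, g.a_ca_c_o);
    ang(i, 0, i, 1, i, 4, g.a_n_ca_cb);
    dih(i, 2, i, 0, i, 1, i, 4, g.t_cb, k_omega);
    if (i < n - 1 && !break_after[i]) {
      bond(i, 2, i + 1, 0, g.b_c_n);
      ang(i, 1, i, 2, i + 1, 0, g.a_ca_c_n);
      ang(i, 3, i, 2, i + 1, 0, g.a_o_c_n);
      ang(i, 2, i + 1, 0, i + 1, 1, g.a_c_n_ca);
      dih(i, 1, i, 2, i + 1, 0, i + 1, 1, M_PI, k_omega);      // omega planarity
      dih(i + 1, 0, i, 1, i, 2, i, 3, M_PI, k_omega);          // carbonyl O improper
    }
  }
  return List::create(_["energy"] = E, _["grad"] = grad, _["max_bond_dev"] = max_bond_dev);
}

// ------------------------------------------------------------ density sim

// [[Rcpp::export]]
NumericVector cpp_simulate_map(NumericMatrix atoms, NumericVector amps,
                               NumericVector origin, NumericVector spacing,
                               IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  out.attr("dim") = dims;
  double *v = out.begin();
  double norm3 = std::pow(2.0 * M_PI * sigma * sigma, -1.5);
  double cut = 4.5 * sigma;
  int m = atoms.nrow();
  for (int a = 0; a < m; ++a) {
    double ax = atoms(a, 0), ay = atoms(a, 1), az = atoms(a, 2);
    double amp = amps[a] * norm3;
    int i0 = std::max(0, (int)std::ceil((ax - cut - origin[0]) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::floor((ax + cut - origin[0]) / spacing[0]));
    int j0 = std::max(0, (int)std::ceil((ay - cut - origin[1]) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::floor((ay + cut - origin[1]) / spacing[1]));
    int k0 = std::max(0, (int)std::ceil((az - cut - origin[2]) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::floor((az + cut - origin[2]) / spacing[2]));
    double s2 = 2.0 * sigma * sigma;
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * spacing[2] - az;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing[1] - ay;
        double r2yz = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * spacing[0] - ax;
          v[base + i] += amp * std::exp(-(dx * dx + r2yz) / s2);
        }
      }
    }
  }
  return out;
}

// ------------------------------------------------------ masked residue CC

// Pearson CC of rho_calc vs rho_obs over voxels within mask_radius of any
// atom of each residue; mask recomputed from current coordinates each call.
// [[Rcpp::export]]
List cpp_masked_cc(NumericMatrix atoms, IntegerVector atom_res, int nres,
                   NumericVector obs, NumericVector calc,
                   NumericVector origin, NumericVector spacing, IntegerVector dims,
                   double mask_radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *po = obs.begin();
  const double *pc = calc.begin();
  NumericVector cc(nres, NA_REAL);
  IntegerVector nvox(nres);
  std::vector<int> stamp((size_t)nx * ny * nz, -1);
  int m = atoms.nrow();

  for (int r = 0; r < nres; ++r) {
    double so = 0, sc = 0, soo = 0, scc = 0, soc = 0;
    long cnt = 0;
    for (int a = 0; a < m; ++a) {
      if (atom_res[a] != r + 1) continue;
      double ax = atoms(a, 0), ay = atoms(a, 1), az = atoms(a, 2);
      int i0 = std::max(0, (int)std::ceil((ax - mask_radius - origin[0]) / spacing[0]));
      int i1 = std::min(nx - 1, (int)std::floor((ax + mask_radius - origin[0]) / spacing[0]));
      int j0 = std::max(0, (int)std::ceil((ay - mask_radius - origin[1]) / spacing[1]));
      int j1 = std::min(ny - 1, (int)std::floor((ay + mask_radius - origin[1]) / spacing[1]));
      int k0 = std::max(0, (int)std::ceil((az - mask_radius - origin[2]) / spacing[2]));
      int k1 = std::min(nz - 1, (int)std::floor((az + mask_radius - origin[2]) / spacing[2]));
      double r2max = mask_radius * mask_radius;
      for (int k = k0; k <= k1; ++k) {
        double dz = origin[2] + k * spacing[2] - az;
        for (int j = j0; j <= j1; ++j) {
          double dy = origin[1] + j * spacing[1] - ay;
          double r2yz = dy * dy + dz * dz;
          if (r2yz > r2max) continue;
          R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          for (int i = i0; i <= i1; ++i) {
            double dx = origin[0] + i * spacing[0] - ax;
            if (dx * dx + r2yz > r2max) continue;
            R_xlen_t id = base + i;
            if (stamp[id] == r) continue; // already in this residue's mask
            stamp[id] = r;
            double o = po[id], c = pc[id];
            so += o; sc += c; soo += o * o; scc += c * c; soc += o * c;
            ++cnt;
          }
        }
      }
    }
    nvox[r] = (int)cnt;
    if (cnt >= 2) {
      double varo = soo - so * so / cnt;
      double varc = scc - sc * sc / cnt;
      double cov = soc - so * sc / cnt;
      if (varo > 1e-30 && varc > 1e-30) cc[r] = cov / std::sqrt(varo * varc);
    }
  }
  return List::create(_["cc"] = cc, _["nvox"] = nvox);
}

// -------------------------------------------------- tricubic interpolation

// separable cubic B-spline on prefiltered coefficients: interpolates node
// values exactly (via the prefilter) and is C2, so analytic gradients agree
// with finite differences everywhere, including across cell boundaries
static inline void bs_weights(double t, double *w, double *dw) {
  double t2 = t * t, t3 = t2 * t, it = 1.0 - t;
  w[0] = it * it * it / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
  dw[0] = -0.5 * it * it;
  dw[1] = (-12.0 * t + 9.0 * t2) / 6.0;
  dw[2] = (3.0 + 6.0 * t - 9.0 * t2) / 6.0;
  dw[3] = 0.5 * t2;
}

// recursive prefilter (pole sqrt(3)-2) along one line
static void bs_prefilter_line(double *c, int n, R_xlen_t stride) {
  const double z = -0.2679491924311227;
  if (n < 2) return;
  for (int k = 0; k < n; ++k) c[(R_xlen_t)k * stride] *= 6.0;
  int horizon = n < 28 ? n : 28;
  double sum = c[0], zn = z;
  for (int k = 1; k < horizon; ++k) {
    sum += zn * c[(R_xlen_t)k * stride];
    zn *= z;
  }
  c[0] = sum;
  for (int k = 1; k < n; ++k)
    c[(R_xlen_t)k * stride] += z * c[(R_xlen_t)(k - 1) * stride];
  c[(R_xlen_t)(n - 1) * stride] =
      (z / (z * z - 1.0)) *
      (c[(R_xlen_t)(n - 1) * stride] + z * c[(R_xlen_t)(n - 2) * stride]);
  for (int k = n - 2; k >= 0; --k)
    c[(R_xlen_t)k * stride] =
        z * (c[(R_xlen_t)(k + 1) * stride] - c[(R_xlen_t)k * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector field) {
  IntegerVector dims = field.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(field);
  double *p = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      bs_prefilter_line(p + (R_xlen_t)nx * (j + (R_xlen_t)ny * k), nx, 1);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      bs_prefilter_line(p + i + (R_xlen_t)nx * ny * k, ny, nx);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      bs_prefilter_line(p + i + (R_xlen_t)nx * j, nz, (R_xlen_t)nx * ny);
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List cpp_tricubic(NumericVector field, NumericVector origin, NumericVector spacing,
                  NumericMatrix pts) {
  IntegerVector dims = field.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = field.begin();
  int m = pts.nrow();
  NumericVector val(m);
  NumericMatrix grd(m, 3);
  int nclamp = 0;

  for (int p = 0; p < m; ++p) {
    double fx = (pts(p, 0) - origin[0]) / spacing[0];
    double fy = (pts(p, 1) - origin[1]) / spacing[1];
    double fz = (pts(p, 2) - origin[2]) / spacing[2];
    // interior margin: need i-1 .. i+2 in range
    bool clamped = false;
    auto clampf = [&](double v, int nmax) {
      if (v < 1.0) { clamped = true; return 1.0; }
      if (v > nmax - 3.0) { clamped = true; return nmax - 3.0; }
      return v;
    };
    fx = clampf(fx, nx); fy = clampf(fy, ny); fz = clampf(fz, nz);
    if (clamped) ++nclamp;
    int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
    if (ix > nx - 3) ix = nx - 3;
    if (iy > ny - 3) iy = ny - 3;
    if (iz > nz - 3) iz = nz - 3;
    double tx = fx - ix, ty = fy - iy, tz = fz - iz;
    double wx[4], dwx[4], wy[4], dwy[4], wz[4], dwz[4];
    bs_weights(tx, wx, dwx);
    bs_weights(ty, wy, dwy);
    bs_weights(tz, wz, dwz);
    double v = 0, gx = 0, gy = 0, gz = 0;
    for (int c = 0; c < 4; ++c) {
      int kz = iz - 1 + c;
      for (int b = 0; b < 4; ++b) {
        int ky = iy - 1 + b;
        R_xlen_t base = (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz);
        double wyz = wy[b] * wz[c];
        double dyz = dwy[b] * wz[c];
        double ydz = wy[b] * dwz[c];
        for (int a = 0; a < 4; ++a) {
          double fv = f[base + (ix - 1 + a)];
          v += fv * wx[a] * wyz;
          gx += fv * dwx[a] * wyz;
          gy += fv * wx[a] * dyz;
          gz += fv * wx[a] * ydz;
        }
      }
    }
    val[p] = v;
    grd(p, 0) = gx / spacing[0];
    grd(p, 1) = gy / spacing[1];
    grd(p, 2) = gz / spacing[2];
  }
  return List::create(_["value"] = val, _["grad"] = grd, _["n_clamped"] = nclamp);
}
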