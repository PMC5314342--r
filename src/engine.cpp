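// Coarse-grained strand engine: force field, Langevin (BAOAB) integrator,
// collective-variable gradients and a grid-backed well-tempered
// metadynamics bias.  Units: nm, ps, kJ/mol; site masses are 1 in reduced
// units; kB = 0.0083144621 kJ/mol/K.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0083144621;

// ---------------------------------------------------------------------------
// rational switching function f(x) = (1 - x^n) / (1 - x^m), x = r / r0
// stable at x = 1 (limit n/m); returns value and d f / d r
// ---------------------------------------------------------------------------
static inline void rational_switch(double r, double r0, int n, int m,
                                   double &f, double &dfdr) {
  double x = r / r0;
  if (std::fabs(x - 1.0) < 1e-6) {
    double u = x - 1.0;
    f = (double)n / m + (double)n * (n - m) / (2.0 * m) * u;
    dfdr = (double)n * (n - m) / (2.0 * m) / r0;
    return;
  }
  double xn = std::pow(x, n), xm = std::pow(x, m);
  double den = 1.0 - xm;
  f = (1.0 - xn) / den;
  dfdr = (-n * std::pow(x, n - 1) * den + m * std::pow(x, m - 1) * (1.0 - xn)) /
         (den * den) / r0;
}

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double *a) { return std::sqrt(dot3(a, a)); }

// ---------------------------------------------------------------------------
// topology + parameters unpacked from R lists into plain vectors
// ---------------------------------------------------------------------------
struct CGTopo {
  int nsites;
  std::vector<int> bond_i, bond_j;
  std::vector<double> bond_r0, bond_k;
  std::vector<int> ang_i, ang_j, ang_l;   // j is the apex
  std::vector<double> ang_cos0, ang_kf;
  std::vector<int> tor_a, tor_b, tor_c, tor_d;
  std::vector<double> tor_phi0, tor_kf;
  std::vector<int> plane1, plane2, plane3;        // per base
  std::vector<int> stack_a, stack_b;              // base indices
  std::vector<int> hb_a, hb_b;                    // base indices
  std::vector<double> hb_w;
  std::vector<int> ev_i, ev_j;                    // site indices
  std::vector<int> head_sites, tail_sites;        // for the HT CV
  std::vector<int> seq_a, seq_b;                  // sequential base pairs (SStk)
  std::vector<double> ev_rad;              // per-pair EV radius
  double eps_stack, eps_hb, ev_k;
  double sw_stack_r0, sw_hb_r0;
  int sw_stack_n, sw_stack_m, sw_hb_n, sw_hb_m;
};

static std::vector<int> as_int0(SEXP x) {
  IntegerVector v(x);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i];
  return out;
}
static std::vector<double> as_dbl(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}

// topo list comes from R with 0-based indices already
static CGTopo unpack_topo(const List &tl) {
  CGTopo t;
  t.nsites = as<int>(tl["nsites"]);
  t.bond_i = as_int0(tl["bond_i"]); t.bond_j = as_int0(tl["bond_j"]);
  t.bond_r0 = as_dbl(tl["bond_r0"]); t.bond_k = as_dbl(tl["bond_k"]);
  t.ang_i = as_int0(tl["ang_i"]); t.ang_j = as_int0(tl["ang_j"]);
  t.ang_l = as_int0(tl["ang_l"]);
  t.ang_cos0 = as_dbl(tl["ang_cos0"]); t.ang_kf = as_dbl(tl["ang_kf"]);
  t.tor_a = as_int0(tl["tor_a"]); t.tor_b = as_int0(tl["tor_b"]);
  t.tor_c = as_int0(tl["tor_c"]); t.tor_d = as_int0(tl["tor_d"]);
  t.tor_phi0 = as_dbl(tl["tor_phi0"]); t.tor_kf = as_dbl(tl["tor_k"]);
  t.plane1 = as_int0(tl["plane1"]); t.plane2 = as_int0(tl["plane2"]);
  t.plane3 = as_int0(tl["plane3"]);
  t.stack_a = as_int0(tl["stack_a"]); t.stack_b = as_int0(tl["stack_b"]);
  t.hb_a = as_int0(tl["hb_a"]); t.hb_b = as_int0(tl["hb_b"]);
  t.hb_w = as_dbl(tl["hb_w"]);
  t.ev_i = as_int0(tl["ev_i"]); t.ev_j = as_int0(tl["ev_j"]);
  t.head_sites = as_int0(tl["head_sites"]);
  t.tail_sites = as_int0(tl["tail_sites"]);
  t.seq_a = as_int0(tl["seq_a"]); t.seq_b = as_int0(tl["seq_b"]);
  t.eps_stack = as<double>(tl["eps_stack"]);
  t.eps_hb = as<double>(tl["eps_hb"]);
  t.ev_k = as<double>(tl["ev_k"]); t.ev_rad = as_dbl(tl["ev_rad"]);
  t.sw_stack_r0 = as<double>(tl["sw_stack_r0"]);
  t.sw_stack_n = as<int>(tl["sw_stack_n"]);
  t.sw_stack_m = as<int>(tl["sw_stack_m"]);
  t.sw_hb_r0 = as<double>(tl["sw_hb_r0"]);
  t.sw_hb_n = as<int>(tl["sw_hb_n"]);
  t.sw_hb_m = as<int>(tl["sw_hb_m"]);
  return t;
}

// ---------------------------------------------------------------------------
// base-plane geometry: centroid + unit normal, with gradient adjoints
// ---------------------------------------------------------------------------
struct PlaneGeom {
  double cen[3], nrm[3];   // centroid, unit normal
  double v1[3], v2[3];     // p2-p1, p3-p1
  double wlen;             // |v1 x v2|
};

static void plane_geom(const double *x, const CGTopo &t, int b, PlaneGeom &g) {
  const double *p1 = x + 3 * t.plane1[b];
  const double *p2 = x + 3 * t.plane2[b];
  const double *p3 = x + 3 * t.plane3[b];
  for (int k = 0; k < 3; ++k) {
    g.cen[k] = (p1[k] + p2[k] + p3[k]) / 3.0;
    g.v1[k] = p2[k] - p1[k];
    g.v2[k] = p3[k] - p1[k];
  }
  double w[3];
  cross3(g.v1, g.v2, w);
  g.wlen = norm3(w);
  if (g.wlen < 1e-12) stop("degenerate base-plane triplet");
  for (int k = 0; k < 3; ++k) g.nrm[k] = w[k] / g.wlen;
}

// accumulate d(gdot)/dsites for plane b given adjoint vector a = d g / d n
// (g = n_b . other_normal); chain through the normalized cross product
static void plane_normal_adjoint(const PlaneGeom &g, const double *a,
                                 double *gp1, double *gp2, double *gp3) {
  // q = (I - n n^T) a / |w|
  double na = dot3(g.nrm, a);
  double q[3];
  for (int k = 0; k < 3; ++k) q[k] = (a[k] - na * g.nrm[k]) / g.wlen;
  // w = v1 x v2, v1 = p2 - p1, v2 = p3 - p1
  double v2xq[3], qxv1[3];
  cross3(g.v2, q, v2xq);
  cross3(q, g.v1, qxv1);
  for (int k = 0; k < 3; ++k) {
    gp2[k] = v2xq[k];
    gp3[k] = qxv1[k];
    gp1[k] = -v2xq[k] - qxv1[k];
  }
}

// distance-and-orientation score of a base pair and its gradient (added
// into grad with prefactor); returns s = f(d) cos^2(theta).  The switch
// parameters are passed in so the same geometry serves the stacking CV /
// well (sw_stack_*) and the orientation-gated pairing well (sw_hb_*).
static double plane_pair_score(const double *x, const CGTopo &t, int a,
                               int b, double r0, int n, int m, double pref,
                               double *grad) {
  PlaneGeom ga, gb;
  plane_geom(x, t, a, ga);
  plane_geom(x, t, b, gb);
  double u[3];
  for (int k = 0; k < 3; ++k) u[k] = ga.cen[k] - gb.cen[k];
  double d = norm3(u);
  double f, dfdr;
  rational_switch(d, r0, n, m, f, dfdr);
  double g = dot3(ga.nrm, gb.nrm);
  double s = f * g * g;
  if (grad) {
    // distance part: d s/d cen_a = f'(d) g^2 u/d, split over triplet /3
    double cd = (d > 1e-12) ? pref * dfdr * g * g / d / 3.0 : 0.0;
    int pa[3] = {t.plane1[a], t.plane2[a], t.plane3[a]};
    int pb[3] = {t.plane1[b], t.plane2[b], t.plane3[b]};
    for (int s3 = 0; s3 < 3; ++s3)
      for (int k = 0; k < 3; ++k) {
        grad[3 * pa[s3] + k] += cd * u[k];
        grad[3 * pb[s3] + k] -= cd * u[k];
      }
    // orientation part: d s/d g = 2 f g ; adjoint a-side: dg/dn_a = n_b
    double co = pref * 2.0 * f * g;
    double g1[3], g2[3], g3[3];
    plane_normal_adjoint(ga, gb.nrm, g1, g2, g3);
    for (int k = 0; k < 3; ++k) {
      grad[3 * pa[0] + k] += co * g1[k];
      grad[3 * pa[1] + k] += co * g2[k];
      grad[3 * pa[2] + k] += co * g3[k];
    }
    plane_normal_adjoint(gb, ga.nrm, g1, g2, g3);
    for (int k = 0; k < 3; ++k) {
      grad[3 * pb[0] + k] += co * g1[k];
      grad[3 * pb[1] + k] += co * g2[k];
      grad[3 * pb[2] + k] += co * g3[k];
    }
  }
  return s;
}

static double stack_pair(const double *x, const CGTopo &t, int a, int b,
                         double pref, double *grad) {
  return plane_pair_score(x, t, a, b, t.sw_stack_r0, t.sw_stack_n,
                          t.sw_stack_m, pref, grad);
}

// signed dihedral (radians) with gradient (optional, accumulated with pref)
static double dihedral_cpp(const double *x, int ia, int ib, int ic, int id,
                           double pref, double *grad) {
  const double *p1 = x + 3 * ia, *p2 = x + 3 * ib, *p3 = x + 3 * ic,
               *p4 = x + 3 * id;
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = p2[k] - p1[k];
    b2[k] = p3[k] - p2[k];
    b3[k] = p4[k] - p3[k];
  }
  double n1[3], n2[3], n1xn2[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  cross3(n1, n2, n1xn2);
  double nb2 = norm3(b2);
  double xcomp = dot3(n1, n2);
  double ycomp = dot3(n1xn2, b2) / nb2;
  double phi = std::atan2(ycomp, xcomp);
  if (grad && pref != 0.0) {
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    double f1[3], f4[3], f2[3], f3[3];
    for (int k = 0; k < 3; ++k) {
      f1[k] = -nb2 / n1sq * n1[k];
      f4[k] = nb2 / n2sq * n2[k];
    }
    double c12 = dot3(b1, b2) / (nb2 * nb2);
    double c32 = dot3(b3, b2) / (nb2 * nb2);
    for (int k = 0; k < 3; ++k) {
      f2[k] = -(1.0 + c12) * f1[k] + c32 * f4[k];
      f3[k] = c12 * f1[k] - (1.0 + c32) * f4[k];
    }
    for (int k = 0; k < 3; ++k) {
      grad[3 * ia + k] += pref * f1[k];
      grad[3 * ib + k] += pref * f2[k];
      grad[3 * ic + k] += pref * f3[k];
      grad[3 * id + k] += pref * f4[k];
    }
  }
  return phi;
}

// ---------------------------------------------------------------------------
// full potential energy and gradient of the coarse-grained model
// ---------------------------------------------------------------------------
static double cg_energy(const double *x, const CGTopo &t, double *grad) {
  int n3 = 3 * t.nsites;
  if (grad) std::fill(grad, grad + n3, 0.0);
  double E = 0.0;
  // bonds
  for (size_t i = 0; i < t.bond_i.size(); ++i) {
    const double *pi = x + 3 * t.bond_i[i];
    const double *pj = x + 3 * t.bond_j[i];
    double u[3] = {pi[0] - pj[0], pi[1] - pj[1], pi[2] - pj[2]};
    double r = norm3(u);
    double dr = r - t.bond_r0[i];
    E += 0.5 * t.bond_k[i] * dr * dr;
    if (grad && r > 1e-12) {
      double c = t.bond_k[i] * dr / r;
      for (int k = 0; k < 3; ++k) {
        grad[3 * t.bond_i[i] + k] += c * u[k];
        grad[3 * t.bond_j[i] + k] -= c * u[k];
      }
    }
  }
  // angles: E = k (cos - cos0)^2 with apex j
  for (size_t i = 0; i < t.ang_i.size(); ++i) {
    const double *pa = x + 3 * t.ang_i[i];
    const double *pj = x + 3 * t.ang_j[i];
    const double *pb = x + 3 * t.ang_l[i];
    double u[3] = {pa[0] - pj[0], pa[1] - pj[1], pa[2] - pj[2]};
    double v[3] = {pb[0] - pj[0], pb[1] - pj[1], pb[2] - pj[2]};
    double nu = norm3(u), nv = norm3(v);
    double c = dot3(u, v) / (nu * nv);
    double dc = c - t.ang_cos0[i];
    E += t.ang_kf[i] * dc * dc;
    if (grad) {
      double pre = 2.0 * t.ang_kf[i] * dc;
      for (int k = 0; k < 3; ++k) {
        double du = (v[k] / (nu * nv)) - c * u[k] / (nu * nu);
        double dv = (u[k] / (nu * nv)) - c * v[k] / (nv * nv);
        grad[3 * t.ang_i[i] + k] += pre * du;
        grad[3 * t.ang_l[i] + k] += pre * dv;
        grad[3 * t.ang_j[i] + k] -= pre * (du + dv);
      }
    }
  }
  // torsional bias: E = k (1 - cos(phi - phi0))
  for (size_t i = 0; i < t.tor_a.size(); ++i) {
    double phi = dihedral_cpp(x, t.tor_a[i], t.tor_b[i], t.tor_c[i],
                              t.tor_d[i], 0.0, NULL);
    E += t.tor_kf[i] * (1.0 - std::cos(phi - t.tor_phi0[i]));
    if (grad)
      dihedral_cpp(x, t.tor_a[i], t.tor_b[i], t.tor_c[i], t.tor_d[i],
                   t.tor_kf[i] * std::sin(phi - t.tor_phi0[i]), grad);
  }
  // stacking wells (all listed intra-strand base pairs)
  for (size_t i = 0; i < t.stack_a.size(); ++i)
    E += -t.eps_stack *
         stack_pair(x, t, t.stack_a[i], t.stack_b[i], -t.eps_stack, grad);
  // base pairing wells between the centroids of WC partners,
  // weight = H-bond count: E = -eps_hb w f(d)
  for (size_t i = 0; i < t.hb_a.size(); ++i) {
    int a = t.hb_a[i], b = t.hb_b[i];
    double ca[3], cb[3];
    for (int k = 0; k < 3; ++k) {
      ca[k] = (x[3 * t.plane1[a] + k] + x[3 * t.plane2[a] + k] +
               x[3 * t.plane3[a] + k]) / 3.0;
      cb[k] = (x[3 * t.plane1[b] + k] + x[3 * t.plane2[b] + k] +
               x[3 * t.plane3[b] + k]) / 3.0;
    }
    double u[3] = {ca[0] - cb[0], ca[1] - cb[1], ca[2] - cb[2]};
    double d = norm3(u);
    double f, dfdr;
    rational_switch(d, t.sw_hb_r0, t.sw_hb_n, t.sw_hb_m, f, dfdr);
    double w = t.eps_hb * t.hb_w[i];
    E += -w * f;
    if (grad && d > 1e-12) {
      double c = -w * dfdr / d / 3.0;
      int pa[3] = {t.plane1[a], t.plane2[a], t.plane3[a]};
      int pb[3] = {t.plane1[b], t.plane2[b], t.plane3[b]};
      for (int s3 = 0; s3 < 3; ++s3)
        for (int k = 0; k < 3; ++k) {
          grad[3 * pa[s3] + k] += c * u[k];
          grad[3 * pb[s3] + k] -= c * u[k];
        }
    }
  }
  // soft excluded volume between listed site pairs
  for (size_t i = 0; i < t.ev_i.size(); ++i) {
    const double *pi = x + 3 * t.ev_i[i];
    const double *pj = x + 3 * t.ev_j[i];
    double u[3] = {pi[0] - pj[0], pi[1] - pj[1], pi[2] - pj[2]};
    double r = norm3(u);
    if (r < t.ev_rad[i]) {
      double dr = r - t.ev_rad[i];
      E += 0.5 * t.ev_k * dr * dr;
      if (grad && r > 1e-12) {
        double c = t.ev_k * dr / r;
        for (int k = 0; k < 3; ++k) {
          grad[3 * t.ev_i[i] + k] += c * u[k];
          grad[3 * t.ev_j[i] + k] -= c * u[k];
        }
      }
    }
  }
  return E;
}

// ---------------------------------------------------------------------------
// collective variables of the strand (value + optional gradient adjoint)
// ---------------------------------------------------------------------------
static double cv_ht(const double *x, const CGTopo &t, double pref,
                    double *grad) {
  double ch[3] = {0, 0, 0}, ct[3] = {0, 0, 0};
  int nh = t.head_sites.size(), nt = t.tail_sites.size();
  for (int i = 0; i < nh; ++i)
    for (int k = 0; k < 3; ++k) ch[k] += x[3 * t.head_sites[i] + k] / nh;
  for (int i = 0; i < nt; ++i)
    for (int k = 0; k < 3; ++k) ct[k] += x[3 * t.tail_sites[i] + k] / nt;
  double u[3] = {ch[0] - ct[0], ch[1] - ct[1], ch[2] - ct[2]};
  double d = norm3(u);
  if (grad && pref != 0.0 && d > 1e-12) {
    for (int i = 0; i < nh; ++i)
      for (int k = 0; k < 3; ++k)
        grad[3 * t.head_sites[i] + k] += pref * u[k] / d / nh;
    for (int i = 0; i < nt; ++i)
      for (int k = 0; k < 3; ++k)
        grad[3 * t.tail_sites[i] + k] -= pref * u[k] / d / nt;
  }
  return d;
}

static double cv_stk(const double *x, const CGTopo &t, double pref,
                     double *grad) {
  double s = 0.0;
  for (size_t i = 0; i < t.stack_a.size(); ++i)
    s += stack_pair(x, t, t.stack_a[i], t.stack_b[i], pref,
                    (grad && pref != 0.0) ? grad : NULL);
  return s;
}

static double cv_sstk(const double *x, const CGTopo &t) {
  double s = 0.0;
  for (size_t i = 0; i < t.seq_a.size(); ++i)
    s += stack_pair(x, t, t.seq_a[i], t.seq_b[i], 0.0, NULL);
  return s;
}

// ---------------------------------------------------------------------------
// grid-backed metadynamics bias (1 or 2 CVs)
// ---------------------------------------------------------------------------
struct BiasGrid {
  int dim;
  double lo[2], hi[2], h[2], sigma[2];
  int n[2];
  double W0, gamma, kT, dT;   // dT = (gamma - 1) * T in energy units (kB dT)
  int stride_steps;
  double cutoff_sigmas;
  std::vector<double> V, G0, G1;   // value and per-CV gradient grids
  // hills log
  std::vector<double> hill_time, hill_c0, hill_c1, hill_W;

  void init(const List &ml) {
    dim = as<int>(ml["dim"]);
    NumericVector lo_ = ml["lo"], hi_ = ml["hi"], h_ = ml["spacing"],
                  sg = ml["sigma"];
    for (int d = 0; d < dim; ++d) {
      lo[d] = lo_[d]; hi[d] = hi_[d]; h[d] = h_[d]; sigma[d] = sg[d];
      n[d] = (int)std::floor((hi[d] - lo[d]) / h[d]) + 1;
    }
    W0 = as<double>(ml["W0"]);
    gamma = as<double>(ml["gamma"]);
    kT = as<double>(ml["kT"]);
    dT = (gamma - 1.0) * kT;    // kB*DeltaT in energy units
    stride_steps = as<int>(ml["stride_steps"]);
    cutoff_sigmas = as<double>(ml["cutoff"]);
    size_t tot = (dim == 1) ? (size_t)n[0] : (size_t)n[0] * n[1];
    V.assign(tot, 0.0);
    G0.assign(tot, 0.0);
    if (dim == 2) G1.assign(tot, 0.0);
  }

  inline size_t idx(int i, int j) const { return (size_t)j * n[0] + i; }

  // bilinear interpolation of grid arr at s (clamped to the grid)
  double interp(const std::vector<double> &arr, const double *s) const {
    double u[2]; int i0[2];
    for (int d = 0; d < dim; ++d) {
      double z = (s[d] - lo[d]) / h[d];
      if (z < 0) z = 0;
      if (z > n[d] - 1.000001) z = n[d] - 1.000001;
      i0[d] = (int)std::floor(z);
      u[d] = z - i0[d];
    }
    if (dim == 1)
      return arr[i0[0]] * (1 - u[0]) + arr[i0[0] + 1] * u[0];
    double v00 = arr[idx(i0[0], i0[1])], v10 = arr[idx(i0[0] + 1, i0[1])];
    double v01 = arr[idx(i0[0], i0[1] + 1)],
           v11 = arr[idx(i0[0] + 1, i0[1] + 1)];
    return (1 - u[1]) * ((1 - u[0]) * v00 + u[0] * v10) +
           u[1] * ((1 - u[0]) * v01 + u[0] * v11);
  }

  double value(const double *s) const { return interp(V, s); }
  void gradient(const double *s, double *g) const {
    g[0] = interp(G0, s);
    if (dim == 2) g[1] = interp(G1, s);
  }

  // deposit a well-tempered hill at s, time tm; returns the height
  double deposit(const double *s, double tm) {
    double W = W0 * std::exp(-value(s) / dT);
    int ilo[2], ihi[2];
    for (int d = 0; d < dim; ++d) {
      ilo[d] = (int)std::floor((s[d] - cutoff_sigmas * sigma[d] - lo[d]) / h[d]);
      ihi[d] = (int)std::ceil((s[d] + cutoff_sigmas * sigma[d] - lo[d]) / h[d]);
      if (ilo[d] < 0) ilo[d] = 0;
      if (ihi[d] > n[d] - 1) ihi[d] = n[d] - 1;
    }
    if (dim == 1) {
      for (int i = ilo[0]; i <= ihi[0]; ++i) {
        double dx = lo[0] + i * h[0] - s[0];
        double g = W * std::exp(-dx * dx / (2.0 * sigma[0] * sigma[0]));
        V[i] += g;
        G0[i] += -dx / (sigma[0] * sigma[0]) * g;
      }
    } else {
      for (int j = ilo[1]; j <= ihi[1]; ++j) {
        double dy = lo[1] + j * h[1] - s[1];
        double ey = std::exp(-dy * dy / (2.0 * sigma[1] * sigma[1]));
        for (int i = ilo[0]; i <= ihi[0]; ++i) {
          double dx = lo[0] + i * h[0] - s[0];
          double g = W * std::exp(-dx * dx / (2.0 * sigma[0] * sigma[0])) * ey;
          size_t q = idx(i, j);
          V[q] += g;
          G0[q] += -dx / (sigma[0] * sigma[0]) * g;
          G1[q] += -dy / (sigma[1] * sigma[1]) * g;
        }
      }
    }
    hill_time.push_back(tm);
    hill_c0.push_back(s[0]);
    if (dim == 2) hill_c1.push_back(s[1]);
    hill_W.push_back(W);
    return W;
  }

  List hills_list() const {
    int k = hill_time.size();
    NumericMatrix centers(k, dim);
    NumericVector tms(k), Ws(k);
    for (int i = 0; i < k; ++i) {
      tms[i] = hill_time[i];
      centers(i, 0) = hill_c0[i];
      if (dim == 2) centers(i, 1) = hill_c1[i];
      Ws[i] = hill_W[i];
    }
    return List::create(_["time"] = tms, _["centers"] = centers,
                        _["heights"] = Ws);
  }
};

// ---------------------------------------------------------------------------
// exported: energy + forces of the CG model (for tests / analysis)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_cg_energy(NumericMatrix coords, List topo) {
  CGTopo t = unpack_topo(topo);
  if (coords.nrow() != t.nsites) stop("coordinate/site count mismatch");
  std::vector<double> x(3 * t.nsites), g(3 * t.nsites);
  for (int i = 0; i < t.nsites; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double E = cg_energy(x.data(), t, g.data());
  NumericMatrix forces(t.nsites, 3);
  for (int i = 0; i < t.nsites; ++i)
    for (int k = 0; k < 3; ++k) forces(i, k) = -g[3 * i + k];
  return List::create(_["energy"] = E, _["forces"] = forces);
}

// [[Rcpp::export]]
NumericVector cpp_cg_cvs(NumericMatrix coords, List topo) {
  CGTopo t = unpack_topo(topo);
  std::vector<double> x(3 * t.nsites);
  for (int i = 0; i < t.nsites; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  return NumericVector::create(_["ht"] = cv_ht(x.data(), t, 0.0, NULL),
                               _["stk"] = cv_stk(x.data(), t, 0.0, NULL),
                               _["sstk"] = cv_sstk(x.data(), t));
}

// ---------------------------------------------------------------------------
// exported: steepest-descent minimization with step capping
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_cg_minimize(NumericMatrix coords, List topo, int steps,
                              double step_size, double max_disp) {
  CGTopo t = unpack_topo(topo);
  std::vector<double> x(3 * t.nsites), g(3 * t.nsites);
  for (int i = 0; i < t.nsites; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  for (int s = 0; s < steps; ++s) {
    cg_energy(x.data(), t, g.data());
    for (int q = 0; q < 3 * t.nsites; ++q) {
      double d = -step_size * g[q];
      if (d > max_disp) d = max_disp;
      if (d < -max_disp) d = -max_disp;
      x[q] += d;
    }
  }
  NumericMatrix out(t.nsites, 3);
  for (int i = 0; i < t.nsites; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return out;
}

// ---------------------------------------------------------------------------
// Langevin BAOAB driver for the CG model, with optional WT-MetaD on
// (HT, Stk).  Unit site masses.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_cg(NumericMatrix coords, List topo, int steps, double dt,
                double temperature, double friction, int sample_stride,
                int seed, Nullable<List> metad, bool store_frames) {
  CGTopo t = unpack_topo(topo);
  if (coords.nrow() != t.nsites) stop("coordinate/site count mismatch");
  int n3 = 3 * t.nsites;
  std::vector<double> x(n3), v(n3, 0.0), f(n3), g(n3);
  for (int i = 0; i < t.nsites; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double kT = KB * temperature;
  double c1 = std::exp(-friction * dt);
  double c2 = (friction > 0) ? std::sqrt((1.0 - c1 * c1) * kT) : 0.0;

  if (temperature > 0)
    for (int q = 0; q < n3; ++q) v[q] = std::sqrt(kT) * gauss(rng);

  bool do_metad = metad.isNotNull();
  BiasGrid bias;
  if (do_metad) bias.init(List(metad));

  int nsamp = steps / sample_stride;
  NumericVector samp_time(nsamp), samp_ht(nsamp), samp_stk(nsamp),
      samp_sstk(nsamp), samp_bias(nsamp), samp_epot(nsamp), samp_ekin(nsamp);
  NumericVector frames;
  if (store_frames) {
    frames = NumericVector(Dimension(t.nsites, 3, nsamp));
  }

  // initial forces (potential + bias)
  double s[2], gs[2];
  double epot = cg_energy(x.data(), t, g.data());
  for (int q = 0; q < n3; ++q) f[q] = -g[q];
  if (do_metad) {
    s[0] = cv_ht(x.data(), t, 0.0, NULL);
    s[1] = cv_stk(x.data(), t, 0.0, NULL);
    bias.gradient(s, gs);
    std::fill(g.begin(), g.end(), 0.0);
    cv_ht(x.data(), t, gs[0], g.data());
    cv_stk(x.data(), t, gs[1], g.data());
    for (int q = 0; q < n3; ++q) f[q] -= g[q];
  }

  int isamp = 0;
  for (int step = 1; step <= steps; ++step) {
    // B A O A B
    for (int q = 0; q < n3; ++q) v[q] += 0.5 * dt * f[q];
    for (int q = 0; q < n3; ++q) x[q] += 0.5 * dt * v[q];
    if (friction > 0)
      for (int q = 0; q < n3; ++q) v[q] = c1 * v[q] + c2 * gauss(rng);
    for (int q = 0; q < n3; ++q) x[q] += 0.5 * dt * v[q];

    epot = cg_energy(x.data(), t, g.data());
    for (int q = 0; q < n3; ++q) f[q] = -g[q];
    if (do_metad) {
      s[0] = cv_ht(x.data(), t, 0.0, NULL);
      s[1] = cv_stk(x.data(), t, 0.0, NULL);
      if (step % bias.stride_steps == 0) bias.deposit(s, step * dt);
      bias.gradient(s, gs);
      std::fill(g.begin(), g.end(), 0.0);
      cv_ht(x.data(), t, gs[0], g.data());
      cv_stk(x.data(), t, gs[1], g.data());
      for (int q = 0; q < n3; ++q) f[q] -= g[q];
    }
    for (int q = 0; q < n3; ++q) v[q] += 0.5 * dt * f[q];

    if (step % sample_stride == 0 && isamp < nsamp) {
      if (!std::isfinite(epot) || !std::isfinite(x[0]))
        stop("divergence: non-finite coordinates/energy at step %d (t = %g ps)",
             step, step * dt);
      double ekin = 0.0;
      for (int q = 0; q < n3; ++q) ekin += 0.5 * v[q] * v[q];
      samp_time[isamp] = step * dt;
      samp_epot[isamp] = epot;
      samp_ekin[isamp] = ekin;
      if (do_metad) {
        samp_ht[isamp] = s[0];
        samp_stk[isamp] = s[1];
        samp_bias[isamp] = bias.value(s);
      } else {
        samp_ht[isamp] = cv_ht(x.data(), t, 0.0, NULL);
        samp_stk[isamp] = cv_stk(x.data(), t, 0.0, NULL);
        samp_bias[isamp] = 0.0;
      }
      samp_sstk[isamp] = cv_sstk(x.data(), t);
      if (store_frames)
        for (int i = 0; i < t.nsites; ++i)
          for (int k = 0; k < 3; ++k)
            frames[(size_t)isamp * n3 + (size_t)k * t.nsites + i] =
                x[3 * i + k];
      ++isamp;
    }
  }

  NumericMatrix xout(t.nsites, 3);
  for (int i = 0; i < t.nsites; ++i)
    for (int k = 0; k < 3; ++k) xout(i, k) = x[3 * i + k];

  List out = List::create(
      _["time"] = samp_time, _["ht"] = samp_ht, _["stk"] = samp_stk,
      _["sstk"] = samp_sstk, _["bias"] = samp_bias, _["epot"] = samp_epot,
      _["ekin"] = samp_ekin, _["final"] = xout,
      _["hills"] = do_metad ? SEXP(bias.hills_list()) : R_NilValue);
  if (store_frames) out["frames"] = frames;
  return out;
}

// ---------------------------------------------------------------------------
// analytic benchmark potentials: particle Langevin + WT-MetaD
// pot types: "double_well_1d" (h, a, c), "double_well_2d" (h, a, c, ky),
// "harmonic" (k per dim)
// ---------------------------------------------------------------------------
struct Potential {
  int type;   // 0 = dw1d, 1 = dw2d, 2 = harmonic
  int dim;
  double h, a, c, ky;
  std::vector<double> kharm;

  double energy(const double *x, double *grad) const {
    if (type == 0 || type == 1) {
      double a2 = a * a;
      double q = (x[0] * x[0] - a2) / a2;
      double E = h * q * q + c * x[0];
      if (grad) grad[0] = 4.0 * h * x[0] * (x[0] * x[0] - a2) / (a2 * a2) + c;
      if (type == 1) {
        E += 0.5 * ky * x[1] * x[1];
        if (grad) grad[1] = ky * x[1];
      }
      return E;
    }
    double E = 0.0;
    for (int d = 0; d < dim; ++d) {
      E += 0.5 * kharm[d] * x[d] * x[d];
      if (grad) grad[d] = kharm[d] * x[d];
    }
    return E;
  }
};

static Potential unpack_pot(const List &pl) {
  Potential p;
  std::string ty = as<std::string>(pl["type"]);
  if (ty == "double_well_1d") { p.type = 0; p.dim = 1; }
  else if (ty == "double_well_2d") { p.type = 1; p.dim = 2; }
  else if (ty == "harmonic") { p.type = 2; }
  else stop("unknown potential type");
  List pp = pl["params"];
  if (p.type != 2) {
    p.h = as<double>(pp["h"]); p.a = as<double>(pp["a"]);
    p.c = as<double>(pp["c"]);
    p.ky = (p.type == 1) ? as<double>(pp["ky"]) : 0.0;
  } else {
    p.kharm = as_dbl(pp["k"]);
    p.dim = p.kharm.size();
  }
  return p;
}

// [[Rcpp::export]]
List cpp_run_particle(List pot, NumericVector x0, int steps, double dt,
                      double temperature, double friction, int sample_stride,
                      int seed, Nullable<List> metad) {
  Potential P = unpack_pot(pot);
  int dim = P.dim;
  if (x0.size() != dim) stop("x0 dimension mismatch");
  std::vector<double> x(x0.begin(), x0.end()), v(dim, 0.0), grad(dim);

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double kT = KB * temperature;
  double c1 = std::exp(-friction * dt);
  double c2 = (friction > 0) ? std::sqrt((1.0 - c1 * c1) * kT) : 0.0;
  if (temperature > 0)
    for (int d = 0; d < dim; ++d) v[d] = std::sqrt(kT) * gauss(rng);

  bool do_metad = metad.isNotNull();
  BiasGrid bias;
  int bias_dim = 0;
  if (do_metad) {
    bias.init(List(metad));
    bias_dim = bias.dim;   // bias acts on the first bias_dim coordinates
    if (bias_dim > dim) stop("bias dimension exceeds system dimension");
  }

  int nsamp = steps / sample_stride;
  NumericMatrix samp_x(nsamp, dim);
  NumericVector samp_time(nsamp), samp_bias(nsamp), samp_epot(nsamp),
      samp_ekin(nsamp);

  double epot = P.energy(x.data(), grad.data());
  std::vector<double> f(dim);
  for (int d = 0; d < dim; ++d) f[d] = -grad[d];
  double gs[2];
  if (do_metad) {
    bias.gradient(x.data(), gs);
    for (int d = 0; d < bias_dim; ++d) f[d] -= gs[d];
  }

  int isamp = 0;
  for (int step = 1; step <= steps; ++step) {
    for (int d = 0; d < dim; ++d) v[d] += 0.5 * dt * f[d];
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * v[d];
    if (friction > 0)
      for (int d = 0; d < dim; ++d) v[d] = c1 * v[d] + c2 * gauss(rng);
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * v[d];
    epot = P.energy(x.data(), grad.data());
    for (int d = 0; d < dim; ++d) f[d] = -grad[d];
    if (do_metad) {
      if (step % bias.stride_steps == 0) bias.deposit(x.data(), step * dt);
      bias.gradient(x.data(), gs);
      for (int d = 0; d < bias_dim; ++d) f[d] -= gs[d];
    }
    for (int d = 0; d < dim; ++d) v[d] += 0.5 * dt * f[d];

    if (step % sample_stride == 0 && isamp < nsamp) {
      if (!std::isfinite(x[0]))
        stop("divergence at step %d", step);
      double ekin = 0.0;
      for (int d = 0; d < dim; ++d) ekin += 0.5 * v[d] * v[d];
      samp_time[isamp] = step * dt;
      for (int d = 0; d < dim; ++d) samp_x(isamp, d) = x[d];
      samp_bias[isamp] = do_metad ? bias.value(x.data()) : 0.0;
      samp_epot[isamp] = epot;
      samp_ekin[isamp] = ekin;
      ++isamp;
    }
  }
  return List::create(_["time"] = samp_time, _["x"] = samp_x,
                      _["bias"] = samp_bias, _["epot"] = samp_epot,
                      _["ekin"] = samp_ekin,
                      _["hills"] = do_metad ? SEXP(bias.hills_list()) : R_NilValue);
}

// ---------------------------------------------------------------------------
// sum of Gaussian hills evaluated on a grid (1D or 2D), 6-sigma cutoff
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_sum_hills_grid(NumericMatrix centers, NumericVector sigma,
                                 NumericVector heights, List grid_axes,
                                 double cutoff) {
  int dim = grid_axes.size();
  int k = centers.nrow();
  if (dim == 1) {
    NumericVector ax = grid_axes[0];
    int n0 = ax.size();
    NumericVector V(n0);
    double s0 = sigma[0];
    for (int hgl = 0; hgl < k; ++hgl) {
      double c0 = centers(hgl, 0), W = heights[hgl];
      for (int i = 0; i < n0; ++i) {
        double dx = ax[i] - c0;
        if (std::fabs(dx) > cutoff * s0) continue;
        V[i] += W * std::exp(-dx * dx / (2.0 * s0 * s0));
      }
    }
    return V;
  }
  NumericVector ax = grid_axes[0], ay = grid_axes[1];
  int n0 = ax.size(), n1 = ay.size();
  NumericVector V(n0 * n1);
  V.attr("dim") = Dimension(n0, n1);
  double s0 = sigma[0], s1 = sigma[1];
  for (int hgl = 0; hgl < k; ++hgl) {
    double c0 = centers(hgl, 0), c1 = centers(hgl, 1), W = heights[hgl];
    for (int j = 0; j < n1; ++j) {
      double dy = ay[j] - c1;
      if (std::fabs(dy) > cutoff * s1) continue;
      double ey = std::exp(-dy * dy / (2.0 * s1 * s1));
      for (int i = 0; i < n0; ++i) {
        double dx = ax[i] - c0;
        if (std::fabs(dx) > cutoff * s0) continue;
        V[(size_t)j * n0 + i] += W * std::exp(-dx * dx / (2.0 * s0 * s0)) * ey;
      }
    }
  }
  return V;
}

// ---------------------------------------------------------------------------
// time-dependent offset c(t) for metadynamics reweighting: iterate over
// hills in time order accumulating V on the grid; every eval_every hills
// compute c(t) = kT * ln[ sum exp(g V / kT) / sum exp((g - 1) V / kT) ]
// with g = gamma / (gamma - 1) (logsumexp-stabilized).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_ct_profile(NumericVector times, NumericMatrix centers,
                    NumericVector sigma, NumericVector heights,
                    List grid_axes, double gamma, double kT, int eval_every,
                    double cutoff) {
  int dim = grid_axes.size();
  int k = centers.nrow();
  double g = gamma / (gamma - 1.0);
  std::vector<const double *> ax(dim);
  int n[2] = {1, 1};
  NumericVector a0 = grid_axes[0];
  ax[0] = a0.begin();
  n[0] = a0.size();
  NumericVector a1;
  if (dim == 2) {
    a1 = grid_axes[1];
    ax[1] = a1.begin();
    n[1] = a1.size();
  }
  size_t tot = (size_t)n[0] * n[1];
  std::vector<double> V(tot, 0.0);

  std::vector<double> ct_times, ct_vals;
  for (int hq = 0; hq < k; ++hq) {
    double c0 = centers(hq, 0), W = heights[hq];
    double c1v = (dim == 2) ? centers(hq, 1) : 0.0;
    for (int j = 0; j < n[1]; ++j) {
      double ey = 1.0;
      if (dim == 2) {
        double dy = ax[1][j] - c1v;
        if (std::fabs(dy) > cutoff * sigma[1]) continue;
        ey = std::exp(-dy * dy / (2.0 * sigma[1] * sigma[1]));
      }
      for (int i = 0; i < n[0]; ++i) {
        double dx = ax[0][i] - c0;
        if (std::fabs(dx) > cutoff * sigma[0]) continue;
        V[(size_t)j * n[0] + i] +=
            W * std::exp(-dx * dx / (2.0 * sigma[0] * sigma[0])) * ey;
      }
    }
    if ((hq + 1) % eval_every == 0 || hq == k - 1) {
      // logsumexp of g*V/kT and (g-1)*V/kT
      double m1 = -1e300, m2 = -1e300;
      for (size_t q = 0; q < tot; ++q) {
        double e1 = g * V[q] / kT, e2 = (g - 1.0) * V[q] / kT;
        if (e1 > m1) m1 = e1;
        if (e2 > m2) m2 = e2;
      }
      double s1 = 0.0, s2 = 0.0;
      for (size_t q = 0; q < tot; ++q) {
        s1 += std::exp(g * V[q] / kT - m1);
        s2 += std::exp((g - 1.0) * V[q] / kT - m2);
      }
      ct_times.push_back(times[hq]);
      ct_vals.push_back(kT * ((m1 + std::log(s1)) - (m2 + std::log(s2))));
    }
  }
  return List::create(_["time"] = NumericVector(ct_times.begin(), ct_times.end()),
                      _["ct"] = NumericVector(ct_vals.begin(), ct_vals.end()));
}
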