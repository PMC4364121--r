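// Axisymmetric total-Lagrangian hyperelastic kernels.
//
// Basis convention at every material point: e1 = R (radial/meridional plane),
// e2 = Z (optical axis, positive posteriorly), e3 = Theta (circumferential).
// Voigt order: (11, 22, 33, 12, 13, 23); Green-Lagrange strain uses the
// engineering-shear convention in the element B-matrix.
//
// Units: mm, MPa, N.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef arma::vec::fixed<6> V6;
typedef arma::mat::fixed<6, 6> M6;

static const int VI[6] = {0, 1, 2, 0, 0, 1};
static const int VJ[6] = {0, 1, 2, 1, 2, 2};

static inline void sym2v(const mat33 &M, V6 &v) {
  for (int k = 0; k < 6; ++k) v(k) = M(VI[k], VJ[k]);
}

// (A (.) A)_{ijkl} = 1/2 (A_ik A_jl + A_il A_jk) in Voigt 6x6
static inline void symouter(const mat33 &A, M6 &M) {
  for (int I = 0; I < 6; ++I)
    for (int K = 0; K < 6; ++K) {
      int i = VI[I], j = VJ[I], k = VI[K], l = VJ[K];
      M(I, K) = 0.5 * (A(i, k) * A(j, l) + A(i, l) * A(j, k));
    }
}

// Strain energy, PK2 stress and material tangent (dS = CC : dE) at one point.
// model 1 = Gasser-Holzapfel-Ogden, par = (C10, k1, k2, kappa, D, kvol),
//           nf unit reference fiber directions in fib.
// model 2 = Yeoh, par = (C10, C20, C30, D1, D2, D3, kvol), fibers ignored.
// part: 0 full, 1 deviatoric (isochoric) only, 2 volumetric only.
static void material_point(const mat33 &F, int model, const double *par,
                           const double fib[][3], int nf, int part,
                           double cap, double &U, mat33 &Sm, M6 &CC,
                           bool wantCC) {
  double J = det(F);
  if (!(J > 0.0)) Rcpp::stop("singular deformation: det F <= 0");
  mat33 C = F.t() * F;
  mat33 Ci = inv(C);
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double I1 = trace(C);
  double Ib1 = Jm23 * I1;

  V6 Ci6, g16;
  sym2v(Ci, Ci6);
  mat33 g1m = Jm23 * eye(3, 3) - (Ib1 / 3.0) * Ci;
  sym2v(g1m, g16);
  M6 CiCi, CiCo;
  if (wantCC) {
    symouter(Ci, CiCi);
    CiCo = Ci6 * Ci6.t();
  }

  U = 0.0;
  Sm.zeros();
  if (wantCC) CC.zeros();

  bool do_dev = (part == 0 || part == 1);
  bool do_vol = (part == 0 || part == 2);

  if (do_dev) {
    if (model == 1) {
      double C10 = par[0], k1 = par[1], k2 = par[2], kap = par[3];
      double psi1 = C10;
      U += C10 * (Ib1 - 3.0);
      V6 g46[2];
      double psi4[2], fp[2], Ib4v[2];
      for (int a = 0; a < nf; ++a) {
        vec3 d = {fib[a][0], fib[a][1], fib[a][2]};
        double I4 = as_scalar(d.t() * C * d);
        double Ib4 = Jm23 * I4;
        Ib4v[a] = Ib4;
        mat33 g4m = Jm23 * (d * d.t()) - (Ib4 / 3.0) * Ci;
        sym2v(g4m, g46[a]);
        double E = kap * (Ib1 - 3.0) + (1.0 - 3.0 * kap) * (Ib4 - 1.0);
        double f = 0.0, fpv = 0.0;
        if (E > 0.0) {
          double q = k2 * E * E;
          if (q > cap)
            Rcpp::stop("diverged material: k2*<E>^2 = %g exceeds cap %g", q, cap);
          double ex = std::exp(q);
          f = k1 * ex * E;
          fpv = k1 * ex * (1.0 + 2.0 * k2 * E * E);
          U += k1 / (2.0 * k2) * (ex - 1.0);
        }
        psi1 += kap * f;
        psi4[a] = (1.0 - 3.0 * kap) * f;
        fp[a] = fpv;
        Sm += 2.0 * psi4[a] * g4m;
      }
      Sm += 2.0 * psi1 * g1m;
      if (wantCC) {
        for (int a = 0; a < nf; ++a) {
          if (fp[a] != 0.0) {
            // fiber curvature term: h = kap g1 + (1 - 3 kap) g4
            V6 h = kap * g16 + (1.0 - 3.0 * kap) * g46[a];
            CC += 4.0 * fp[a] * (h * h.t());
          }
          CC += -(4.0 / 3.0) * psi4[a] *
                (g46[a] * Ci6.t() + Ci6 * g46[a].t() +
                 (Ib4v[a] / 3.0) * CiCo - Ib4v[a] * CiCi);
        }
        CC += -(4.0 / 3.0) * psi1 *
              (g16 * Ci6.t() + Ci6 * g16.t() + (Ib1 / 3.0) * CiCo -
               Ib1 * CiCi);
      }
    } else if (model == 2) {
      double x = Ib1 - 3.0;
      double C10 = par[0], C20 = par[1], C30 = par[2];
      double psi1 = C10 + 2.0 * C20 * x + 3.0 * C30 * x * x;
      double psi1p = 2.0 * C20 + 6.0 * C30 * x;
      U += C10 * x + C20 * x * x + C30 * x * x * x;
      Sm += 2.0 * psi1 * g1m;
      if (wantCC) {
        CC += 4.0 * psi1p * (g16 * g16.t());
        CC += -(4.0 / 3.0) * psi1 *
              (g16 * Ci6.t() + Ci6 * g16.t() + (Ib1 / 3.0) * CiCo -
               Ib1 * CiCi);
      }
    } else {
      Rcpp::stop("unknown material model");
    }
  }

  if (do_vol) {
    double p = 0.0, pp = 0.0, Uv = 0.0;
    if (model == 1) {
      double D = par[4], kv = par[5];
      if (D > 0.0) {
        p = (J - 1.0 / J) / D;
        pp = (1.0 + 1.0 / (J * J)) / D;
        Uv = ((J * J - 1.0) / 2.0 - std::log(J)) / D;
      } else if (kv > 0.0) {
        p = kv * (J - 1.0);
        pp = kv;
        Uv = 0.5 * kv * (J - 1.0) * (J - 1.0);
      }
    } else {
      double kv = par[6];
      bool anyD = (par[3] > 0.0 || par[4] > 0.0 || par[5] > 0.0);
      if (anyD) {
        double dj = J - 1.0;
        for (int i = 1; i <= 3; ++i) {
          double Di = par[2 + i];
          if (Di > 0.0) {
            Uv += std::pow(dj, 2 * i) / Di;
            p += (2.0 * i) * std::pow(dj, 2 * i - 1) / Di;
            if (2 * i - 2 == 0) pp += 2.0 * i * (2.0 * i - 1.0) / Di;
            else pp += 2.0 * i * (2.0 * i - 1.0) * std::pow(dj, 2 * i - 2) / Di;
          }
        }
      } else if (kv > 0.0) {
        p = kv * (J - 1.0);
        pp = kv;
        Uv = 0.5 * kv * (J - 1.0) * (J - 1.0);
      }
    }
    U += Uv;
    Sm += J * p * Ci;
    if (wantCC) {
      CC += (p + J * pp) * J * CiCo;
      CC += -2.0 * J * p * CiCi;
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_material_point(const arma::mat &F, int model,
                              const arma::vec &par, const arma::mat &fib,
                              int part, double cap, bool want_tangent) {
  mat33 Fm = F;
  double U;
  mat33 Sm;
  M6 CC;
  double fb[2][3];
  int nf = std::min((int)fib.n_rows, 2);
  for (int a = 0; a < nf; ++a)
    for (int k = 0; k < 3; ++k) fb[a][k] = fib(a, k);
  std::vector<double> pv(par.begin(), par.end());
  pv.resize(8, 0.0);
  material_point(Fm, model, pv.data(), fb, nf, part, cap, U, Sm, CC,
                 want_tangent);
  double J = det(Fm);
  mat33 cauchy = Fm * Sm * Fm.t() / J;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("energy") = U,
      Rcpp::Named("pk2") = Rcpp::wrap(mat(Sm)),
      Rcpp::Named("cauchy") = Rcpp::wrap(mat(cauchy)));
  if (want_tangent) out["tangent"] = Rcpp::wrap(mat(CC));
  return out;
}

// ---- 9-node Lagrangian quadrilateral shape functions --------------------

struct ShapeGP {
  double N[9], dxi[9], deta[9], w;
};

static void shape_at(double xi, double eta, double w, ShapeGP &s) {
  double L[3] = {0.5 * xi * (xi - 1.0), 1.0 - xi * xi, 0.5 * xi * (xi + 1.0)};
  double dL[3] = {xi - 0.5, -2.0 * xi, xi + 0.5};
  double M[3] = {0.5 * eta * (eta - 1.0), 1.0 - eta * eta,
                 0.5 * eta * (eta + 1.0)};
  double dM[3] = {eta - 0.5, -2.0 * eta, eta + 0.5};
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) {
      int k = 3 * j + i;
      s.N[k] = L[i] * M[j];
      s.dxi[k] = dL[i] * M[j];
      s.deta[k] = L[i] * dM[j];
    }
  s.w = w;
}

// precomputed Gauss tables: 3x3 (full) and 2x2 (reduced)
static std::vector<ShapeGP> make_table(int n) {
  std::vector<double> x, w;
  if (n == 2) {
    double a = 1.0 / std::sqrt(3.0);
    x = {-a, a};
    w = {1.0, 1.0};
  } else {
    double a = std::sqrt(3.0 / 5.0);
    x = {-a, 0.0, a};
    w = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
  }
  std::vector<ShapeGP> tab(n * n);
  int k = 0;
  for (size_t a = 0; a < x.size(); ++a)
    for (size_t b = 0; b < x.size(); ++b)
      shape_at(x[a], x[b], w[a] * w[b], tab[k++]);
  return tab;
}

static const std::vector<ShapeGP> TAB3 = make_table(3);
static const std::vector<ShapeGP> TAB2 = make_table(2);

// Element pass over one Gauss table with one material part.
static void element_pass(const mat::fixed<9, 2> &Xe,
                         const mat::fixed<9, 2> &Ue, int model,
                         const double *par, bool has_fibers, int part,
                         double cap, const std::vector<ShapeGP> &tab,
                         bool wantK, vec::fixed<18> &fe,
                         mat::fixed<18, 18> &Ke, double &energy) {
  const double TWO_PI = 2.0 * M_PI;
  double dNR[9], dNZ[9];
  for (size_t q = 0; q < tab.size(); ++q) {
    const ShapeGP &s = tab[q];
    double dRdxi = 0, dZdxi = 0, dRdeta = 0, dZdeta = 0, Rgp = 0, ur = 0;
    for (int k = 0; k < 9; ++k) {
      dRdxi += s.dxi[k] * Xe(k, 0);
      dZdxi += s.dxi[k] * Xe(k, 1);
      dRdeta += s.deta[k] * Xe(k, 0);
      dZdeta += s.deta[k] * Xe(k, 1);
      Rgp += s.N[k] * Xe(k, 0);
      ur += s.N[k] * Ue(k, 0);
    }
    double detJ = dRdxi * dZdeta - dZdxi * dRdeta;
    if (!(detJ > 0.0)) Rcpp::stop("non-positive element Jacobian");
    if (Rgp <= 0.0) Rcpp::stop("Gauss point at non-positive radius");
    double F11 = 1, F12 = 0, F21 = 0, F22 = 1;
    for (int k = 0; k < 9; ++k) {
      dNR[k] = (dZdeta * s.dxi[k] - dZdxi * s.deta[k]) / detJ;
      dNZ[k] = (-dRdeta * s.dxi[k] + dRdxi * s.deta[k]) / detJ;
      F11 += dNR[k] * Ue(k, 0);
      F12 += dNZ[k] * Ue(k, 0);
      F21 += dNR[k] * Ue(k, 1);
      F22 += dNZ[k] * Ue(k, 1);
    }
    double F33 = 1.0 + ur / Rgp;
    mat33 F = {{F11, F12, 0.0}, {F21, F22, 0.0}, {0.0, 0.0, F33}};

    double fb[2][3];
    int nf = 0;
    if (has_fibers) {
      double tn = std::sqrt(dRdxi * dRdxi + dZdxi * dZdxi);
      fb[0][0] = dRdxi / tn; fb[0][1] = dZdxi / tn; fb[0][2] = 0.0;
      fb[1][0] = 0.0; fb[1][1] = 0.0; fb[1][2] = 1.0;
      nf = 2;
    }

    double U;
    mat33 Sm;
    M6 CC;
    material_point(F, model, par, fb, nf, part, cap, U, Sm, CC, wantK);

    double w = detJ * s.w * TWO_PI * Rgp;
    energy += U * w;

    // B matrix (4 x 18), rows: E_RR, E_ZZ, E_TT, 2 E_RZ
    mat::fixed<4, 18> B;
    B.zeros();
    for (int n = 0; n < 9; ++n) {
      B(0, 2 * n) = F11 * dNR[n];
      B(0, 2 * n + 1) = F21 * dNR[n];
      B(1, 2 * n) = F12 * dNZ[n];
      B(1, 2 * n + 1) = F22 * dNZ[n];
      B(2, 2 * n) = F33 * s.N[n] / Rgp;
      B(3, 2 * n) = F11 * dNZ[n] + F12 * dNR[n];
      B(3, 2 * n + 1) = F21 * dNZ[n] + F22 * dNR[n];
    }
    vec::fixed<4> S4 = {Sm(0, 0), Sm(1, 1), Sm(2, 2), Sm(0, 1)};
    fe += B.t() * (w * S4);
    if (wantK) {
      mat::fixed<4, 4> D4;
      for (int I = 0; I < 4; ++I)
        for (int K = 0; K < 4; ++K) D4(I, K) = CC(I, K);
      Ke += B.t() * (w * D4) * B;
      // geometric stiffness
      double S11 = Sm(0, 0), S22 = Sm(1, 1), S33 = Sm(2, 2), S12 = Sm(0, 1);
      for (int p = 0; p < 9; ++p)
        for (int qn = 0; qn < 9; ++qn) {
          double G = dNR[p] * S11 * dNR[qn] + dNZ[p] * S22 * dNZ[qn] +
                     S12 * (dNR[p] * dNZ[qn] + dNZ[p] * dNR[qn]);
          Ke(2 * p, 2 * qn) += (G + S33 * s.N[p] * s.N[qn] / (Rgp * Rgp)) * w;
          Ke(2 * p + 1, 2 * qn + 1) += G * w;
        }
    }
  }
}

// Assemble internal force, tangent stiffness triplets and total energy.
// nodes, disp: n x 2 (R, Z) / (u_r, u_z); elems: ne x 9 zero-based,
// tensor-product local ordering (xi fastest, meridional direction = xi);
// region: ne zero-based material index; models / params / fibered: per
// material. Deviatoric terms use full 3x3 integration, volumetric terms
// reduced 2x2 (selective reduced integration for near-incompressibility).
// [[Rcpp::export]]
Rcpp::List cpp_assemble(const arma::mat &nodes, const arma::mat &disp,
                        const arma::imat &elems, const arma::ivec &region,
                        const arma::ivec &models, const Rcpp::List &params,
                        const arma::ivec &fibered, double cap, bool wantK) {
  int ne = elems.n_rows, n = nodes.n_rows;
  vec f(2 * n, fill::zeros);
  double energy = 0.0;
  std::vector<int> vi, vj;
  std::vector<double> vv;
  if (wantK) {
    vi.reserve((size_t)ne * 324);
    vj.reserve((size_t)ne * 324);
    vv.reserve((size_t)ne * 324);
  }
  int nmat = params.size();
  std::vector<std::vector<double> > pars(nmat);
  for (int m = 0; m < nmat; ++m) {
    pars[m] = Rcpp::as<std::vector<double> >(params[m]);
    pars[m].resize(8, 0.0);
  }

  mat::fixed<9, 2> Xe, Ue;
  vec::fixed<18> fe;
  mat::fixed<18, 18> Ke;
  for (int e = 0; e < ne; ++e) {
    for (int k = 0; k < 9; ++k) {
      int nd = elems(e, k);
      Xe(k, 0) = nodes(nd, 0); Xe(k, 1) = nodes(nd, 1);
      Ue(k, 0) = disp(nd, 0); Ue(k, 1) = disp(nd, 1);
    }
    int m = region(e);
    fe.zeros();
    Ke.zeros();
    element_pass(Xe, Ue, models(m), pars[m].data(), fibered(m) != 0, 1, cap,
                 TAB3, wantK, fe, Ke, energy);
    element_pass(Xe, Ue, models(m), pars[m].data(), fibered(m) != 0, 2, cap,
                 TAB2, wantK, fe, Ke, energy);
    for (int p = 0; p < 9; ++p) {
      int gp = elems(e, p);
      f(2 * gp) += fe(2 * p);
      f(2 * gp + 1) += fe(2 * p + 1);
    }
    if (wantK) {
      for (int p = 0; p < 18; ++p) {
        int gp = 2 * elems(e, p / 2) + (p % 2);
        for (int q = 0; q < 18; ++q) {
          double v = Ke(p, q);
          if (v != 0.0) {
            int gq = 2 * elems(e, q / 2) + (q % 2);
            vi.push_back(gp + 1);
            vj.push_back(gq + 1);
            vv.push_back(v);
          }
        }
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("f") = Rcpp::wrap(f),
      Rcpp::Named("energy") = energy);
  if (wantK) {
    out["ki"] = Rcpp::wrap(vi);
    out["kj"] = Rcpp::wrap(vj);
    out["kv"] = Rcpp::wrap(vv);
  }
  return out;
}

// Deformed radial coordinate at the Gauss points of quadratic boundary
// edges. edges: nedge x 3 zero-based node triples ordered along the
// meridian.
// [[Rcpp::export]]
arma::mat cpp_edge_gp_r(const arma::mat &nodes, const arma::mat &disp,
                        const arma::imat &edges) {
  double gx[3] = {-std::sqrt(3.0 / 5.0), 0.0, std::sqrt(3.0 / 5.0)};
  int ne = edges.n_rows;
  mat out(ne, 3);
  for (int e = 0; e < ne; ++e)
    for (int q = 0; q < 3; ++q) {
      double xi = gx[q];
      double L[3] = {0.5 * xi * (xi - 1.0), 1.0 - xi * xi,
                     0.5 * xi * (xi + 1.0)};
      double r = 0.0;
      for (int k = 0; k < 3; ++k) {
        int nd = edges(e, k);
        r += L[k] * (nodes(nd, 0) + disp(nd, 0));
      }
      out(e, q) = r;
    }
  return out;
}

// External load vector and load-stiffness triplets for boundary edges.
// mode 1: follower pressure p (MPa), pushing towards (z', -r') of the
//         edge traversal direction (outward for interior edges ordered
//         apex -> equator).
// mode 2: collimated axial jet: traction q(r) (MPa) acting on the
//         projected annulus, force along +Z; dpg = dq/dr at the Gauss
//         points.
// pg, dpg: nedge x 3 values at the 3 Gauss points.
// [[Rcpp::export]]
Rcpp::List cpp_edge_load(const arma::mat &nodes, const arma::mat &disp,
                         const arma::imat &edges, int mode,
                         const arma::mat &pg, const arma::mat &dpg) {
  double gx[3] = {-std::sqrt(3.0 / 5.0), 0.0, std::sqrt(3.0 / 5.0)};
  double gw[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
  int n = nodes.n_rows, ne = edges.n_rows;
  vec f(2 * n, fill::zeros);
  std::vector<int> vi, vj;
  std::vector<double> vv;
  const double TWO_PI = 2.0 * M_PI;
  for (int e = 0; e < ne; ++e) {
    vec::fixed<6> fe;
    mat::fixed<6, 6> Ke;  // d f_e / d u_e (added to the external force)
    fe.zeros();
    Ke.zeros();
    for (int q = 0; q < 3; ++q) {
      double xi = gx[q], w = gw[q];
      double L[3] = {0.5 * xi * (xi - 1.0), 1.0 - xi * xi,
                     0.5 * xi * (xi + 1.0)};
      double dL[3] = {xi - 0.5, -2.0 * xi, xi + 0.5};
      double r = 0.0, rp = 0.0, zp = 0.0;
      for (int k = 0; k < 3; ++k) {
        int nd = edges(e, k);
        double rc = nodes(nd, 0) + disp(nd, 0);
        double zc = nodes(nd, 1) + disp(nd, 1);
        r += L[k] * rc;
        rp += dL[k] * rc;
        zp += dL[k] * zc;
      }
      double p = pg(e, q);
      if (mode == 1) {
        for (int a = 0; a < 3; ++a) {
          fe(2 * a) += TWO_PI * p * L[a] * r * zp * w;
          fe(2 * a + 1) += -TWO_PI * p * L[a] * r * rp * w;
          for (int b = 0; b < 3; ++b) {
            Ke(2 * a, 2 * b) += TWO_PI * p * L[a] * L[b] * zp * w;
            Ke(2 * a, 2 * b + 1) += TWO_PI * p * L[a] * r * dL[b] * w;
            Ke(2 * a + 1, 2 * b) +=
                -TWO_PI * p * (L[a] * L[b] * rp + L[a] * r * dL[b]) * w;
          }
        }
      } else {
        double dp = dpg(e, q);
        for (int a = 0; a < 3; ++a) {
          fe(2 * a + 1) += TWO_PI * p * L[a] * r * rp * w;
          for (int b = 0; b < 3; ++b) {
            Ke(2 * a + 1, 2 * b) +=
                TWO_PI * w * (dp * L[b] * L[a] * r * rp +
                              p * L[a] * (L[b] * rp + r * dL[b]));
          }
        }
      }
    }
    for (int a = 0; a < 3; ++a) {
      int ga = edges(e, a);
      f(2 * ga) += fe(2 * a);
      f(2 * ga + 1) += fe(2 * a + 1);
    }
    for (int p = 0; p < 6; ++p) {
      int gp = 2 * edges(e, p / 2) + (p % 2);
      for (int q2 = 0; q2 < 6; ++q2) {
        double v = Ke(p, q2);
        if (v != 0.0) {
          int gq = 2 * edges(e, q2 / 2) + (q2 % 2);
          vi.push_back(gp + 1);
          vj.push_back(gq + 1);
          vv.push_back(v);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("f") = Rcpp::wrap(f),
                            Rcpp::Named("ki") = Rcpp::wrap(vi),
                            Rcpp::Named("kj") = Rcpp::wrap(vj),
                            Rcpp::Named("kv") = Rcpp::wrap(vv));
}

// Minimum reference Jacobian over all Gauss points (mesh validity check).
// [[Rcpp::export]]
double cpp_min_jacobian(const arma::mat &nodes, const arma::imat &elems) {
  double mn = datum::inf;
  for (unsigned e = 0; e < elems.n_rows; ++e) {
    mat::fixed<9, 2> Xe;
    for (int k = 0; k < 9; ++k) {
      int nd = elems(e, k);
      Xe(k, 0) = nodes(nd, 0); Xe(k, 1) = nodes(nd, 1);
    }
    for (size_t q = 0; q < TAB3.size(); ++q) {
      const ShapeGP &s = TAB3[q];
      double a = 0, b = 0, c = 0, d = 0;
      for (int k = 0; k < 9; ++k) {
        a += s.dxi[k] * Xe(k, 0);
        b += s.dxi[k] * Xe(k, 1);
        c += s.deta[k] * Xe(k, 0);
        d += s.deta[k] * Xe(k, 1);
      }
      double detJ = a * d - b * c;
      if (detJ < mn) mn = detJ;
    }
  }
  return mn;
}

// Per-Gauss-point field quantities for post-processing / snapshots.
// Columns: elem, Rref, Zref, rdef, zdef, J, lam_merid, lam_hoop,
//          sig_merid, sig_hoop, log_hoop_strain, s_rr, s_zz, s_tt, s_rz,
//          energy, region (1-based).
// [[Rcpp::export]]
arma::mat cpp_field(const arma::mat &nodes, const arma::mat &disp,
                    const arma::imat &elems, const arma::ivec &region,
                    const arma::ivec &models, const Rcpp::List &params,
                    const arma::ivec &fibered, double cap) {
  int ne = elems.n_rows;
  mat out(ne * 9, 17);
  int nmat = params.size();
  std::vector<std::vector<double> > pars(nmat);
  for (int m = 0; m < nmat; ++m) {
    pars[m] = Rcpp::as<std::vector<double> >(params[m]);
    pars[m].resize(8, 0.0);
  }
  int row = 0;
  for (int e = 0; e < ne; ++e) {
    mat::fixed<9, 2> Xe, Ue;
    for (int k = 0; k < 9; ++k) {
      int nd = elems(e, k);
      Xe(k, 0) = nodes(nd, 0); Xe(k, 1) = nodes(nd, 1);
      Ue(k, 0) = disp(nd, 0); Ue(k, 1) = disp(nd, 1);
    }
    int m = region(e);
    for (size_t q = 0; q < TAB3.size(); ++q) {
      const ShapeGP &s = TAB3[q];
      double dRdxi = 0, dZdxi = 0, dRdeta = 0, dZdeta = 0, Rgp = 0, Zgp = 0,
             ur = 0, uz = 0;
      for (int k = 0; k < 9; ++k) {
        dRdxi += s.dxi[k] * Xe(k, 0);
        dZdxi += s.dxi[k] * Xe(k, 1);
        dRdeta += s.deta[k] * Xe(k, 0);
        dZdeta += s.deta[k] * Xe(k, 1);
        Rgp += s.N[k] * Xe(k, 0);
        Zgp += s.N[k] * Xe(k, 1);
        ur += s.N[k] * Ue(k, 0);
        uz += s.N[k] * Ue(k, 1);
      }
      double detJ = dRdxi * dZdeta - dZdxi * dRdeta;
      double F11 = 1, F12 = 0, F21 = 0, F22 = 1;
      for (int k = 0; k < 9; ++k) {
        double dNR = (dZdeta * s.dxi[k] - dZdxi * s.deta[k]) / detJ;
        double dNZ = (-dRdeta * s.dxi[k] + dRdxi * s.deta[k]) / detJ;
        F11 += dNR * Ue(k, 0);
        F12 += dNZ * Ue(k, 0);
        F21 += dNR * Ue(k, 1);
        F22 += dNZ * Ue(k, 1);
      }
      double F33 = 1.0 + ur / Rgp;
      mat33 F = {{F11, F12, 0.0}, {F21, F22, 0.0}, {0.0, 0.0, F33}};
      double tn = std::sqrt(dRdxi * dRdxi + dZdxi * dZdxi);
      double fb[2][3] = {{dRdxi / tn, dZdxi / tn, 0.0}, {0.0, 0.0, 1.0}};
      int nf = fibered(m) != 0 ? 2 : 0;
      double U;
      mat33 Sm;
      M6 CC;
      material_point(F, models(m), pars[m].data(), fb, nf, 0, cap, U, Sm,
                     CC, false);
      double J = det(F);
      mat33 sig = F * Sm * F.t() / J;
      vec3 a0 = {dRdxi / tn, dZdxi / tn, 0.0};
      vec3 md = F * a0;
      double lamM = norm(md);
      md /= lamM;
      double sigM = as_scalar(md.t() * sig * md);
      out(row, 0) = e + 1;
      out(row, 1) = Rgp; out(row, 2) = Zgp;
      out(row, 3) = Rgp + ur; out(row, 4) = Zgp + uz;
      out(row, 5) = J;
      out(row, 6) = lamM; out(row, 7) = F33;
      out(row, 8) = sigM; out(row, 9) = sig(2, 2);
      out(row, 10) = std::log(F33);
      out(row, 11) = sig(0, 0); out(row, 12) = sig(1, 1);
      out(row, 13) = sig(2, 2); out(row, 14) = sig(0, 1);
      out(row, 15) = U;
      out(row, 16) = m + 1;
      ++row;
    }
  }
  return out;
}
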