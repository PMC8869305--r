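// Material-point and element-level kernels for the fiber-reinforced
// hyperelastic law with continuum damage, and total-Lagrangian assembly
// over 4-node tetrahedra. All quantities in SI (Pa, m, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct MatPars {
  double C1, D, k1, k2, kdisp, l0, lc, beta, gfloor;
  bool isochoric, damage_vol;
};

static MatPars parse_pars(const List& p) {
  MatPars m;
  m.C1 = as<double>(p["C1"]);
  m.D = as<double>(p["D"]);
  m.k1 = as<double>(p["k1"]);
  m.k2 = as<double>(p["k2"]);
  m.kdisp = as<double>(p["k"]);
  m.l0 = as<double>(p["lambda0"]);
  m.lc = as<double>(p["lambdaC"]);
  m.beta = as<double>(p["beta"]);
  m.gfloor = as<double>(p["gFloor"]);
  m.isochoric = p.containsElementNamed("isochoric") ? as<bool>(p["isochoric"]) : true;
  m.damage_vol = p.containsElementNamed("damageVolumetric") ? as<bool>(p["damageVolumetric"]) : false;
  return m;
}

// Damage multiplier G(lambdaMax): 1 below lambda0, exponential decay law
// above, clamped at the residual degradation floor.
static double damage_G(double lm, const MatPars& p) {
  if (lm <= p.l0) return 1.0;
  double den = 1.0 - std::exp(0.5 * p.beta * (std::pow(p.l0, 4) - std::pow(p.lc, 4)));
  double num = 1.0 - std::exp(0.5 * p.beta * (std::pow(lm, 4) - std::pow(p.lc, 4)));
  double g = num / den;
  if (g < p.gfloor) g = p.gfloor;
  if (g > 1.0) g = 1.0;
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_damage_factor(NumericVector lambdaMax, List params) {
  MatPars mp = parse_pars(params);
  NumericVector out(lambdaMax.size());
  for (int i = 0; i < lambdaMax.size(); ++i) out[i] = damage_G(lambdaMax[i], mp);
  return out;
}

// Evaluate energy density W, first Piola stress P = dW/dF and (optionally)
// the full tangent A = d2W/dFdF (9x9, column-major pairing (i,p)->i+3p)
// at one material point. G is the frozen damage multiplier. include_vol
// switches the element-local volumetric term (off when the nodal-averaged
// pressure treatment supplies it).
static bool point_eval(const arma::mat33& F, const arma::vec3& a0, const MatPars& mp,
                       double G, bool include_vol, bool want_A,
                       double& W, arma::mat33& P, arma::mat& A,
                       double& J_out, double& I1_out, double& I4_out,
                       double& u1_out, double& u4_out) {
  double J = arma::det(F);
  J_out = J;
  if (!(J > 0.0)) return false;
  arma::mat33 Finv = arma::inv(F);
  double I1 = arma::accu(F % F);
  arma::vec3 m = F * a0;
  double I4 = arma::dot(m, m);
  I1_out = I1; I4_out = I4;

  double s = mp.isochoric ? std::pow(J, -2.0 / 3.0) : 1.0;
  double u1 = s * I1, u4 = s * I4;
  u1_out = u1; u4_out = u4;

  arma::mat33 du1, du4;
  if (mp.isochoric) {
    // d(u)/dF for the isochoric invariants; indices (i,p) = dW/dF_ip
    du1 = 2.0 * s * F;
    du4 = 2.0 * s * (m * a0.t());
    for (int i = 0; i < 3; ++i)
      for (int p = 0; p < 3; ++p) {
        du1(i, p) -= (2.0 / 3.0) * u1 * Finv(p, i);
        du4(i, p) -= (2.0 / 3.0) * u4 * Finv(p, i);
      }
  } else {
    du1 = 2.0 * F;
    du4 = 2.0 * (m * a0.t());
  }

  bool active = (u4 > 1.0) && (mp.k1 > 0.0);
  double E = mp.kdisp * (u1 - 3.0) + (1.0 - 3.0 * mp.kdisp) * (u4 - 1.0);
  double expf = active ? std::exp(mp.k2 * E * E) : 1.0;
  double Wf = active ? mp.k1 / (2.0 * mp.k2) * (expf - 1.0) : 0.0;
  double Phi1 = active ? mp.k1 * E * expf : 0.0;
  double Phi2 = active ? mp.k1 * expf * (1.0 + 2.0 * mp.k2 * E * E) : 0.0;
  double psi1 = mp.C1 + Phi1 * mp.kdisp;
  double psi4 = Phi1 * (1.0 - 3.0 * mp.kdisp);
  double psi11 = Phi2 * mp.kdisp * mp.kdisp;
  double psi14 = Phi2 * mp.kdisp * (1.0 - 3.0 * mp.kdisp);
  double psi44 = Phi2 * (1.0 - 3.0 * mp.kdisp) * (1.0 - 3.0 * mp.kdisp);

  double Wiso = mp.C1 * (u1 - 3.0) + Wf;
  double U = (1.0 / mp.D) * ((J * J - 1.0) / 2.0 - std::log(J));
  double Up = (1.0 / mp.D) * (J - 1.0 / J);
  double Upp = (1.0 / mp.D) * (1.0 + 1.0 / (J * J));
  double Gv = mp.damage_vol ? G : 1.0;

  W = G * Wiso + (include_vol ? Gv * U : 0.0);
  P = G * (psi1 * du1 + psi4 * du4);
  if (include_vol)
    for (int i = 0; i < 3; ++i)
      for (int p = 0; p < 3; ++p)
        P(i, p) += Gv * Up * J * Finv(p, i);

  if (want_A) {
    A.set_size(9, 9);
    for (int i = 0; i < 3; ++i)
      for (int p = 0; p < 3; ++p)
        for (int j = 0; j < 3; ++j)
          for (int q = 0; q < 3; ++q) {
            double d2u1, d2u4;
            double dij = (i == j) ? 1.0 : 0.0;
            if (mp.isochoric) {
              double dpq = (p == q) ? 1.0 : 0.0;
              d2u1 = -(4.0 / 3.0) * s * (F(i, p) * Finv(q, j) + F(j, q) * Finv(p, i))
                   + 2.0 * s * dij * dpq
                   + (4.0 / 9.0) * u1 * Finv(p, i) * Finv(q, j)
                   + (2.0 / 3.0) * u1 * Finv(p, j) * Finv(q, i);
              d2u4 = -(4.0 / 3.0) * s * (Finv(q, j) * m(i) * a0(p) + m(j) * a0(q) * Finv(p, i))
                   + 2.0 * s * dij * a0(p) * a0(q)
                   + (4.0 / 9.0) * u4 * Finv(q, j) * Finv(p, i)
                   + (2.0 / 3.0) * u4 * Finv(p, j) * Finv(q, i);
            } else {
              double dpq = (p == q) ? 1.0 : 0.0;
              d2u1 = 2.0 * dij * dpq;
              d2u4 = 2.0 * dij * a0(p) * a0(q);
            }
            double val = G * (psi11 * du1(i, p) * du1(j, q)
                            + psi14 * (du1(i, p) * du4(j, q) + du4(i, p) * du1(j, q))
                            + psi44 * du4(i, p) * du4(j, q)
                            + psi1 * d2u1 + psi4 * d2u4);
            if (include_vol) {
              val += Gv * (Upp * J * J * Finv(q, j) * Finv(p, i)
                         + Up * J * Finv(q, j) * Finv(p, i)
                         - Up * J * Finv(p, j) * Finv(q, i));
            }
            A(i + 3 * p, j + 3 * q) = val;
          }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_point(arma::mat F, arma::vec a0, List params, double lambdaMax,
               bool want_tangent = false, bool include_vol = true) {
  MatPars mp = parse_pars(params);
  double G = damage_G(lambdaMax, mp);
  double W, J, I1, I4, u1, u4;
  arma::mat33 Fm = F, P;
  arma::mat A;
  bool ok = point_eval(Fm, a0, mp, G, include_vol, want_tangent, W, P, A, J, I1, I4, u1, u4);
  if (!ok) stop("invalid deformation: det(F) <= 0");
  arma::mat33 cauchy = (1.0 / J) * P * Fm.t();
  List out = List::create(
    _["J"] = J, _["I1"] = I1, _["I4"] = I4, _["Ib1"] = u1, _["Ib4"] = u4,
    _["G"] = G, _["energy"] = W,
    _["P"] = wrap(arma::mat(P)), _["cauchy"] = wrap(arma::mat(cauchy)));
  if (want_tangent) out["A"] = wrap(A);
  return out;
}

// Total-Lagrangian assembly over linear tetrahedra.
// mode: 0 = displacement (element-local volumetric term),
//       1 = averaged nodal pressure (mixed u-p; volumetric term evaluated at
//           volume-weighted nodal Jacobians, rank-one nodal stiffness
//           returned factored as H / cU for K_vol = H' diag(cU) H).
// [[Rcpp::export]]
List cpp_assemble(NumericMatrix X, NumericMatrix xcur, IntegerMatrix elems,
                  NumericMatrix fibers, NumericVector lambdaMax,
                  LogicalVector damage_on, List params,
                  int mode = 1, bool want_K = true) {
  MatPars mp = parse_pars(params);
  const int nn = X.nrow(), ne = elems.nrow();
  arma::vec f(3 * nn, arma::fill::zeros);
  arma::vec fabsacc(3 * nn, arma::fill::zeros);  // |contribution| sums: round-off scale
  arma::vec Je(ne), Ib4e(ne), We(ne), V0e(ne), Ge(ne);
  arma::mat cauchy_e(ne, 6);
  bool nodal = (mode == 1);

  std::vector<double> Ki, Kj, Kv;
  if (want_K) { Ki.reserve((size_t)ne * 144); Kj.reserve((size_t)ne * 144); Kv.reserve((size_t)ne * 144); }

  // per-element data cached for the nodal-pressure pass
  arma::mat w_all(nodal ? ne : 1, nodal ? 12 : 1, arma::fill::zeros);
  arma::vec V0node(nn, arma::fill::zeros), VJnode(nn, arma::fill::zeros);

  arma::mat gradN_all(ne, 12);  // 4 nodes x 3 comps
  bool ok = true;
  int bad_elem = -1;

  // pass 1: kinematics, isochoric (or full) element contributions
  std::vector<arma::mat> Kes;
  if (want_K) Kes.resize(ne);
  std::vector<arma::mat33> Finv_all(ne);
  for (int e = 0; e < ne; ++e) {
    int n1 = elems(e, 0) - 1, n2 = elems(e, 1) - 1, n3 = elems(e, 2) - 1, n4 = elems(e, 3) - 1;
    arma::mat33 Dm, dm;
    for (int i = 0; i < 3; ++i) {
      Dm(i, 0) = X(n2, i) - X(n1, i); Dm(i, 1) = X(n3, i) - X(n1, i); Dm(i, 2) = X(n4, i) - X(n1, i);
      dm(i, 0) = xcur(n2, i) - xcur(n1, i); dm(i, 1) = xcur(n3, i) - xcur(n1, i); dm(i, 2) = xcur(n4, i) - xcur(n1, i);
    }
    double detDm = arma::det(Dm);
    if (!(detDm > 0.0)) stop("reference mesh has a non-positively-oriented tetrahedron (element %d)", e + 1);
    double V0 = detDm / 6.0;
    V0e(e) = V0;
    arma::mat33 Bm = arma::inv(Dm);
    // gradN rows: node 1 = -sum, nodes 2..4 = rows of Bm
    arma::mat gN(4, 3);
    for (int p = 0; p < 3; ++p) {
      gN(1, p) = Bm(0, p); gN(2, p) = Bm(1, p); gN(3, p) = Bm(2, p);
      gN(0, p) = -(Bm(0, p) + Bm(1, p) + Bm(2, p));
    }
    for (int a = 0; a < 4; ++a) for (int p = 0; p < 3; ++p) gradN_all(e, 3 * a + p) = gN(a, p);

    arma::mat33 F = dm * Bm;
    arma::vec3 a0 = { fibers(e, 0), fibers(e, 1), fibers(e, 2) };
    double G = damage_on[e] ? damage_G(lambdaMax[e], mp) : 1.0;
    Ge(e) = G;
    double W, J, I1, I4, u1, u4;
    arma::mat33 P;
    arma::mat A;
    bool pe = point_eval(F, a0, mp, G, !nodal, want_K, W, P, A, J, I1, I4, u1, u4);
    if (!pe) { ok = false; bad_elem = e; break; }
    Je(e) = J; Ib4e(e) = mp.isochoric ? u4 : std::pow(J, -2.0 / 3.0) * I4; We(e) = W;
    arma::mat33 Finv = arma::inv(F);
    Finv_all[e] = Finv;

    arma::mat33 sig = (1.0 / J) * P * F.t();
    cauchy_e(e, 0) = sig(0, 0); cauchy_e(e, 1) = sig(1, 1); cauchy_e(e, 2) = sig(2, 2);
    cauchy_e(e, 3) = sig(0, 1); cauchy_e(e, 4) = sig(1, 2); cauchy_e(e, 5) = sig(0, 2);

    int nd[4] = { n1, n2, n3, n4 };
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double fa = 0.0;
        for (int p = 0; p < 3; ++p) fa += P(i, p) * gN(a, p);
        f(3 * nd[a] + i) += V0 * fa;
        fabsacc(3 * nd[a] + i) += std::abs(V0 * fa);
      }

    if (want_K) {
      // K_e = V0 * L' A L with L(9x12), L(i+3p, 3a+i) = gN(a,p)
      arma::mat L(9, 12, arma::fill::zeros);
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          for (int p = 0; p < 3; ++p)
            L(i + 3 * p, 3 * a + i) = gN(a, p);
      Kes[e] = V0 * (L.t() * A * L);
    }

    if (nodal) {
      // w = dJ/dx (12-vector), nodal reference volumes and J averages
      for (int a = 0; a < 4; ++a) {
        double wx[3];
        for (int i = 0; i < 3; ++i) {
          double v = 0.0;
          for (int p = 0; p < 3; ++p) v += Finv(p, i) * gN(a, p);
          wx[i] = J * v;
          w_all(e, 3 * a + i) = wx[i];
        }
        V0node(nd[a]) += V0 / 4.0;
        VJnode(nd[a]) += V0 / 4.0 * J;
      }
    }
  }

  if (!ok) {
    return List::create(_["ok"] = false, _["bad_elem"] = bad_elem + 1);
  }

  arma::vec Jbar, pnode, cU;
  double vol_energy = 0.0;
  if (nodal) {
    Jbar.set_size(nn); pnode.set_size(nn); cU.set_size(nn);
    for (int a = 0; a < nn; ++a) {
      if (V0node(a) > 0.0) {
        Jbar(a) = VJnode(a) / V0node(a);
        pnode(a) = (1.0 / mp.D) * (Jbar(a) - 1.0 / Jbar(a));
        cU(a) = (1.0 / mp.D) * (1.0 + 1.0 / (Jbar(a) * Jbar(a))) / V0node(a);
        vol_energy += V0node(a) * (1.0 / mp.D) * ((Jbar(a) * Jbar(a) - 1.0) / 2.0 - std::log(Jbar(a)));
      } else { Jbar(a) = 1.0; pnode(a) = 0.0; cU(a) = 0.0; }
    }
  }

  std::vector<double> Hi, Hj, Hv;
  if (nodal) { Hi.reserve((size_t)ne * 16 * 3); Hj.reserve((size_t)ne * 16 * 3); Hv.reserve((size_t)ne * 16 * 3); }

  for (int e = 0; e < ne; ++e) {
    int nd[4] = { elems(e, 0) - 1, elems(e, 1) - 1, elems(e, 2) - 1, elems(e, 3) - 1 };
    if (nodal) {
      double pbar = 0.25 * (pnode(nd[0]) + pnode(nd[1]) + pnode(nd[2]) + pnode(nd[3]));
      if (mp.damage_vol) pbar *= Ge(e);
      double V0 = V0e(e), J = Je(e);
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) {
          f(3 * nd[a] + i) += V0 * pbar * w_all(e, 3 * a + i);
          fabsacc(3 * nd[a] + i) += std::abs(V0 * pbar * w_all(e, 3 * a + i));
        }
      // mean pressure enters the reported element stress hydrostatically
      cauchy_e(e, 0) += pbar; cauchy_e(e, 1) += pbar; cauchy_e(e, 2) += pbar;
      if (want_K) {
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i)
            for (int b = 0; b < 4; ++b)
              for (int j = 0; j < 3; ++j)
                Kes[e](3 * a + i, 3 * b + j) += V0 * pbar / J *
                  (w_all(e, 3 * a + i) * w_all(e, 3 * b + j) - w_all(e, 3 * a + j) * w_all(e, 3 * b + i));
        // rows of H: scatter (V0/4) w into global dofs for each corner node
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b)
            for (int j = 0; j < 3; ++j) {
              Hi.push_back(nd[a] + 1);
              Hj.push_back(3 * nd[b] + j + 1);
              Hv.push_back(V0 / 4.0 * w_all(e, 3 * b + j));
            }
      }
    }
    if (want_K) {
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 4; ++b)
            for (int j = 0; j < 3; ++j) {
              Ki.push_back(3 * nd[a] + i + 1);
              Kj.push_back(3 * nd[b] + j + 1);
              Kv.push_back(Kes[e](3 * a + i, 3 * b + j));
            }
    }
  }

  double total_energy = arma::dot(We, V0e) + vol_energy;
  List out = List::create(
    _["ok"] = true,
    _["f"] = wrap(f),
    _["fabs"] = wrap(fabsacc),
    _["J"] = wrap(Je), _["Ib4"] = wrap(Ib4e), _["G"] = wrap(Ge),
    _["W"] = wrap(We), _["V0"] = wrap(V0e),
    _["cauchy"] = wrap(cauchy_e),
    _["total_energy"] = total_energy);
  if (want_K) {
    out["Ki"] = wrap(Ki); out["Kj"] = wrap(Kj); out["Kv"] = wrap(Kv);
    if (nodal) {
      out["Hi"] = wrap(Hi); out["Hj"] = wrap(Hj); out["Hv"] = wrap(Hv);
      out["cU"] = wrap(cU);
    }
  }
  if (nodal) out["Jbar"] = wrap(Jbar);
  return out;
}
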