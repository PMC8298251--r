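// Element kernels for the total-Lagrangian quasi-static solver.
// Quadratic (6-node) triangles, in-plane displacement unknowns, prescribed
// axial stretch lambda_z folded into the 3D invariants of the modified
// Mooney-Rivlin laws. All stresses in kPa, coordinates in mm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// 6-point degree-4 rule on the reference triangle (weights sum to 1/2)
const double GP[6][2] = {
  {0.445948490915965, 0.445948490915965},
  {0.108103018168070, 0.445948490915965},
  {0.445948490915965, 0.108103018168070},
  {0.091576213509771, 0.091576213509771},
  {0.816847572980459, 0.091576213509771},
  {0.091576213509771, 0.816847572980459}};
const double GW[6] = {
  0.111690794839005, 0.111690794839005, 0.111690794839005,
  0.054975871827661, 0.054975871827661, 0.054975871827661};

// shape function derivatives wrt (xi, eta) for the 6-node triangle
inline void dshape(double xi, double eta, double dN[6][2]) {
  double L1 = 1.0 - xi - eta, L2 = xi, L3 = eta;
  dN[0][0] = -(4.0 * L1 - 1.0); dN[0][1] = -(4.0 * L1 - 1.0);
  dN[1][0] = 4.0 * L2 - 1.0;    dN[1][1] = 0.0;
  dN[2][0] = 0.0;               dN[2][1] = 4.0 * L3 - 1.0;
  dN[3][0] = 4.0 * (L1 - L2);   dN[3][1] = -4.0 * L2;
  dN[4][0] = 4.0 * L3;          dN[4][1] = 4.0 * L2;
  dN[5][0] = -4.0 * L3;         dN[5][1] = 4.0 * (L1 - L3);
}

struct MatPar {
  double c1, c2, D1, D2, K1, K2, kappa;
  bool aniso;
};

// Second Piola-Kirchhoff in-plane block + scalars needed for the tangent.
// Deviatoric terms see the isochoric invariants I1b = J^(-2/3) I1,
// I2b = J^(-4/3) I2 (nearly-incompressible split); volumetric penalty sees J.
struct ConstState {
  arma::mat22 S2;
  double W1, W11, W2, W4, W44, WJ, J, I1, I2v, I4, g1, g2, C33;
  arma::mat22 C2, C2inv, M, A2, B2;
  bool fiber_on;
};

inline bool const_eval(const arma::mat22& F, double lz, const MatPar& mp,
                       const arma::vec2& nfib, ConstState& cs) {
  double detF2 = F(0, 0) * F(1, 1) - F(0, 1) * F(1, 0);
  if (detF2 <= 0.0) return false;
  cs.C2 = F.t() * F;
  cs.C33 = lz * lz;
  cs.I1 = cs.C2(0, 0) + cs.C2(1, 1) + cs.C33;
  cs.I2v = 0.5 * (cs.I1 * cs.I1 -
                  (arma::accu(cs.C2 % cs.C2) + cs.C33 * cs.C33));
  cs.J = detF2 * lz;
  cs.g1 = std::pow(cs.J, -2.0 / 3.0);
  cs.g2 = std::pow(cs.J, -4.0 / 3.0);
  double I1b = cs.g1 * cs.I1;
  double e1 = mp.D2 * (I1b - 3.0);
  if (e1 > 500.0) return false;
  cs.W1 = mp.c1 + mp.D1 * mp.D2 * std::exp(e1);
  cs.W11 = mp.D1 * mp.D2 * mp.D2 * std::exp(e1);
  cs.W2 = mp.c2;
  cs.I4 = arma::as_scalar(nfib.t() * cs.C2 * nfib);
  cs.fiber_on = mp.aniso && cs.I4 > 1.0;
  if (cs.fiber_on) {
    double q = mp.K2 * (cs.I4 - 1.0) * (cs.I4 - 1.0);
    if (q > 500.0) return false;
    double eq = std::exp(q);
    cs.W4 = 2.0 * mp.K1 * (cs.I4 - 1.0) * eq;
    cs.W44 = 2.0 * mp.K1 * eq * (1.0 + 2.0 * mp.K2 * (cs.I4 - 1.0) * (cs.I4 - 1.0));
    cs.M = nfib * nfib.t();
  } else {
    cs.W4 = cs.W44 = 0.0;
    cs.M.zeros();
  }
  cs.WJ = mp.kappa * (cs.J - 1.0);
  cs.C2inv = arma::inv(cs.C2);
  arma::mat22 I2(arma::fill::eye);
  cs.A2 = I2 - (cs.I1 / 3.0) * cs.C2inv;
  cs.B2 = cs.I1 * I2 - cs.C2 - (2.0 * cs.I2v / 3.0) * cs.C2inv;
  cs.S2 = 2.0 * cs.W1 * cs.g1 * cs.A2 + 2.0 * cs.W2 * cs.g2 * cs.B2 +
          cs.WJ * cs.J * cs.C2inv;
  if (cs.fiber_on) cs.S2 += 2.0 * cs.W4 * cs.M;
  return true;
}

// dS2 for an in-plane increment dC (C33 fixed).
inline arma::mat22 dS_of_dC(const ConstState& cs, const MatPar& mp,
                            const arma::mat22& dC) {
  arma::mat22 I2(arma::fill::eye);
  double trd = dC(0, 0) + dC(1, 1);
  double cid = arma::accu(cs.C2inv % dC);
  double dJ = 0.5 * cs.J * cid;
  double dI1 = trd;
  double dI2 = cs.I1 * trd - arma::accu(cs.C2 % dC);
  double dg1 = -(1.0 / 3.0) * cs.g1 * cid;
  double dg2 = -(2.0 / 3.0) * cs.g2 * cid;
  double dI1b = dg1 * cs.I1 + cs.g1 * dI1;
  double dW1 = cs.W11 * dI1b;
  arma::mat22 dCinv = -cs.C2inv * dC * cs.C2inv;
  arma::mat22 dA2 = -(1.0 / 3.0) * (dI1 * cs.C2inv + cs.I1 * dCinv);
  arma::mat22 dB2 = dI1 * I2 - dC -
                    (2.0 / 3.0) * (dI2 * cs.C2inv + cs.I2v * dCinv);
  arma::mat22 dS =
      2.0 * (dW1 * cs.g1 + cs.W1 * dg1) * cs.A2 + 2.0 * cs.W1 * cs.g1 * dA2 +
      2.0 * cs.W2 * dg2 * cs.B2 + 2.0 * cs.W2 * cs.g2 * dB2;
  if (cs.fiber_on) {
    double MdC = arma::accu(cs.M % dC);
    dS += 2.0 * cs.W44 * MdC * cs.M;
  }
  dS += mp.kappa * (2.0 * cs.J - 1.0) * dJ * cs.C2inv + cs.WJ * cs.J * dCinv;
  return dS;
}

inline MatPar row_to_par(const NumericMatrix& matpar, int e) {
  MatPar mp;
  mp.c1 = matpar(e, 0); mp.c2 = matpar(e, 1); mp.D1 = matpar(e, 2);
  mp.D2 = matpar(e, 3); mp.K1 = matpar(e, 4); mp.K2 = matpar(e, 5);
  mp.kappa = matpar(e, 6); mp.aniso = matpar(e, 7) > 0.5;
  return mp;
}

} // namespace

// Internal force vector and consistent tangent triplets.
// nodes: N x 2; tri: E x 6 (1-based); matpar: E x 8; fiber: E x 2;
// u: 2N (node-major: ux1, uy1, ux2, ...); lambda_z scalar.
// [[Rcpp::export(name = ".fem_assemble")]]
List fem_assemble(NumericMatrix nodes, IntegerMatrix tri,
                  NumericMatrix matpar, NumericMatrix fiber,
                  NumericVector u, double lambda_z) {
  const int nel = tri.nrow();
  const int ndof = 2 * nodes.nrow();
  NumericVector fint(ndof);
  const int ntrip = nel * 144;
  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector tv(ntrip);
  double min_detF = R_PosInf;
  int bad = 0;

  double dN[6][2];
  for (int e = 0; e < nel; ++e) {
    MatPar mp = row_to_par(matpar, e);
    arma::vec2 nfib; nfib(0) = fiber(e, 0); nfib(1) = fiber(e, 1);
    int nd[6]; double X[6][2], ue[6][2];
    for (int a = 0; a < 6; ++a) {
      nd[a] = tri(e, a) - 1;
      X[a][0] = nodes(nd[a], 0); X[a][1] = nodes(nd[a], 1);
      ue[a][0] = u[2 * nd[a]]; ue[a][1] = u[2 * nd[a] + 1];
    }
    double ke[12][12] = {{0.0}};
    double fe[12] = {0.0};
    for (int g = 0; g < 6; ++g) {
      dshape(GP[g][0], GP[g][1], dN);
      arma::mat22 Jac(arma::fill::zeros);
      for (int a = 0; a < 6; ++a) {
        Jac(0, 0) += X[a][0] * dN[a][0]; Jac(0, 1) += X[a][0] * dN[a][1];
        Jac(1, 0) += X[a][1] * dN[a][0]; Jac(1, 1) += X[a][1] * dN[a][1];
      }
      double detJ = Jac(0, 0) * Jac(1, 1) - Jac(0, 1) * Jac(1, 0);
      if (detJ <= 0.0 || !std::isfinite(detJ)) { ++bad; continue; }
      arma::mat22 Jinv = arma::inv(Jac);
      double G[6][2]; // physical gradients dN_a/dX
      for (int a = 0; a < 6; ++a) {
        G[a][0] = dN[a][0] * Jinv(0, 0) + dN[a][1] * Jinv(1, 0);
        G[a][1] = dN[a][0] * Jinv(0, 1) + dN[a][1] * Jinv(1, 1);
      }
      arma::mat22 F(arma::fill::eye);
      for (int a = 0; a < 6; ++a) {
        F(0, 0) += ue[a][0] * G[a][0]; F(0, 1) += ue[a][0] * G[a][1];
        F(1, 0) += ue[a][1] * G[a][0]; F(1, 1) += ue[a][1] * G[a][1];
      }
      double detF2 = F(0, 0) * F(1, 1) - F(0, 1) * F(1, 0);
      if (detF2 < min_detF) min_detF = detF2;
      ConstState cs;
      if (!const_eval(F, lambda_z, mp, nfib, cs)) { ++bad; continue; }
      arma::mat22 P = F * cs.S2;
      double w = GW[g] * detJ;
      for (int a = 0; a < 6; ++a) {
        fe[2 * a]     += w * (P(0, 0) * G[a][0] + P(0, 1) * G[a][1]);
        fe[2 * a + 1] += w * (P(1, 0) * G[a][0] + P(1, 1) * G[a][1]);
      }
      // tangent: perturb dF = e_j (x) G_b
      for (int b = 0; b < 6; ++b) {
        for (int j = 0; j < 2; ++j) {
          arma::mat22 dF(arma::fill::zeros);
          dF(j, 0) = G[b][0]; dF(j, 1) = G[b][1];
          arma::mat22 dC = dF.t() * F + F.t() * dF;
          arma::mat22 dS = dS_of_dC(cs, mp, dC);
          arma::mat22 dP = dF * cs.S2 + F * dS;
          for (int a = 0; a < 6; ++a) {
            ke[2 * a][2 * b + j]     += w * (dP(0, 0) * G[a][0] + dP(0, 1) * G[a][1]);
            ke[2 * a + 1][2 * b + j] += w * (dP(1, 0) * G[a][0] + dP(1, 1) * G[a][1]);
          }
        }
      }
    }
    for (int a = 0; a < 6; ++a) {
      fint[2 * nd[a]]     += fe[2 * a];
      fint[2 * nd[a] + 1] += fe[2 * a + 1];
    }
    int base = e * 144;
    for (int a = 0; a < 12; ++a) {
      int ga = 2 * nd[a / 2] + (a % 2);
      for (int b = 0; b < 12; ++b) {
        int gb = 2 * nd[b / 2] + (b % 2);
        int idx = base + a * 12 + b;
        ti[idx] = ga + 1; tj[idx] = gb + 1; tv[idx] = ke[a][b];
      }
    }
  }
  return List::create(_["fint"] = fint, _["i"] = ti, _["j"] = tj,
                      _["v"] = tv, _["min_detF"] = min_detF,
                      _["n_bad"] = bad);
}

// Follower pressure on quadratic boundary edges (end, end, midside; 1-based),
// traversed CCW around the lumen so the load pushes the wall outward.
// Returns external force and the (negated) load-stiffness triplets to ADD to
// the system matrix of r = fint - fext.
// [[Rcpp::export(name = ".fem_pressure")]]
List fem_pressure(NumericMatrix nodes, IntegerMatrix edges,
                  NumericVector u, double p) {
  const int nedge = edges.nrow();
  const int ndof = 2 * nodes.nrow();
  NumericVector fext(ndof);
  const double gx[3] = {0.1127016653792583, 0.5, 0.8872983346207417};
  const double gw[3] = {5.0 / 18.0, 4.0 / 9.0, 5.0 / 18.0};
  const int ntrip = nedge * 36;
  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector tv(ntrip);
  for (int e = 0; e < nedge; ++e) {
    int nd[3] = {edges(e, 0) - 1, edges(e, 1) - 1, edges(e, 2) - 1};
    double x[3][2];
    for (int a = 0; a < 3; ++a) {
      x[a][0] = nodes(nd[a], 0) + u[2 * nd[a]];
      x[a][1] = nodes(nd[a], 1) + u[2 * nd[a] + 1];
    }
    double fe[6] = {0.0}, kl[6][6] = {{0.0}};
    for (int g = 0; g < 3; ++g) {
      double xi = gx[g];
      double N[3]  = {(1 - xi) * (1 - 2 * xi), xi * (2 * xi - 1), 4 * xi * (1 - xi)};
      double dNd[3] = {4 * xi - 3, 4 * xi - 1, 4 - 8 * xi};
      double tx = 0, ty = 0;
      for (int a = 0; a < 3; ++a) { tx += dNd[a] * x[a][0]; ty += dNd[a] * x[a][1]; }
      double w = gw[g] * p;
      for (int a = 0; a < 3; ++a) {
        fe[2 * a]     += w * N[a] * ty;
        fe[2 * a + 1] -= w * N[a] * tx;
        for (int b = 0; b < 3; ++b) {
          // d fe / d u_b: t depends on current coords
          kl[2 * a][2 * b + 1]     += w * N[a] * dNd[b]; // d(ty)/duy_b
          kl[2 * a + 1][2 * b]     -= w * N[a] * dNd[b]; // d(-tx)/dux_b
        }
      }
    }
    for (int a = 0; a < 3; ++a) {
      fext[2 * nd[a]]     += fe[2 * a];
      fext[2 * nd[a] + 1] += fe[2 * a + 1];
    }
    int base = e * 36;
    for (int a = 0; a < 6; ++a) {
      int ga = 2 * nd[a / 2] + (a % 2);
      for (int b = 0; b < 6; ++b) {
        int gb = 2 * nd[b / 2] + (b % 2);
        int idx = base + a * 6 + b;
        // residual r = fint - fext, so add -dfext/du
        ti[idx] = ga + 1; tj[idx] = gb + 1; tv[idx] = -kl[a][b];
      }
    }
  }
  return List::create(_["fext"] = fext, _["i"] = ti, _["j"] = tj, _["v"] = tv);
}

// Per-element mean fields at the converged state: Cauchy stress components
// (s11, s22, s12, szz), Green strain (E11, E22, E12, Ezz), J, W.
// [[Rcpp::export(name = ".fem_fields")]]
NumericMatrix fem_fields(NumericMatrix nodes, IntegerMatrix tri,
                         NumericMatrix matpar, NumericMatrix fiber,
                         NumericVector u, double lambda_z) {
  const int nel = tri.nrow();
  NumericMatrix out(nel, 10);
  double dN[6][2];
  for (int e = 0; e < nel; ++e) {
    MatPar mp = row_to_par(matpar, e);
    arma::vec2 nfib; nfib(0) = fiber(e, 0); nfib(1) = fiber(e, 1);
    int nd[6]; double X[6][2], ue[6][2];
    for (int a = 0; a < 6; ++a) {
      nd[a] = tri(e, a) - 1;
      X[a][0] = nodes(nd[a], 0); X[a][1] = nodes(nd[a], 1);
      ue[a][0] = u[2 * nd[a]]; ue[a][1] = u[2 * nd[a] + 1];
    }
    double acc[10] = {0.0}, wtot = 0.0;
    for (int g = 0; g < 6; ++g) {
      dshape(GP[g][0], GP[g][1], dN);
      arma::mat22 Jac(arma::fill::zeros);
      for (int a = 0; a < 6; ++a) {
        Jac(0, 0) += X[a][0] * dN[a][0]; Jac(0, 1) += X[a][0] * dN[a][1];
        Jac(1, 0) += X[a][1] * dN[a][0]; Jac(1, 1) += X[a][1] * dN[a][1];
      }
      double detJ = Jac(0, 0) * Jac(1, 1) - Jac(0, 1) * Jac(1, 0);
      arma::mat22 Jinv = arma::inv(Jac);
      double G[6][2];
      for (int a = 0; a < 6; ++a) {
        G[a][0] = dN[a][0] * Jinv(0, 0) + dN[a][1] * Jinv(1, 0);
        G[a][1] = dN[a][0] * Jinv(0, 1) + dN[a][1] * Jinv(1, 1);
      }
      arma::mat22 F(arma::fill::eye);
      for (int a = 0; a < 6; ++a) {
        F(0, 0) += ue[a][0] * G[a][0]; F(0, 1) += ue[a][0] * G[a][1];
        F(1, 0) += ue[a][1] * G[a][0]; F(1, 1) += ue[a][1] * G[a][1];
      }
      ConstState cs;
      if (!const_eval(F, lambda_z, mp, nfib, cs)) continue;
      arma::mat22 sig = (F * cs.S2 * F.t()) / cs.J;
      double C33 = cs.C33;
      double A33 = 1.0 - cs.I1 / (3.0 * C33);
      double B33 = cs.I1 - C33 - 2.0 * cs.I2v / (3.0 * C33);
      double S33 = 2.0 * cs.W1 * cs.g1 * A33 + 2.0 * cs.W2 * cs.g2 * B33 +
                   cs.WJ * cs.J / C33;
      double szz = C33 * S33 / cs.J;
      double w = GW[g] * detJ;
      double I1b = cs.g1 * cs.I1, I2b = cs.g2 * cs.I2v;
      double e1 = mp.D2 * (I1b - 3.0);
      double W = mp.c1 * (I1b - 3.0) + mp.c2 * (I2b - 3.0) +
                 mp.D1 * (std::exp(e1) - 1.0) +
                 0.5 * mp.kappa * (cs.J - 1.0) * (cs.J - 1.0);
      if (cs.fiber_on)
        W += (mp.K1 / mp.K2) *
             (std::exp(mp.K2 * (cs.I4 - 1.0) * (cs.I4 - 1.0)) - 1.0);
      acc[0] += w * sig(0, 0); acc[1] += w * sig(1, 1); acc[2] += w * sig(0, 1);
      acc[3] += w * szz;
      acc[4] += w * 0.5 * (cs.C2(0, 0) - 1.0);
      acc[5] += w * 0.5 * (cs.C2(1, 1) - 1.0);
      acc[6] += w * 0.5 * cs.C2(0, 1);
      acc[7] += w * 0.5 * (C33 - 1.0);
      acc[8] += w * cs.J; acc[9] += w * W;
      wtot += w;
    }
    for (int k = 0; k < 10; ++k) out(e, k) = wtot > 0 ? acc[k] / wtot : NA_REAL;
  }
  colnames(out) = CharacterVector::create("s11", "s22", "s12", "szz",
                                          "E11", "E22", "E12", "Ezz",
                                          "J", "W");
  return out;
}

// Area-weighted nodal field recovery: within each element the 6 Gauss-point
// values are fitted with a linear polynomial and extrapolated to the element
// nodes (removing the O(h) bias of centroid averaging at boundaries), then
// averaged over the elements sharing each node.
// [[Rcpp::export(name = ".fem_nodal_fields")]]
NumericMatrix fem_nodal_fields(NumericMatrix nodes, IntegerMatrix tri,
                               NumericMatrix matpar, NumericMatrix fiber,
                               NumericVector u, double lambda_z) {
  const int nel = tri.nrow();
  const int nn = nodes.nrow();
  NumericMatrix acc(nn, 10);
  NumericVector wsum(nn);
  double dN[6][2];
  for (int e = 0; e < nel; ++e) {
    MatPar mp = row_to_par(matpar, e);
    arma::vec2 nfib; nfib(0) = fiber(e, 0); nfib(1) = fiber(e, 1);
    int nd[6]; double X[6][2], ue[6][2];
    for (int a = 0; a < 6; ++a) {
      nd[a] = tri(e, a) - 1;
      X[a][0] = nodes(nd[a], 0); X[a][1] = nodes(nd[a], 1);
      ue[a][0] = u[2 * nd[a]]; ue[a][1] = u[2 * nd[a] + 1];
    }
    arma::mat A(6, 3);            // [1, x, y] at the Gauss points
    arma::mat vals(6, 10, arma::fill::zeros);
    double area = 0.0;
    bool ok = true;
    for (int g = 0; g < 6 && ok; ++g) {
      double xi = GP[g][0], eta = GP[g][1];
      double L1 = 1.0 - xi - eta;
      double N[6] = {L1 * (2 * L1 - 1), xi * (2 * xi - 1), eta * (2 * eta - 1),
                     4 * L1 * xi, 4 * xi * eta, 4 * eta * L1};
      double gx = 0, gy = 0;
      for (int a = 0; a < 6; ++a) { gx += N[a] * X[a][0]; gy += N[a] * X[a][1]; }
      A(g, 0) = 1.0; A(g, 1) = gx; A(g, 2) = gy;
      dshape(xi, eta, dN);
      arma::mat22 Jac(arma::fill::zeros);
      for (int a = 0; a < 6; ++a) {
        Jac(0, 0) += X[a][0] * dN[a][0]; Jac(0, 1) += X[a][0] * dN[a][1];
        Jac(1, 0) += X[a][1] * dN[a][0]; Jac(1, 1) += X[a][1] * dN[a][1];
      }
      double detJ = Jac(0, 0) * Jac(1, 1) - Jac(0, 1) * Jac(1, 0);
      if (detJ <= 0.0 || !std::isfinite(detJ)) { ok = false; break; }
      area += GW[g] * detJ;
      arma::mat22 Jinv = arma::inv(Jac);
      double G[6][2];
      for (int a = 0; a < 6; ++a) {
        G[a][0] = dN[a][0] * Jinv(0, 0) + dN[a][1] * Jinv(1, 0);
        G[a][1] = dN[a][0] * Jinv(0, 1) + dN[a][1] * Jinv(1, 1);
      }
      arma::mat22 F(arma::fill::eye);
      for (int a = 0; a < 6; ++a) {
        F(0, 0) += ue[a][0] * G[a][0]; F(0, 1) += ue[a][0] * G[a][1];
        F(1, 0) += ue[a][1] * G[a][0]; F(1, 1) += ue[a][1] * G[a][1];
      }
      ConstState cs;
      if (!const_eval(F, lambda_z, mp, nfib, cs)) { ok = false; break; }
      arma::mat22 sig = (F * cs.S2 * F.t()) / cs.J;
      double C33 = cs.C33;
      double A33 = 1.0 - cs.I1 / (3.0 * C33);
      double B33 = cs.I1 - C33 - 2.0 * cs.I2v / (3.0 * C33);
      double S33 = 2.0 * cs.W1 * cs.g1 * A33 + 2.0 * cs.W2 * cs.g2 * B33 +
                   cs.WJ * cs.J / C33;
      double I1b = cs.g1 * cs.I1, I2b = cs.g2 * cs.I2v;
      double Wv = mp.c1 * (I1b - 3.0) + mp.c2 * (I2b - 3.0) +
                  mp.D1 * (std::exp(mp.D2 * (I1b - 3.0)) - 1.0) +
                  0.5 * mp.kappa * (cs.J - 1.0) * (cs.J - 1.0);
      if (cs.fiber_on)
        Wv += (mp.K1 / mp.K2) *
              (std::exp(mp.K2 * (cs.I4 - 1.0) * (cs.I4 - 1.0)) - 1.0);
      vals(g, 0) = sig(0, 0); vals(g, 1) = sig(1, 1); vals(g, 2) = sig(0, 1);
      vals(g, 3) = C33 * S33 / cs.J;
      vals(g, 4) = 0.5 * (cs.C2(0, 0) - 1.0);
      vals(g, 5) = 0.5 * (cs.C2(1, 1) - 1.0);
      vals(g, 6) = 0.5 * cs.C2(0, 1);
      vals(g, 7) = 0.5 * (C33 - 1.0);
      vals(g, 8) = cs.J; vals(g, 9) = Wv;
    }
    if (!ok) continue;
    arma::mat coef = arma::solve(A.t() * A, A.t() * vals);  // 3 x 10
    for (int a = 0; a < 6; ++a) {
      for (int k = 0; k < 10; ++k) {
        double v = coef(0, k) + coef(1, k) * X[a][0] + coef(2, k) * X[a][1];
        acc(nd[a], k) += area * v;
      }
      wsum[nd[a]] += area;
    }
  }
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < 10; ++k)
      acc(i, k) = wsum[i] > 0 ? acc(i, k) / wsum[i] : NA_REAL;
  colnames(acc) = CharacterVector::create("s11", "s22", "s12", "szz",
                                          "E11", "E22", "E12", "Ezz",
                                          "J", "W");
  return acc;
}
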