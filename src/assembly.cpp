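#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear 8-node hexahedron, VTK node ordering (bottom quad CCW, then top).
// Quadrature: 2x2x2 Gauss for the deviatoric + fiber terms; the volumetric
// penalty is integrated mostly at a single central point (selective reduced
// integration, avoids volumetric locking at near-incompressibility) with a
// small fraction VOL_STAB evaluated at the full points to stabilize the
// local-dilatation (hourglass) modes the central point cannot see.
static const double VOL_STAB = 0.05;

static const double SG[8][3] = {
  {-1,-1,-1},{ 1,-1,-1},{ 1, 1,-1},{-1, 1,-1},
  {-1,-1, 1},{ 1,-1, 1},{ 1, 1, 1},{-1, 1, 1}};

static void dshape(double xi, double eta, double ze, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    const double sx = SG[a][0], sy = SG[a][1], sz = SG[a][2];
    dN[a][0] = 0.125 * sx * (1.0 + sy * eta) * (1.0 + sz * ze);
    dN[a][1] = 0.125 * sy * (1.0 + sx * xi) * (1.0 + sz * ze);
    dN[a][2] = 0.125 * sz * (1.0 + sx * xi) * (1.0 + sy * eta);
  }
}

static inline double det3(const double A[3][3]) {
  return A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
       - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
       + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
}

static inline bool inv3(const double A[3][3], double Ai[3][3], double &d) {
  d = det3(A);
  if (d == 0.0 || !std::isfinite(d)) return false;
  const double id = 1.0 / d;
  Ai[0][0] =  (A[1][1]*A[2][2]-A[1][2]*A[2][1])*id;
  Ai[0][1] = -(A[0][1]*A[2][2]-A[0][2]*A[2][1])*id;
  Ai[0][2] =  (A[0][1]*A[1][2]-A[0][2]*A[1][1])*id;
  Ai[1][0] = -(A[1][0]*A[2][2]-A[1][2]*A[2][0])*id;
  Ai[1][1] =  (A[0][0]*A[2][2]-A[0][2]*A[2][0])*id;
  Ai[1][2] = -(A[0][0]*A[1][2]-A[0][2]*A[1][0])*id;
  Ai[2][0] =  (A[1][0]*A[2][1]-A[1][1]*A[2][0])*id;
  Ai[2][1] = -(A[0][0]*A[2][1]-A[0][1]*A[2][0])*id;
  Ai[2][2] =  (A[0][0]*A[1][1]-A[0][1]*A[1][0])*id;
  return true;
}

// Piecewise collagen fiber force term f(lambda) (toe exponential / linear),
// zero in compression. mat = {c1, c4, c5, lambda_star, c3, c6, kappa}.
static inline double fiber_force(double lam, const double *mat) {
  if (lam <= 1.0) return 0.0;
  if (lam < mat[3]) return mat[4] * (std::exp(mat[1] * (lam - 1.0)) - 1.0);
  return mat[2] * lam + mat[5];
}

// First Piola-Kirchhoff stress, split into deviatoric+fiber ("dev") and
// volumetric ("vol") parts for selective reduced integration.
// W = c1/2 (J^{-2/3} I1 - 3) + W_f(lambda) + kappa/2 (J-1)^2.
static bool pk1(const double F[3][3], const double a0[3], const double *mat,
                bool dev_part, double kvol, double P[3][3]) {
  double Fi[3][3], J;
  if (!inv3(F, Fi, J) || J <= 0.0) return false;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) P[i][j] = 0.0;
  if (dev_part) {
    double I1 = 0.0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) I1 += F[i][j] * F[i][j];
    const double Jm23 = std::pow(J, -2.0 / 3.0);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        P[i][j] += mat[0] * Jm23 * (F[i][j] - I1 / 3.0 * Fi[j][i]);
    double m[3] = {0, 0, 0};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) m[i] += F[i][j] * a0[j];
    const double lam = std::sqrt(m[0]*m[0] + m[1]*m[1] + m[2]*m[2]);
    if (lam > 1.0) {
      const double fl = fiber_force(lam, mat) / lam;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) P[i][j] += fl * m[i] * a0[j];
    }
  }
  if (kvol > 0.0) {
    const double c = kvol * (J - 1.0) * J;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) P[i][j] += c * Fi[j][i];
  }
  return true;
}

struct ElemGeom {
  // Per element: 9 quadrature points (8 full + 1 central), each with
  // dN/dX (8x3) and weight*detJ0.
  std::vector<double> dNdX;  // E * 9 * 8 * 3
  std::vector<double> wdet;  // E * 9
  int nelem;
};

static void precompute_geom(const NumericMatrix &coords,
                            const IntegerMatrix &elems, ElemGeom &G) {
  const int E = elems.nrow();
  G.nelem = E;
  G.dNdX.assign((size_t)E * 9 * 24, 0.0);
  G.wdet.assign((size_t)E * 9, 0.0);
  const double g = 1.0 / std::sqrt(3.0);
  double pts[9][3];
  double wts[9];
  for (int q = 0; q < 8; ++q) {
    pts[q][0] = g * SG[q][0]; pts[q][1] = g * SG[q][1]; pts[q][2] = g * SG[q][2];
    wts[q] = 1.0;
  }
  pts[8][0] = pts[8][1] = pts[8][2] = 0.0;
  wts[8] = 8.0;
  for (int e = 0; e < E; ++e) {
    double X[8][3];
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) X[a][i] = coords(n, i);
    }
    for (int q = 0; q < 9; ++q) {
      double dN[8][3], J0[3][3] = {{0,0,0},{0,0,0},{0,0,0}}, Ji[3][3], d;
      dshape(pts[q][0], pts[q][1], pts[q][2], dN);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) J0[i][j] += X[a][i] * dN[a][j];
      if (!inv3(J0, Ji, d) || d <= 0.0)
        stop("degenerate element %d (reference Jacobian %g at quadrature point %d)",
             e + 1, d, q + 1);
      double *out = &G.dNdX[((size_t)e * 9 + q) * 24];
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double v = 0.0;
          for (int j = 0; j < 3; ++j) v += dN[a][j] * Ji[j][i];
          out[a * 3 + i] = v;
        }
      G.wdet[(size_t)e * 9 + q] = wts[q] * d;
    }
  }
}

// Internal force of one element given its 24 nodal displacements (node-major:
// u[a*3+i]). Returns false on element inversion.
static bool elem_force(const ElemGeom &G, int e, const double *ue,
                       const double a0[3], const double *mat, double fe[24]) {
  for (int k = 0; k < 24; ++k) fe[k] = 0.0;
  for (int q = 0; q < 9; ++q) {
    const double *dNdX = &G.dNdX[((size_t)e * 9 + q) * 24];
    const double w = G.wdet[(size_t)e * 9 + q];
    double F[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) F[i][j] += ue[a*3+i] * dNdX[a*3+j];
    double P[3][3];
    const bool dev = (q < 8);
    const double kvol = dev ? VOL_STAB * mat[6] : (1.0 - VOL_STAB) * mat[6];
    if (!pk1(F, a0, mat, dev, kvol, P)) return false;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        double v = 0.0;
        for (int j = 0; j < 3; ++j) v += P[i][j] * dNdX[a*3+j];
        fe[a*3+i] += v * w;
      }
  }
  return true;
}

static void gather_ue(const IntegerMatrix &elems, int e,
                      const NumericVector &u, double *ue) {
  for (int a = 0; a < 8; ++a) {
    const int n = elems(e, a) - 1;
    for (int i = 0; i < 3; ++i) ue[a*3+i] = u[n*3+i];
  }
}

// [[Rcpp::export]]
NumericVector fe_internal_force_cpp(NumericMatrix coords, IntegerMatrix elems,
                                    NumericVector u, NumericMatrix dirs,
                                    NumericVector mat) {
  ElemGeom G;
  precompute_geom(coords, elems, G);
  const int N = coords.nrow(), E = elems.nrow();
  NumericVector f(3 * N);
  double ue[24], fe[24], a0[3];
  for (int e = 0; e < E; ++e) {
    gather_ue(elems, e, u, ue);
    for (int i = 0; i < 3; ++i) a0[i] = dirs(e, i);
    if (!elem_force(G, e, ue, a0, REAL(mat), fe)) {
      std::fill(f.begin(), f.end(), NA_REAL);
      return f;
    }
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) f[n*3+i] += fe[a*3+i];
    }
  }
  return f;
}

// Assemble internal force and consistent tangent (central finite differences
// of the element residual; exact geometry reused, so the cost is 48 extra
// residual evaluations per element). Returns COO triplets for the tangent.
// [[Rcpp::export]]
List fe_assemble_cpp(NumericMatrix coords, IntegerMatrix elems,
                     NumericVector u, NumericMatrix dirs, NumericVector mat,
                     double h = 1e-6) {
  ElemGeom G;
  precompute_geom(coords, elems, G);
  const int N = coords.nrow(), E = elems.nrow();
  NumericVector f(3 * N);
  IntegerVector ti((size_t)E * 576), tj((size_t)E * 576);
  NumericVector tx((size_t)E * 576);
  double ue[24], fe[24], fp[24], fm[24], a0[3], Ke[24][24];
  bool ok = true;
  for (int e = 0; e < E && ok; ++e) {
    gather_ue(elems, e, u, ue);
    for (int i = 0; i < 3; ++i) a0[i] = dirs(e, i);
    if (!elem_force(G, e, ue, a0, REAL(mat), fe)) { ok = false; break; }
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) f[n*3+i] += fe[a*3+i];
    }
    for (int k = 0; k < 24; ++k) {
      const double u0 = ue[k];
      ue[k] = u0 + h;
      if (!elem_force(G, e, ue, a0, REAL(mat), fp)) { ok = false; break; }
      ue[k] = u0 - h;
      if (!elem_force(G, e, ue, a0, REAL(mat), fm)) { ok = false; break; }
      ue[k] = u0;
      for (int r = 0; r < 24; ++r) Ke[r][k] = (fp[r] - fm[r]) / (2.0 * h);
    }
    size_t base = (size_t)e * 576;
    for (int r = 0; r < 24; ++r) {
      const int nr = elems(e, r / 3) - 1, dr = 3 * nr + r % 3 + 1;
      for (int c = 0; c < 24; ++c) {
        const int nc = elems(e, c / 3) - 1, dc = 3 * nc + c % 3 + 1;
        ti[base] = dr; tj[base] = dc; tx[base] = Ke[r][c];
        ++base;
      }
    }
  }
  return List::create(_["f"] = f, _["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["ok"] = ok);
}

// Per-element centroid kinematics and stress recovery.
// [[Rcpp::export]]
List fe_stress_cpp(NumericMatrix coords, IntegerMatrix elems, NumericVector u,
                   NumericMatrix dirs, NumericVector mat) {
  ElemGeom G;
  precompute_geom(coords, elems, G);
  const int E = elems.nrow();
  NumericMatrix green(E, 6), cauchy(E, 6);
  NumericVector vm(E), Jout(E);
  double ue[24], a0[3];
  for (int e = 0; e < E; ++e) {
    gather_ue(elems, e, u, ue);
    for (int i = 0; i < 3; ++i) a0[i] = dirs(e, i);
    const double *dNdX = &G.dNdX[((size_t)e * 9 + 8) * 24];  // central point
    double F[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) F[i][j] += ue[a*3+i] * dNdX[a*3+j];
    double C[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k) C[i][j] += F[k][i] * F[k][j];
    green(e,0) = 0.5*(C[0][0]-1); green(e,1) = 0.5*(C[1][1]-1);
    green(e,2) = 0.5*(C[2][2]-1); green(e,3) = 0.5*C[0][1];
    green(e,4) = 0.5*C[0][2];     green(e,5) = 0.5*C[1][2];
    double P[3][3];
    if (!pk1(F, a0, REAL(mat), true, REAL(mat)[6], P)) {
      vm[e] = NA_REAL; Jout[e] = NA_REAL;
      continue;
    }
    const double J = det3(F);
    double sig[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        for (int k = 0; k < 3; ++k) sig[i][j] += P[i][k] * F[j][k];
        sig[i][j] /= J;
      }
    cauchy(e,0) = sig[0][0]; cauchy(e,1) = sig[1][1]; cauchy(e,2) = sig[2][2];
    cauchy(e,3) = 0.5*(sig[0][1]+sig[1][0]);
    cauchy(e,4) = 0.5*(sig[0][2]+sig[2][0]);
    cauchy(e,5) = 0.5*(sig[1][2]+sig[2][1]);
    const double p = (sig[0][0]+sig[1][1]+sig[2][2]) / 3.0;
    const double d0 = sig[0][0]-p, d1 = sig[1][1]-p, d2 = sig[2][2]-p;
    vm[e] = std::sqrt(1.5 * (d0*d0 + d1*d1 + d2*d2
              + 2.0*(cauchy(e,3)*cauchy(e,3) + cauchy(e,4)*cauchy(e,4)
                     + cauchy(e,5)*cauchy(e,5))));
    Jout[e] = J;
  }
  return List::create(_["green"] = green, _["cauchy"] = cauchy,
                      _["von_mises"] = vm, _["J"] = Jout);
}

// Corner Jacobians of every element (mesh validity check).
// [[Rcpp::export]]
NumericMatrix hex_corner_jacobians_cpp(NumericMatrix coords,
                                       IntegerMatrix elems) {
  const int E = elems.nrow();
  NumericMatrix out(E, 8);
  for (int e = 0; e < E; ++e) {
    double X[8][3];
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) X[a][i] = coords(n, i);
    }
    for (int c = 0; c < 8; ++c) {
      double dN[8][3], J0[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
      dshape(SG[c][0], SG[c][1], SG[c][2], dN);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) J0[i][j] += X[a][i] * dN[a][j];
      out(e, c) = det3(J0);
    }
  }
  return out;
}
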