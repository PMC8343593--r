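// Trilinear hexahedral element kernels for the finite-growth neo-Hookean
// bilayer: internal force, strain energy and consistent tangent with a
// per-element growth tensor G (multiplicative decomposition F = A G).
//
// Energy per unit reference volume:
//   W(A) = 1/2 lam ln^2 J + 1/2 mu (A:A - 3 - 2 ln J),  J = det A,  A = F G^-1
// First Piola stress (exact gradient of W wrt F):
//   P = mu F Ghat + (lam ln J - mu) F^-T,   Ghat = G^-1 G^-T
// Consistent tangent:
//   dP = mu dF Ghat + lam (F^-T : dF) F^-T - (lam ln J - mu) F^-T dF^T F^-T

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// local corner coordinates of the reference hex
const double XI[8]  = {-1, 1, 1, -1, -1, 1, 1, -1};
const double ETA[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
const double ZET[8] = {-1, -1, -1, -1, 1, 1, 1, 1};

// dN/dxi at a quadrature point -> 8x3
inline void shape_grad(double xi, double eta, double zet, mat &dN) {
  for (int a = 0; a < 8; ++a) {
    dN(a, 0) = 0.125 * XI[a] * (1 + ETA[a] * eta) * (1 + ZET[a] * zet);
    dN(a, 1) = 0.125 * (1 + XI[a] * xi) * ETA[a] * (1 + ZET[a] * zet);
    dN(a, 2) = 0.125 * (1 + XI[a] * xi) * (1 + ETA[a] * eta) * ZET[a];
  }
}

} // namespace

// Assemble internal force (and optionally the consistent tangent) for the
// current displacement field.
//
// coords : N x 3 reference node coordinates
// conn   : M x 8 1-based connectivity
// u      : N x 3 nodal displacements
// Gmat   : M x 9 per-element growth tensor, row-major rows of G
// Returns list(force = N*3 vector [node-major: (n1x,n1y,n1z,n2x,...)],
//              energy, min_detA, tangent = dgCMatrix | NULL)
// [[Rcpp::export(name = ".hex_assemble")]]
Rcpp::List hex_assemble(const arma::mat &coords, const arma::imat &conn,
                        const arma::mat &u, const arma::mat &Gmat,
                        double mu, double lam, bool want_tangent) {
  const uword M = conn.n_rows, N = coords.n_rows;
  const double gq = 1.0 / std::sqrt(3.0);

  // quadrature-point shape gradients (fixed reference element)
  std::vector<mat> dNq(8, mat(8, 3));
  int q = 0;
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k, ++q)
        shape_grad(gq * (2 * i - 1), gq * (2 * j - 1), gq * (2 * k - 1), dNq[q]);

  vec force(3 * N, fill::zeros);
  double energy = 0.0, min_detA = datum::inf;

  umat locs;
  vec vals;
  uword nt = 0;
  if (want_tangent) {
    locs.set_size(2, 576 * M);
    vals.set_size(576 * M);
  }

  mat Xe(8, 3), ue(8, 3), dNdX(8, 3), J0(3, 3), F(3, 3), Finv(3, 3);
  mat G(3, 3), Ginv(3, 3), Ghat(3, 3), P(3, 3), Ke(24, 24);
  vec ga(3), gb(3);

  for (uword e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) {
      const uword n = (uword)conn(e, a) - 1;
      Xe.row(a) = coords.row(n);
      ue.row(a) = u.row(n);
    }
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) G(r, c) = Gmat(e, 3 * r + c);
    bool okG = inv(Ginv, G);
    if (!okG) Rcpp::stop("singular growth tensor in element %d", (int)e + 1);
    Ghat = Ginv * Ginv.t();
    const double detG = det(G);

    if (want_tangent) Ke.zeros();
    for (int qp = 0; qp < 8; ++qp) {
      const mat &dN = dNq[qp];
      J0 = Xe.t() * dN;                 // dX/dxi
      const double detJ0 = det(J0);
      dNdX = dN * inv(J0);              // 8x3
      F = eye(3, 3) + ue.t() * dNdX;    // deformation gradient
      const double detF = det(F);
      const double JA = detF / detG;
      if (JA < min_detA) min_detA = JA;
      if (JA <= 0.0) {
        // inverted element: report and let the solver reject the step
        return Rcpp::List::create(
            Rcpp::Named("force") = R_NilValue, Rcpp::Named("energy") = NA_REAL,
            Rcpp::Named("min_detA") = min_detA,
            Rcpp::Named("tangent") = R_NilValue);
      }
      const double lnJ = std::log(JA);
      const double w = detJ0; // unit quadrature weights
      Finv = inv(F);
      P = mu * F * Ghat + (lam * lnJ - mu) * Finv.t();

      energy += w * (0.5 * lam * lnJ * lnJ +
                     0.5 * mu * (accu(square(F * Ginv)) - 3.0 - 2.0 * lnJ));
      // scatter force
      for (int a = 0; a < 8; ++a) {
        const uword n = (uword)conn(e, a) - 1;
        for (int i = 0; i < 3; ++i) {
          double f = 0;
          for (int J = 0; J < 3; ++J) f += P(i, J) * dNdX(a, J);
          force(3 * n + i) += w * f;
        }
      }
      if (want_tangent) {
        const double c1 = lam * lnJ - mu;
        // ga = Finv^T * dNa ; block(a,b) = mu*s1*I + lam ga gb^T - c1 gb ga^T
        mat gAll = dNdX * Finv;          // 8x3, row a = (Finv^T dNa)^T
        mat sG = dNdX * Ghat * dNdX.t(); // 8x8
        for (int a = 0; a < 8; ++a) {
          for (int b = 0; b < 8; ++b) {
            const double s1 = mu * sG(a, b);
            for (int i = 0; i < 3; ++i)
              for (int k = 0; k < 3; ++k) {
                double v = lam * gAll(a, i) * gAll(b, k) -
                           c1 * gAll(b, i) * gAll(a, k);
                if (i == k) v += s1;
                Ke(3 * a + i, 3 * b + k) += w * v;
              }
          }
        }
      }
    }
    if (want_tangent) {
      for (int a = 0; a < 8; ++a) {
        const uword na = (uword)conn(e, a) - 1;
        for (int b = 0; b < 8; ++b) {
          const uword nb = (uword)conn(e, b) - 1;
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k) {
              locs(0, nt) = 3 * na + i;
              locs(1, nt) = 3 * nb + k;
              vals(nt) = Ke(3 * a + i, 3 * b + k);
              ++nt;
            }
        }
      }
    }
  }

  Rcpp::RObject tangent = R_NilValue;
  if (want_tangent) {
    sp_mat K(true, locs, vals, 3 * N, 3 * N); // batch insert, sums duplicates
    tangent = Rcpp::wrap(K);
  }
  return Rcpp::List::create(Rcpp::Named("force") = force,
                            Rcpp::Named("energy") = energy,
                            Rcpp::Named("min_detA") = min_detA,
                            Rcpp::Named("tangent") = tangent);
}

// Element volumes in the reference configuration (for diagnostics/tests).
// [[Rcpp::export(name = ".hex_volumes")]]
arma::vec hex_volumes(const arma::mat &coords, const arma::imat &conn) {
  const uword M = conn.n_rows;
  const double gq = 1.0 / std::sqrt(3.0);
  std::vector<mat> dNq(8, mat(8, 3));
  int q = 0;
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k, ++q)
        shape_grad(gq * (2 * i - 1), gq * (2 * j - 1), gq * (2 * k - 1), dNq[q]);
  vec vol(M, fill::zeros);
  mat Xe(8, 3);
  for (uword e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) Xe.row(a) = coords.row((uword)conn(e, a) - 1);
    for (int qp = 0; qp < 8; ++qp) vol(e) += det(Xe.t() * dNq[qp]);
  }
  return vol;
}
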