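// Hot loops for Gauss-Newton registration:
//  * per-voxel 3x3 matrix fields (polar rotations, singular values,
//    derivative terms of the finite-strain rotation and of log singular
//    values with respect to the local Jacobian);
//  * accumulation of sparse Gauss-Newton gradients and Hessians from
//    separable B-spline weights.
//
// Conventions: N x 9 matrices hold one 3x3 matrix per row in column-major
// order; N x 6 tensor rows are (xx, xy, xz, yy, yz, zz).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat33 row_to_mat(const NumericMatrix& X, int i) {
  arma::mat33 A;
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      A(r, c) = X(i, r + 3 * c);
  return A;
}

static inline arma::mat33 row_to_tensor(const NumericMatrix& D, int i) {
  arma::mat33 T;
  T(0, 0) = D(i, 0); T(0, 1) = D(i, 1); T(0, 2) = D(i, 2);
  T(1, 0) = D(i, 1); T(1, 1) = D(i, 3); T(1, 2) = D(i, 4);
  T(2, 0) = D(i, 2); T(2, 1) = D(i, 4); T(2, 2) = D(i, 5);
  return T;
}

// Polar (finite-strain) rotation factor R = (J J^T)^{-1/2} J = U V^T of each
// Jacobian; requires det J > 0.
// [[Rcpp::export]]
NumericMatrix cpp_polar_rotations(const NumericMatrix& J) {
  const int N = J.nrow();
  NumericMatrix out(N, 9);
  arma::mat33 U, V, R;
  arma::vec3 s;
  for (int i = 0; i < N; ++i) {
    arma::mat33 A = row_to_mat(J, i);
    if (arma::det(A) <= 0.0)
      stop("finite-strain rotation undefined: Jacobian determinant <= 0 at sample %d", i + 1);
    if (!arma::svd(U, s, V, A, "std"))
      stop("SVD failed at sample %d", i + 1);
    R = U * V.t();
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        out(i, r + 3 * c) = R(r, c);
  }
  return out;
}

// Singular values of each Jacobian, descending.
// [[Rcpp::export]]
NumericMatrix cpp_singular_values(const NumericMatrix& J) {
  const int N = J.nrow();
  NumericMatrix out(N, 3);
  arma::vec3 s;
  for (int i = 0; i < N; ++i) {
    arma::mat33 A = row_to_mat(J, i);
    if (!arma::svd(s, A))
      stop("SVD failed at sample %d", i + 1);
    out(i, 0) = s(0); out(i, 1) = s(1); out(i, 2) = s(2);
  }
  return out;
}

// Residual terms for the log-singular-value penalty: per sample the three
// residuals log s_i and the 27 derivatives d(log s_i)/dJ_{d,a} =
// u_{d,i} v_{a,i} / s_i.  P layout: column i + 3*d + 9*a.
// [[Rcpp::export]]
List cpp_logsv_terms(const NumericMatrix& J) {
  const int N = J.nrow();
  NumericMatrix logs(N, 3), P(N, 27);
  arma::mat33 U, V;
  arma::vec3 s;
  bool ok = true;
  for (int i = 0; i < N; ++i) {
    arma::mat33 A = row_to_mat(J, i);
    if (!arma::svd(U, s, V, A, "std"))
      stop("SVD failed at sample %d", i + 1);
    if (s(2) <= 0.0 || arma::det(A) <= 0.0) { ok = false; break; }
    for (int k = 0; k < 3; ++k) {
      logs(i, k) = std::log(s(k));
      for (int d = 0; d < 3; ++d)
        for (int a = 0; a < 3; ++a)
          P(i, k + 3 * d + 9 * a) = U(d, k) * V(a, k) / s(k);
    }
  }
  return List::create(_["ok"] = ok, _["logs"] = logs, _["P"] = P);
}

// Derivatives of the reoriented reference tensor R F R^T with respect to the
// local Jacobian.  For dJ = e_d e_a^T the polar factor perturbs as
// dR = R [w]_x with w = (tr(S) I - S)^{-1} axial(R^T dJ - dJ^T R), S = R^T J,
// giving d(R F R^T) = R ([w]_x Fq - Fq [w]_x) R^T with Fq = F.
// Output: N x 54, column k + 6*d + 18*a for unique element k of
// (xx, xy, xz, yy, yz, zz); also returns the rotated tensors R F R^T (N x 6).
// [[Rcpp::export]]
List cpp_rotation_terms(const NumericMatrix& J, const NumericMatrix& F) {
  const int N = J.nrow();
  NumericMatrix T(N, 54), RFRt(N, 6);
  arma::mat33 U, V;
  arma::vec3 s;
  const int ur[6] = {0, 0, 0, 1, 1, 2};
  const int uc[6] = {0, 1, 2, 1, 2, 2};
  for (int i = 0; i < N; ++i) {
    arma::mat33 A = row_to_mat(J, i);
    if (arma::det(A) <= 0.0)
      stop("finite-strain rotation undefined: Jacobian determinant <= 0 at sample %d", i + 1);
    if (!arma::svd(U, s, V, A, "std"))
      stop("SVD failed at sample %d", i + 1);
    arma::mat33 R = U * V.t();
    arma::mat33 S = R.t() * A;
    S = 0.5 * (S + S.t());
    arma::mat33 M = arma::trace(S) * arma::eye<arma::mat>(3, 3) - S;
    arma::mat33 Minv = arma::inv(M);
    arma::mat33 Fq = row_to_tensor(F, i);
    arma::mat33 RF = R * Fq * R.t();
    for (int k = 0; k < 6; ++k) RFRt(i, k) = RF(ur[k], uc[k]);
    for (int a = 0; a < 3; ++a) {
      for (int d = 0; d < 3; ++d) {
        // K = r_d e_a^T - e_a r_d^T with r_d the d-th row of R
        arma::vec3 rd = R.row(d).t();
        arma::mat33 K(arma::fill::zeros);
        for (int r = 0; r < 3; ++r) { K(r, a) += rd(r); K(a, r) -= rd(r); }
        arma::vec3 ax = {K(2, 1), K(0, 2), K(1, 0)};
        arma::vec3 w = Minv * ax;
        arma::mat33 W(arma::fill::zeros);
        W(0, 1) = -w(2); W(0, 2) =  w(1);
        W(1, 0) =  w(2); W(1, 2) = -w(0);
        W(2, 0) = -w(1); W(2, 1) =  w(0);
        arma::mat33 dT = R * (W * Fq - Fq * W) * R.t();
        for (int k = 0; k < 6; ++k)
          T(i, k + 6 * d + 18 * a) = dT(ur[k], uc[k]);
      }
    }
  }
  return List::create(_["T"] = T, _["RFRt"] = RFRt);
}

// Eigendecomposition of symmetric tensors: eigenvalues descending with
// matching eigenvectors (V column-major, v1 first).
// [[Rcpp::export]]
List cpp_tensor_eigen(const NumericMatrix& D) {
  const int N = D.nrow();
  NumericMatrix L(N, 3), V(N, 9);
  arma::vec3 ev;
  arma::mat33 evec;
  for (int i = 0; i < N; ++i) {
    arma::mat33 T = row_to_tensor(D, i);
    if (!arma::eig_sym(ev, evec, T))
      stop("eigendecomposition failed at sample %d", i + 1);
    // arma returns ascending; flip to descending
    for (int k = 0; k < 3; ++k) {
      L(i, k) = ev(2 - k);
      for (int r = 0; r < 3; ++r)
        V(i, r + 3 * k) = evec(r, 2 - k);
    }
  }
  return List::create(_["L"] = L, _["V"] = V);
}

// Gauss-Newton accumulation engine.
//
// The residual Jacobian entry for residual r at sample x and coefficient
// (direction d, spline m) is
//     sum over terms t with (r_t = r, d_t = d) of
//         fields(x, t) * wx[ox_t](x, ax) * wy[oy_t](x, ay) * wz[oz_t](x, az)
// where (ax, ay, az) are the per-axis offsets (0..3) of spline m within the
// sample's active 4x4x4 window and o* are per-axis derivative orders.
// Returns the gradient J^T resid and the triplets of H = J^T J.
//
// cells:  N x 3 integer, 0-based first active spline per axis.
// wts:    list of 3 axes, each a list of 3 (orders 0..2) N x 4 matrices or NULL.
// terms:  K x 5 integer (r, d, ox, oy, oz), 0-based.
// fields: N x K; resid: N x R; counts: splines per axis; ndir: directions.
// active: logical N; inactive samples are skipped.
// [[Rcpp::export]]
List cpp_gn_engine(const IntegerMatrix& cells, const List& wts,
                   const IntegerMatrix& terms, const NumericMatrix& fields,
                   const NumericMatrix& resid, const IntegerVector& counts,
                   const int ndir, const LogicalVector& active) {
  const int N = cells.nrow();
  const int K = terms.nrow();
  const int R = resid.ncol();
  const int c1 = counts[0], c2 = counts[1];
  const long M = (long)counts[0] * counts[1] * counts[2];
  const int NA_COL = ndir * 64;

  // resolve weight matrices
  const NumericMatrix* W[3][3] = {{nullptr}};
  std::vector<NumericMatrix> keep;
  keep.reserve(9);
  for (int ax = 0; ax < 3; ++ax) {
    List axl = wts[ax];
    for (int o = 0; o < 3; ++o) {
      if (o < axl.size() && !Rf_isNull(axl[o])) {
        keep.push_back(as<NumericMatrix>(axl[o]));
        W[ax][o] = &keep.back();
      }
    }
  }
  // distinct order patterns among terms
  std::vector<int> pat_of(K), pox, poy, poz;
  for (int k = 0; k < K; ++k) {
    int ox = terms(k, 2), oy = terms(k, 3), oz = terms(k, 4);
    int found = -1;
    for (size_t p = 0; p < pox.size(); ++p)
      if (pox[p] == ox && poy[p] == oy && poz[p] == oz) { found = (int)p; break; }
    if (found < 0) {
      found = (int)pox.size();
      pox.push_back(ox); poy.push_back(oy); poz.push_back(oz);
      if (W[0][ox] == nullptr || W[1][oy] == nullptr || W[2][oz] == nullptr)
        stop("missing weight matrix for a requested derivative order");
    }
    pat_of[k] = found;
  }
  const int NP = (int)pox.size();

  // static 64-window tables
  int shift64[64], offx[64], offy[64], offz[64];
  for (int a = 0; a < 64; ++a) {
    int ox = a & 3, oy = (a >> 2) & 3, oz = (a >> 4) & 3;
    offx[a] = ox; offy[a] = oy; offz[a] = oz;
    shift64[a] = ox + c1 * oy + c1 * c2 * oz;
  }
  // pairwise per-axis knot-offset index tables (7^3 offsets)
  std::vector<int> poff(64 * 64);
  for (int a1 = 0; a1 < 64; ++a1)
    for (int a2 = 0; a2 < 64; ++a2)
      poff[a1 * 64 + a2] = (offx[a2] - offx[a1] + 3) +
        7 * (offy[a2] - offy[a1] + 3) + 49 * (offz[a2] - offz[a1] + 3);

  std::vector<double> grad((size_t)ndir * M, 0.0);
  // H blocks: layout ((dp * M + m1) * 343 + off)
  const size_t nblk = (size_t)ndir * ndir;
  std::vector<double> H(nblk * (size_t)M * 343, 0.0);

  std::vector<double> c(R * NA_COL);
  std::vector<double> prod(NP * 64);

  for (int x = 0; x < N; ++x) {
    if (!active[x]) continue;
    // pattern products over the 64-window
    for (int p = 0; p < NP; ++p) {
      const NumericMatrix& wx = *W[0][pox[p]];
      const NumericMatrix& wy = *W[1][poy[p]];
      const NumericMatrix& wz = *W[2][poz[p]];
      double vx[4], vy[4], vz[4];
      for (int o = 0; o < 4; ++o) {
        vx[o] = wx(x, o); vy[o] = wy(x, o); vz[o] = wz(x, o);
      }
      double* pr = &prod[p * 64];
      for (int a = 0; a < 64; ++a)
        pr[a] = vx[offx[a]] * vy[offy[a]] * vz[offz[a]];
    }
    std::fill(c.begin(), c.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double fv = fields(x, k);
      if (fv == 0.0) continue;
      const int r = terms(k, 0), d = terms(k, 1);
      const double* pr = &prod[pat_of[k] * 64];
      double* cc = &c[(size_t)r * NA_COL + d * 64];
      for (int a = 0; a < 64; ++a) cc[a] += fv * pr[a];
    }
    const long m0 = (long)cells(x, 0) + c1 * (long)cells(x, 1) +
      (long)c1 * c2 * cells(x, 2);
    // gradient
    for (int d = 0; d < ndir; ++d) {
      for (int a = 0; a < 64; ++a) {
        double g = 0.0;
        for (int r = 0; r < R; ++r) g += c[(size_t)r * NA_COL + d * 64 + a] * resid(x, r);
        if (g != 0.0) grad[(size_t)d * M + m0 + shift64[a]] += g;
      }
    }
    // Hessian: same-direction blocks, a1 <= a2
    for (int d = 0; d < ndir; ++d) {
      const size_t dp = (size_t)(d * ndir + d);
      for (int a1 = 0; a1 < 64; ++a1) {
        const long m1 = m0 + shift64[a1];
        double* Hrow = &H[(dp * (size_t)M + m1) * 343];
        const int* po = &poff[a1 * 64];
        for (int a2 = a1; a2 < 64; ++a2) {
          double s = 0.0;
          for (int r = 0; r < R; ++r)
            s += c[(size_t)r * NA_COL + d * 64 + a1] *
                 c[(size_t)r * NA_COL + d * 64 + a2];
          Hrow[po[a2]] += s;
        }
      }
    }
    // cross-direction blocks d1 < d2, all ordered (a1, a2)
    for (int d1 = 0; d1 < ndir; ++d1) {
      for (int d2 = d1 + 1; d2 < ndir; ++d2) {
        const size_t dp = (size_t)(d1 * ndir + d2);
        for (int a1 = 0; a1 < 64; ++a1) {
          const long m1 = m0 + shift64[a1];
          double* Hrow = &H[(dp * (size_t)M + m1) * 343];
          const int* po = &poff[a1 * 64];
          for (int a2 = 0; a2 < 64; ++a2) {
            double s = 0.0;
            for (int r = 0; r < R; ++r)
              s += c[(size_t)r * NA_COL + d1 * 64 + a1] *
                   c[(size_t)r * NA_COL + d2 * 64 + a2];
            Hrow[po[a2]] += s;
          }
        }
      }
    }
  }

  // emit triplets (1-based, both triangles)
  std::vector<int> ii, jj;
  std::vector<double> xx;
  for (int d1 = 0; d1 < ndir; ++d1) {
    for (int d2 = d1; d2 < ndir; ++d2) {
      const size_t dp = (size_t)(d1 * ndir + d2);
      for (long m1 = 0; m1 < M; ++m1) {
        const double* Hrow = &H[(dp * (size_t)M + m1) * 343];
        for (int off = 0; off < 343; ++off) {
          const double v = Hrow[off];
          if (v == 0.0) continue;
          const int dx = off % 7 - 3, dy = (off / 7) % 7 - 3, dz = off / 49 - 3;
          const long m2 = m1 + dx + c1 * dy + (long)c1 * c2 * dz;
          const long colA = (long)d1 * M + m1, colB = (long)d2 * M + m2;
          ii.push_back((int)colA + 1); jj.push_back((int)colB + 1); xx.push_back(v);
          if (colA != colB) {
            ii.push_back((int)colB + 1); jj.push_back((int)colA + 1); xx.push_back(v);
          }
        }
      }
    }
  }
  return List::create(_["grad"] = NumericVector(grad.begin(), grad.end()),
                      _["i"] = IntegerVector(ii.begin(), ii.end()),
                      _["j"] = IntegerVector(jj.begin(), jj.end()),
                      _["x"] = NumericVector(xx.begin(), xx.end()));
}
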