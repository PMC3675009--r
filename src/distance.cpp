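// Pairwise substructure dissimilarity kernel.
//
// Each substructure is a triad of side-chain centroids (3 x 3 matrix, one
// row per residue, columns x/y/z) plus three residue-type indices.  The
// structural term is the least RMSD over the three corresponding centroids
// under an optimal proper rigid superposition (reflections disallowed);
// the chemical term sums per-position entries of a 20 x 20 pharmacophore
// dissimilarity matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Least RMSD between two point sets (rows = points) under optimal
// translation + proper rotation, via the closed-form SVD solution:
// lrmsd^2 = (E0 - 2 * (s1 + s2 + sign(det) * s3)) / n
static double lrmsd_points(const mat& A, const mat& B) {
  const unsigned n = A.n_rows;
  rowvec ca = mean(A, 0), cb = mean(B, 0);
  mat Ac = A.each_row() - ca;
  mat Bc = B.each_row() - cb;
  double e0 = accu(square(Ac)) + accu(square(Bc));
  mat C = Ac.t() * Bc;           // 3 x 3 covariance
  mat U, V;
  vec s;
  if (!svd(U, s, V, C)) {
    // fall back for pathological inputs: no rotation
    double d2 = accu(square(Ac - Bc)) / n;
    return std::sqrt(std::max(d2, 0.0));
  }
  double sgn = (det(U) * det(V) < 0.0) ? -1.0 : 1.0;
  double d = s(0) + s(1) + sgn * s(2);
  double msd = (e0 - 2.0 * d) / n;
  return std::sqrt(std::max(msd, 0.0));
}

// [[Rcpp::export(name = ".lrmsd3_cpp")]]
double lrmsd3_cpp(const arma::mat& a, const arma::mat& b) {
  if (a.n_rows != b.n_rows || a.n_cols != 3 || b.n_cols != 3)
    Rcpp::stop("point sets must be n x 3 matrices of equal size");
  return lrmsd_points(a, b);
}

// coords: N x 9 (x1,y1,z1,x2,y2,z2,x3,y3,z3); types: N x 3 one-based
// indices into the pharmacophore matrix.
// [[Rcpp::export(name = ".pairwise_dist_cpp")]]
arma::mat pairwise_dist_cpp(const arma::mat& coords,
                            const arma::imat& types,
                            const arma::mat& pharm,
                            double w_struct, double w_pharm) {
  const unsigned N = coords.n_rows;
  if (coords.n_cols != 9) Rcpp::stop("coords must be N x 9");
  if (types.n_rows != N || types.n_cols != 3) Rcpp::stop("types must be N x 3");
  mat D(N, N, fill::zeros);
  mat Ai(3, 3), Bj(3, 3);
  for (unsigned i = 0; i + 1 < N + 1; ++i) {
    for (unsigned p = 0; p < 3; ++p)
      for (unsigned c = 0; c < 3; ++c) Ai(p, c) = coords(i, 3 * p + c);
    for (unsigned j = i + 1; j < N; ++j) {
      for (unsigned p = 0; p < 3; ++p)
        for (unsigned c = 0; c < 3; ++c) Bj(p, c) = coords(j, 3 * p + c);
      double d = w_struct > 0.0 ? w_struct * lrmsd_points(Ai, Bj) : 0.0;
      if (w_pharm > 0.0) {
        double ph = 0.0;
        for (unsigned p = 0; p < 3; ++p)
          ph += pharm(types(i, p) - 1, types(j, p) - 1);
        d += w_pharm * ph;
      }
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
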