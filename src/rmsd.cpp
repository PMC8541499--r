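// Kabsch superposition kernels for ensemble fitting. Coordinates arrive as
// an R array frames x atoms x 3 (column-major); atom matrices are A x 3.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat frame_matrix(const Rcpp::NumericVector &coords, int nf, int na,
                        int f) {
  mat m(na, 3);
  for (int ax = 0; ax < 3; ++ax)
    for (int a = 0; a < na; ++a)
      m(a, ax) = coords[f + nf * (a + na * ax)];
  return m;
}

// Eigenvalues of a symmetric 3x3 matrix by the trigonometric closed form
// (ascending order not guaranteed; returns all three).
static void eig_sym3(const mat33 &A, double ev[3]) {
  double p1 = A(0, 1) * A(0, 1) + A(0, 2) * A(0, 2) + A(1, 2) * A(1, 2);
  double q = (A(0, 0) + A(1, 1) + A(2, 2)) / 3.0;
  if (p1 < 1e-30) {
    ev[0] = A(0, 0); ev[1] = A(1, 1); ev[2] = A(2, 2);
    return;
  }
  double p2 = (A(0, 0) - q) * (A(0, 0) - q) + (A(1, 1) - q) * (A(1, 1) - q) +
              (A(2, 2) - q) * (A(2, 2) - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  mat33 B = (A - q * eye(3, 3)) / p;
  double r = det(B) / 2.0;
  r = std::max(-1.0, std::min(1.0, r));
  double phi = std::acos(r) / 3.0;
  ev[0] = q + 2.0 * p * std::cos(phi);
  ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  ev[1] = 3.0 * q - ev[0] - ev[2];
}

// Minimal RMSD between two centred frames (Kabsch trace via the singular
// values of the cross-covariance, computed analytically for speed).
static double rmsd_centred(const mat &x, const mat &y, double x2, double y2) {
  mat33 h = x.t() * y;
  mat33 hth = h.t() * h;
  double ev[3];
  eig_sym3(hth, ev);
  double s0 = std::sqrt(std::max(0.0, ev[0]));
  double s1 = std::sqrt(std::max(0.0, ev[1]));
  double s2 = std::sqrt(std::max(0.0, ev[2]));
  // smallest singular value gets the sign of det(h)
  double smin = std::min(s0, std::min(s1, s2));
  double tr = s0 + s1 + s2 - smin + (det(h) < 0 ? -smin : smin);
  double msd = (x2 + y2 - 2.0 * tr) / x.n_rows;
  return msd > 0 ? std::sqrt(msd) : 0.0;
}

// Sum of pairwise RMSDs from each subsampled frame to all others; used for
// medoid (central-structure) selection. `idx` is 1-based.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_medoid_sums(Rcpp::NumericVector coords,
                                    Rcpp::IntegerVector idx) {
  Rcpp::IntegerVector dims = coords.attr("dim");
  int nf = dims[0], na = dims[1];
  int m = idx.size();
  std::vector<mat> frames(m);
  std::vector<double> sq(m);
  for (int i = 0; i < m; ++i) {
    mat x = frame_matrix(coords, nf, na, idx[i] - 1);
    x.each_row() -= mean(x, 0);
    frames[i] = x;
    sq[i] = accu(x % x);
  }
  Rcpp::NumericVector sums(m);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double r = rmsd_centred(frames[i], frames[j], sq[i], sq[j]);
      sums[i] += r;
      sums[j] += r;
    }
  }
  return sums;
}

// Least-squares superpose every frame onto the reference frame (1-based
// index `ref`); the transform is computed on the selected atoms (1-based
// `sel`) and applied to all atoms. Returns the fitted coordinate array.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_fit_frames(Rcpp::NumericVector coords, int ref,
                                   Rcpp::IntegerVector sel) {
  Rcpp::IntegerVector dims = coords.attr("dim");
  int nf = dims[0], na = dims[1];
  uvec s_idx(sel.size());
  for (int i = 0; i < sel.size(); ++i) s_idx(i) = sel[i] - 1;

  mat yfull = frame_matrix(coords, nf, na, ref - 1);
  mat y = yfull.rows(s_idx);
  rowvec ycen = mean(y, 0);
  y.each_row() -= ycen;

  Rcpp::NumericVector out(coords.size());
  out.attr("dim") = dims;
  for (int f = 0; f < nf; ++f) {
    mat xfull = frame_matrix(coords, nf, na, f);
    mat x = xfull.rows(s_idx);
    rowvec xcen = mean(x, 0);
    x.each_row() -= xcen;
    mat h = x.t() * y;
    mat U, V;
    vec s;
    svd(U, s, V, h);
    mat R = U * V.t();
    if (det(R) < 0) {
      U.col(2) *= -1.0;
      R = U * V.t();
    }
    xfull.each_row() -= xcen;
    mat fit = xfull * R;
    fit.each_row() += ycen;
    for (int ax = 0; ax < 3; ++ax)
      for (int a = 0; a < na; ++a)
        out[f + nf * (a + na * ax)] = fit(a, ax);
  }
  return out;
}

// RMSD of every frame to a reference frame of the same ensemble after
// optimal superposition.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_rmsd_to_ref(Rcpp::NumericVector coords, int ref) {
  Rcpp::IntegerVector dims = coords.attr("dim");
  int nf = dims[0], na = dims[1];
  mat y = frame_matrix(coords, nf, na, ref - 1);
  y.each_row() -= mean(y, 0);
  double y2 = accu(y % y);
  Rcpp::NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    mat x = frame_matrix(coords, nf, na, f);
    x.each_row() -= mean(x, 0);
    out[f] = rmsd_centred(x, y, accu(x % x), y2);
  }
  return out;
}
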