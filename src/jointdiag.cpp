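// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Orthogonal joint approximate diagonalization of a set of symmetric
// matrices by Givens rotations (Jacobi-like sweeps).  For each pair (p,q)
// the rotation angle has the closed form
//   theta = 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
// with ton/toff accumulated over all matrices; a sweep visits every pair
// once and the algorithm stops when every |sin(theta)| in a sweep is
// below `tol`.
// [[Rcpp::export]]
List jointdiag_cpp(arma::cube M, double tol = 1e-9, int max_sweeps = 100) {
  const arma::uword n = M.n_rows;
  const arma::uword K = M.n_slices;
  arma::mat V(n, n, arma::fill::eye);

  std::vector<double> off_trace;
  auto offdiag_ss = [&]() {
    double ss = 0.0;
    for (arma::uword k = 0; k < K; ++k) {
      arma::mat A = M.slice(k);
      A.diag().zeros();
      ss += arma::accu(arma::square(A));
    }
    return ss;
  };
  off_trace.push_back(offdiag_ss());

  bool converged = false;
  int sweeps = 0;
  for (int sweep = 0; sweep < max_sweeps && !converged; ++sweep) {
    converged = true;
    for (arma::uword p = 0; p + 1 < n; ++p) {
      for (arma::uword q = p + 1; q < n; ++q) {
        double ton = 0.0, toff = 0.0;
        for (arma::uword k = 0; k < K; ++k) {
          const double h1 = M(p, p, k) - M(q, q, k);
          const double h2 = M(p, q, k) + M(q, p, k);
          ton += h1 * h1 - h2 * h2;
          toff += 2.0 * h1 * h2;
        }
        const double theta =
            0.5 * std::atan2(toff, ton + std::sqrt(ton * ton + toff * toff));
        const double c = std::cos(theta), s = std::sin(theta);
        if (std::fabs(s) > tol) {
          converged = false;
          for (arma::uword k = 0; k < K; ++k) {
            // rows
            arma::rowvec rp = M.slice(k).row(p), rq = M.slice(k).row(q);
            M.slice(k).row(p) = c * rp + s * rq;
            M.slice(k).row(q) = -s * rp + c * rq;
            // columns
            arma::vec cp = M.slice(k).col(p), cq = M.slice(k).col(q);
            M.slice(k).col(p) = c * cp + s * cq;
            M.slice(k).col(q) = -s * cp + c * cq;
          }
          arma::vec vp = V.col(p), vq = V.col(q);
          V.col(p) = c * vp + s * vq;
          V.col(q) = -s * vp + c * vq;
        }
      }
    }
    ++sweeps;
    off_trace.push_back(offdiag_ss());
  }

  return List::create(_["rotation"] = V, _["sweeps"] = sweeps,
                      _["converged"] = converged,
                      _["offdiag_trace"] =
                          NumericVector(off_trace.begin(), off_trace.end()));
}
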