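// Lawson-Hanson active-set non-negative least squares.
//
// This is the inner solver of the T2 spectrum fit: each voxel requires
// dozens of NNLS solves (8 candidate flip angles plus the regularization
// bisection), so the solver lives in C++. Problem sizes are tiny
// (<= ~80 rows x 40 columns) and the passive set rarely exceeds a handful
// of columns, so dense normal-free least squares via arma::solve on the
// passive submatrix is both accurate and fast.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".nnls_cpp")]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b) {
    const uword n = A.n_cols;
    if (b.n_elem != A.n_rows)
        Rcpp::stop("nnls: length(b) must equal nrow(A)");

    vec x(n, fill::zeros);
    std::vector<bool> passive(n, false);
    vec w = A.t() * b;                     // gradient at x = 0
    const double tol = 10.0 * datum::eps * norm(A, "inf") * std::max(A.n_rows, n);

    const uword itmax = 3 * n + 30;
    uword iter = 0;

    while (iter++ < itmax) {
        // select the most violated constraint among the active set
        double wmax = tol;
        sword j = -1;
        for (uword k = 0; k < n; ++k) {
            if (!passive[k] && w(k) > wmax) { wmax = w(k); j = (sword)k; }
        }
        if (j < 0) break;                  // KKT satisfied
        passive[(uword)j] = true;

        // inner loop: restrict to passive columns, back off if infeasible
        for (;;) {
            std::vector<uword> pidx;
            for (uword k = 0; k < n; ++k) if (passive[k]) pidx.push_back(k);
            uvec P(pidx);
            vec zP;
            bool ok = solve(zP, A.cols(P), b, solve_opts::fast);
            if (!ok) {
                // rank-deficient passive set: fall back to pinv
                zP = pinv(A.cols(P)) * b;
            }
            if (zP.n_elem && zP.min() > 0) {
                x.zeros();
                x(P) = zP;
                break;
            }
            // step toward zP until the first passive coefficient hits zero
            double alpha = datum::inf;
            for (uword k = 0; k < P.n_elem; ++k) {
                if (zP(k) <= 0) {
                    double a = x(P(k)) / (x(P(k)) - zP(k));
                    if (a < alpha) alpha = a;
                }
            }
            for (uword k = 0; k < P.n_elem; ++k)
                x(P(k)) += alpha * (zP(k) - x(P(k)));
            for (uword k = 0; k < P.n_elem; ++k) {
                if (x(P(k)) <= tol) { passive[P(k)] = false; x(P(k)) = 0.0; }
            }
        }
        w = A.t() * (b - A * x);
    }

    vec r = b - A * x;
    return Rcpp::List::create(Rcpp::Named("x") = x,
                              Rcpp::Named("chi2") = dot(r, r));
}
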