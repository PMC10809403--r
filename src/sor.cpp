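#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation for the 7-point finite-difference
// heterogeneous-dielectric Poisson operator, in the form (after multiplying
// the discrete equation by h^2):
//
//   sum_edges eps_e (phi_nb - phi_c) - kterm_c * phi_c + b_c = 0
//
// with b = 4*pi*f*q_node/h and kterm = eps_out * kappa^2 * h^2 * mask.
// Arrays are column-major (R array order), 0-based index
// idx = i + n1*(j + n2*k). epsx[idx] is the edge between node (i,j,k) and
// (i+1,j,k) (wrapped when periodic); likewise epsy, epsz.
// In Dirichlet mode the boundary nodes of phi are held fixed.

static inline int wrap(int i, int n) { return i < 0 ? i + n : (i >= n ? i - n : i); }

// [[Rcpp::export]]
List sor_solve_cpp(NumericVector phi_init, NumericVector b,
                   NumericVector epsx, NumericVector epsy, NumericVector epsz,
                   NumericVector kterm, IntegerVector dims, bool periodic,
                   double omega, double tol, int max_iter) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector phi = clone(phi_init);
  double bnorm = 0.0;
  for (R_xlen_t t = 0; t < ntot; ++t) bnorm += b[t] * b[t];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;

  const int lo = periodic ? 0 : 1;
  const int hi1 = periodic ? n1 : n1 - 1;
  const int hi2 = periodic ? n2 : n2 - 1;
  const int hi3 = periodic ? n3 : n3 - 1;

  double resid = R_PosInf;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    for (int color = 0; color < 2; ++color) {
      for (int k = lo; k < hi3; ++k) {
        const int km = wrap(k - 1, n3), kp = wrap(k + 1, n3);
        for (int j = lo; j < hi2; ++j) {
          const int jm = wrap(j - 1, n2), jp = wrap(j + 1, n2);
          const R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
          const R_xlen_t basejm = (R_xlen_t)n1 * (jm + (R_xlen_t)n2 * k);
          const R_xlen_t basejp = (R_xlen_t)n1 * (jp + (R_xlen_t)n2 * k);
          const R_xlen_t basekm = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * km);
          const R_xlen_t basekp = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * kp);
          int i0 = lo + ((lo + j + k + color) % 2 + 2) % 2;
          for (int i = i0; i < hi1; i += 2) {
            const int im = wrap(i - 1, n1), ip = wrap(i + 1, n1);
            const R_xlen_t c = base + i;
            const double exm = epsx[base + im], exp_ = epsx[c];
            const double eym = epsy[basejm + i], eyp = epsy[base + i];
            const double ezm = epsz[basekm + i], ezp = epsz[base + i];
            const double num = exm * phi[base + im] + exp_ * phi[base + ip] +
                               eym * phi[basejm + i] + eyp * phi[basejp + i] +
                               ezm * phi[basekm + i] + ezp * phi[basekp + i] +
                               b[c];
            const double den = exm + exp_ + eym + eyp + ezm + ezp + kterm[c];
            const double gs = num / den;
            phi[c] += omega * (gs - phi[c]);
          }
        }
      }
    }
    if (iter % 10 == 0 || iter == max_iter) {
      double r2 = 0.0;
      for (int k = lo; k < hi3; ++k) {
        const int km = wrap(k - 1, n3), kp = wrap(k + 1, n3);
        for (int j = lo; j < hi2; ++j) {
          const int jm = wrap(j - 1, n2), jp = wrap(j + 1, n2);
          const R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
          const R_xlen_t basejm = (R_xlen_t)n1 * (jm + (R_xlen_t)n2 * k);
          const R_xlen_t basejp = (R_xlen_t)n1 * (jp + (R_xlen_t)n2 * k);
          const R_xlen_t basekm = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * km);
          const R_xlen_t basekp = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * kp);
          for (int i = lo; i < hi1; ++i) {
            const int im = wrap(i - 1, n1), ip = wrap(i + 1, n1);
            const R_xlen_t c = base + i;
            const double res =
                epsx[base + im] * (phi[base + im] - phi[c]) +
                epsx[c] * (phi[base + ip] - phi[c]) +
                epsy[basejm + i] * (phi[basejm + i] - phi[c]) +
                epsy[base + i] * (phi[basejp + i] - phi[c]) +
                epsz[basekm + i] * (phi[basekm + i] - phi[c]) +
                epsz[base + i] * (phi[basekp + i] - phi[c]) -
                kterm[c] * phi[c] + b[c];
            r2 += res * res;
          }
        }
      }
      resid = std::sqrt(r2) / bnorm;
      if (resid <= tol) break;
    }
  }
  return List::create(_["phi"] = phi, _["iterations"] = iter,
                      _["residual"] = resid);
}
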