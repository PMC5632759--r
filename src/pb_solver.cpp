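#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Successive over-relaxation (Gauss-Seidel) sweeps for the linearized
// Poisson-Boltzmann equation in dimensionless kT/e form:
//
//   div(eps grad phi) - eps_out * kappa^2 * h_ion * phi = -4*pi*L*rho
//
// discretized on a cubic grid with node-based dielectric (link value =
// harmonic mean of the two node values) and trilinearly spread charges.
// Boundary nodes are Dirichlet (preset in phi and never updated).
//
// phi  : initial guess with boundary values set (modified in place copy)
// eps  : node dielectric
// ion  : 1 outside the molecular region, 0 inside (ion exclusion)
// src  : 4*pi*L*q_node/spacing per node (q_node in e)
// screen: eps_out * kappa^2 * spacing^2
//
// Converges when the largest absolute node update in a sweep drops below
// tol; errors out (handled by the R caller) if maxSweeps is exhausted.

static inline double hmean(double a, double b) {
  return 2.0 * a * b / (a + b);
}

// [[Rcpp::export]]
List pb_sor_cpp(NumericVector phi_, NumericVector eps, IntegerVector ion,
                NumericVector src, int nx, int ny, int nz,
                double screen, double omega, double tol, int maxSweeps) {
  NumericVector phi = clone(phi_);
  double *p = phi.begin();
  const double *e = eps.begin();
  const int *io = ion.begin();
  const double *s = src.begin();
  const int sx = 1, sy = nx, sz = nx * ny;

  double maxupd = R_PosInf;
  int sweep = 0;
  for (; sweep < maxSweeps && maxupd >= tol; ++sweep) {
    maxupd = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        int base = j * sy + k * sz;
        for (int i = 1; i < nx - 1; ++i) {
          int id = i * sx + base;
          double e0 = e[id];
          double exm = hmean(e0, e[id - sx]), exp_ = hmean(e0, e[id + sx]);
          double eym = hmean(e0, e[id - sy]), eyp = hmean(e0, e[id + sy]);
          double ezm = hmean(e0, e[id - sz]), ezp = hmean(e0, e[id + sz]);
          double num = exm * p[id - sx] + exp_ * p[id + sx] +
                       eym * p[id - sy] + eyp * p[id + sy] +
                       ezm * p[id - sz] + ezp * p[id + sz] + s[id];
          double den = exm + exp_ + eym + eyp + ezm + ezp +
                       (io[id] ? screen : 0.0);
          double gs = num / den;
          double upd = omega * (gs - p[id]);
          p[id] += upd;
          double a = std::fabs(upd);
          if (a > maxupd) maxupd = a;
        }
      }
    }
  }
  return List::create(_["phi"] = phi, _["sweeps"] = sweep,
                      _["maxUpdate"] = maxupd,
                      _["converged"] = (maxupd < tol));
}
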