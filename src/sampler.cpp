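#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Wrap an angle onto [-180, 180).
static inline double wrap_angle(double x) {
  return x - 360.0 * std::floor((x + 180.0) / 360.0);
}

// Minimal-image wrap of an angular difference onto [-180, 180).
static inline double wrap_delta(double d) { return wrap_angle(d); }

// Sum-of-Gaussian-basins potential on the 2D torus, kcal/mol.
static inline double potential(double phi, double psi,
                               const NumericMatrix &centers,
                               const NumericVector &depths,
                               const NumericVector &widths) {
  double v = 0.0;
  const int k = centers.nrow();
  for (int j = 0; j < k; ++j) {
    const double dp = wrap_delta(phi - centers(j, 0));
    const double ds = wrap_delta(psi - centers(j, 1));
    const double w2 = widths[j] * widths[j];
    v -= depths[j] * std::exp(-(dp * dp + ds * ds) / (2.0 * w2));
  }
  return v;
}

// aMD boost: (E - V)^2 / (alpha + E - V) for V < E, else 0.
static inline double boost_dv(double v, double E, double alpha) {
  if (v >= E) return 0.0;
  const double d = E - v;
  return d * d / (alpha + d);
}

// Metropolis sampler targeting exp(-(V + dV)/kT) on the 2D torus.
// Uses R's RNG so set.seed() makes the trajectory bit-reproducible.
// [[Rcpp::export(name = ".metropolis2d")]]
List metropolis2d(NumericMatrix centers, NumericVector depths,
                  NumericVector widths, double kT, int nSteps,
                  double stepSize, double startPhi, double startPsi,
                  bool boost, double E, double alpha, int recordStride) {
  const int nRec = nSteps / recordStride;
  NumericVector phi(nRec), psi(nRec), dv(nRec);
  double x = wrap_angle(startPhi), y = wrap_angle(startPsi);
  double v = potential(x, y, centers, depths, widths);
  double b = boost ? boost_dv(v, E, alpha) : 0.0;
  int nAcc = 0, rec = 0;
  for (int i = 1; i <= nSteps; ++i) {
    const double xp = wrap_angle(x + R::rnorm(0.0, stepSize));
    const double yp = wrap_angle(y + R::rnorm(0.0, stepSize));
    const double vp = potential(xp, yp, centers, depths, widths);
    const double bp = boost ? boost_dv(vp, E, alpha) : 0.0;
    const double dE = (vp + bp) - (v + b);
    if (dE <= 0.0 || R::unif_rand() < std::exp(-dE / kT)) {
      x = xp; y = yp; v = vp; b = bp; ++nAcc;
    }
    if (i % recordStride == 0) {
      phi[rec] = x; psi[rec] = y; dv[rec] = b; ++rec;
    }
  }
  return List::create(_["phi"] = phi, _["psi"] = psi, _["dV"] = dv,
                      _["acceptance"] = (double)nAcc / nSteps);
}

// Grid evaluation of the basin potential (row-major over phi grid x psi grid).
// [[Rcpp::export(name = ".potential_grid")]]
NumericMatrix potential_grid(NumericVector phi, NumericVector psi,
                             NumericMatrix centers, NumericVector depths,
                             NumericVector widths) {
  NumericMatrix out(phi.size(), psi.size());
  for (int i = 0; i < phi.size(); ++i)
    for (int j = 0; j < psi.size(); ++j)
      out(i, j) = potential(phi[i], psi[j], centers, depths, widths);
  return out;
}
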