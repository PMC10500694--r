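#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Rotation-then-relaxation splitting of the Bloch equations for a train of
// piecewise-constant RF slices, evaluated for a batch of resonance offsets.
//
// The rotation solves dM/dt = M x Omega with Omega = (w1x, w1y, w0), i.e. a
// Rodrigues rotation by theta = |Omega| * dt about the *negated* field
// direction u = -Omega/|Omega|.  Slices with |Omega|*dt below 1e-15 rad apply
// the identity rotation.  Relaxation then damps (mx, my) by exp(-r2*dt) and
// pulls mz toward mz_eq with exp(-r1*dt).
//
// m0:        length-3 start vector (mx, my, mz), shared by all offsets
// w1x, w1y:  per-slice RF components, rad/s (length N)
// dt:        per-slice durations, s (length N)
// omega0:    resonance offsets, rad/s (batch; the scalar case is length 1)
// n_repeats: number of times the whole slice train is applied
// subdiv:    each slice is split into `subdiv` equal sub-slices (refinement)
//
// Returns an (n_offsets x 3) matrix of final states.  The per-offset loop is
// strictly independent, so batched results are bit-identical to scalar calls.
// [[Rcpp::export]]
NumericMatrix bloch_propagate_cpp(NumericVector m0, double mz_eq,
                                  NumericVector w1x, NumericVector w1y,
                                  NumericVector dt, NumericVector omega0,
                                  double r1, double r2,
                                  int n_repeats, int subdiv)
{
  const R_xlen_t n = w1x.size();
  const R_xlen_t g = omega0.size();
  if (n == 0) stop("waveform must contain at least one slice");
  if (dt.size() != n || w1y.size() != n)
    stop("w1x, w1y and dt must have equal length");
  if (n_repeats < 1) stop("n_repeats must be >= 1");
  if (subdiv < 1) stop("subdiv must be >= 1");

  std::vector<double> sdt(n), e1(n), e2(n);
  for (R_xlen_t j = 0; j < n; ++j) {
    sdt[j] = dt[j] / subdiv;
    e1[j] = std::exp(-r1 * sdt[j]);
    e2[j] = std::exp(-r2 * sdt[j]);
  }

  NumericMatrix out(g, 3);
  for (R_xlen_t i = 0; i < g; ++i) {
    double mx = m0[0], my = m0[1], mz = m0[2];
    const double w0 = omega0[i];
    for (int rep = 0; rep < n_repeats; ++rep) {
      for (R_xlen_t j = 0; j < n; ++j) {
        const double ax = w1x[j], ay = w1y[j];
        const double om = std::sqrt(ax * ax + ay * ay + w0 * w0);
        const double th = om * sdt[j];
        const bool rotate = th >= 1e-15;
        double ux = 0.0, uy = 0.0, uz = 0.0, c = 1.0, si = 0.0, oc = 0.0;
        if (rotate) {
          ux = -ax / om; uy = -ay / om; uz = -w0 / om;
          c = std::cos(th); si = std::sin(th); oc = 1.0 - c;
        }
        const double ee1 = e1[j], ee2 = e2[j];
        for (int s = 0; s < subdiv; ++s) {
          if (rotate) {
            const double dot = ux * mx + uy * my + uz * mz;
            const double cx = uy * mz - uz * my;
            const double cy = uz * mx - ux * mz;
            const double cz = ux * my - uy * mx;
            const double nx = c * mx + oc * dot * ux + si * cx;
            const double ny = c * my + oc * dot * uy + si * cy;
            const double nz = c * mz + oc * dot * uz + si * cz;
            mx = nx; my = ny; mz = nz;
          }
          mx *= ee2;
          my *= ee2;
          mz = mz_eq + (mz - mz_eq) * ee1;
        }
      }
    }
    out(i, 0) = mx; out(i, 1) = my; out(i, 2) = mz;
  }
  return out;
}

// Same propagation, but records the state after every slice (single offset,
// no repeats/subdivision).  Used for trajectory-level invariant checks.
// Returns an (N x 3) matrix.
// [[Rcpp::export]]
NumericMatrix bloch_trajectory_cpp(NumericVector m0, double mz_eq,
                                   NumericVector w1x, NumericVector w1y,
                                   NumericVector dt, double omega0,
                                   double r1, double r2)
{
  const R_xlen_t n = w1x.size();
  if (n == 0) stop("waveform must contain at least one slice");
  NumericMatrix out(n, 3);
  double mx = m0[0], my = m0[1], mz = m0[2];
  for (R_xlen_t j = 0; j < n; ++j) {
    const double ax = w1x[j], ay = w1y[j];
    const double om = std::sqrt(ax * ax + ay * ay + omega0 * omega0);
    const double th = om * dt[j];
    if (th >= 1e-15) {
      const double ux = -ax / om, uy = -ay / om, uz = -omega0 / om;
      const double c = std::cos(th), si = std::sin(th), oc = 1.0 - c;
      const double dot = ux * mx + uy * my + uz * mz;
      const double cx = uy * mz - uz * my;
      const double cy = uz * mx - ux * mz;
      const double cz = ux * my - uy * mx;
      const double nx = c * mx + oc * dot * ux + si * cx;
      const double ny = c * my + oc * dot * uy + si * cy;
      const double nz = c * mz + oc * dot * uz + si * cz;
      mx = nx; my = ny; mz = nz;
    }
    const double ee1 = std::exp(-r1 * dt[j]), ee2 = std::exp(-r2 * dt[j]);
    mx *= ee2;
    my *= ee2;
    mz = mz_eq + (mz - mz_eq) * ee1;
    out(j, 0) = mx; out(j, 1) = my; out(j, 2) = mz;
  }
  return out;
}
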