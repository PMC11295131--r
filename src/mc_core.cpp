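#include <Rcpp.h>
using namespace Rcpp;

// Particle-based drift-tube propagation: all particles advance in lockstep
// through shared time steps.  Per step and particle: (1) resample the
// identity from the column of the (cumulative) transition matrix belonging
// to the current identity and position cell, (2) advance the position by the
// new identity's drift step K*E*dt plus a random-walk diffusion step of
// magnitude sqrt(2*D_L*dt) with a fair-coin sign, (3) advance the clock.
// A particle terminates when it crosses x = L (arrival time linearly
// interpolated within the final step) or, in fixed-time mode, when its clock
// reaches tMax.  Uses R's RNG so set.seed() governs determinism.
//
// cumphi: n*n*ncell array, cumphi[i + n*j + n*n*c] = sum_{i'<=i} phi[i',j]
// for position cell c; cells are uniform over [0, L].

// [[Rcpp::export]]
List mc_core(IntegerVector id0, NumericVector x0, NumericVector t0,
             NumericVector v, NumericVector sig, NumericVector cumphi,
             int ncell, double L, double dt, double tMax, double maxSteps) {
  const int np = id0.size();
  const int n = v.size();
  std::vector<int> id(np);
  std::vector<double> x(np), t(np);
  std::vector<bool> done(np, false);
  NumericVector arrival(np);
  NumericMatrix events(n, n);
  const bool fixedTime = R_finite(tMax);
  const double cellWidth = (ncell > 1) ? (L / ncell) : 0.0;

  for (int p = 0; p < np; ++p) {
    id[p] = id0[p] - 1;
    x[p] = x0[p];
    t[p] = t0[p];
  }

  int ndone = 0;
  double steps = 0;
  while (ndone < np) {
    if (++steps > maxSteps)
      stop("particle propagation exceeded the step cap (%g); check the time step and drift velocities", maxSteps);
    for (int p = 0; p < np; ++p) {
      if (done[p]) continue;
      int cell = 0;
      if (ncell > 1) {
        cell = (int)std::floor(x[p] / cellWidth);
        if (cell < 0) cell = 0;
        if (cell >= ncell) cell = ncell - 1;
      }
      // reaction sampling (at most one recorded event per step; the
      // step-size guard keeps multi-reaction probability negligible)
      const double u = unif_rand();
      const double *col = &cumphi[(R_xlen_t)n * id[p] + (R_xlen_t)n * n * cell];
      int inew = n - 1;
      for (int i = 0; i < n; ++i) {
        if (u <= col[i]) { inew = i; break; }
      }
      if (inew != id[p]) {
        events(inew, id[p]) += 1.0;
        id[p] = inew;
      }
      // drift + random-walk diffusion with the *new* identity's transport
      const double sgn = (unif_rand() < 0.5) ? -1.0 : 1.0;
      const double xold = x[p];
      x[p] += v[id[p]] * dt + sgn * sig[id[p]];
      t[p] += dt;
      if (!fixedTime) {
        if (x[p] >= L) {
          // linear interpolation of the crossing within the final step
          arrival[p] = t[p] - dt + dt * (L - xold) / (x[p] - xold);
          done[p] = true;
          ++ndone;
        }
      } else if (t[p] >= tMax) {
        arrival[p] = t[p];
        done[p] = true;
        ++ndone;
      }
    }
  }

  IntegerVector idOut(np);
  for (int p = 0; p < np; ++p) idOut[p] = id[p] + 1;
  return List::create(_["id"] = idOut, _["arrival"] = arrival,
                      _["events"] = events, _["steps"] = steps);
}
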