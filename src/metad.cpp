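#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin dynamics on a periodic 1D collective variable with
// history-dependent Gaussian bias. The bias potential/force are accumulated
// on a fine grid (linear interpolation of the force); the static surface
// force is supplied on the same grid. Units: kcal/mol, degrees, ps.
//
// s_{t+1} = s_t + mu F(s_t) dt + sqrt(2 kT mu dt) xi
//
// Returns the sampled trajectory (every sample_stride steps), the hill
// centers (one every hill_stride steps) and the final bias grid.
// [[Rcpp::export(name = ".metad_run_cpp")]]
List metad_run_cpp(NumericVector surf_force, double s0, int nsteps,
                   double dt_ps, double mobility, double kT,
                   int hill_stride, double hill_w, double hill_sigma,
                   int sample_stride, double lo, double hi) {
  const int ng = surf_force.size();
  const double range = hi - lo;
  const double dg = range / ng;
  NumericVector bias_force(ng);   // -dV/ds at grid nodes lo + i*dg
  NumericVector bias_pot(ng);
  const int nhills = nsteps / hill_stride;
  NumericVector centers(nhills);
  NumericVector hill_steps(nhills);
  const int nsamp = nsteps / sample_stride + 1;
  NumericVector traj(nsamp);
  const double noise = std::sqrt(2.0 * kT * mobility * dt_ps);
  const double inv2s2 = 1.0 / (2.0 * hill_sigma * hill_sigma);

  double s = s0;
  int ih = 0, is = 0;
  traj[is++] = s;
  RNGScope scope;
  for (int t = 1; t <= nsteps; ++t) {
    // force by linear interpolation on the periodic grid
    double u = (s - lo) / dg;
    int i0 = (int)std::floor(u);
    double frac = u - i0;
    i0 = ((i0 % ng) + ng) % ng;
    int i1 = (i0 + 1) % ng;
    double F = (1 - frac) * (surf_force[i0] + bias_force[i0]) +
               frac * (surf_force[i1] + bias_force[i1]);
    double ds = mobility * F * dt_ps + noise * norm_rand();
    if (std::fabs(ds) > 90.0)
      stop("integration step exceeded 90 degrees; reduce the timestep");
    s += ds;
    // wrap into [lo, hi)
    s = s - range * std::floor((s - lo) / range);
    s = lo + (s - lo);
    if (s >= hi) s -= range;

    if (t % hill_stride == 0 && ih < nhills) {
      centers[ih] = s;
      hill_steps[ih] = t;
      ++ih;
      // deposit the hill on the grid (periodic minimum-image distance)
      for (int g = 0; g < ng; ++g) {
        double x = lo + g * dg - s;
        x -= range * std::round(x / range);
        double e = hill_w * std::exp(-x * x * inv2s2);
        bias_pot[g] += e;
        // force = -dV/ds evaluated at the node: e * x / sigma^2
        bias_force[g] += e * x / (hill_sigma * hill_sigma);
      }
    }
    if (t % sample_stride == 0 && is < nsamp) traj[is++] = s;
  }
  return List::create(_["traj"] = traj, _["centers"] = centers,
                      _["hill_steps"] = hill_steps,
                      _["bias_pot"] = bias_pot);
}
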