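#include <Rcpp.h>
using namespace Rcpp;

// Rejection-free (n-fold way) kinetic Monte Carlo random walk on a hopping
// network.  Sites are 0-based; the edges of site s occupy rows
// offset[s] .. offset[s+1]-1 of the rate/displacement arrays.  Each step
// draws a hop with probability rate/total and advances the clock by an
// exponential waiting time with mean 1/total.  Trajectories start cycling
// uniformly over the sites.  Uses R's RNG so set.seed() governs the walk.
//
// Returns the pooled displacement-moment sums needed for the diffusion
// tensor D = sum(dr dr^T) / (2 sum(t)) plus per-trajectory first/second
// moments of the isotropic estimate tr(dr dr^T)/(6 t) for a standard error.
// [[Rcpp::export]]
List kmc_walk(IntegerVector offset, NumericVector rate, NumericVector cum_rate,
              NumericMatrix disp, IntegerVector target,
              int n_sites, double n_traj, int n_steps) {
  NumericMatrix moment(3, 3);
  double time_sum = 0.0;
  double iso_sum = 0.0, iso_sq_sum = 0.0;

  long n_traj_l = (long) n_traj;
  for (long tr = 0; tr < n_traj_l; ++tr) {
    int s = (int)(tr % n_sites);
    double x = 0.0, y = 0.0, z = 0.0, t = 0.0;
    for (int step = 0; step < n_steps; ++step) {
      int lo = offset[s], hi = offset[s + 1];  // [lo, hi)
      double total = cum_rate[hi - 1];
      // waiting time
      double u = unif_rand();
      while (u <= 0.0) u = unif_rand();
      t += -std::log(u) / total;
      // pick the hop by binary search on the cumulative rates
      double v = unif_rand() * total;
      int a = lo, b = hi - 1;
      while (a < b) {
        int mid = (a + b) / 2;
        if (cum_rate[mid] >= v) b = mid; else a = mid + 1;
      }
      x += disp(a, 0);
      y += disp(a, 1);
      z += disp(a, 2);
      s = target[a];
    }
    moment(0, 0) += x * x; moment(0, 1) += x * y; moment(0, 2) += x * z;
    moment(1, 1) += y * y; moment(1, 2) += y * z;
    moment(2, 2) += z * z;
    time_sum += t;
    double iso = (x * x + y * y + z * z) / (6.0 * t);
    iso_sum += iso;
    iso_sq_sum += iso * iso;
  }
  moment(1, 0) = moment(0, 1);
  moment(2, 0) = moment(0, 2);
  moment(2, 1) = moment(1, 2);
  return List::create(
    _["moment"] = moment,
    _["time_sum"] = time_sum,
    _["iso_sum"] = iso_sum,
    _["iso_sq_sum"] = iso_sq_sum
  );
}
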