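#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy cross-sample peak clustering.
//
// Peaks arrive in processing order (descending amplitude with deterministic
// tie keys). Each unassigned peak either joins an existing cluster -- if it
// passes the mass ppm tolerance and the migration-time window of the
// cluster's consensus (frozen at the seed peak's coordinates) and its sample
// is not yet represented -- or seeds a new cluster. Ties between eligible
// clusters are broken by smallest ppm deviation, then smallest |dt|, then
// lowest cluster index.
//
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(NumericVector mass, NumericVector time,
                                 IntegerVector sample, int n_samples,
                                 double ppm_small, double ppm_large,
                                 double small_mass_limit,
                                 double width_lo, double width_hi,
                                 double time_lo, double time_hi) {
  int n = mass.size();
  IntegerVector assign(n);
  std::vector<double> seed_mass, seed_time, seed_tol_ppm, seed_halfwidth;
  std::vector<std::vector<char> > occupied;

  double span = time_hi - time_lo;
  for (int i = 0; i < n; ++i) {
    double m = mass[i], t = time[i];
    int s = sample[i] - 1;
    int best = -1;
    double best_ppm = 0.0, best_dt = 0.0;
    int nc = seed_mass.size();
    for (int c = 0; c < nc; ++c) {
      double dppm = std::fabs(m - seed_mass[c]) / seed_mass[c] * 1e6;
      if (dppm > seed_tol_ppm[c]) continue;
      double dt = std::fabs(t - seed_time[c]);
      if (dt > seed_halfwidth[c]) continue;
      if (occupied[c][s]) continue;
      if (best < 0 || dppm < best_ppm ||
          (dppm == best_ppm && dt < best_dt)) {
        best = c;
        best_ppm = dppm;
        best_dt = dt;
      }
    }
    if (best < 0) {
      // seed a new cluster; consensus frozen at the seed coordinates
      double frac;
      if (t <= time_lo) frac = width_lo;
      else if (t >= time_hi) frac = width_hi;
      else frac = width_lo + (width_hi - width_lo) * (t - time_lo) / span;
      seed_mass.push_back(m);
      seed_time.push_back(t);
      seed_tol_ppm.push_back(m < small_mass_limit ? ppm_small : ppm_large);
      seed_halfwidth.push_back(frac * t / 2.0);
      occupied.push_back(std::vector<char>(n_samples, 0));
      best = seed_mass.size() - 1;
    }
    occupied[best][s] = 1;
    assign[i] = best + 1;
  }
  return assign;
}
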