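#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis sampler over protonation microstates.
// h: pH/shift energy of the protonated form per site; acid: 1 if acid;
// w: unit-charge coupling matrix (zero diagonal); ion: unit-charge bound-ion
// factor per site (zeros when no ion); pairs: 0-based index pairs given
// joint double-flip proposals. Counts of the protonated form are
// accumulated once per sweep after burn_in, split into two halves for the
// convergence diagnostic. Uses R's RNG: set.seed() upstream gives
// bit-identical counts.
// [[Rcpp::export]]
List mc_titrate_cpp(NumericVector h, IntegerVector acid, NumericMatrix w,
                    NumericVector ion, double beta, int sweeps, int burn_in,
                    IntegerMatrix pairs) {
  const int n = h.size();
  std::vector<int> x(n);
  std::vector<double> q(n);
  for (int i = 0; i < n; ++i) {
    x[i] = (h[i] < 0.0) ? 1 : 0;
    q[i] = acid[i] ? (x[i] - 1.0) : x[i];
  }
  auto local_field = [&](int i) {
    double s = ion[i];
    for (int j = 0; j < n; ++j) s += w(i, j) * q[j];
    return s;
  };
  const int kept = sweeps - burn_in;
  const int half = kept / 2;
  std::vector<double> counts(n, 0.0), c1(n, 0.0), c2(n, 0.0);
  long attempted = 0, accepted = 0;
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      double dx = 1.0 - 2.0 * x[i];   // charge change equals dx for both kinds
      double de = dx * h[i] + dx * local_field(i);
      ++attempted;
      if (de <= 0.0 || unif_rand() < std::exp(-beta * de)) {
        x[i] = 1 - x[i];
        q[i] += dx;
        ++accepted;
      }
    }
    for (int p = 0; p < pairs.nrow(); ++p) {
      int i = pairs(p, 0), j = pairs(p, 1);
      double dxi = 1.0 - 2.0 * x[i];
      double de = dxi * h[i] + dxi * local_field(i);
      // apply i's charge change before evaluating j's local field
      q[i] += dxi;
      double dxj = 1.0 - 2.0 * x[j];
      de += dxj * h[j] + dxj * local_field(j);
      q[i] -= dxi;
      ++attempted;
      if (de <= 0.0 || unif_rand() < std::exp(-beta * de)) {
        x[i] = 1 - x[i];
        q[i] += dxi;
        x[j] = 1 - x[j];
        q[j] += dxj;
        ++accepted;
      }
    }
    if (s >= burn_in) {
      int k = s - burn_in;
      for (int i = 0; i < n; ++i) {
        counts[i] += x[i];
        if (k < half) c1[i] += x[i]; else c2[i] += x[i];
      }
    }
  }
  return List::create(
    _["counts"] = NumericVector(counts.begin(), counts.end()),
    _["counts_first"] = NumericVector(c1.begin(), c1.end()),
    _["counts_second"] = NumericVector(c2.begin(), c2.end()),
    _["kept_first"] = half,
    _["kept_second"] = kept - half,
    _["accepted"] = (double)accepted,
    _["attempted"] = (double)attempted);
}

// ---- toy binding-cage FEP sampler ---------------------------------------

static inline double lj_coul(double r, double rmin, double eps, double qq) {
  if (r < 1e-9) r = 1e-9;
  double s = rmin / r;
  double s6 = s * s * s;
  s6 = s6 * s6;
  return eps * (s6 * s6 - 2.0 * s6) + 332.06 * qq / r;
}

// Metropolis sampling of a single ion (and optionally mobile ligands) in a
// harmonic cage with Lennard-Jones + Coulomb ligand interactions and
// flat-harmonic ligand-ligand distance restraints. Records, for every
// post-equilibration step, the energy difference between the ion
// parameters of the next window (p1) and the sampled window (p0).
// [[Rcpp::export]]
List toy_fep_window_cpp(NumericMatrix lig_ref, NumericVector qlig,
                        NumericVector rlig, NumericVector elig, bool mobile,
                        double cage_k, double lig_k, NumericVector p0,
                        NumericVector p1, NumericMatrix restr,
                        IntegerMatrix tracked, int steps, int n_equil,
                        double beta, double step_ion, double step_lig) {
  const int n = lig_ref.nrow();
  std::vector<double> lig(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) lig[3 * i + d] = lig_ref(i, d);
  double ion[3] = {0.0, 0.0, 0.0};

  auto dist_il = [&](const double* pos, int i) {
    double dx = pos[0] - lig[3 * i], dy = pos[1] - lig[3 * i + 1],
           dz = pos[2] - lig[3 * i + 2];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  auto pair_energy = [&](double r, int i, const NumericVector& p) {
    return lj_coul(r, p[0] + rlig[i], std::sqrt(p[1] * elig[i]),
                   p[2] * qlig[i]);
  };
  auto ion_energy = [&](const double* pos, const NumericVector& p) {
    double e = cage_k * (pos[0] * pos[0] + pos[1] * pos[1] + pos[2] * pos[2]);
    for (int i = 0; i < n; ++i) e += pair_energy(dist_il(pos, i), i, p);
    return e;
  };
  auto restr_energy_for = [&](int i) {
    double e = 0.0;
    for (int m = 0; m < restr.nrow(); ++m) {
      int a = (int)restr(m, 0), b = (int)restr(m, 1);
      if (i >= 0 && a != i && b != i) continue;
      double dx = lig[3 * a] - lig[3 * b], dy = lig[3 * a + 1] - lig[3 * b + 1],
             dz = lig[3 * a + 2] - lig[3 * b + 2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ex = std::fabs(d - restr(m, 2)) - restr(m, 3);
      if (ex > 0.0) e += 0.5 * restr(m, 4) * ex * ex;
    }
    return e;
  };
  auto tether_energy = [&](int i) {
    double dx = lig[3 * i] - lig_ref(i, 0), dy = lig[3 * i + 1] - lig_ref(i, 1),
           dz = lig[3 * i + 2] - lig_ref(i, 2);
    return lig_k * (dx * dx + dy * dy + dz * dz);
  };

  int n_keep = steps - n_equil;
  NumericVector du(n_keep > 0 ? n_keep : 0);
  double acc = 0.0;
  double ion_sum[3] = {0, 0, 0}, ion_sq[3] = {0, 0, 0};
  std::vector<double> dsum(tracked.nrow(), 0.0);
  int kept = 0;

  for (int s = 0; s < steps; ++s) {
    int pick = 0;  // 0 = ion, 1..n = ligand index + 1
    if (mobile && n > 0) pick = (int)(unif_rand() * (n + 1));
    if (pick == 0) {
      double trial[3];
      for (int d = 0; d < 3; ++d)
        trial[d] = ion[d] + step_ion * (2.0 * unif_rand() - 1.0);
      double de = ion_energy(trial, p0) - ion_energy(ion, p0);
      if (de <= 0.0 || unif_rand() < std::exp(-beta * de)) {
        for (int d = 0; d < 3; ++d) ion[d] = trial[d];
        acc += 1.0;
      }
    } else {
      int i = pick - 1;
      double old[3] = {lig[3 * i], lig[3 * i + 1], lig[3 * i + 2]};
      double e_old = pair_energy(dist_il(ion, i), i, p0) + tether_energy(i) +
                     restr_energy_for(i);
      for (int d = 0; d < 3; ++d)
        lig[3 * i + d] = old[d] + step_lig * (2.0 * unif_rand() - 1.0);
      double e_new = pair_energy(dist_il(ion, i), i, p0) + tether_energy(i) +
                     restr_energy_for(i);
      double de = e_new - e_old;
      if (de <= 0.0 || unif_rand() < std::exp(-beta * de)) {
        acc += 1.0;
      } else {
        for (int d = 0; d < 3; ++d) lig[3 * i + d] = old[d];
      }
    }
    if (s >= n_equil) {
      double d_u = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = dist_il(ion, i);
        d_u += pair_energy(r, i, p1) - pair_energy(r, i, p0);
      }
      du[kept] = d_u;
      for (int d = 0; d < 3; ++d) {
        ion_sum[d] += ion[d];
        ion_sq[d] += ion[d] * ion[d];
      }
      for (int t = 0; t < tracked.nrow(); ++t) {
        int a = tracked(t, 0), b = tracked(t, 1);
        double dx = lig[3 * a] - lig[3 * b],
               dy = lig[3 * a + 1] - lig[3 * b + 1],
               dz = lig[3 * a + 2] - lig[3 * b + 2];
        dsum[t] += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      ++kept;
    }
  }
  NumericVector ion_mean(3), ion_var(3);
  for (int d = 0; d < 3; ++d) {
    ion_mean[d] = ion_sum[d] / kept;
    ion_var[d] = ion_sq[d] / kept - ion_mean[d] * ion_mean[d];
  }
  NumericVector md(tracked.nrow());
  for (int t = 0; t < tracked.nrow(); ++t) md[t] = dsum[t] / kept;
  return List::create(_["du"] = du, _["acceptance"] = acc / steps,
                      _["ion_mean"] = ion_mean, _["ion_var"] = ion_var,
                      _["mean_distances"] = md);
}
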