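#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (Brownian) 1D integrator with optional umbrella or
// well-tempered metadynamics bias, using the Leimkuhler-Matthews
// (BAOAB-limit) scheme: the Gaussian increment is the average of two
// consecutive noise draws, which gives O(dt^2) accuracy of
// configurational averages instead of Euler-Maruyama's O(dt).
// The well-tempered bias is accumulated on a grid (value and force
// arrays), as PLUMED does, so the per-step cost stays O(1) in the
// number of deposited hills.
//
// pot_type: 0 flat, 1 harmonic (k, z0), 2 double well (barrier, center,
// half-separation), 3 tabulated (force interpolated from tab_z/tab_F).
// bias_type: 0 none, 1 umbrella (k, z0),
// 2 wtmetad (h0, sigma, stride, gamma, grid_min, grid_max, grid_dz).
// noise holds pre-scaled Gaussian increments sqrt(2 kT dt / friction) * N(0,1).

static inline double tab_force(double z, const NumericVector& tz,
                               const NumericVector& tf) {
  int n = tz.size();
  if (z <= tz[0]) return tf[0];
  if (z >= tz[n - 1]) return tf[n - 1];
  double dz = tz[1] - tz[0];
  int i = (int)((z - tz[0]) / dz);
  if (i > n - 2) i = n - 2;
  double w = (z - tz[i]) / dz;
  return tf[i] * (1.0 - w) + tf[i + 1] * w;
}

// [[Rcpp::export]]
List langevin_run_cpp(double zinit, int n_steps, double dt, double friction,
                      double kbt, int pot_type, NumericVector pot_params,
                      NumericVector tab_z, NumericVector tab_F,
                      int bias_type, NumericVector bias_params,
                      NumericVector noise) {
  NumericVector z(n_steps + 1);
  z[0] = zinit;

  // metadynamics state
  int grid_n = 0, stride = 0;
  double h0 = 0, sigma = 0, gamma = 0, gmin = 0, gdz = 0, kbt_dT = 0;
  std::vector<double> Vb, Fb;
  std::vector<double> hill_t, hill_c, hill_h;
  if (bias_type == 2) {
    h0 = bias_params[0];
    sigma = bias_params[1];
    stride = (int)bias_params[2];
    gamma = bias_params[3];
    gmin = bias_params[4];
    double gmax = bias_params[5];
    gdz = bias_params[6];
    grid_n = (int)std::floor((gmax - gmin) / gdz) + 1;
    Vb.assign(grid_n, 0.0);
    Fb.assign(grid_n, 0.0);
    kbt_dT = (gamma - 1.0) * kbt; // k_B * DeltaT
  }

  double cur = zinit;
  for (int t = 1; t <= n_steps; ++t) {
    double F = 0.0;
    switch (pot_type) {
    case 0: break;
    case 1: F = -pot_params[0] * (cur - pot_params[1]); break;
    case 2: {
      double u = cur - pot_params[1];
      double a2 = pot_params[2] * pot_params[2];
      F = -pot_params[0] * 4.0 * u * (u * u - a2) / (a2 * a2);
      break;
    }
    case 3: F = tab_force(cur, tab_z, tab_F); break;
    }
    if (bias_type == 1) {
      F += -bias_params[0] * (cur - bias_params[1]);
    } else if (bias_type == 2 && grid_n > 1) {
      double gpos = (cur - gmin) / gdz;
      if (gpos >= 0 && gpos <= grid_n - 1) {
        int i = (int)gpos;
        if (i > grid_n - 2) i = grid_n - 2;
        double w = gpos - i;
        F += Fb[i] * (1.0 - w) + Fb[i + 1] * w;
      }
    }
    if (!std::isfinite(F)) {
      stop("divergence: non-finite force at step %d (z = %g)", t, cur);
    }
    cur += dt * F / friction + 0.5 * (noise[t - 1] + noise[t]);
    if (!std::isfinite(cur)) {
      stop("divergence: non-finite position at step %d", t);
    }
    z[t] = cur;

    if (bias_type == 2 && stride > 0 && t % stride == 0) {
      // tempered height from the bias already accumulated at z_t
      double vb_here = 0.0;
      double gpos = (cur - gmin) / gdz;
      if (gpos >= 0 && gpos <= grid_n - 1) {
        int i = (int)gpos;
        if (i > grid_n - 2) i = grid_n - 2;
        double w = gpos - i;
        vb_here = Vb[i] * (1.0 - w) + Vb[i + 1] * w;
      }
      double h = h0 * std::exp(-vb_here / kbt_dT);
      int lo = (int)std::floor((cur - 5.0 * sigma - gmin) / gdz);
      int hi = (int)std::ceil((cur + 5.0 * sigma - gmin) / gdz);
      if (lo < 0) lo = 0;
      if (hi > grid_n - 1) hi = grid_n - 1;
      for (int i = lo; i <= hi; ++i) {
        double zg = gmin + i * gdz;
        double arg = (zg - cur) / sigma;
        double g = h * std::exp(-0.5 * arg * arg);
        Vb[i] += g;
        Fb[i] += g * (zg - cur) / (sigma * sigma); // force = -dVb/dz
      }
      hill_t.push_back(t * dt);
      hill_c.push_back(cur);
      hill_h.push_back(h);
    }
  }

  List out = List::create(_["z"] = z);
  if (bias_type == 2) {
    out["hill_time"] = wrap(hill_t);
    out["hill_center"] = wrap(hill_c);
    out["hill_height"] = wrap(hill_h);
  }
  return out;
}

// Minimum-image pair distances between two position sets (orthorhombic).
// Used by the RDF and hydrogen-bond hot paths.
// [[Rcpp::export]]
NumericVector pair_distances_cpp(NumericMatrix a, NumericMatrix b,
                                 IntegerVector ia, IntegerVector ib,
                                 NumericVector cell) {
  int n = ia.size();
  NumericVector out(n);
  double lx = cell[0], ly = cell[1], lz = cell[2];
  for (int k = 0; k < n; ++k) {
    int i = ia[k], j = ib[k];
    double dx = b(j, 0) - a(i, 0);
    double dy = b(j, 1) - a(i, 1);
    double dz = b(j, 2) - a(i, 2);
    dx -= lx * std::round(dx / lx);
    dy -= ly * std::round(dy / ly);
    dz -= lz * std::round(dz / lz);
    out[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return out;
}
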