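#include <Rcpp.h>
using namespace Rcpp;

// Correlated-random-walk path for a single fish in a circular arena.
//
// Heading receives a Gaussian perturbation each tick (a wrapped-normal /
// von-Mises-style draw; sd scales with sqrt(dt) so heading diffusion is
// tick-size invariant).  While a learned stimulus is active the heading
// drifts toward the reward port at rate bias_gain * bias_w * sin(bearing -
// heading) rad/s (a biased correlated random walk; the stationary heading
// concentration scales with bias_w, so weak associations give weak,
// noise-dominated homing and bias_w = 1 converges on the port bearing with
// a time constant of about 1 / bias_gain seconds).  Speed is
// a truncated-normal draw; both speed and turning are multiplied by
// arousal_gain while any stimulus is on.  Wall collisions reflect the
// heading off the tangent; an optional chord divider with a gap blocks and
// reflects crossings outside the gap.
//
// Uses R's RNG, so results are reproducible under set.seed().
// Returns an (n_steps + 1) x 4 matrix: x, y, heading (rad), speed (cm/s);
// row 1 is the initial state (speed 0).
// [[Rcpp::export]]
NumericMatrix sim_path_cpp(int n_steps, double dt,
                           double x, double y, double heading,
                           double base_speed, double speed_sd, double turn_sd,
                           double arousal_gain,
                           double bias_gain,
                           NumericVector bias_w,
                           double port_x, double port_y,
                           IntegerVector stim_on,
                           double radius,
                           int has_divider,
                           double div_offset, double div_gap_center,
                           double div_gap_halfwidth,
                           double div_ux, double div_uy) {
  if (bias_w.size() < n_steps || stim_on.size() < n_steps)
    stop("bias_w and stim_on must have length >= n_steps");
  NumericMatrix out(n_steps + 1, 4);
  out(0, 0) = x; out(0, 1) = y; out(0, 2) = heading; out(0, 3) = 0.0;
  const double r2 = radius * radius;
  const double sq_dt = std::sqrt(dt);

  for (int i = 0; i < n_steps; ++i) {
    double ag = stim_on[i] ? arousal_gain : 1.0;
    heading += R::rnorm(0.0, turn_sd * sq_dt * ag);

    double w = bias_w[i];
    if (w > 0.0) {
      double tgt = std::atan2(port_y - y, port_x - x);
      heading += bias_gain * w * dt * std::sin(tgt - heading);
    }

    double sp = R::rnorm(base_speed, speed_sd);
    if (sp < 0.0) sp = 0.0;
    sp *= ag;

    double nx = x + sp * dt * std::cos(heading);
    double ny = y + sp * dt * std::sin(heading);

    if (nx * nx + ny * ny > r2) {
      // reflect off the circular wall: flip the radial velocity component
      double nrm = std::sqrt(x * x + y * y);
      double nxu, nyu;
      if (nrm < 1e-9) { nxu = std::cos(heading); nyu = std::sin(heading); }
      else            { nxu = x / nrm;           nyu = y / nrm; }
      double vx = std::cos(heading), vy = std::sin(heading);
      double d = vx * nxu + vy * nyu;
      vx -= 2.0 * d * nxu; vy -= 2.0 * d * nyu;
      heading = std::atan2(vy, vx);
      nx = x + sp * dt * std::cos(heading);
      ny = y + sp * dt * std::sin(heading);
      if (nx * nx + ny * ny > r2) { nx = x; ny = y; }  // wedged in a corner
    }

    if (has_divider) {
      double a0 = x * div_ux + y * div_uy;
      double a1 = nx * div_ux + ny * div_uy;
      if ((a0 - div_offset) * (a1 - div_offset) < 0.0) {
        double f = (div_offset - a0) / (a1 - a0);
        double cx = x + f * (nx - x), cy = y + f * (ny - y);
        double lat = -cx * div_uy + cy * div_ux;
        if (std::fabs(lat - div_gap_center) > div_gap_halfwidth) {
          // blocked: reflect the normal velocity component, stay put
          double vx = std::cos(heading), vy = std::sin(heading);
          double d = vx * div_ux + vy * div_uy;
          vx -= 2.0 * d * div_ux; vy -= 2.0 * d * div_uy;
          heading = std::atan2(vy, vx);
          nx = x; ny = y;
        }
      }
    }

    x = nx; y = ny;
    out(i + 1, 0) = x; out(i + 1, 1) = y;
    out(i + 1, 2) = heading; out(i + 1, 3) = sp;
  }
  return out;
}

// Association-strength path under the rewarded-update rule.
// V <- V + alpha * (lam - V) after a rewarded presentation,
// V <- V * (1 - alpha / 4)  after an unrewarded one (mild extinction).
// Returns V *before* each presentation (length of `rewarded`).
// [[Rcpp::export]]
NumericVector assoc_path_cpp(IntegerVector rewarded, double alpha, double v0,
                             double lam) {
  int n = rewarded.size();
  NumericVector v(n);
  double V = v0;
  for (int i = 0; i < n; ++i) {
    v[i] = V;
    if (rewarded[i]) V += alpha * (lam - V);
    else             V *= (1.0 - alpha / 4.0);
  }
  return v;
}
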