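#include <Rcpp.h>
using namespace Rcpp;

// Closed-loop stepping of the linearized inverted pendulum under a delayed
// PD controller with torque-level noise and virtual angular limits.
//
// State update is the exact zero-order-hold discretization passed in as
// (a11, a12, a21, a22, b1, b2). All angles are radians internally.
//
// Delays, in samples:
//   intrinsic : sensing delay of the controller (state it reacts to)
//   tds[i]    : total torque-path delay (motor + imposed) at sample i
// Torque produced before t = 0 is the pre-trial hold (zero net torque).
// [[Rcpp::export]]
List simulate_loop_cpp(int n,
                       double a11, double a12, double a21, double a22,
                       double b1, double b2,
                       double kp, double kd,
                       int intrinsic,
                       IntegerVector tds,
                       NumericVector noise,
                       double ant_lim, double post_lim, double ramp,
                       double support, double damp, double barrier_gain,
                       bool use_limits,
                       double theta0, double theta_dot0) {
  NumericVector theta(n), theta_dot(n), torque(n);
  LogicalVector engaged(n);
  theta[0] = theta0;
  theta_dot[0] = theta_dot0;

  for (int i = 0; i < n; ++i) {
    // controller senses the state through the intrinsic delay
    int j = i - intrinsic;
    double th_s = (j >= 0) ? theta[j] : 0.0;
    double thd_s = (j >= 0) ? theta_dot[j] : 0.0;
    torque[i] = -kp * th_s - kd * thd_s + noise[i];

    // torque reaches the plant through the motor + imposed delay buffer
    int k = i - tds[i];
    double u = (k >= 0) ? torque[k] : 0.0;

    // virtual limit mechanics (undelayed: they live in the simulator)
    double tl = 0.0;
    if (use_limits) {
      double th = theta[i], thd = theta_dot[i];
      if (th > ant_lim) {
        double exc = th - ant_lim;
        double frac = exc < ramp ? exc / ramp : 1.0;
        double over = exc > ramp ? (exc - ramp) / ramp : 0.0;
        tl = -support * (frac + barrier_gain * over) - damp * thd;
        engaged[i] = true;
      } else if (th < post_lim) {
        double exc = post_lim - th;
        double frac = exc < ramp ? exc / ramp : 1.0;
        double over = exc > ramp ? (exc - ramp) / ramp : 0.0;
        tl = support * (frac + barrier_gain * over) - damp * thd;
        engaged[i] = true;
      }
    }

    if (i + 1 < n) {
      double T = u + tl;
      double th1 = a11 * theta[i] + a12 * theta_dot[i] + b1 * T;
      double thd1 = a21 * theta[i] + a22 * theta_dot[i] + b2 * T;
      // clamp runaway trajectories (limits disabled) instead of overflowing;
      // the R side flags these as diverged
      if (!R_finite(th1) || fabs(th1) > 1e3) {
        double s = (th1 > 0 || theta[i] > 0) ? 1.0 : -1.0;
        for (int r = i + 1; r < n; ++r) { theta[r] = s * 1e3; theta_dot[r] = 0.0; }
        break;
      }
      // the secondary limits are a kinematic constraint: the robot cannot
      // rotate further regardless of torque (inelastic stop)
      if (use_limits) {
        if (th1 > ant_lim + ramp) {
          th1 = ant_lim + ramp;
          if (thd1 > 0) thd1 = 0;
        } else if (th1 < post_lim - ramp) {
          th1 = post_lim - ramp;
          if (thd1 < 0) thd1 = 0;
        }
      }
      theta[i + 1] = th1;
      theta_dot[i + 1] = thd1;
    }
  }
  return List::create(_["theta"] = theta, _["theta_dot"] = theta_dot,
                      _["torque"] = torque, _["engaged"] = engaged);
}
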