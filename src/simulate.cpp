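// Inner loops of the CA3 simulation: per-step synchronous relaxation of the
// threshold-linear rate equation with sparsity/mean control, and the
// learning-phase driver with the trace-based Hebbian rule.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Bisection on the threshold so that the rectified rates meet the sparsity
// target, then closed-form gain for the mean target. Mirrors the R-level
// adjust_threshold_gain(); sparsity is monotone decreasing in T. Fused,
// allocation-free inner loop: this runs once per relaxation sweep.
static void control_rates(const vec& drive, double target_a,
                          double target_mean, vec& eta) {
  const uword n = drive.n_elem;
  const double* d = drive.memptr();
  double dmin = d[0], dmax = d[0];
  for (uword i = 1; i < n; ++i) {
    if (d[i] < dmin) dmin = d[i];
    if (d[i] > dmax) dmax = d[i];
  }
  const double range = dmax - dmin;
  if (range < 1e-12)
    Rcpp::stop("sparsity control failure: flat drive");
  double lo = dmin - range;
  double hi = dmax;
  for (int it = 0; it < 48; ++it) {
    const double T = 0.5 * (lo + hi);
    double s1 = 0.0, s2 = 0.0;
    for (uword i = 0; i < n; ++i) {
      const double v = d[i] - T;
      if (v > 0.0) { s1 += v; s2 += v * v; }
    }
    const double a = (s2 > 0.0) ? (s1 * s1) / (n * s2) : 1.0 / n;
    if (a > target_a) lo = T; else hi = T;
  }
  double T = 0.5 * (lo + hi);
  double s1 = 0.0;
  double* e = eta.memptr();
  for (uword i = 0; i < n; ++i) {
    const double v = d[i] - T;
    e[i] = v > 0.0 ? v : 0.0;
    s1 += e[i];
  }
  if (s1 <= 0.0) {
    // threshold landed above every drive; back off to the minimum
    T = dmin; s1 = 0.0;
    for (uword i = 0; i < n; ++i) { e[i] = d[i] - T; s1 += e[i]; }
  }
  const double g = target_mean * n / s1;
  for (uword i = 0; i < n; ++i) e[i] *= g;
}

static vec step_noise(int n, double noise_sd) {
  if (noise_sd <= 0.0) return vec(n, fill::zeros);
  Rcpp::NumericVector z = Rcpp::rnorm(n, 0.0, noise_sd);
  return vec(z.begin(), n);
}

// Relax one time step: `n_iter` synchronous sweeps with the given MF scale
// schedule, re-controlling T and g each sweep. `eta` is updated in place.
// Damped synchronous updates: eta <- (1 - damping) * F(eta) + damping * eta,
// where F is the controlled rectification of the total drive. Damping leaves
// the fixed points of the rate equation unchanged but suppresses the
// period-2 cycling that pure synchronous winner-take-all updates exhibit.
static void relax_step(const vec& mf, const mat& Jrc, const vec& schedule,
                       const vec& noise, double target_a, double target_mean,
                       double damping, vec& eta, vec& drive, vec& fresh) {
  const uword n_iter = schedule.n_elem;
  for (uword k = 0; k < n_iter; ++k) {
    drive = noise;
    if (schedule[k] != 0.0) drive += schedule[k] * mf;
    drive += Jrc * eta; // gemv accumulate, no temporary
    control_rates(drive, target_a, target_mean, fresh);
    if (damping > 0.0) eta = (1.0 - damping) * fresh + damping * eta;
    else eta = fresh;
  }
}

// Run a template/test phase. mf_drive is n_ca3 x n_steps; schedule gives
// the MF scaling of each within-step sweep (all 1 with DG on; 1, 1/3,
// 0 x 13 for the DG-off reverberation protocol). Returns the final rates
// of every step (n_ca3 x n_steps). Rates warm-start from the previous step.
// [[Rcpp::export]]
arma::mat cpp_run_phase(const arma::mat& mf_drive, const arma::mat& j_rc,
                        const arma::vec& schedule, double noise_sd,
                        double target_sparsity, double target_mean,
                        double damping) {
  const uword n = mf_drive.n_rows;
  const uword n_steps = mf_drive.n_cols;
  mat out(n, n_steps);
  vec eta(n, fill::zeros);
  vec drive(n), fresh(n);
  for (uword t = 0; t < n_steps; ++t) {
    vec noise = step_noise(n, noise_sd);
    relax_step(mf_drive.col(t), j_rc, schedule, noise, target_sparsity,
               target_mean, damping, eta, drive, fresh);
    out.col(t) = eta;
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Learning phase: activity each step from the frozen uniform RC weights;
// Hebbian increments accumulate on W (started at the uniform weights),
// clipped at zero after every step. The presynaptic trace is the mean of
// the previous `tau` rate vectors (current step excluded; early steps use
// whatever history exists). Returns the accumulated, unnormalized W.
// [[Rcpp::export]]
arma::mat cpp_learning_phase(const arma::mat& mf_drive,
                             const arma::mat& j_uniform,
                             const arma::mat& conn_rc,
                             const arma::vec& schedule, double noise_sd,
                             double target_sparsity, double target_mean,
                             double damping, double gamma, int tau) {
  const uword n = mf_drive.n_rows;
  const uword n_steps = mf_drive.n_cols;
  mat W = j_uniform;
  mat hist(n, tau, fill::zeros);
  vec trace_sum(n, fill::zeros);
  int hcount = 0, hpos = 0;
  vec eta(n, fill::zeros);
  vec drive(n), fresh(n);
  for (uword t = 0; t < n_steps; ++t) {
    vec noise = step_noise(n, noise_sd);
    relax_step(mf_drive.col(t), j_uniform, schedule, noise, target_sparsity,
               target_mean, damping, eta, drive, fresh);
    if (gamma > 0.0) {
      vec lambda = (hcount > 0) ? vec(trace_sum / hcount)
                                : vec(n, fill::zeros);
      vec dev = eta - lambda;
      W += gamma * (eta * dev.t()) % conn_rc;
      W.transform([](double v) { return v > 0.0 ? v : 0.0; });
    }
    // push current rates into the ring buffer
    if (hcount == tau) trace_sum -= hist.col(hpos);
    else ++hcount;
    hist.col(hpos) = eta;
    trace_sum += eta;
    hpos = (hpos + 1) % tau;
    if (t % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return W;
}
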