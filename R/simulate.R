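#' Simulate a template or test phase
#'
#' Runs the network along a trajectory and returns the CA3 rate vector
#' attained at every time step. With `dg_mode = "on"` every within-step
#' relaxation sweep receives the full MF drive. With `dg_mode = "off"`
#' (attractor/reverberation protocol) each step runs 15 sweeps with the MF
#' input scaled by 1 on the first sweep, 1/3 on the second and 0 on the
#' remaining 13; the final configuration is the step's state. Rates
#' warm-start from the previous step's final state.
#'
#' @param net A [ca3_network()].
#' @param pop A `dg_population`.
#' @param traj A trajectory (its `env` is the spatial reference).
#' @param dg_mode `"on"` or `"off"`.
#' @param n_iter Sweeps per step with DG on (default 15, matching the
#'   DG-off protocol length).
#' @param damping Mixing weight of the previous state in each damped
#'   synchronous sweep, `eta <- (1 - damping) * F(eta) + damping * eta`
#'   (default 0.3). Damping leaves the fixed points unchanged but removes
#'   the period-2 cycling of undamped synchronous winner-take-all updates;
#'   0 recovers the undamped iteration.
#' @param steps Optional row indices of the trajectory to use (default all).
#' @param seed Optional integer seed for the per-step noise.
#' @return A list of class `phase_rates`: `rates` (n_ca3 x n_steps matrix),
#'   `bin` (actual bin per step), `dg_mode`, `env`.
#' @export
simulate_phase <- function(net, pop, traj, dg_mode = c("on", "off"),
                           n_iter = 15, damping = 0.3, steps = NULL,
                           seed = NULL) {
  dg_mode <- match.arg(dg_mode)
  if (is.null(steps)) steps <- seq_len(nrow(traj$positions))
  pos <- traj$positions[steps, , drop = FALSE]
  mf <- mf_drive_matrix(net, pop, pos)
  schedule <- if (dg_mode == "on") rep(1, n_iter)
              else c(1, 1 / 3, rep(0, 13))
  runner <- function() {
    cpp_run_phase(mf, net$j_rc, schedule, net$noise_sd,
                  net$target_sparsity, net$target_mean, damping)
  }
  rates <- if (is.null(seed)) runner() else local_seed_eval(seed, runner)
  structure(
    list(rates = rates, bin = traj$bin[steps], dg_mode = dg_mode,
         env = traj$env),
    class = "phase_rates"
  )
}
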