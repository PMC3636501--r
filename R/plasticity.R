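#' Presynaptic activity trace
#'
#' A running trace `Lambda_j` equal to the arithmetic mean of the last
#' `tau` presynaptic rate vectors (the mean of whatever history exists
#' during the first `tau` steps). The trace enters the Hebbian rule as the
#' baseline the presynaptic rate is compared against, so only deviations
#' from recent activity drive weight change.
#'
#' @param n Number of presynaptic units.
#' @param tau Trace window in time steps (default 14, i.e. 1750 ms).
#' @return A `trace_state` object with elements `trace`, `tau`, `history`
#'   (n x tau ring buffer), `count`, `pos`.
#' @export
trace_state <- function(n, tau = 14) {
  structure(
    list(trace = numeric(n), tau = as.integer(tau),
         history = matrix(0, n, tau), count = 0L, pos = 1L),
    class = "trace_state"
  )
}

#' Push a rate vector into the trace
#'
#' Appends `pre_rates` to the history ring buffer and recomputes the trace
#' as the mean of the stored vectors.
#'
#' @param state A [trace_state()].
#' @param pre_rates Presynaptic rate vector.
#' @return The updated `trace_state`.
#' @export
update_trace <- function(state, pre_rates) {
  if (length(pre_rates) != nrow(state$history))
    stop("`pre_rates` has wrong length")
  state$history[, state$pos] <- pre_rates
  state$pos <- (state$pos %% state$tau) + 1L
  state$count <- min(state$count + 1L, state$tau)
  state$trace <- rowSums(state$history[, seq_len(state$count), drop = FALSE],
                         ) / state$count
  state
}

#' One Hebbian weight update
#'
#' Applies the trace-based associative rule to every existing synapse
#' `(i, j)`: `J_ij <- J_ij + gamma * eta_i * (eta_j - Lambda_j)`, where
#' `eta_i` is the postsynaptic and `eta_j` the presynaptic rate. Weights
#' are constrained to be non-negative: any weight driven below zero is
#' reset to zero. Non-synapses (zeros of `conn_rc`) are untouched.
#'
#' @param j_rc Current RC weight matrix (post x pre).
#' @param conn_rc Binary connectivity matrix.
#' @param post_rates,pre_rates Rate vectors.
#' @param trace A [trace_state()] holding `Lambda` (the mean of rates over
#'   the preceding `tau` steps, not including the current one).
#' @param gamma Learning rate (> 0).
#' @return The updated weight matrix.
#' @export
hebbian_step <- function(j_rc, conn_rc, post_rates, pre_rates, trace,
                         gamma) {
  if (gamma <= 0) stop("`gamma` must be > 0")
  if (length(post_rates) != nrow(j_rc) || length(pre_rates) != ncol(j_rc))
    stop("rate vector lengths do not match the weight matrix")
  lam <- if (inherits(trace, "trace_state")) trace$trace else trace
  dj <- gamma * outer(post_rates, pre_rates - lam)
  pmax(j_rc + dj * as.matrix(conn_rc), 0)
}

#' Normalize incoming RC weights
#'
#' Rescales each row (the incoming weights of one postsynaptic unit) to sum
#' to 1. Applied once, at the end of the learning phase.
#'
#' @param j_rc Non-negative weight matrix.
#' @return The row-normalized matrix.
#' @export
normalize_incoming <- function(j_rc) {
  rs <- rowSums(j_rc)
  bad <- which(rs <= 0)
  if (length(bad))
    stop("normalization failure: unit(s) with no positive incoming weight: ",
         paste(utils::head(bad, 10), collapse = ", "))
  j_rc / rs
}

#' Learning-phase configuration
#'
#' @param gamma Learning rate (default 0.01: accumulated increments then
#'   have the same order of magnitude as the initial uniform weight at the
#'   default rate targets; the end-of-phase normalization removes the
#'   overall scale).
#' @param n_steps Length of the learning session in time steps (default
#'   10,000, enough for the walk to cover the environment repeatedly).
#' @param tau Trace window (default 14 steps).
#' @param n_iter Within-step relaxation sweeps (default 15).
#' @param damping Damped-update mixing weight (see [simulate_phase()]).
#' @return A `learning_config` list.
#' @export
learning_config <- function(gamma = 0.01, n_steps = 10000, tau = 14,
                            n_iter = 15, damping = 0.3) {
  if (gamma < 0) stop("`gamma` must be >= 0")
  structure(list(gamma = gamma, n_steps = as.integer(n_steps),
                 tau = as.integer(tau), n_iter = as.integer(n_iter),
                 damping = damping),
            class = "learning_config")
}

#' Run the learning phase
#'
#' Simulates the exploration session during which the RC weights
#' self-organize. At every step the CA3 activity is computed from the DG
#' input with the RC contribution frozen at the uniform initial weight
#' `j_rc0` (plasticity does not feed back within the session); the Hebbian
#' increments accumulate on a separate copy of the weights, clipped at zero
#' each step. At the end the accumulated weights are row-normalized and
#' installed in the returned network.
#'
#' @param net A [ca3_network()] with uniform RC weights.
#' @param pop A `dg_population`.
#' @param traj A trajectory of at least `cfg$n_steps` steps.
#' @param cfg A [learning_config()].
#' @param seed Optional integer seed (noise draws).
#' @return A `ca3_network` with the learned, normalized RC weights.
#' @export
run_learning_phase <- function(net, pop, traj, cfg = learning_config(),
                               seed = NULL) {
  n_steps <- cfg$n_steps
  if (nrow(traj$positions) < n_steps)
    stop("trajectory shorter than the learning phase")
  mf <- mf_drive_matrix(net, pop, traj$positions[seq_len(n_steps), , drop = FALSE])
  j_uniform <- as.matrix(net$conn_rc) * net$j_rc0
  runner <- function() {
    cpp_learning_phase(mf, j_uniform, as.matrix(net$conn_rc),
                       rep(1, cfg$n_iter), net$noise_sd,
                       net$target_sparsity, net$target_mean,
                       cfg$damping, cfg$gamma, cfg$tau)
  }
  w <- if (is.null(seed)) runner() else local_seed_eval(seed, runner)
  ca3_network(net$conn_mf, net$conn_rc, j_mf = net$j_mf, j_rc0 = net$j_rc0,
              j_rc = normalize_incoming(w),
              target_sparsity = net$target_sparsity,
              target_mean = net$target_mean, noise_sd = net$noise_sd)
}

# Dense MF drive matrix (n_ca3 x n_steps) restricted to the active DG cells.
mf_drive_matrix <- function(net, pop, positions) {
  if (length(pop$active) == 0)
    return(matrix(0, net$n_ca3, nrow(positions)))
  beta <- dg_rates_active(pop, positions)
  w <- as.matrix(net$conn_mf[, pop$active, drop = FALSE])
  net$j_mf * (w %*% beta)
}
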