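#' Sample random binary connectivity
#'
#' Entries are i.i.d. Bernoulli with `P(1) = c / n_pre`, giving an expected
#' in-degree of `c` per postsynaptic unit. For recurrent matrices the
#' diagonal (self-connections) can be forced to zero.
#'
#' @param n_pre,n_post Numbers of pre- and postsynaptic units.
#' @param c Expected in-degree (`0 < c <= n_pre`).
#' @param exclude_self If `TRUE`, zero the diagonal (requires
#'   `n_pre == n_post`).
#' @param seed Optional integer seed.
#' @return A sparse binary `n_post x n_pre` matrix (`Matrix::dgCMatrix`).
#' @export
sample_connectivity <- function(n_pre, n_post, c, exclude_self = FALSE,
                                seed = NULL) {
  if (c <= 0 || c > n_pre) stop("`c` must satisfy 0 < c <= n_pre")
  if (exclude_self && n_pre != n_post)
    stop("`exclude_self` requires a square matrix")
  p <- c / n_pre
  draw <- function() {
    m <- Matrix::Matrix(stats::rbinom(n_post * n_pre, 1L, p), n_post, n_pre,
                        sparse = TRUE)
    if (exclude_self) diag(m) <- 0
    Matrix::drop0(m)
  }
  if (is.null(seed)) draw() else local_seed_eval(seed, draw)
}

#' Population sparsity
#'
#' The sparsity of a rate vector is `a = <eta>^2 / <eta^2>`, the effective
#' fraction of units active: 1 for a uniform positive vector, `1/N` for a
#' one-hot vector.
#'
#' @param rates Non-negative rate vector with at least one positive entry.
#' @return The sparsity, in `(0, 1]`.
#' @examples
#' sparsity(c(1, 1, 0, 0)) # 0.5
#' @export
sparsity <- function(rates) {
  s2 <- mean(rates^2)
  if (s2 <= 0) stop("sparsity undefined: all rates are zero")
  mean(rates)^2 / s2
}

#' Set threshold and gain to meet sparsity and mean-rate targets
#'
#' Models the tight inhibitory control of CA3: the activation threshold `T`
#' is adjusted so that the rectified rates `[g (drive - T)]_+` have the
#' target population sparsity, and the gain `g` is then set in closed form
#' so their mean equals `target_mean`. Sparsity does not depend on `g`, so
#' `T` is solved first, by bisection on `[min(drive) - range, max(drive)]`.
#'
#' @param drive Total input drive per unit (must not be flat).
#' @param target_sparsity Sparsity target (default 0.1).
#' @param target_mean Mean-rate target (default 0.1).
#' @param tol Absolute tolerance on the achieved sparsity.
#' @return A list with `T`, `g`, `rates`, `sparsity` and `mean_rate`.
#' @export
adjust_threshold_gain <- function(drive, target_sparsity = 0.1,
                                  target_mean = 0.1, tol = 1e-3) {
  rng <- range(drive)
  if (diff(rng) < 1e-12)
    stop("sparsity control failure: flat drive (all inputs equal, drive = ",
         signif(rng[1], 4), ")")
  f <- function(T) {
    r <- pmax(drive - T, 0)
    if (all(r == 0)) return(1 / length(drive) - target_sparsity)
    sparsity(r) - target_sparsity
  }
  lo <- rng[1] - diff(rng)
  hi <- rng[2]
  # sparsity decreases from ~1 (T << min) towards 1/N (T -> max)
  if (f(lo) < 0) {
    # even with all units active the sparsity is below target
    if (target_sparsity >= 1 - 1e-12) {
      T <- lo
    } else {
      stop("sparsity control failure: target ", target_sparsity,
           " unattainable (max achievable ", signif(f(lo) + target_sparsity, 4), ")")
    }
  } else {
    if (f(hi) > 0)
      stop("sparsity control failure: target ", target_sparsity,
           " below the 1/N floor")
    T <- stats::uniroot(f, c(lo, hi), tol = min(tol, 1e-9) * max(1, diff(rng)))$root
  }
  r0 <- pmax(drive - T, 0)
  if (all(r0 == 0)) stop("sparsity control failure: no unit above threshold")
  g <- target_mean / mean(r0)
  rates <- g * r0
  list(T = T, g = g, rates = rates, sparsity = sparsity(rates),
       mean_rate = mean(rates))
}

#' Construct a CA3 network
#'
#' A population of `n_ca3` threshold-linear units receiving mossy-fibre (MF)
#' input from a DG population and recurrent-collateral (RC) input from each
#' other. The firing rate of unit i solves
#' `eta_i = g [ sum_j c^MF_ij J^MF beta_j + sum_k c^RC_ik J^RC_ik eta_k
#' + delta_i - T ]_+`, with the threshold `T` and gain `g` continuously
#' re-adjusted to hold the population sparsity and mean rate at their
#' targets (0.1 each by default).
#'
#' @param conn_mf Binary MF connectivity (`n_ca3 x n_dg`), e.g. from
#'   [sample_connectivity()].
#' @param conn_rc Binary RC connectivity (`n_ca3 x n_ca3`, zero diagonal).
#' @param j_mf Uniform MF weight; defaults to `1 / C_MF` (the mean in-degree
#'   inferred from `conn_mf`), making the MF drive an average of connected
#'   granule-cell rates. Only the ratio of the MF to the RC drive matters
#'   (the gain control removes the overall scale); the experiment pipeline
#'   sets `j_mf = target_mean / (C_MF * dg_mean_rate(pop))` so the mean MF
#'   drive matches the mean normalized RC drive — see [run_experiment()].
#' @param j_rc0 Initial uniform RC weight; defaults to `1 / C_RC`.
#' @param j_rc Optional full RC weight matrix (dense, non-negative, zero off
#'   the synapses of `conn_rc`); defaults to the uniform `j_rc0` matrix.
#' @param target_sparsity,target_mean Activity targets (defaults 0.1).
#' @param noise_sd SD of the fast noise `delta_i`, redrawn each time step
#'   (default 0.002).
#' @return An object of class `ca3_network`.
#' @export
ca3_network <- function(conn_mf, conn_rc, j_mf = NULL, j_rc0 = NULL,
                        j_rc = NULL, target_sparsity = 0.1,
                        target_mean = 0.1, noise_sd = 0.002) {
  n_ca3 <- nrow(conn_mf)
  if (nrow(conn_rc) != n_ca3 || ncol(conn_rc) != n_ca3)
    stop("`conn_rc` must be n_ca3 x n_ca3")
  c_mf <- sum(conn_mf) / n_ca3
  c_rc <- sum(conn_rc) / n_ca3
  if (is.null(j_mf)) j_mf <- 1 / max(c_mf, 1)
  if (is.null(j_rc0)) j_rc0 <- 1 / max(c_rc, 1)
  if (is.null(j_rc)) j_rc <- as.matrix(conn_rc) * j_rc0
  j_rc <- as.matrix(j_rc)
  if (any(j_rc < 0)) stop("RC weights must be non-negative")
  structure(
    list(conn_mf = conn_mf, conn_rc = conn_rc, n_ca3 = n_ca3,
         n_dg = ncol(conn_mf), c_mf = c_mf, c_rc = c_rc,
         j_mf = j_mf, j_rc0 = j_rc0, j_rc = j_rc,
         target_sparsity = target_sparsity, target_mean = target_mean,
         noise_sd = noise_sd),
    class = "ca3_network"
  )
}

#' @export
print.ca3_network <- function(x, ...) {
  cat(sprintf("CA3 network: %d units, %d DG inputs, C_MF ~ %.1f, C_RC ~ %.1f, targets a = %.3g, <eta> = %.3g\n",
              x$n_ca3, x$n_dg, x$c_mf, x$c_rc, x$target_sparsity,
              x$target_mean))
  invisible(x)
}

# MF drive for a full-length DG rate vector
mf_drive_vector <- function(net, dg_vector) {
  as.numeric(net$conn_mf %*% dg_vector) * net$j_mf
}

#' CA3 activity at one position
#'
#' Solves the implicit threshold-linear rate equation by synchronous
#' iteration: each sweep recomputes the total drive (scaled MF input plus
#' RC feedback plus noise), then re-adjusts the threshold and gain so that
#' the rectified rates meet the sparsity and mean-rate targets. With
#' `control = FALSE` the fixed `T` and `g` supplied are used instead (linear
#' regime testing).
#'
#' @param net A [ca3_network()].
#' @param dg_vector Full DG rate vector (length `n_dg`).
#' @param dg_scale Multiplier on the MF drive: 1 (DG on), 1/3, or 0 (DG off).
#' @param prev_rates Starting rates for the iteration (default zeros).
#' @param n_iter Number of synchronous sweeps (default 15).
#' @param damping Mixing weight of the previous state in each damped sweep,
#'   `eta <- (1 - damping) * F(eta) + damping * eta` (default 0.3; 0 gives
#'   the undamped iteration). Damping does not move the fixed points but
#'   suppresses period-2 cycling of the synchronous update.
#' @param noise_sd Fast-noise SD; drawn once per call (one time step) and
#'   held fixed across the sweeps. Defaults to `net$noise_sd`.
#' @param control Re-adjust `T`, `g` every sweep (default `TRUE`).
#' @param T,g Fixed threshold/gain used when `control = FALSE`.
#' @param seed Optional integer seed for the noise draw.
#' @return A list (`ActivityState`): `rates`, `sparsity` (NA if all rates
#'   zero), `mean_rate`, `T`, `g`.
#' @export
ca3_activity <- function(net, dg_vector, dg_scale = 1, prev_rates = NULL,
                         n_iter = 15, damping = 0.3,
                         noise_sd = net$noise_sd,
                         control = TRUE, T = 0, g = 1, seed = NULL) {
  if (length(dg_vector) != net$n_dg) stop("`dg_vector` has wrong length")
  if (n_iter < 1) stop("`n_iter` must be >= 1")
  mf <- mf_drive_vector(net, dg_vector) * dg_scale
  eta <- if (is.null(prev_rates)) numeric(net$n_ca3) else prev_rates
  if (length(eta) != net$n_ca3) stop("`prev_rates` has wrong length")
  draw_noise <- function() {
    if (noise_sd > 0) stats::rnorm(net$n_ca3, 0, noise_sd)
    else numeric(net$n_ca3)
  }
  noise <- if (is.null(seed)) draw_noise() else local_seed_eval(seed, draw_noise)
  Tv <- T; gv <- g
  for (k in seq_len(n_iter)) {
    drive <- mf + as.numeric(net$j_rc %*% eta) + noise
    if (control) {
      ctl <- adjust_threshold_gain(drive, net$target_sparsity,
                                   net$target_mean)
      fresh <- ctl$rates; Tv <- ctl$T; gv <- ctl$g
    } else {
      fresh <- gv * pmax(drive - Tv, 0)
    }
    eta <- (1 - damping) * fresh + damping * eta
  }
  a <- if (all(eta == 0)) NA_real_ else sparsity(eta)
  list(rates = eta, sparsity = a, mean_rate = mean(eta), T = Tv, g = gv)
}

#' Write network state as delimited text
#'
#' Writes a directory of CSV files describing the network: `params.csv`
#' (scalar parameters), `conn_mf.csv` / `conn_rc.csv` (synapse lists) and
#' `j_rc.csv` (nonzero RC weights as post, pre, weight).
#'
#' @param net A [ca3_network()].
#' @param dir Output directory (created if missing).
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(n_ca3 = net$n_ca3, n_dg = net$n_dg, j_mf = net$j_mf,
               j_rc0 = net$j_rc0, target_sparsity = net$target_sparsity,
               target_mean = net$target_mean, noise_sd = net$noise_sd),
    file.path(dir, "params.csv"), row.names = FALSE)
  edge_df <- function(m) {
    idx <- Matrix::which(m != 0, arr.ind = TRUE)
    data.frame(post = idx[, 1], pre = idx[, 2])
  }
  utils::write.csv(edge_df(net$conn_mf), file.path(dir, "conn_mf.csv"),
                   row.names = FALSE)
  utils::write.csv(edge_df(net$conn_rc), file.path(dir, "conn_rc.csv"),
                   row.names = FALSE)
  write_weights(net$j_rc, file.path(dir, "j_rc.csv"))
  invisible(dir)
}

#' Write an RC weight matrix as delimited text
#'
#' One CSV row per nonzero synapse: `post`, `pre`, `weight`.
#'
#' @param j_rc Weight matrix.
#' @param path Output file path.
#' @export
write_weights <- function(j_rc, path) {
  idx <- which(j_rc != 0, arr.ind = TRUE)
  utils::write.csv(
    data.frame(post = idx[, 1], pre = idx[, 2], weight = j_rc[idx]),
    path, row.names = FALSE)
  invisible(path)
}
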