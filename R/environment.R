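#' Periodic square environment
#'
#' Defines the arena the virtual rat explores: a square of side `side` metres
#' with periodic boundary conditions (a torus), discretized at analysis time
#' into an `L x L` grid of square bins. With the defaults (`side = 1`,
#' `L = 8`) the arena is 1 m^2 and each bin is 12.5 cm on a side.
#'
#' @param side Side length of the square, in metres (> 0).
#' @param L Number of bins per side (>= 2). The total number of spatial bins
#'   is `S = L^2`.
#' @return An object of class `torus_environment` with elements `side`, `L`,
#'   `S` and `bin_size`.
#' @examples
#' env <- torus_environment()
#' env$S # 64
#' @export
torus_environment <- function(side = 1, L = 8) {
  if (!is.numeric(side) || length(side) != 1 || side <= 0)
    stop("`side` must be a positive number")
  if (!is.numeric(L) || length(L) != 1 || L < 2 || L != round(L))
    stop("`L` must be an integer >= 2")
  structure(
    list(side = side, L = as.integer(L), S = as.integer(L)^2L,
         bin_size = side / L),
    class = "torus_environment"
  )
}

#' @export
print.torus_environment <- function(x, ...) {
  cat(sprintf("Torus environment: %.3g m x %.3g m, %d x %d bins (%.3g m each)\n",
              x$side, x$side, x$L, x$L, x$bin_size))
  invisible(x)
}

wrap_position <- function(p, env) p %% env$side

#' Minimum-image displacement on the torus
#'
#' Returns the displacement `p2 - p1` using the minimum-image convention,
#' i.e. the shortest of the displacement vectors among all periodic images.
#' Each component lies in `[-side/2, side/2)`.
#'
#' @param p1,p2 Positions: length-2 vectors or n x 2 matrices (recycled
#'   row-wise against each other).
#' @param env A [torus_environment()].
#' @return A vector (or n x 2 matrix) of displacements.
#' @examples
#' env <- torus_environment()
#' torus_displacement(c(0.95, 0), c(0.05, 0), env) # c(0.10, 0)
#' @export
torus_displacement <- function(p1, p2, env) {
  d <- (rbind(p2) - rbind(p1)) %% env$side
  d <- ((d + env$side / 2) %% env$side) - env$side / 2
  if (is.vector(p1) && is.vector(p2)) drop(d) else d
}

torus_distance <- function(p1, p2, env) {
  d <- torus_displacement(p1, p2, env)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' Spatial bin of a position
#'
#' Maps positions to 1-based row-major bin indices on the `L x L` grid.
#' Bins are half-open: bin rows/columns cover `[k*side/L, (k+1)*side/L)`.
#' Row index is taken from the y coordinate, column from x, so
#' `bin = row * L + col + 1` with 0-based row/col.
#'
#' @param p A length-2 position or an n x 2 matrix of positions. Coordinates
#'   are wrapped onto `[0, side)` first, so any periodic image maps to the
#'   same bin.
#' @param env A [torus_environment()].
#' @return Integer bin indices in `1..S`.
#' @export
bin_index <- function(p, env) {
  p <- rbind(p)
  p <- wrap_position(p, env)
  cx <- pmin(floor(p[, 1] / env$bin_size), env$L - 1)
  cy <- pmin(floor(p[, 2] / env$bin_size), env$L - 1)
  as.integer(cy * env$L + cx + 1)
}

#' Row/column coordinates of bins
#'
#' Inverse bookkeeping for [bin_index()]: 0-based (col, row) grid coordinates
#' of each 1-based bin index.
#'
#' @param bins Integer bin indices in `1..S`.
#' @param env A [torus_environment()].
#' @return A matrix with columns `col`, `row` (0-based).
#' @export
bin_coords <- function(bins, env) {
  b0 <- as.integer(bins) - 1L
  cbind(col = b0 %% env$L, row = b0 %/% env$L)
}

#' Bin-level torus displacement
#'
#' Displacement (in bin units) from bin `from` to bin `to` on the L x L
#' grid torus, each component mapped to `[-L/2, L/2)`.
#'
#' @param from,to Integer bin indices (recycled against each other).
#' @param env A [torus_environment()].
#' @return A matrix with columns `dc`, `dr`.
#' @export
bin_displacement <- function(from, to, env) {
  L <- env$L
  a <- bin_coords(from, env)
  b <- bin_coords(to, env)
  d <- (b - a) %% L
  d <- ((d + L %/% 2) %% L) - L %/% 2
  colnames(d) <- c("dc", "dr")
  d
}

#' Generate a persistent random-walk trajectory
#'
#' The virtual rat advances a fixed distance each time step (one theta
#' period, 125 ms) in a direction similar to that of the previous step:
#' the heading performs a Gaussian random walk with per-step standard
#' deviation `heading_noise_sd`. Positions are wrapped on the torus.
#' With the defaults the rat moves 2.5 cm per 125 ms step, i.e. 20 cm/s.
#'
#' @param env A [torus_environment()].
#' @param n_steps Number of steps (>= 1). The returned trajectory holds the
#'   position after each step; the starting position is not included.
#' @param step_length Distance moved per step, metres (must be positive and
#'   smaller than `env$side`).
#' @param heading_noise_sd Standard deviation of the per-step Gaussian
#'   heading increment, radians.
#' @param dt Step duration in seconds (bookkeeping only).
#' @param start Starting position (wrapped onto the torus). Default `c(0, 0)`.
#' @param heading0 Initial heading in radians.
#' @param seed Optional integer seed; when supplied the walk is reproducible
#'   and the caller's RNG state is untouched.
#' @return An object of class `trajectory`: a list with `positions`
#'   (n_steps x 2 matrix), `headings`, `bin` (bin index per step),
#'   `step_length`, `dt` and `env`.
#' @examples
#' env <- torus_environment()
#' traj <- generate_trajectory(env, 1000, seed = 1)
#' table(traj$bin)[1:4]
#' @export
generate_trajectory <- function(env, n_steps, step_length = 0.025,
                                heading_noise_sd = 0.35, dt = 0.125,
                                start = c(0, 0), heading0 = 0, seed = NULL) {
  if (!is.numeric(n_steps) || n_steps < 1)
    stop("`n_steps` must be a positive integer")
  if (!is.numeric(step_length) || step_length <= 0 || step_length >= env$side)
    stop("`step_length` must be positive and smaller than the side")
  if (heading_noise_sd < 0) stop("`heading_noise_sd` must be >= 0")
  n_steps <- as.integer(n_steps)
  run <- function() {
    eps <- if (heading_noise_sd > 0) stats::rnorm(n_steps, 0, heading_noise_sd)
           else numeric(n_steps)
    headings <- heading0 + cumsum(eps)
    dx <- step_length * cos(headings)
    dy <- step_length * sin(headings)
    pos <- cbind(start[1] + cumsum(dx), start[2] + cumsum(dy)) %% env$side
    list(headings = headings, positions = pos)
  }
  w <- if (is.null(seed)) run() else local_seed_eval(seed, run)
  structure(
    list(positions = w$positions, headings = w$headings,
         bin = bin_index(w$positions, env),
         step_length = step_length, dt = dt, env = env),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("Trajectory: %d steps of %.3g m (dt = %.3g s), %d/%d bins visited\n",
              n, x$step_length, x$dt, length(unique(x$bin)), x$env$S))
  invisible(x)
}

#' Write a trajectory as delimited text
#'
#' Columns `t`, `x`, `y`, `heading`, `bin`, one row per step.
#'
#' @param traj A [generate_trajectory()] result.
#' @param path Output file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = seq_len(nrow(traj$positions)),
                   x = traj$positions[, 1], y = traj$positions[, 2],
                   heading = traj$headings, bin = traj$bin)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Evaluate `fn()` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
local_seed_eval <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}
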