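#' Construct a dentate-gyrus population from explicit fields
#'
#' Low-level constructor used by [sample_dg_population()] and by tests that
#' need hand-placed fields. Each active granule cell carries `Q >= 0`
#' Gaussian firing fields, all with the same peak rate `beta0` and width
#' `sigma_f`; its rate at position x is the sum of its field Gaussians
#' evaluated with torus (minimum-image) displacements. Inactive cells are
#' silent everywhere.
#'
#' @param fields A data frame (or matrix) with columns `cell`, `x`, `y`:
#'   one row per field. `cell` indexes into `1..n_dg`. Cells listed here are
#'   the active ones; active cells with zero fields can be declared through
#'   `active`.
#' @param n_dg Total number of granule cells.
#' @param active Optional integer vector of active cell ids (defaults to the
#'   cells appearing in `fields`). Active cells without fields fire 0
#'   everywhere but count as active.
#' @param beta0 Peak rate of a single field (arbitrary rate units).
#' @param sigma_f Field width (Gaussian SD), metres.
#' @param env A [torus_environment()].
#' @return An object of class `dg_population`.
#' @export
dg_population <- function(fields, n_dg, active = NULL, beta0 = 1,
                          sigma_f = 0.1, env = torus_environment()) {
  fields <- as.data.frame(fields)
  if (nrow(fields) > 0 &&
      !all(c("cell", "x", "y") %in% names(fields)))
    stop("`fields` needs columns cell, x, y")
  if (is.null(active)) active <- sort(unique(as.integer(fields$cell)))
  if (length(active) && (min(active) < 1 || max(active) > n_dg))
    stop("active cell ids outside 1..n_dg")
  structure(
    list(fields = fields, n_dg = as.integer(n_dg),
         active = as.integer(active),
         beta0 = beta0, sigma_f = sigma_f, env = env),
    class = "dg_population"
  )
}

#' Sample a random dentate-gyrus population
#'
#' Granule cells are independently active with probability `p_dg` (population
#' activity in any one environment is sparse). Each active cell receives a
#' Poisson(`q`) number of firing fields, centred uniformly on the torus; all
#' fields share the same peak rate `beta0` and width `sigma_f`.
#'
#' @param n_dg Number of granule cells (>= 1).
#' @param q Mean field multiplicity of active cells (> 0).
#' @param p_dg Probability that a cell is active in this environment
#'   (`0 <= p_dg <= 1`; the model regime is `p_dg << 1`, default 0.033).
#' @param beta0 Peak field rate.
#' @param sigma_f Field width (m).
#' @param env A [torus_environment()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `dg_population` object.
#' @examples
#' pop <- sample_dg_population(1000, seed = 1)
#' length(pop$active) / pop$n_dg # ~ 0.033
#' @export
sample_dg_population <- function(n_dg, q = 1.7, p_dg = 0.033, beta0 = 1,
                                 sigma_f = 0.1, env = torus_environment(),
                                 seed = NULL) {
  if (n_dg < 1) stop("`n_dg` must be >= 1")
  if (p_dg < 0 || p_dg > 1) stop("`p_dg` must be in [0, 1]")
  if (q <= 0) stop("`q` must be > 0")
  if (beta0 <= 0 || sigma_f <= 0) stop("`beta0` and `sigma_f` must be > 0")
  draw <- function() {
    active <- which(stats::runif(n_dg) < p_dg)
    Q <- stats::rpois(length(active), q)
    cell <- rep(active, Q)
    nf <- length(cell)
    list(fields = data.frame(cell = cell,
                             x = stats::runif(nf, 0, env$side),
                             y = stats::runif(nf, 0, env$side)),
         active = active)
  }
  d <- if (is.null(seed)) draw() else local_seed_eval(seed, draw)
  dg_population(d$fields, n_dg = n_dg, active = d$active,
                beta0 = beta0, sigma_f = sigma_f, env = env)
}

#' @export
print.dg_population <- function(x, ...) {
  cat(sprintf("DG population: %d cells, %d active (%.3f), %d fields, beta0 = %.3g, sigma_f = %.3g m\n",
              x$n_dg, length(x$active), length(x$active) / x$n_dg,
              nrow(x$fields), x$beta0, x$sigma_f))
  invisible(x)
}

#' DG firing-rate vector at a position
#'
#' Evaluates every granule cell's rate at position `p`: the sum over the
#' cell's fields of `beta0 * exp(-||d||^2 / (2 sigma_f^2))`, where `d` is the
#' minimum-image displacement from `p` to the field centre. Inactive cells
#' return 0.
#'
#' @param pop A `dg_population`.
#' @param p A length-2 position.
#' @param env Environment (defaults to the one stored in `pop`).
#' @return A numeric vector of length `pop$n_dg`.
#' @export
dg_rates <- function(pop, p, env = pop$env) {
  rates <- numeric(pop$n_dg)
  if (nrow(pop$fields) == 0) return(rates)
  d <- torus_displacement(matrix(p, nrow(pop$fields), 2, byrow = TRUE),
                          cbind(pop$fields$x, pop$fields$y), env)
  g <- pop$beta0 * exp(-rowSums(rbind(d)^2) / (2 * pop$sigma_f^2))
  v <- tapply(g, pop$fields$cell, sum)
  rates[as.integer(names(v))] <- v
  rates
}

#' Spatial mean rate of a DG population
#'
#' The mean granule-cell rate over the torus and the population:
#' each field contributes `beta0 * 2 * pi * sigma_f^2 / A` (the Gaussian
#' integral; minimum-image truncation is negligible for `sigma_f <= side/6`),
#' so the population mean is `n_fields * beta0 * 2 * pi * sigma_f^2 /
#' (A * n_dg)`. Used to balance the mossy-fibre weight against the
#' recurrent drive.
#'
#' @param pop A `dg_population`.
#' @return The expected mean rate (scalar).
#' @export
dg_mean_rate <- function(pop) {
  nrow(pop$fields) * pop$beta0 * 2 * pi * pop$sigma_f^2 /
    (pop$env$side^2 * pop$n_dg)
}

# Rates of the *active* cells at every trajectory position.
# Returns a matrix n_active x n_steps (rows ordered as pop$active).
# Only the active cells ever drive CA3, so phase drivers work in this
# reduced basis.
dg_rates_active <- function(pop, positions, env = pop$env) {
  n_steps <- nrow(positions)
  out <- matrix(0, length(pop$active), n_steps)
  if (nrow(pop$fields) == 0) return(out)
  row_of <- match(pop$fields$cell, pop$active)
  half <- env$side / 2
  inv2s2 <- 1 / (2 * pop$sigma_f^2)
  px <- positions[, 1]; py <- positions[, 2]
  for (f in seq_len(nrow(pop$fields))) {
    dx <- abs(px - pop$fields$x[f]); dx <- pmin(dx, env$side - dx)
    dy <- abs(py - pop$fields$y[f]); dy <- pmin(dy, env$side - dy)
    out[row_of[f], ] <- out[row_of[f], ] +
      pop$beta0 * exp(-(dx^2 + dy^2) * inv2s2)
  }
  out
}

#' Write a DG population as delimited text
#'
#' A header of population parameters (as `#`-prefixed comment lines)
#' followed by one CSV row per field (`cell`, `x`, `y`).
#'
#' @param pop A `dg_population`.
#' @param path Output file path.
#' @export
write_dg_population <- function(pop, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_dg=%d beta0=%g sigma_f=%g n_active=%d side=%g",
                     pop$n_dg, pop$beta0, pop$sigma_f, length(pop$active),
                     pop$env$side), con)
  writeLines(paste0("# active=", paste(pop$active, collapse = ",")), con)
  utils::write.csv(pop$fields, con, row.names = FALSE)
  invisible(path)
}
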