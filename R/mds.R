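#' Correlation distance matrix between templates
#'
#' Builds the similarity structure of the spatial representation: the
#' distance between two bins is `1 - r`, the Pearson correlation between
#' their full-population template vectors, clipped at 0.
#'
#' @param templates A `template_set` (ideally full-population) or a plain
#'   S x n matrix with one template per row.
#' @param transform `"one_minus_r"` (default) for `1 - r`, or `"sqrt"` for
#'   the chordal form `sqrt(2 (1 - r))`, which de-emphasizes very small
#'   distances in stress-based embeddings.
#' @return An S x S symmetric distance matrix with zero diagonal.
#' @export
correlation_distance_matrix <- function(templates,
                                        transform = c("one_minus_r",
                                                      "sqrt")) {
  transform <- match.arg(transform)
  tm <- if (inherits(templates, "template_set")) templates$templates
        else as.matrix(templates)
  if (nrow(tm) < 3) stop("need at least 3 template rows")
  v <- apply(tm, 1, stats::sd)
  if (any(v == 0))
    stop("degenerate template(s) with zero variance: ",
         paste(which(v == 0), collapse = ", "))
  d <- 1 - stats::cor(t(tm))
  d[d < 0] <- 0
  if (transform == "sqrt") d <- sqrt(2 * d)
  diag(d) <- 0
  d
}

#' Sammon stress of an embedding
#'
#' `E = (1 / sum_{i<j} D_ij) * sum_{i<j} (D_ij - dhat_ij)^2 / D_ij`, where
#' `dhat` is the Euclidean distance between the embedded coordinates.
#'
#' @param coords An S x k coordinate matrix.
#' @param D The original S x S distance matrix.
#' @return The stress value (>= 0).
#' @export
sammon_stress <- function(coords, D) {
  D <- as.matrix(D)
  if (nrow(coords) != nrow(D)) stop("shape mismatch")
  dhat <- as.matrix(stats::dist(coords))
  iu <- upper.tri(D)
  sum((D[iu] - dhat[iu])^2 / D[iu]) / sum(D[iu])
}

#' Sammon mapping of a distance matrix
#'
#' Metric multidimensional scaling under the Sammon criterion: iterative
#' minimization of [sammon_stress()], initialized from classical MDS
#' (`stats::cmdscale`). The optimization (MASS::sammon) is deterministic
#' given the distance matrix.
#'
#' @param D A symmetric distance matrix with zero diagonal and positive
#'   off-diagonal entries.
#' @param dim Embedding dimension (default 3).
#' @param n_iter Maximum number of iterations (default 500).
#' @param tol Convergence tolerance on the stress.
#' @return A list of class `sammon_embedding`: `coords` (S x dim), `stress`.
#' @export
sammon_map <- function(D, dim = 3, n_iter = 500, tol = 1e-9) {
  D <- as.matrix(D)
  if (any(D[upper.tri(D)] <= 0))
    stop("off-diagonal distances must be positive for the Sammon criterion")
  init <- stats::cmdscale(D, k = dim)
  if (ncol(init) < dim) {
    # degenerate classical solution; pad with tiny jitter-free columns
    init <- cbind(init, matrix(1e-8, nrow(D), dim - ncol(init)))
  }
  fit <- MASS::sammon(stats::as.dist(D), y = init, k = dim, niter = n_iter,
                      tol = tol, trace = FALSE)
  if (!is.finite(fit$stress)) stop("Sammon optimization failed: non-finite stress")
  structure(list(coords = fit$points, stress = fit$stress),
            class = "sammon_embedding")
}

#' @export
print.sammon_embedding <- function(x, ...) {
  cat(sprintf("Sammon embedding: %d points in %d-D, stress = %.4f\n",
              nrow(x$coords), ncol(x$coords), x$stress))
  invisible(x)
}

#' Torus-adjacency summary of an embedding
#'
#' Checks whether the embedding preserves the grid structure on average:
#' compares the mean embedded distance between bins that are axis
#' neighbours on the torus against the mean distance between maximally
#' separated bins (displacement (L/2, L/2)).
#'
#' @param emb A `sammon_embedding` of the S = L^2 bin templates (row-major
#'   bin order).
#' @param env The [torus_environment()].
#' @return A list with `mean_adjacent`, `mean_far` and `ratio`.
#' @export
embedding_adjacency <- function(emb, env) {
  S <- env$S
  L <- env$L
  dhat <- as.matrix(stats::dist(emb$coords))
  adj <- far <- c()
  half <- L %/% 2
  for (s in seq_len(S)) {
    nb <- bin_neighbors(s, env)
    adj <- c(adj, dhat[s, nb])
    d <- bin_displacement(rep(s, S), seq_len(S), env)
    opp <- which(d[, "dc"] == -half & d[, "dr"] == -half)
    far <- c(far, dhat[s, opp])
  }
  list(mean_adjacent = mean(adj), mean_far = mean(far),
       ratio = mean(adj) / mean(far))
}

#' Write an embedding as delimited text
#'
#' One CSV row per bin: `bin`, `row`, `col`, and the embedded coordinates.
#' The `row`/`col` grid coordinates provide the connectivity metadata for
#' drawing the two orthogonal families of grid lines.
#'
#' @param emb A `sammon_embedding`.
#' @param env The [torus_environment()].
#' @param path Output file path.
#' @export
write_embedding <- function(emb, env, path) {
  S <- nrow(emb$coords)
  rc <- bin_coords(seq_len(S), env)
  df <- data.frame(bin = seq_len(S), row = rc[, "row"], col = rc[, "col"],
                   emb$coords)
  names(df)[-(1:3)] <- paste0("dim", seq_len(ncol(emb$coords)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
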