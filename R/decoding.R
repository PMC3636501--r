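#' Build per-bin activity templates
#'
#' The template of a spatial bin is the mean population vector over all the
#' time steps the rat spent in that bin during the training run. Templates
#' are the reference vectors the decoder compares test activity against.
#'
#' @param phase A `phase_rates` object from [simulate_phase()] (the training
#'   run), or a plain rate matrix together with `bins`.
#' @param sample Unit ids to keep (default: the full population).
#' @param bins Actual bin per step (taken from `phase` when omitted).
#' @param env A [torus_environment()] (taken from `phase` when omitted).
#' @return An object of class `template_set`: `templates` (S x n matrix,
#'   rows = bins), `sample`, `occupancy` (visits per bin), `env`, `dg_mode`.
#' @export
build_templates <- function(phase, sample = NULL, bins = NULL, env = NULL) {
  if (inherits(phase, "phase_rates")) {
    rates <- phase$rates
    if (is.null(bins)) bins <- phase$bin
    if (is.null(env)) env <- phase$env
    dg_mode <- phase$dg_mode
  } else {
    rates <- phase
    dg_mode <- NA_character_
  }
  if (is.null(bins) || is.null(env))
    stop("`bins` and `env` are required with a raw rate matrix")
  if (is.null(sample)) sample <- seq_len(nrow(rates))
  if (length(sample) == 0 || any(sample < 1) || any(sample > nrow(rates)))
    stop("invalid unit sample")
  S <- env$S
  occ <- tabulate(bins, S)
  if (any(occ == 0))
    stop("incomplete coverage: unvisited bin(s) ",
         paste(which(occ == 0), collapse = ", "))
  # per-bin means: indicator (steps x S) cross rates
  sub <- rates[sample, , drop = FALSE]
  sums <- matrix(0, S, length(sample))
  for (b in seq_len(S)) {
    idx <- which(bins == b)
    sums[b, ] <- rowSums(sub[, idx, drop = FALSE])
  }
  structure(
    list(templates = sums / occ, sample = as.integer(sample),
         occupancy = occ, env = env, dg_mode = dg_mode),
    class = "template_set"
  )
}

#' Subset a template set to a unit sample
#'
#' Templates are per-unit means, so the template set of a sample is the
#' corresponding column subset of the full-population template set.
#'
#' @param tset A full-population `template_set`.
#' @param sample Unit ids (indices into the original population).
#' @return A `template_set` restricted to `sample`.
#' @export
subset_templates <- function(tset, sample) {
  cols <- match(sample, tset$sample)
  if (anyNA(cols)) stop("sample units not present in the template set")
  out <- tset
  out$templates <- tset$templates[, cols, drop = FALSE]
  out$sample <- as.integer(sample)
  out
}

#' Decode one population vector
#'
#' Maximum-likelihood Euclidean decoding: the decoded bin is the one whose
#' template has the smallest Euclidean distance to the observed vector.
#' Ties break deterministically to the lowest bin id.
#'
#' @param rates_sample Observed rate vector for the sampled units.
#' @param templates A `template_set` for the same sample.
#' @return The decoded bin id.
#' @export
decode_step <- function(rates_sample, templates) {
  tm <- templates$templates
  if (length(rates_sample) != ncol(tm))
    stop("vector length does not match the template sample")
  d2 <- rowSums(sweep(tm, 2, rates_sample)^2)
  which.min(d2) # which.min takes the first (lowest id) on ties
}

# Decode every column of a rate matrix (n_units x n_steps) against the
# template rows. Returns the decoded bin per step.
decode_population <- function(rates, templates) {
  tm <- templates$templates
  if (nrow(rates) != ncol(tm)) stop("rate matrix does not match templates")
  g <- tm %*% rates                      # S x n_steps
  scores <- 2 * g - rowSums(tm^2)        # argmax = argmin distance^2
  max.col(t(scores), ties.method = "first")
}

#' Assemble a spatial confusion matrix
#'
#' Counts decoding events by (actual bin, decoded bin).
#'
#' @param actual,decoded Integer bin vectors of equal length.
#' @param env A [torus_environment()].
#' @param meta Optional named list of metadata (sample size, dg_mode, ...).
#' @return An object of class `confusion_matrix`: `counts` (S x S integer
#'   matrix, rows = actual), `S`, `L`, `n_events`, `meta`. Row-normalized
#'   probabilities and the empirical prior are derived on demand by the
#'   internal helper `row_probabilities()`.
#' @export
confusion_matrix <- function(actual, decoded, env, meta = list()) {
  S <- env$S
  if (length(actual) != length(decoded)) stop("length mismatch")
  counts <- matrix(tabulate(actual + S * (decoded - 1L), S * S), S, S)
  structure(
    list(counts = counts, S = S, L = env$L,
         n_events = length(actual), meta = meta),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix: %d x %d, %d events, percent correct %.3f\n",
              x$S, x$S, x$n_events, percent_correct(x)))
  invisible(x)
}

# Row-normalized decoding probabilities P(decoded | actual) and the
# empirical prior P(actual). Rows with zero visits are an error.
row_probabilities <- function(C) {
  rs <- rowSums(C$counts)
  if (any(rs == 0))
    stop("confusion matrix has unvisited row(s): ",
         paste(which(rs == 0), collapse = ", "))
  list(row_prob = C$counts / rs, prior = rs / sum(rs))
}

#' Fraction of correct decodings
#'
#' `f_cor = sum_s P(s | s) P(s)` with the empirical prior, i.e. the total
#' diagonal count over the total event count.
#'
#' @param C A `confusion_matrix` (or a plain counts / row-probability
#'   matrix, in which case a uniform prior over rows is used for a
#'   row-stochastic input).
#' @return The fraction correct.
#' @export
percent_correct <- function(C) {
  if (inherits(C, "confusion_matrix")) return(sum(diag(C$counts)) / sum(C$counts))
  m <- as.matrix(C)
  rs <- rowSums(m)
  sum(diag(m / rs) * (rs / sum(rs)))
}

#' Translation-averaged (reduced) confusion matrix
#'
#' Averages all decoding events with the same vector displacement between
#' decoded and actual bin on the L x L torus. The result is an L x L
#' probability table `Q(x - x0)` whose central cell (zero displacement)
#' holds the correct-decoding mass.
#'
#' @param C A `confusion_matrix`.
#' @param env A [torus_environment()] with the same `L`.
#' @return An object of class `reduced_matrix`: `probs` (L x L, entries sum
#'   to 1; row index = dr + L/2 + 1, column = dc + L/2 + 1, origin at the
#'   centre cell), `origin` (its index), `n_events`.
#' @export
reduce_confusion <- function(C, env) {
  L <- env$L
  if (C$S != env$S) stop("environment does not match the confusion matrix")
  if (sum(C$counts) == 0) stop("empty confusion matrix")
  all_bins <- seq_len(C$S)
  acc <- matrix(0, L, L)
  half <- L %/% 2
  for (s in all_bins) {
    d <- bin_displacement(rep(s, C$S), all_bins, env)
    idx <- cbind(d[, "dr"] + half + 1, d[, "dc"] + half + 1)
    acc[idx] <- acc[idx] + C$counts[s, ]
  }
  structure(
    list(probs = acc / sum(acc), origin = c(half + 1, half + 1),
         L = L, n_events = sum(C$counts)),
    class = "reduced_matrix"
  )
}

#' Information content of a reduced matrix
#'
#' The reduced matrix defines a translation-invariant channel: every actual
#' bin decodes to displacement `d` with probability `Q(d)`. With a uniform
#' prior over the S bins its mutual information is `log2(S) - H(Q)` bits.
#'
#' @param R A `reduced_matrix`.
#' @return Information in bits.
#' @export
reduced_information <- function(R) {
  q <- as.vector(R$probs)
  q <- q[q > 0]
  log2(length(as.vector(R$probs))) + sum(q * log2(q))
}

#' Run the test phase and accumulate confusion matrices
#'
#' Simulates the test trajectory under the given DG mode, then decodes the
#' activity of each requested unit sample against the matching column
#' subset of the (same-mode) full-population template set, accumulating one
#' confusion matrix per sample.
#'
#' @param net A [ca3_network()].
#' @param pop A `dg_population`.
#' @param traj The test trajectory.
#' @param templates Full-population `template_set` built under the same
#'   `dg_mode`.
#' @param samples A list of integer unit-id vectors.
#' @param dg_mode `"on"` or `"off"`.
#' @param seed Optional integer seed (noise draws).
#' @return A list of `confusion_matrix` objects, one per sample.
#' @export
run_test_phase <- function(net, pop, traj, templates, samples,
                           dg_mode = c("on", "off"), seed = NULL) {
  dg_mode <- match.arg(dg_mode)
  if (!identical(templates$dg_mode, dg_mode) && !is.na(templates$dg_mode))
    warning("templates were built under dg_mode = ", templates$dg_mode)
  phase <- simulate_phase(net, pop, traj, dg_mode = dg_mode, seed = seed)
  decode_against_templates(phase, templates, samples)
}

# Decode an already-simulated phase for each unit sample.
decode_against_templates <- function(phase, templates, samples) {
  lapply(samples, function(sm) {
    tset <- subset_templates(templates, sm)
    dec <- decode_population(phase$rates[sm, , drop = FALSE], tset)
    confusion_matrix(phase$bin, dec, phase$env,
                     meta = list(sample_size = length(sm),
                                 dg_mode = phase$dg_mode,
                                 n_steps = length(dec)))
  })
}

#' Write a confusion or reduced matrix as delimited text
#'
#' Metadata (sample size, dg_mode, event count, ...) is written as
#' `#`-prefixed header lines followed by the CSV table.
#'
#' @param x A `confusion_matrix` or `reduced_matrix`.
#' @param path Output file path.
#' @export
write_confusion <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "confusion_matrix")) {
    meta <- c(list(S = x$S, n_events = x$n_events), x$meta)
    tab <- x$counts
  } else {
    meta <- list(L = x$L, n_events = x$n_events)
    tab <- x$probs
  }
  writeLines(paste0("# ", paste(names(meta), unlist(meta), sep = "=",
                                collapse = " ")), con)
  utils::write.table(tab, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
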