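# A deterministic "network" whose rate vector is an injective function of
# the bin: unit u fires 1 in bins where (bin + u) is divisible by u + 1.
# Used to test templates/decoding without simulating dynamics.
fake_phase <- function(bins, n_units, env, noise = 0) {
  rates <- sapply(seq_along(bins), function(t) {
    b <- bins[t]
    v <- as.numeric(((b + seq_len(n_units)) %% (seq_len(n_units) + 1)) == 0)
    v + b / 100
  })
  structure(list(rates = rates, bin = bins, dg_mode = "on", env = env),
            class = "phase_rates")
}

test_that("templates average activity per visited bin", {
  env <- torus_environment(L = 2)
  bins <- c(1, 2, 3, 4, 2, 2)
  rates <- matrix(0, 2, 6)
  rates[, 1] <- c(1, 0); rates[, 2] <- c(2, 1); rates[, 3] <- c(0, 3)
  rates[, 4] <- c(1, 1); rates[, 5] <- c(4, 1); rates[, 6] <- c(6, 4)
  tset <- build_templates(rates, bins = bins, env = env)
  expect_equal(tset$templates[2, ], c(4, 2))  # mean of (2,1),(4,1),(6,4)
  expect_equal(tset$templates[1, ], c(1, 0))  # single visit
  expect_equal(tset$occupancy, c(1, 3, 1, 1))
  # constant output -> identical template rows
  cst <- matrix(0.5, 2, 6)
  tc <- build_templates(cst, bins = bins, env = env)
  expect_true(all(tc$templates == 0.5))
})

test_that("template building fails on unvisited bins, naming them", {
  env <- torus_environment(L = 2)
  expect_error(build_templates(matrix(1, 2, 3), bins = c(1, 1, 2), env = env),
               "incomplete coverage.*3, 4")
})

test_that("decoding picks the nearest template with deterministic ties", {
  env <- torus_environment(L = 2)
  tm <- structure(list(templates = rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 2)),
                       sample = 1:2, env = env, dg_mode = "on"),
                  class = "template_set")
  expect_equal(decode_step(c(1, 0), tm), 2L)
  # (1, 1) is equidistant from templates 2 and 3 -> lowest id wins
  expect_equal(decode_step(c(1, 1), tm), 2L)
  # (0.5, 0.5) ties templates 1, 2 and 3 -> template 1
  expect_equal(decode_step(c(0.5, 0.5), tm), 1L)
  # brute-force oracle on random vectors vs random templates
  set.seed(1)
  tm64 <- structure(list(templates = matrix(runif(64 * 5), 64, 5),
                         sample = 1:5, env = torus_environment(),
                         dg_mode = "on"), class = "template_set")
  for (i in 1:20) {
    v <- runif(5)
    brute <- which.min(apply(tm64$templates, 1, function(r) sum((r - v)^2)))
    expect_equal(decode_step(v, tm64), brute)
    expect_equal(ca3metric:::decode_population(matrix(v), tm64), brute)
  }
})

test_that("an injective position code with exact templates decodes perfectly", {
  env <- torus_environment()
  bins <- rep(1:64, 4)
  ph <- fake_phase(bins, 10, env)
  tset <- build_templates(ph)
  cms <- ca3metric:::decode_against_templates(ph, tset, list(1:10))
  C <- cms[[1]]
  expect_equal(percent_correct(C), 1)
  expect_equal(sum(C$counts), length(bins))
  expect_true(all(C$counts[upper.tri(C$counts)] == 0,
                  C$counts[lower.tri(C$counts)] == 0))
  # identity confusion matrix reduces to a delta at the origin
  R <- reduce_confusion(C, env)
  expect_equal(R$probs[R$origin[1], R$origin[2]], 1)
  expect_equal(sum(R$probs), 1)
})

test_that("percent correct weighs rows by the empirical prior", {
  env <- torus_environment(L = 2)
  # hand-built counts: identity -> 1; uniform rows -> 1/S
  idc <- confusion_matrix(rep(1:4, 5), rep(1:4, 5), env)
  expect_equal(percent_correct(idc), 1)
  unif <- matrix(1, 4, 4)
  expect_equal(percent_correct(unif), 1 / 4)
  # 2-bin toy: P(1|1) = 0.8, P(2|2) = 0.6, equal priors -> 0.7
  toy <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(percent_correct(toy), 0.7)
})

test_that("reduced matrices match a brute-force displacement histogram", {
  env <- torus_environment()
  set.seed(2)
  counts <- matrix(rpois(64 * 64, 2), 64, 64)
  C <- structure(list(counts = counts, S = 64, L = 8,
                      n_events = sum(counts), meta = list()),
                 class = "confusion_matrix")
  R <- reduce_confusion(C, env)
  brute <- matrix(0, 8, 8)
  for (s in 1:64) for (r in 1:64) {
    d <- bin_displacement(s, r, env)
    brute[d[1, "dr"] + 5, d[1, "dc"] + 5] <-
      brute[d[1, "dr"] + 5, d[1, "dc"] + 5] + counts[s, r]
  }
  expect_equal(R$probs, brute / sum(brute))
  expect_equal(sum(R$probs), 1)
})

test_that("translation-invariant confusion reduces to its generating kernel", {
  env <- torus_environment()
  kern <- ca3metric:::bump_kernel(8, 1.0)
  # build a 64x64 matrix whose every row is the kernel shifted to its bin
  K2 <- ca3metric:::centered_kernels(env, 1.0)
  C <- structure(list(counts = K2 * 1e6, S = 64, L = 8,
                      n_events = 64e6, meta = list()),
                 class = "confusion_matrix")
  R <- reduce_confusion(C, env)
  expect_equal(R$probs, kern, tolerance = 1e-12)
})

test_that("full test phase conserves events and is reproducible", {
  env <- torus_environment()
  pop <- sample_dg_population(150, p_dg = 0.3, env = env, seed = 3)
  conn_mf <- sample_connectivity(150, 30, 40, seed = 4)
  conn_rc <- sample_connectivity(30, 30, 15, exclude_self = TRUE, seed = 5)
  net <- ca3_network(conn_mf, conn_rc,
                     j_mf = 0.1 / (50 * dg_mean_rate(pop)))
  tr_tmpl <- generate_trajectory(env, 4000, seed = 6)
  tr_test <- generate_trajectory(env, 2000, seed = 7)
  tmpl <- build_templates(simulate_phase(net, pop, tr_tmpl, "on", seed = 8))
  cms1 <- run_test_phase(net, pop, tr_test, tmpl, list(1:5, 1:30), "on",
                         seed = 9)
  cms2 <- run_test_phase(net, pop, tr_test, tmpl, list(1:5, 1:30), "on",
                         seed = 9)
  expect_identical(cms1[[2]]$counts, cms2[[2]]$counts)
  expect_equal(sum(cms1[[1]]$counts), 2000)
  expect_equal(sum(cms1[[2]]$counts), 2000)
  # larger samples decode better
  expect_gt(percent_correct(cms1[[2]]), percent_correct(cms1[[1]]))
})

test_that("an unstructured attractor network decodes at chance without DG", {
  env <- torus_environment(L = 4)
  pop <- sample_dg_population(120, p_dg = 0.3, env = env, seed = 10)
  conn_mf <- sample_connectivity(120, 40, 30, seed = 11)
  conn_rc <- sample_connectivity(40, 40, 20, exclude_self = TRUE, seed = 12)
  net <- ca3_network(conn_mf, conn_rc,
                     j_mf = 0.1 / (30 * dg_mean_rate(pop)))  # uniform RC, no learning
  tr_tmpl <- generate_trajectory(env, 3000, seed = 13)
  tr_test <- generate_trajectory(env, 3000, seed = 14)
  tmpl <- build_templates(simulate_phase(net, pop, tr_tmpl, "off", seed = 15))
  cms <- run_test_phase(net, pop, tr_test, tmpl, list(1:40), "off",
                        seed = 16)
  expect_lt(percent_correct(cms[[1]]), 3 / env$S)
})

test_that("confusion matrices serialize with their metadata", {
  env <- torus_environment(L = 2)
  C <- confusion_matrix(rep(1:4, 3), rep(c(2, 2, 3, 4), 3), env,
                        meta = list(sample_size = 7, dg_mode = "on"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_confusion(C, f)
  lines <- readLines(f)
  expect_match(lines[1], "sample_size=7")
  tab <- as.matrix(read.csv(f, comment.char = "#", header = FALSE))
  expect_equal(unname(tab), unname(C$counts))
})
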