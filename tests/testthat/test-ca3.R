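test_that("connectivity sampling respects density, self-exclusion and bounds", {
  expect_error(sample_connectivity(10, 10, 11), "c")
  full <- sample_connectivity(5, 4, 5, seed = 1)
  expect_true(all(as.matrix(full) == 1))
  rc <- sample_connectivity(200, 200, 50, exclude_self = TRUE, seed = 2)
  expect_equal(sum(Matrix::diag(rc)), 0)
  # mean in-degree within 3 binomial SEs
  indeg <- Matrix::rowSums(sample_connectivity(1000, 1000, 50, seed = 3))
  se <- sqrt(50 * (1 - 50 / 1000) / 1000)
  expect_lt(abs(mean(indeg) - 50), 3 * se)
})

test_that("sparsity matches its closed forms", {
  expect_equal(sparsity(rep(0.3, 7)), 1)
  expect_equal(sparsity(c(1, rep(0, 9))), 1 / 10)
  expect_equal(sparsity(c(1, 1, 0, 0)), 0.5)
  expect_error(sparsity(numeric(5)), "all rates are zero")
})

test_that("threshold/gain control hits the sparsity and mean targets", {
  set.seed(10)
  drive <- rnorm(500)
  ctl <- adjust_threshold_gain(drive, target_sparsity = 0.1,
                               target_mean = 0.1)
  expect_lt(abs(ctl$sparsity - 0.1), 1e-3)
  expect_equal(ctl$mean_rate, 0.1, tolerance = 1e-9)
  # two-level drive: k units far above the rest -> sparsity ~ k/N
  k <- 50; N <- 500
  drive2 <- c(rep(10, k), rep(0, N - k)) + rnorm(N, 0, 1e-3)
  ctl2 <- adjust_threshold_gain(drive2, target_sparsity = k / N,
                                target_mean = 0.1)
  expect_lt(abs(ctl2$sparsity - k / N), 1e-3)
  # essentially all mass sits on the k high-drive units
  expect_gt(sum(ctl2$rates[1:k]) / sum(ctl2$rates), 0.999)
})

test_that("sparsity target 1 drops the threshold below every drive", {
  set.seed(11)
  drive <- rnorm(100)
  ctl <- adjust_threshold_gain(drive, target_sparsity = 1, target_mean = 0.1)
  expect_lte(ctl$T, min(drive))
  expect_true(all(ctl$rates > 0))
})

test_that("control failures are reported, not silently absorbed", {
  expect_error(adjust_threshold_gain(rep(2, 10)), "flat drive")
  expect_error(adjust_threshold_gain(rnorm(4), target_sparsity = 0.1),
               "floor")
})

test_that("threshold-linear activity reduces to the expected limits", {
  env <- torus_environment()
  conn_mf <- sample_connectivity(20, 5, 20, seed = 1) # all-ones
  conn_rc <- Matrix::Matrix(0, 5, 5, sparse = TRUE)
  net <- ca3_network(conn_mf, conn_rc, j_mf = 1, j_rc0 = 0, noise_sd = 0)
  # all drive below threshold -> silence, flagged sparsity
  st <- ca3_activity(net, rep(0.01, 20), control = FALSE, T = 1, g = 1,
                     noise_sd = 0, damping = 0)
  expect_true(all(st$rates == 0))
  expect_true(is.na(st$sparsity))
  # linear regime: g = 1, T = 0 -> rate equals drive
  dg <- c(rep(0.02, 20))
  st2 <- ca3_activity(net, dg, control = FALSE, T = 0, g = 1, noise_sd = 0,
                      damping = 0)
  expect_equal(st2$rates, rep(sum(dg), 5))
})

test_that("damped relaxation converges geometrically to a fixed point", {
  set.seed(12)
  n <- 60
  env <- torus_environment()
  pop <- sample_dg_population(100, p_dg = 0.5, env = env, seed = 1)
  conn_mf <- sample_connectivity(100, n, 30, seed = 2)
  conn_rc <- sample_connectivity(n, n, 20, exclude_self = TRUE, seed = 3)
  net <- ca3_network(conn_mf, conn_rc,
                     j_mf = 0.1 / (30 * dg_mean_rate(pop)), noise_sd = 0)
  dg <- dg_rates(pop, c(0.3, 0.4), env)
  st <- ca3_activity(net, dg, n_iter = 200, noise_sd = 0)
  st2 <- ca3_activity(net, dg, prev_rates = st$rates, n_iter = 1,
                      noise_sd = 0)
  rel <- sqrt(sum((st2$rates - st$rates)^2)) / sqrt(sum(st$rates^2))
  expect_lt(rel, 1e-6)
  # the 15-sweep protocol state is already close to the fixed point
  st15 <- ca3_activity(net, dg, n_iter = 15, noise_sd = 0)
  rel15 <- sqrt(sum((st15$rates - st$rates)^2)) / sqrt(sum(st$rates^2))
  expect_lt(rel15, 0.05)
  expect_lt(abs(st15$sparsity - 0.1), 2e-2)
  expect_equal(st15$mean_rate, 0.1, tolerance = 1e-6)
})

test_that("threshold-linear response is monotone in the drive at fixed T, g", {
  env <- torus_environment()
  conn_mf <- sample_connectivity(10, 4, 10, seed = 4)
  conn_rc <- Matrix::Matrix(0, 4, 4, sparse = TRUE)
  net <- ca3_network(conn_mf, conn_rc, j_mf = 1, noise_sd = 0)
  dg <- runif(10, 0, 0.2)
  base <- ca3_activity(net, dg, control = FALSE, T = 0.5, g = 2,
                       noise_sd = 0, damping = 0)$rates
  up <- ca3_activity(net, dg + 0.05, control = FALSE, T = 0.5, g = 2,
                     noise_sd = 0, damping = 0)$rates
  expect_true(all(up >= base))
})

test_that("the compiled phase driver matches the R-level single step", {
  set.seed(13)
  n <- 40
  conn_mf <- sample_connectivity(80, n, 20, seed = 5)
  conn_rc <- sample_connectivity(n, n, 15, exclude_self = TRUE, seed = 6)
  net <- ca3_network(conn_mf, conn_rc, noise_sd = 0)
  env <- torus_environment()
  pop <- sample_dg_population(80, p_dg = 0.5, env = env, seed = 7)
  traj <- generate_trajectory(env, 3, seed = 8)
  ph <- simulate_phase(net, pop, traj, "on", n_iter = 15)
  # step 1 starts from zero rates, like ca3_activity's default
  st <- ca3_activity(net, dg_rates(pop, traj$positions[1, ], env),
                     n_iter = 15, noise_sd = 0)
  expect_equal(ph$rates[, 1], st$rates, tolerance = 1e-4)
})

test_that("network state serializes to a directory of delimited text", {
  conn_mf <- sample_connectivity(30, 10, 10, seed = 9)
  conn_rc <- sample_connectivity(10, 10, 5, exclude_self = TRUE, seed = 10)
  net <- ca3_network(conn_mf, conn_rc)
  d <- withr::local_tempdir()
  write_network(net, d)
  expect_true(all(file.exists(file.path(d, c("params.csv", "conn_mf.csv",
                                             "conn_rc.csv", "j_rc.csv")))))
  w <- read.csv(file.path(d, "j_rc.csv"))
  expect_equal(nrow(w), sum(net$j_rc != 0))
})
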