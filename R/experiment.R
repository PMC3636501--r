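#' Experiment configuration
#'
#' Bundles every model and protocol parameter of the full pipeline
#' (learning, template building, testing under both DG modes, information
#' and metric-resolution analysis, MDS). Three presets are provided:
#'
#' * `"paper"` — the full-scale protocol: 45,000 DG units, 1,500 CA3 units,
#'   C_MF = 50, C_RC = 900; learning 10,000 steps, templates 100,000,
#'   test 400,000.
#' * `"desk"` — a scaled-down replication that preserves the connectivity
#'   ratios (4,500 DG / 300 CA3 units, C_RC = 180) with the full
#'   100,000-step template phase and a 50,000-step test phase; runs on a
#'   single CPU in minutes.
#' * `"tiny"` — a smoke-test scale (1,000 DG / 100 CA3 units).
#'
#' @param preset `"desk"` (default), `"paper"` or `"tiny"`.
#' @param seed Base integer seed; every stochastic stage derives its own
#'   seed from it by a fixed offset.
#' @param ... Named overrides of any configuration field.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("desk", "paper", "tiny"), seed = 1,
                              ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    side = 1, L = 8L,
    step_length = 0.025, dt = 0.125, heading_noise_sd = 0.35,
    n_dg = 4500L, n_ca3 = 300L, c_mf = 50, c_rc = 180,
    p_dg = 0.033, q = 1.7, beta0 = 1, sigma_f = 0.1,
    target_sparsity = 0.1, target_mean = 0.1, noise_sd = 0.002,
    gamma = 0.01, tau = 14L, n_iter = 15L, damping = 0.3,
    n_learn = 10000L, n_template = 100000L, n_test = 50000L,
    sample_sizes = 2L^(0:8), n_samples = 10L,
    n_draws = 50L,
    seed = as.integer(seed)
  )
  if (preset == "paper") {
    base$n_dg <- 45000L; base$n_ca3 <- 1500L; base$c_rc <- 900
    base$n_template <- 100000L; base$n_test <- 400000L
  } else if (preset == "tiny") {
    base$n_dg <- 1000L; base$n_ca3 <- 100L; base$c_rc <- 60
    base$n_learn <- 2000L; base$n_template <- 10000L; base$n_test <- 20000L
    base$sample_sizes <- 2L^(0:6); base$n_samples <- 4L
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  base[names(over)] <- over
  base$sample_sizes <- base$sample_sizes[base$sample_sizes <= base$n_ca3]
  stopifnot(base$n_learn > 0, base$n_template > 0, base$n_test > 0,
            base$n_samples > 0)
  structure(base, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment config (%s): %d DG / %d CA3, C_MF %g, C_RC %g, learn %d / template %d / test %d steps, seed %d\n",
              x$preset, x$n_dg, x$n_ca3, x$c_mf, x$c_rc,
              x$n_learn, x$n_template, x$n_test, x$seed))
  invisible(x)
}

#' Write / read an experiment configuration
#'
#' JSON round-trip of an [experiment_config()].
#'
#' @param cfg An `experiment_config`.
#' @param path File path.
#' @return `read_experiment_config` returns the `experiment_config`.
#' @export
write_experiment_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- experiment_config(preset = x$preset, seed = x$seed)
  for (nm in setdiff(names(x), c("preset", "seed")))
    cfg[[nm]] <- if (nm %in% c("L", "n_dg", "n_ca3", "tau", "n_iter",
                               "n_learn", "n_template", "n_test",
                               "sample_sizes", "n_samples", "n_draws"))
      as.integer(x[[nm]]) else x[[nm]]
  cfg
}

# Fixed seed offsets for the pipeline stages (all well below 2^31 for any
# reasonable base seed).
stage_seed <- function(cfg, stage) {
  offs <- c(pop = 1L, conn_mf = 2L, conn_rc = 3L, traj_learn = 4L,
            learn = 5L, traj_template = 6L, traj_test = 7L, samples = 8L,
            template_on = 10L, test_on = 11L, template_off = 12L,
            test_off = 13L, chi = 20L)
  cfg$seed + unname(offs[stage])
}

# Draw the unit samples: for each size, n_samples independent draws
# without replacement from 1..n_ca3.
draw_unit_samples <- function(cfg) {
  local_seed_eval(stage_seed(cfg, "samples"), function() {
    lapply(cfg$sample_sizes, function(sz) {
      lapply(seq_len(cfg$n_samples), function(i)
        sort(sample.int(cfg$n_ca3, sz)))
    })
  })
}

#' Run the full experiment
#'
#' Executes the whole pipeline: sample the DG population and connectivity,
#' run the learning phase, then for each requested DG mode build templates
#' and run the test phase, decode every unit sample, accumulate full and
#' reduced confusion matrices, fit the information/percent-correct sigmoid
#' curves and the reduced-matrix Gaussian bumps, solve the metric
#' resolution index chi (drift-adjusted references in the DG-off mode,
#' with the bump parameters taken from the DG-on reduced matrices), and
#' Sammon-map the full-population DG-on templates.
#'
#' @param cfg An [experiment_config()].
#' @param dg_modes Character vector, subset of `c("on", "off")`.
#' @param out_dir Optional directory: when given, confusion matrices,
#'   per-size analysis tables, fits, chi results, the embedding and a JSON
#'   manifest are written there as delimited text.
#' @param verbose Print per-stage progress.
#' @return A list of class `experiment_result` with elements `cfg`, `env`,
#'   `net` (learned), `templates` (per mode), `analysis` (per mode: sizes,
#'   `info_full`, `info_reduced`, `f_cor`, `bumps`, `fit_info_full`,
#'   `fit_info_reduced`, `fit_pcor`, `reduced_avg`), `chi` (per mode
#'   `metric_resolution` objects) and `mds` (embedding, stress, adjacency).
#' @export
run_experiment <- function(cfg = experiment_config(),
                           dg_modes = c("on", "off"), out_dir = NULL,
                           verbose = interactive()) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf("[%s] %s",
    format(round(difftime(Sys.time(), t0, units = "secs"))), sprintf(...)))
  env <- torus_environment(cfg$side, cfg$L)

  say("sampling DG population and connectivity")
  pop <- sample_dg_population(cfg$n_dg, q = cfg$q, p_dg = cfg$p_dg,
                              beta0 = cfg$beta0, sigma_f = cfg$sigma_f,
                              env = env, seed = stage_seed(cfg, "pop"))
  conn_mf <- sample_connectivity(cfg$n_dg, cfg$n_ca3, cfg$c_mf,
                                 seed = stage_seed(cfg, "conn_mf"))
  conn_rc <- sample_connectivity(cfg$n_ca3, cfg$n_ca3, cfg$c_rc,
                                 exclude_self = TRUE,
                                 seed = stage_seed(cfg, "conn_rc"))
  # Balance the MF and RC drives: after normalization the RC input to a
  # unit is ~ the target mean rate, so scale J^MF for the same mean MF
  # drive. The external input then competes with, rather than being
  # swamped by, the recurrent feedback.
  j_mf <- cfg$target_mean / (cfg$c_mf * dg_mean_rate(pop))
  net0 <- ca3_network(conn_mf, conn_rc, j_mf = j_mf,
                      target_sparsity = cfg$target_sparsity,
                      target_mean = cfg$target_mean,
                      noise_sd = cfg$noise_sd)

  say("learning phase (%d steps)", cfg$n_learn)
  traj_learn <- generate_trajectory(env, cfg$n_learn, cfg$step_length,
                                    cfg$heading_noise_sd, cfg$dt,
                                    seed = stage_seed(cfg, "traj_learn"))
  net <- run_learning_phase(net0, pop, traj_learn,
                            learning_config(cfg$gamma, cfg$n_learn,
                                            cfg$tau, cfg$n_iter,
                                            cfg$damping),
                            seed = stage_seed(cfg, "learn"))

  traj_template <- generate_trajectory(env, cfg$n_template, cfg$step_length,
                                       cfg$heading_noise_sd, cfg$dt,
                                       seed = stage_seed(cfg, "traj_template"))
  traj_test <- generate_trajectory(env, cfg$n_test, cfg$step_length,
                                   cfg$heading_noise_sd, cfg$dt,
                                   seed = stage_seed(cfg, "traj_test"))
  samples <- draw_unit_samples(cfg)

  templates <- list()
  analysis <- list()
  for (mode in dg_modes) {
    say("template phase, DG %s (%d steps)", mode, cfg$n_template)
    ph_tmpl <- simulate_phase(net, pop, traj_template, dg_mode = mode,
                              n_iter = cfg$n_iter, damping = cfg$damping,
                              seed = stage_seed(cfg, paste0("template_", mode)))
    templates[[mode]] <- build_templates(ph_tmpl)
    say("test phase, DG %s (%d steps)", mode, cfg$n_test)
    ph_test <- simulate_phase(net, pop, traj_test, dg_mode = mode,
                              n_iter = cfg$n_iter, damping = cfg$damping,
                              seed = stage_seed(cfg, paste0("test_", mode)))
    analysis[[mode]] <- analyze_mode(ph_test, templates[[mode]], samples,
                                     cfg, env)
    say("DG %s: f_cor %s", mode,
        paste(signif(analysis[[mode]]$f_cor, 3), collapse = " "))
  }

  # A chi solve can be unidentifiable at every size for very small or
  # poorly-trained networks; record the failure instead of voiding the
  # rest of the (expensive) run.
  solve_or_mark <- function(mode, expr) {
    tryCatch(expr, error = function(e) {
      warning("metric resolution (", mode, ") failed: ",
              conditionMessage(e), call. = FALSE)
      structure(list(error = conditionMessage(e)), class = "chi_failure")
    })
  }
  chi <- list()
  if ("on" %in% dg_modes) {
    say("solving metric resolution, DG on")
    an <- analysis$on
    chi$on <- solve_or_mark("on", solve_metric_resolution(
      an$sizes, an$fit_info_full$predict(an$sizes), an$bumps, env,
      drift = FALSE, n_draws = cfg$n_draws, seed = stage_seed(cfg, "chi")))
    if ("off" %in% dg_modes) {
      say("solving metric resolution, DG off (drift references)")
      chi$off <- solve_or_mark("off", solve_metric_resolution(
        an$sizes, analysis$off$fit_info_full$predict(an$sizes), an$bumps,
        env, drift = TRUE, n_draws = cfg$n_draws,
        seed = stage_seed(cfg, "chi") + 1L))
    }
  }

  mds <- NULL
  if ("on" %in% dg_modes) {
    say("Sammon mapping of the full-population templates")
    D <- correlation_distance_matrix(templates$on)
    emb <- sammon_map(D, dim = 3, n_iter = 500)
    mds <- list(embedding = emb, stress = emb$stress,
                adjacency = embedding_adjacency(emb, env))
  }

  res <- structure(
    list(cfg = cfg, env = env, net = net, templates = templates,
         analysis = analysis, chi = chi, mds = mds),
    class = "experiment_result"
  )
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  say("done")
  res
}

# Per-mode decoding + information analysis.
analyze_mode <- function(ph_test, tmpl_full, samples, cfg, env) {
  sizes <- cfg$sample_sizes
  n_sizes <- length(sizes)
  info_full <- info_reduced <- f_cor <- numeric(n_sizes)
  reduced_avg <- vector("list", n_sizes)
  for (i in seq_len(n_sizes)) {
    cms <- decode_against_templates(ph_test, tmpl_full, samples[[i]])
    iv <- vapply(cms, mutual_information, numeric(1))
    red <- lapply(cms, reduce_confusion, env = env)
    ir <- vapply(red, reduced_information, numeric(1))
    fc <- vapply(cms, percent_correct, numeric(1))
    info_full[i] <- mean(iv)
    info_reduced[i] <- mean(ir)
    f_cor[i] <- mean(fc)
    qavg <- Reduce(`+`, lapply(red, `[[`, "probs")) / length(red)
    reduced_avg[[i]] <- structure(
      list(probs = qavg, origin = red[[1]]$origin, L = env$L,
           n_events = sum(vapply(red, `[[`, numeric(1), "n_events"))),
      class = "reduced_matrix")
  }
  bumps <- lapply(reduced_avg, fit_gaussian_bump)
  list(sizes = sizes, info_full = info_full, info_reduced = info_reduced,
       f_cor = f_cor, reduced_avg = reduced_avg, bumps = bumps,
       fit_info_full = fit_sigmoid(sizes, info_full, "info"),
       fit_info_reduced = fit_sigmoid(sizes, info_reduced, "info"),
       fit_pcor = fit_sigmoid(sizes, f_cor, "pcor"))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result\n")
  print(x$cfg)
  for (mode in names(x$analysis)) {
    an <- x$analysis[[mode]]
    cat(sprintf("  DG %s: I_full %s bits; f_cor %s\n", mode,
                paste(signif(an$info_full, 3), collapse = " "),
                paste(signif(an$f_cor, 3), collapse = " ")))
  }
  for (mode in names(x$chi)) {
    if (inherits(x$chi[[mode]], "chi_failure"))
      cat(sprintf("  chi (%s): unavailable (%s)\n", mode,
                  x$chi[[mode]]$error))
    else
      cat(sprintf("  chi (%s): %.3f +/- %.3f\n", mode,
                  x$chi[[mode]]$chi_mean, x$chi[[mode]]$chi_sd))
  }
  if (!is.null(x$mds))
    cat(sprintf("  Sammon stress: %.4f\n", x$mds$stress))
  invisible(x)
}

# Write the result bundle as delimited text + a JSON manifest.
write_experiment <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$cfg
  for (mode in names(res$analysis)) {
    an <- res$analysis[[mode]]
    tab <- data.frame(n = an$sizes, info_full = an$info_full,
                      info_reduced = an$info_reduced, f_cor = an$f_cor,
                      pc = vapply(an$bumps, `[[`, numeric(1), "pc"),
                      w = vapply(an$bumps, `[[`, numeric(1), "w"),
                      a = vapply(an$bumps, `[[`, numeric(1), "a"))
    if (inherits(res$chi[[mode]], "metric_resolution")) {
      tab$sigma <- res$chi[[mode]]$sigma
      tab$chi <- res$chi[[mode]]$chi
    }
    utils::write.csv(tab, file.path(out_dir,
                                    sprintf("analysis_dg_%s.csv", mode)),
                     row.names = FALSE)
    for (i in seq_along(an$reduced_avg))
      write_confusion(an$reduced_avg[[i]],
                      file.path(out_dir, sprintf("reduced_dg_%s_n%d.csv",
                                                 mode, an$sizes[i])))
  }
  if (!is.null(res$mds))
    write_embedding(res$mds$embedding, res$env,
                    file.path(out_dir, "embedding.csv"))
  manifest <- list(
    package = "ca3metric",
    version = as.character(utils::packageVersion("ca3metric")),
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    stages = as.list(vapply(c("pop", "conn_mf", "conn_rc", "traj_learn",
                              "learn", "traj_template", "traj_test",
                              "samples", "chi"),
                            function(s) stage_seed(cfg, s), integer(1))),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Order-independent hash of the configuration values.
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small rolling hash; no external digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
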