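# Reproducible experiment driver: a JSON-serialisable config in, a directory
# of tidy CSV summaries + JSON manifest + log out. Every random draw is
# derived from the config's base seed, so identical configs give identical
# outputs.

experiment_schema <- list(
  spectrum_sweep = c("branch", "N", "instances"),
  phase_diagram = c("sigma2_grid", "sigma_mn_grid", "C", "N"),
  input_driven = c("mode", "N", "sigma2", "sigma_nI", "seeds"),
  autonomous = c("sigma2", "sigma_mn", "C", "N", "seeds"),
  task_psychometric = c("N", "sigma2", "sigma_mn", "repeats"))

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path",
                             call. = FALSE)
  missing <- setdiff(c("experiment", "seed"), names(config))
  if (is.null(config$experiment) ||
      !config$experiment %in% names(experiment_schema))
    missing <- union(missing, "experiment")
  if (length(missing) == 0)
    missing <- setdiff(experiment_schema[[config$experiment]], names(config))
  if (length(missing))
    stop("config schema error; missing or invalid keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  config
}

#' Run a reproducible experiment from a config
#'
#' Executes one of the package's standard experiments and writes its outputs
#' (tidy CSV summaries, a JSON manifest recording parameters, seeds, package
#' version and wall time, and a plain-text log) to a directory. Identical
#' configs reproduce identical outputs: all randomness is derived from the
#' config's base \code{seed}.
#'
#' Experiments and their main keys (beyond \code{experiment}, \code{seed},
#' \code{out_dir}):
#' \describe{
#'   \item{\code{spectrum_sweep}}{\code{branch} (\code{"gaussian"},
#'     \code{"rank_one_scaled"}, \code{"rank_one_rescaled"}), \code{N},
#'     \code{instances}, and \code{s_grid} or \code{C_grid}; \code{g} or
#'     \code{sigma2}/\code{sigma_mn}. Empirical vs analytic outlier and bulk
#'     radius per instance.}
#'   \item{\code{phase_diagram}}{\code{sigma2_grid}, \code{sigma_mn_grid},
#'     \code{C}, \code{N}. Regime labels and boundary curves.}
#'   \item{\code{input_driven}}{\code{mode} (\code{"sparse"} with
#'     \code{C_grid}, or \code{"composite"} with \code{g_grid}), \code{N},
#'     \code{sigma2}, \code{sigma_mn}, \code{sigma_nI}, \code{seeds}. Step
#'     input; participation ratio and terminal structure along \code{m}.}
#'   \item{\code{autonomous}}{\code{sigma2}, \code{sigma_mn} (vectors of
#'     equal length, one point per entry), \code{C}, \code{N}, \code{seeds}.
#'     Theory vs empirical regime labels.}
#'   \item{\code{task_psychometric}}{\code{N}, \code{C} (or \code{g}),
#'     \code{sigma2}, \code{sigma_mn}, \code{repeats}, optional
#'     \code{c_bar_grid} (default: spanning the noise-free threshold).}
#' }
#'
#' @param config a named list, or path to a JSON file with the same content.
#'   Must contain \code{experiment}, \code{seed} and the experiment's keys;
#'   \code{out_dir} defaults to \code{tempfile("sparselr_")}.
#' @return Invisibly, a list with \code{out_dir}, the summary data frame(s)
#'   and the manifest.
#' @export
run_experiment <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir %||% tempfile("sparselr_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(sprintf("[%s] ", config$experiment),
                            sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  t0 <- proc.time()[["elapsed"]]
  logf("start: seed = %d", as.integer(config$seed))
  result <- switch(config$experiment,
    spectrum_sweep = exp_spectrum_sweep(config, out_dir, logf),
    phase_diagram = exp_phase_diagram(config, out_dir, logf),
    input_driven = exp_input_driven(config, out_dir, logf),
    autonomous = exp_autonomous(config, out_dir, logf),
    task_psychometric = exp_task_psychometric(config, out_dir, logf))
  wall <- proc.time()[["elapsed"]] - t0
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    experiment = config$experiment, seed = config$seed,
    package_version = as.character(utils::packageVersion("sparselr")),
    wall_time_s = round(wall, 3), files = result$files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done in %.2f s", wall)
  invisible(c(list(out_dir = out_dir, manifest = manifest), result))
}

write_summary <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

exp_spectrum_sweep <- function(config, out_dir, logf) {
  branch <- config$branch
  N <- config$N
  instances <- config$instances
  grid <- if (!is.null(config$s_grid))
    data.frame(s = config$s_grid, C = NA)
  else data.frame(s = 1 - config$C_grid / N, C = config$C_grid)
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    s <- grid$s[i]
    for (inst in seq_len(instances)) {
      k <- k + 1L
      set.seed(derive_seed(config$seed, k))
      if (branch == "gaussian") {
        W <- gaussian_matrix(N, config$g)
        theory <- spectral_theory("gaussian", g = config$g, s = s)
      } else {
        rescaled <- branch == "rank_one_rescaled"
        cv <- connectivity_vectors(N, config$sigma2, config$sigma_mn)
        W <- rank_one_matrix(cv, rescaled = rescaled)
        theory <- spectral_theory(branch, sigma2 = config$sigma2,
                                  sigma_mn = config$sigma_mn, s = s, N = N)
      }
      if (s > 0) {
        scheme <- if (is.na(grid$C[i])) "bernoulli" else "fixed_in_degree"
        mask <- if (scheme == "bernoulli") sparsity_mask(N, scheme, s = s)
        else sparsity_mask(N, scheme, C = grid$C[i])
        W <- sparsify(W, mask)
      }
      est <- estimate_outlier_and_bulk(compute_spectrum(W), theory)
      rows[[k]] <- data.frame(
        s = s, C = grid$C[i], N = N, instance = inst,
        seed = derive_seed(config$seed, k),
        radius_hat = est$bulk_radius_hat, outlier_hat = est$outlier_hat,
        outlier_measurable = est$outlier_measurable,
        radius_theory = theory$bulk_radius, outlier_theory = theory$outlier)
    }
    logf("grid point s = %.3f done (%d instances)", s, instances)
  }
  summary <- do.call(rbind, rows)
  files <- write_summary(summary, out_dir, "spectrum_sweep.csv")
  list(summary = summary, files = files)
}

exp_phase_diagram <- function(config, out_dir, logf) {
  pd <- phase_diagram(config$sigma2_grid, config$sigma_mn_grid,
                      config$C, config$N)
  f1 <- write_summary(cbind(pd$cells, C = pd$C, N = pd$N), out_dir,
                      "phase_diagram.csv")
  b <- pd$boundaries
  bdf <- data.frame(
    boundary = c("outlier_instability", "bulk_instability",
                 "structured_chaotic"),
    value = c(b$outlier_instability$sigma_mn, b$bulk_instability$sigma2,
              b$structured_chaotic$slope_sigma_mn_per_sigma2),
    meaning = c("sigma_mn at outlier = 1", "sigma2 at bulk radius = 1",
                "d sigma_mn / d sigma2 on outlier = bulk"))
  f2 <- write_summary(bdf, out_dir, "boundaries.csv")
  logf("labelled %d cells", nrow(pd$cells))
  list(summary = pd$cells, phase_diagram = pd, files = c(f1, f2))
}

exp_input_driven <- function(config, out_dir, logf) {
  N <- config$N
  sigma2 <- config$sigma2
  sigma_mn <- config$sigma_mn %||% 0
  tau <- config$tau %||% 100
  grid <- if (config$mode == "sparse") config$C_grid else config$g_grid
  rows <- list()
  k <- 0L
  for (v in grid) {
    for (sd_i in seq_len(config$seeds)) {
      k <- k + 1L
      set.seed(derive_seed(config$seed, k))
      cv <- connectivity_vectors(N, sigma2, sigma_mn)
      if (config$mode == "sparse") {
        W <- sparsify(rank_one_matrix(cv, rescaled = TRUE),
                      sparsity_mask(N, "fixed_in_degree", C = v))
        radius <- theory_rank_one_bulk_radius(sigma2, N = N, C = v,
                                              rescaled = TRUE)
      } else {
        W <- composite_matrix(cv, g = v)
        radius <- v
      }
      I <- draw_input_pattern(cv, config$sigma_nI)
      net <- network_model(W, I = I, tau = tau)
      lead <- 2 * tau; stim <- 5 * tau; wash <- 5 * tau
      tr <- stats::simulate(net, duration = lead + stim + wash,
                            input = step_input(lead, lead + stim))
      lat <- latent_projections(tr, m = cv$m, I = I, n = cv$n)
      window <- tr$times >= lead + tau & tr$times <= lead + stim
      pr <- participation_ratio(tr$x[window, ])
      kr_end <- lat$kappa_r[max(which(tr$times <= lead + stim))]
      rows[[k]] <- data.frame(
        mode = config$mode, value = v, seed_index = sd_i, N = N,
        sigma2 = sigma2, sigma_mn = sigma_mn, sigma_nI = config$sigma_nI,
        participation_ratio = pr, kappa_r_end = kr_end,
        radius_theory = radius)
    }
    logf("%s = %g done (%d seeds)", config$mode, v, config$seeds)
  }
  summary <- do.call(rbind, rows)
  files <- write_summary(summary, out_dir, "input_driven.csv")
  list(summary = summary, files = files)
}

exp_autonomous <- function(config, out_dir, logf) {
  pts <- data.frame(sigma2 = config$sigma2, sigma_mn = config$sigma_mn)
  tau <- config$tau %||% 100
  duration <- config$duration %||% (70 * tau)
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(pts))) {
    theory <- spectral_theory("rank_one_rescaled", sigma2 = pts$sigma2[i],
                              sigma_mn = pts$sigma_mn[i], C = config$C,
                              N = config$N)
    for (sd_i in seq_len(config$seeds)) {
      k <- k + 1L
      set.seed(derive_seed(config$seed, k))
      cv <- connectivity_vectors(config$N, pts$sigma2[i], pts$sigma_mn[i])
      W <- sparsify(rank_one_matrix(cv, rescaled = TRUE),
                    sparsity_mask(config$N, "fixed_in_degree", C = config$C))
      net <- network_model(W, tau = tau)
      tr <- stats::simulate(net, duration = duration, x0 = "random")
      rows[[k]] <- data.frame(
        sigma2 = pts$sigma2[i], sigma_mn = pts$sigma_mn[i],
        C = config$C, N = config$N, seed_index = sd_i,
        outlier_theory = theory$outlier, radius_theory = theory$bulk_radius,
        label_theory = classify_regime(theory),
        label_empirical = empirical_regime(tr))
    }
    logf("point (%g, %g): theory %s", pts$sigma2[i], pts$sigma_mn[i],
         classify_regime(theory))
  }
  summary <- do.call(rbind, rows)
  files <- write_summary(summary, out_dir, "autonomous.csv")
  list(summary = summary, files = files)
}

exp_task_psychometric <- function(config, out_dir, logf) {
  set.seed(derive_seed(config$seed, 0L))
  net <- if (!is.null(config$C))
    task_network(config$N, config$C, config$sigma2, config$sigma_mn)
  else control_network(config$N, config$sigma2, config$sigma_mn,
                       g = config$g %||% 0)
  grid <- config$c_bar_grid
  if (is.null(grid)) {
    theta <- locate_threshold(net)
    grid <- seq(0.4 * theta, 1.6 * theta, length.out = 7)
    logf("noise-free threshold located at %.4g", theta)
  }
  curve <- psychometric_curve(
    net, grid, repeats = config$repeats,
    seed = derive_seed(config$seed, 1L),
    stim_sd = config$stim_sd %||% 0.3,
    unit_noise_sd = config$unit_noise_sd %||% 0.05,
    duration = config$duration %||% 500)
  df <- cbind(as.data.frame(curve), repeats = config$repeats,
              C = config$C %||% NA, N = config$N, sigma2 = config$sigma2,
              sigma_mn = config$sigma_mn, g = config$g %||% 0,
              seed_base = config$seed)
  f1 <- write_summary(df, out_dir, "psychometric.csv")
  tr <- run_trial(net, grid[length(grid)], seed = derive_seed(config$seed, 2L),
                  stim_sd = config$stim_sd %||% 0.3,
                  unit_noise_sd = config$unit_noise_sd %||% 0.05,
                  duration = config$duration %||% 500,
                  return_trajectory = TRUE)
  write_trajectory_bundle(tr$trajectory, out_dir, "example_trial")
  logf("psychometric curve over %d strengths x %d repeats",
       length(grid), config$repeats)
  list(summary = df, curve = curve, files = f1)
}

#' Generate small deterministic fixtures
#'
#' Writes tiny instances of every matrix type (Gaussian, sparsified Gaussian,
#' dense scaled rank-one, rescaled rank-one with a fixed in-degree mask) and
#' one short trajectory as plain-text bundles, for use in examples and tests.
#'
#' @param dir output directory.
#' @param size \code{"tiny"} (N = 50) or \code{"small"} (N = 200).
#' @param seed base seed.
#' @return Invisibly, the directory path.
#' @export
generate_fixtures <- function(dir, size = c("tiny", "small"), seed = 1) {
  size <- match.arg(size)
  N <- if (size == "tiny") 50L else 200L
  C <- N %/% 5L
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(seed, 1L))
  write_weight_bundle(gaussian_matrix(N, g = 1), dir, "gaussian")
  set.seed(derive_seed(seed, 2L))
  write_weight_bundle(
    sparsify(gaussian_matrix(N, g = 1), sparsity_mask(N, "bernoulli", s = 0.5)),
    dir, "gaussian_sparse")
  set.seed(derive_seed(seed, 3L))
  cv <- connectivity_vectors(N, sigma2 = 16, sigma_mn = 4)
  write_weight_bundle(rank_one_matrix(cv), dir, "rank_one_dense")
  set.seed(derive_seed(seed, 4L))
  cv2 <- connectivity_vectors(N, sigma2 = 0.1, sigma_mn = 0.04)
  write_weight_bundle(
    sparsify(rank_one_matrix(cv2, rescaled = TRUE),
             sparsity_mask(N, "fixed_in_degree", C = C)),
    dir, "rank_one_rescaled_sparse")
  set.seed(derive_seed(seed, 5L))
  net <- network_model(gaussian_matrix(N, g = 0.5), tau = 100)
  tr <- stats::simulate(net, duration = 500, x0 = "random")
  # bundle lacks latents on purpose: the Gaussian model carries no vectors
  write_trajectory_bundle(tr, dir, "trajectory")
  jsonlite::write_json(list(size = size, N = N, C = C, seed = seed),
                       file.path(dir, "fixtures.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
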