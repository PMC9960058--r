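#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (or JSON, which YAML subsumes) with the
#' blocks: `rates` (`k1`, `k2`, `k3`, optional `ka` — or `k1E0`/`k3E0`
#' to be normalized at `enzyme.E0`), `enzyme` (`E0`, mg/L), `grid`
#' (`t_end_s`, `n_points`) and `stages`, plus optional per-stage blocks
#' (`ss`, `fit`, `ftir`, `afm`). Validation failures raise a
#' `casekin_config_error` naming the offending key.
#'
#' @param path path to a YAML/JSON config file.
#' @return Validated config list with a `rate_constants` object under
#'   `$rate_constants`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    ck_config_error(sprintf("config file '%s' not found", path), key = "path")
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg a raw config list (as parsed from YAML).
#' @export
validate_config <- function(cfg) {
  need <- function(block, key, check = is.numeric) {
    v <- cfg[[block]][[key]]
    full <- paste(block, key, sep = ".")
    if (is.null(v) || !check(v))
      ck_config_error(sprintf("missing or invalid config key '%s'", full),
                      key = full)
    v
  }
  known <- c("simulate", "tmax", "predict_ss", "gen_tmax", "fit_k2",
             "ftir", "afm")
  stages <- cfg$stages
  if (is.null(stages)) stages <- "simulate"
  bad <- setdiff(stages, known)
  if (length(bad))
    ck_config_error(sprintf("unknown stage '%s' in config key 'stages'",
                            bad[1]), key = "stages")
  cfg$stages <- stages

  E0 <- need("enzyme", "E0")
  k2 <- need("rates", "k2")
  r <- cfg$rates
  cfg$rate_constants <-
    if (!is.null(r$k1E0) || !is.null(r$k3E0))
      rate_constants(k2 = k2, k1E0 = r$k1E0, k3E0 = r$k3E0, E0 = E0,
                     ka = if (is.null(r$ka)) 0 else r$ka)
    else
      rate_constants(k1 = need("rates", "k1"), k2 = k2,
                     k3 = need("rates", "k3"),
                     ka = if (is.null(r$ka)) 0 else r$ka)
  need("grid", "t_end_s")
  need("grid", "n_points")
  cfg
}

#' Run the configured analysis stages end to end
#'
#' Executes the requested stages in dependency order — trajectory
#' simulation, peak-time computation, secondary-structure prediction,
#' synthetic peak-time generation, `k2` fitting, FTIR generation +
#' processing, and AFM generation + summaries — writing each stage's
#' outputs as delimited text or JSON under `out_dir`, together with a
#' run manifest (`manifest.json`) recording the config hash, seed,
#' package version, per-stage outputs and timestamps. Re-running with
#' the same config and seed reproduces all outputs.
#'
#' @param config_path path to the YAML config.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed overriding the config's `seed` (default
#'   taken from the config, else 1).
#' @return The manifest, invisibly (class `run_manifest`).
#' @export
run_pipeline <- function(config_path, out_dir, seed = NULL) {
  cfg <- read_config(config_path)
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rc <- cfg$rate_constants
  model <- proteolysis_model(rc, cfg$enzyme$E0)
  times <- seq(0, cfg$grid$t_end_s, length.out = cfg$grid$n_points)
  outputs <- list()
  results <- list()
  t0 <- Sys.time()
  traj <- NULL

  stage <- function(name) name %in% cfg$stages
  get_traj <- function() {
    if (is.null(traj)) traj <<- trajectory(model, times)
    traj
  }

  if (stage("simulate")) {
    p <- file.path(out_dir, "trajectory.csv")
    write_trajectory_csv(get_traj(), p)
    outputs$simulate <- p
  }
  if (stage("tmax")) {
    results$tmax_s <- tmax(model)
    results$lag_time_s <- product_lag_time(get_traj())
  }
  if (stage("predict_ss")) {
    mode <- if (is.null(cfg$ss$mode)) "S+X/2+Y" else cfg$ss$mode
    ss <- secondary_structure(get_traj(), mode)
    p <- file.path(out_dir, "secondary_structure.csv")
    utils::write.csv(ss, p, row.names = FALSE)
    outputs$predict_ss <- p
  }
  if (stage("gen_tmax") || stage("fit_k2")) {
    fit_cfg <- cfg$fit
    E0s <- if (is.null(fit_cfg$E0)) c(0.125, 0.25, 0.5, 1) else
      as.numeric(fit_cfg$E0)
    sigma <- if (is.null(fit_cfg$sigma)) 0 else fit_cfg$sigma
    obs <- gen_tmax_dataset(rc, E0 = E0s, sigma = sigma, seed = seed)
    p <- file.path(out_dir, "tmax_observations.csv")
    write_tmax_csv(obs, p)
    outputs$gen_tmax <- p
    if (stage("fit_k2")) {
      fit <- fit_k2(obs, k1 = rc$k1, k3 = rc$k3)
      results$k2_fitted <- fit$k2
      results$k2_fit_rmse_s <- sqrt(mean(fit$residuals^2))
    }
  }
  if (stage("ftir")) {
    fcfg <- cfg$ftir
    gen <- gen_ftir_series(
      get_traj(),
      noise_sd = if (is.null(fcfg$noise_sd)) 0.002 else fcfg$noise_sd,
      seed = seed)
    p <- file.path(out_dir, "ftir_series.csv")
    write_series_csv(gen$series, p)
    outputs$ftir_series <- p
    proc <- process_reaction_series(gen$series, gen$enzyme)
    for (b in names(proc$traces)) {
      pb <- file.path(out_dir, sprintf("band_%s.csv", b))
      write_band_trace_csv(proc$traces[[b]], pb)
      outputs[[sprintf("band_%s", b)]] <- pb
    }
  }
  if (stage("afm")) {
    acfg <- cfg$afm
    ens <- gen_particle_ensemble(
      n = if (is.null(acfg$n)) 500 else acfg$n, seed = seed)
    p <- file.path(out_dir, "particles.csv")
    write_particles_csv(ens, p)
    outputs$afm <- p
    s <- summary(ens)
    results$afm_mean_D_nm <- s$mean_D
    results$afm_modes_nm <-
      height_histogram(ens, bin_width_nm = 0.2)$modes_nm
  }

  manifest <- structure(list(
    package = "casekin",
    version = as.character(utils::packageVersion("casekin")),
    config = normalizePath(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    stages = cfg$stages,
    outputs = outputs,
    results = results,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("casekin %s run (seed %d)\n", x$version, x$seed))
  cat(sprintf("  config %s (md5 %s)\n", x$config, x$config_md5))
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = ", ")))
  for (nm in names(x$outputs))
    cat(sprintf("  %-12s -> %s\n", nm, x$outputs[[nm]]))
  invisible(x)
}

#' Map a condition to a process exit code
#'
#' Convention used by the command-line wrapper: 0 success, 1 runtime
#' failure, 2 configuration error.
#'
#' @param cond a condition object, or `NULL` for success.
#' @return Integer exit code.
#' @export
exit_code_for <- function(cond = NULL) {
  if (is.null(cond)) return(0L)
  if (inherits(cond, "casekin_config_error")) return(2L)
  1L
}
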