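#' Read and validate a run configuration
#'
#' Configurations are YAML with one block per concern.  Unknown keys are
#' rejected (they are almost always typos), and every parameter block is
#' passed through its constructor so the type invariants hold before any
#' computation runs.
#'
#' Recognized top-level keys: `model`, `params` (sub-blocks `simplified`,
#' `two_compartment`, `blam`, `blam_dimensional`, `transport`), `initial`,
#' `schedule`, `simulation` (`horizon`, `n_out`, `rtol`, `atol`), `scan`
#' (`i_a_values`, `i_s_values`), `synthetic` (`sampling_interval`,
#' `replicates`, `antibiotic_levels`, `nutrient_levels`, `noise`:
#' `kind`/`scale`/`detection_floor`, `gain`), `fitting` (`free_params`,
#' `bounds`, `start`, `n_starts`), `seed`, `outdir`.
#'
#' @param path Path to a YAML configuration file.
#' @return An object of class `run_config`: the validated configuration
#'   with constructed parameter objects in `$objects`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_run_config(raw, source = path)
}

#' Validate an already-parsed configuration list
#'
#' @param raw A named list as produced by parsing the YAML config.
#' @param source Label used in error messages.
#' @return An object of class `run_config`.
#' @export
validate_run_config <- function(raw, source = "config") {
  known_top <- c("model", "params", "initial", "schedule", "simulation",
                 "scan", "synthetic", "fitting", "seed", "outdir")
  bad <- setdiff(names(raw), known_top)
  if (length(bad) > 0L) {
    stop(sprintf("%s: unknown key(s): %s", source,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  check_block <- function(block, known, label) {
    extra <- setdiff(names(block), known)
    if (length(extra) > 0L) {
      stop(sprintf("%s: unknown key(s) in `%s`: %s", source, label,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    block
  }
  models <- c("simplified", "two_compartment", "blam", "blam_dimensional",
              "swarmbot")
  if (is.null(raw$model) || !raw$model %in% models) {
    stop(sprintf("%s: `model` must be one of: %s", source,
                 paste(models, collapse = ", ")), call. = FALSE)
  }
  pb <- check_block(raw$params %||% list(),
                    c("simplified", "two_compartment", "blam",
                      "blam_dimensional", "transport"), "params")
  objects <- list()
  if (!is.null(pb$simplified)) {
    objects$simplified <- do.call(simplified_params, pb$simplified)
  }
  if (!is.null(pb$two_compartment)) {
    tc <- pb$two_compartment
    base <- if (is.null(tc$base)) objects$simplified %||% simplified_params()
            else do.call(simplified_params, tc$base)
    objects$two_compartment <- two_compartment_params(
      base = base, f_n_cells = tc$f_n_cells %||% 0.1,
      v_ratio = tc$v_ratio %||% 100)
  }
  objects$blam <- if (is.null(pb$blam)) blam_params()
                  else do.call(blam_params, pb$blam)
  objects$blam_dimensional <- if (is.null(pb$blam_dimensional)) NULL
    else do.call(blam_dimensional_params, pb$blam_dimensional)
  objects$transport <- if (is.null(pb$transport)) transport_params()
                       else do.call(transport_params, pb$transport)
  sb <- check_block(raw$schedule %||% list(),
                    c("mode", "d_pulse", "pulse_duration", "period",
                      "i_s", "i_a"), "schedule")
  objects$schedule <- do.call(dosing_schedule, sb)
  sim <- check_block(raw$simulation %||% list(),
                     c("horizon", "n_out", "rtol", "atol"), "simulation")
  check_block(raw$scan %||% list(), c("i_a_values", "i_s_values"), "scan")
  syn <- check_block(raw$synthetic %||% list(),
                     c("sampling_interval", "replicates", "noise", "gain",
                       "antibiotic_levels", "nutrient_levels"), "synthetic")
  if (!is.null(syn$noise)) {
    check_block(syn$noise, c("kind", "scale", "detection_floor"),
                "synthetic$noise")
    objects$noise <- do.call(noise_model, syn$noise)
  } else {
    objects$noise <- noise_model()
  }
  check_block(raw$fitting %||% list(),
              c("free_params", "bounds", "start", "n_starts"), "fitting")
  if (!is.null(raw$seed) &&
      (!is.numeric(raw$seed) || raw$seed != round(raw$seed))) {
    stop(sprintf("%s: `seed` must be an integer", source), call. = FALSE)
  }
  cfg <- raw
  cfg$seed <- as.integer(raw$seed %||% 1L)
  cfg$simulation <- utils::modifyList(
    list(horizon = 16, n_out = 200, rtol = 1e-8, atol = 1e-10), sim)
  cfg$objects <- objects
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve the model/parameter/initial-state triple of a config
#' @noRd
.config_sim_args <- function(config) {
  model <- config$model
  params <- switch(model,
    simplified = config$objects$simplified %||% simplified_params(),
    two_compartment = config$objects$two_compartment %||%
      two_compartment_params(),
    blam = config$objects$blam,
    blam_dimensional = config$objects$blam_dimensional %||%
      blam_dimensional_params(),
    swarmbot = config$objects$blam)
  initial <- as.numeric(config$initial %||% switch(model,
    simplified = 0.8,
    two_compartment = c(0.1, 0),
    blam = c(0.5, 10, 0.4, 0),
    blam_dimensional = c(0.5, 10, 0.08, 0),
    swarmbot = swarmbot_state(n1 = 0.5)))
  list(model = model, params = params, initial = initial,
       transport = if (model == "swarmbot") config$objects$transport,
       schedule = config$objects$schedule,
       horizon = config$simulation$horizon,
       n_out = config$simulation$n_out,
       rtol = config$simulation$rtol, atol = config$simulation$atol)
}

#' Echo the resolved configuration into the output directory
#' @noRd
.echo_config <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  keep <- unclass(config)
  keep$objects <- NULL
  yaml::write_yaml(keep, file.path(outdir, "config_used.yaml"))
}

#' Run a simulation from a configuration
#'
#' Thin, file-producing binding over [simulate_model()]: writes the tidy
#' trajectory CSV, its JSON parameter sidecar, and an echo of the resolved
#' configuration into `outdir`.
#'
#' @param config A `run_config` (or path to one).
#' @param outdir Output directory (created if needed); defaults to the
#'   config's `outdir` or `"."`.
#' @return Invisibly, the trajectory.
#' @export
run_simulate <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- outdir %||% config$outdir %||% "."
  args <- .config_sim_args(config)
  traj <- simulate_model(args$model, initial = args$initial,
                         params = args$params, horizon = args$horizon,
                         schedule = args$schedule,
                         transport = args$transport, n_out = args$n_out,
                         rtol = args$rtol, atol = args$atol)
  .echo_config(config, outdir)
  write_trajectory(traj, file.path(outdir, "trajectory.csv"))
  invisible(traj)
}

#' Run the steady-state analysis from a configuration
#'
#' Writes the fixed points and the critical threshold as JSON
#' (`steady_states.json`); when the config's `scan` block carries
#' `i_a_values` it is ignored here — the steady-state sweep instead uses
#' the simplified parameter block.
#'
#' @inheritParams run_simulate
#' @param k_values Optional ascending vector of survival-threshold values
#'   for a `K` sweep, written as `n_ct_vs_k.csv`.
#' @return Invisibly, the `steady_state_set`.
#' @export
run_steady_states <- function(config, outdir = NULL, k_values = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- outdir %||% config$outdir %||% "."
  p <- config$objects$simplified %||% simplified_params()
  ss <- find_steady_states(p)
  .echo_config(config, outdir)
  jsonlite::write_json(
    list(states = ss$states, n_ct = ss$n_ct, params = ss$params),
    file.path(outdir, "steady_states.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(k_values)) {
    utils::write.csv(n_ct_vs_k(k_values, p),
                     file.path(outdir, "n_ct_vs_k.csv"),
                     row.names = FALSE)
  }
  invisible(ss)
}

#' Run the phase-diagram scan from a configuration
#'
#' @inheritParams run_simulate
#' @return Invisibly, the `heatmap_grid`.
#' @export
run_heatmap <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- outdir %||% config$outdir %||% "."
  scan <- config$scan %||% list()
  i_a <- as.numeric(scan$i_a_values %||% seq(0, 3, length.out = 20))
  i_s <- as.numeric(scan$i_s_values %||% seq(1.5, 10, length.out = 20))
  grid <- scan_heatmap(i_a, i_s, p = config$objects$blam,
                       tp = config$objects$transport,
                       schedule = config$objects$schedule,
                       horizon = config$simulation$horizon,
                       rtol = config$simulation$rtol,
                       atol = config$simulation$atol)
  .echo_config(config, outdir)
  write_heatmap(grid, file.path(outdir, "heatmap.csv"))
  invisible(grid)
}

#' Generate synthetic datasets from a configuration
#'
#' @inheritParams run_simulate
#' @return Invisibly, the list of datasets; each is written as
#'   `dataset_<condition>_r<replicate>.csv` (+ JSON sidecar).
#' @export
run_generate_data <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- outdir %||% config$outdir %||% "."
  syn <- config$synthetic %||% list()
  sets <- generate_condition_matrix(
    antibiotic_levels = as.numeric(syn$antibiotic_levels %||% c(0, 0.5, 1)),
    nutrient_levels = as.numeric(syn$nutrient_levels %||% c(4, 10)),
    p = config$objects$blam, tp = config$objects$transport,
    schedule = config$objects$schedule,
    horizon = config$simulation$horizon,
    replicates = as.integer(syn$replicates %||% 1L),
    sampling_interval = as.numeric(syn$sampling_interval %||% 0.5),
    noise = config$objects$noise, seed = config$seed)
  .echo_config(config, outdir)
  for (ds in sets) {
    if (inherits(ds, "condition_failure")) next
    write_dataset(ds, file.path(outdir, sprintf(
      "dataset_%s_r%d.csv", ds$condition$id,
      ds$observations$replicate[1L])))
  }
  invisible(sets)
}

#' Fit the simplified model to a dataset file from a configuration
#'
#' Reads a dataset CSV written by [write_dataset()] (with its JSON
#' sidecar), reconstructs the observation set, runs [fit_simplified()]
#' with the config's `fitting` block, and writes `fit.json`.
#'
#' @inheritParams run_simulate
#' @param dataset Either a `synthetic_dataset` or the path to a dataset
#'   CSV produced by [write_dataset()].
#' @return Invisibly, the `fit_result`.
#' @export
run_fit <- function(config, dataset, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- outdir %||% config$outdir %||% "."
  if (is.character(dataset)) {
    if (!file.exists(dataset)) {
      stop(sprintf("dataset file not found: %s", dataset), call. = FALSE)
    }
    obs <- utils::read.csv(dataset, stringsAsFactors = FALSE)
    needed <- c("time", "compartment", "observed")
    missing_cols <- setdiff(needed, names(obs))
    if (length(missing_cols) > 0L) {
      stop(sprintf("dataset %s lacks column(s): %s", dataset,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    sidecar <- paste0(dataset, ".json")
    if (!file.exists(sidecar)) {
      stop(sprintf("dataset sidecar not found: %s", sidecar),
           call. = FALSE)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(meta$model, "simplified")) {
      stop("dataset was not generated from the 'simplified' model",
           call. = FALSE)
    }
    p <- do.call(simplified_params, as.list(meta$params$model_params))
    truth <- simulate_model("simplified", initial = meta$initial[1L],
                            params = p, horizon = max(obs$time))
    dataset <- structure(
      list(observations = obs, truth = truth,
           condition = list(id = meta$condition %||% "file"),
           noise = do.call(noise_model, as.list(meta$noise)),
           gain = meta$gain %||% 1, seed = meta$seed %||% NA_integer_),
      class = "synthetic_dataset")
  }
  fb <- config$fitting %||% list()
  fit <- fit_simplified(
    dataset,
    free_params = as.character(fb$free_params %||% c("mu", "survival_k")),
    bounds = fb$bounds, start = unlist(fb$start),
    n_starts = as.integer(fb$n_starts %||% 8L), seed = config$seed)
  .echo_config(config, outdir)
  jsonlite::write_json(
    list(estimates = as.list(fit$estimates), residual = fit$residual,
         converged = fit$converged, n_obs = fit$n_obs),
    file.path(outdir, "fit.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(fit)
}
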