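#' Observation noise model for synthetic fluorescence read-outs
#'
#' Fluorescence quantified from time-lapse microscopy is a density proxy
#' with noise that grows with signal, so the default is multiplicative
#' lognormal noise with a fixed coefficient of variation.  Additive
#' Gaussian noise is available as an alternative.  Values that fall below
#' the detection floor are censored to the floor.
#'
#' @param kind `"multiplicative"` (lognormal, `scale` = coefficient of
#'   variation) or `"additive"` (Gaussian, `scale` = standard deviation in
#'   density units).
#' @param scale Noise magnitude (>= 0).
#' @param detection_floor Censoring floor (>= 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative", "additive"),
                        scale = 0.05, detection_floor = 0) {
  kind <- match.arg(kind)
  if (!is.finite(scale) || scale < 0) stop("`scale` must be >= 0",
                                           call. = FALSE)
  if (!is.finite(detection_floor) || detection_floor < 0) {
    stop("`detection_floor` must be >= 0", call. = FALSE)
  }
  structure(list(kind = kind, scale = scale,
                 detection_floor = detection_floor),
            class = "noise_model")
}

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Sample noisy density observations from a trajectory
#'
#' Emulates the fluorescence read-out of a microfluidic time-lapse: the
#' cell-density state(s) of a trajectory are linearly interpolated onto a
#' regular imaging grid, scaled by a fluorescence `gain`, corrupted by the
#' noise model, and censored at the detection floor.  Given the same seed
#' the output is reproducible bit for bit.
#'
#' @param traj A `swarm_trajectory`.
#' @param sampling_interval Imaging interval (> 0, <= horizon), in the
#'   trajectory's time units.
#' @param noise A [noise_model()].
#' @param seed Integer seed for the observation noise.
#' @param gain Fluorescence units per density unit.
#' @param condition_id Optional label describing the condition.
#' @param replicate Replicate number recorded with the observations.
#' @return An object of class `synthetic_dataset`: list with
#'   `observations` (data frame `time`, `compartment`, `observed`,
#'   `condition_id`, `replicate`), `truth` (the trajectory), `condition`,
#'   `noise`, `gain`, `seed`.
#' @export
observe <- function(traj, sampling_interval, noise = noise_model(),
                    seed = 1L, gain = 1, condition_id = "condition_1",
                    replicate = 1L) {
  stopifnot(inherits(traj, "swarm_trajectory"),
            inherits(noise, "noise_model"))
  horizon <- max(traj$times)
  if (length(traj$times) < 2L) stop("trajectory is empty", call. = FALSE)
  if (!(sampling_interval > 0 && sampling_interval <= horizon)) {
    stop("`sampling_interval` must be in (0, horizon]", call. = FALSE)
  }
  layout <- .model_layout(traj$model)
  dens_cols <- which(layout$species == "n")
  grid <- seq(0, horizon, by = sampling_interval)
  obs_list <- lapply(dens_cols, function(j) {
    truth <- stats::approx(traj$times, traj$states[, j], xout = grid)$y
    data.frame(time = grid, compartment = layout$compartment[j],
               truth = truth, stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, obs_list)
  signal <- obs$truth * gain
  observed <- .with_seed(seed, {
    if (noise$scale == 0) {
      signal
    } else if (noise$kind == "multiplicative") {
      sdlog <- sqrt(log(1 + noise$scale^2))
      signal * stats::rlnorm(length(signal), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
    } else {
      signal + stats::rnorm(length(signal), sd = noise$scale)
    }
  })
  observed <- pmax(observed, noise$detection_floor)
  structure(
    list(observations = data.frame(
           time = obs$time, compartment = obs$compartment,
           observed = observed, condition_id = condition_id,
           replicate = replicate, stringsAsFactors = FALSE),
         truth = traj,
         condition = list(id = condition_id,
                          schedule = traj$params$schedule),
         noise = noise, gain = gain, seed = seed),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> '%s' replicate %s: %d observations (%s noise, scale %g, seed %d)\n",
              x$condition$id, x$observations$replicate[1L],
              nrow(x$observations), x$noise$kind, x$noise$scale, x$seed))
  invisible(x)
}

#' Synthetic observation sets over an antibiotic-by-nutrient matrix
#'
#' Emulates a condition-matrix experiment: one full two-compartment
#' swarmbot simulation per (antibiotic, nutrient) feed combination, each
#' observed `replicates` times with independent noise.  Replicates within a
#' condition share the underlying truth trajectory and differ only in
#' their noise draws.  All per-dataset seeds derive deterministically from
#' the master seed.
#'
#' @param antibiotic_levels,nutrient_levels Non-empty condition axes for
#'   the feed concentrations `i_a` and `i_s`.
#' @param p A [blam_params()] object.
#' @param tp A [transport_params()] object.
#' @param schedule A [dosing_schedule()] template whose `i_a`/`i_s` are
#'   replaced per condition.
#' @param initial A [swarmbot_state()]; nutrient components are reset to
#'   the condition's `i_s`.
#' @param horizon Integration horizon.
#' @param replicates Observation sets per condition (>= 1).
#' @param sampling_interval Imaging interval for [observe()].
#' @param noise A [noise_model()].
#' @param seed Master seed.
#' @param ... Passed on to [simulate_model()].
#' @return A list of `synthetic_dataset` objects; conditions whose
#'   simulation failed are recorded as entries of class
#'   `condition_failure` instead of aborting the matrix.
#' @export
generate_condition_matrix <- function(antibiotic_levels, nutrient_levels,
                                      p = blam_params(),
                                      tp = transport_params(),
                                      schedule = dosing_schedule("pulsing"),
                                      initial = swarmbot_state(n1 = 0.2),
                                      horizon = 16, replicates = 1L,
                                      sampling_interval = 0.5,
                                      noise = noise_model(), seed = 1L,
                                      ...) {
  if (length(antibiotic_levels) == 0L || length(nutrient_levels) == 0L) {
    stop("condition axes must be non-empty", call. = FALSE)
  }
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  out <- list()
  cond_idx <- 0L
  for (i_s in nutrient_levels) {
    for (i_a in antibiotic_levels) {
      cond_idx <- cond_idx + 1L
      cond_id <- sprintf("ia_%g_is_%g", i_a, i_s)
      sched <- dosing_schedule(schedule$mode, d_pulse = schedule$d_pulse,
                               pulse_duration = schedule$pulse_duration,
                               period = schedule$period,
                               i_s = i_s, i_a = i_a)
      init <- as.numeric(initial)
      init[c(2L, 6L)] <- i_s
      if (sched$mode == "static") init[c(3L, 7L)] <- i_a
      traj <- tryCatch(
        simulate_model("swarmbot", initial = init, params = p,
                       horizon = horizon, schedule = sched,
                       transport = tp, ...),
        error = function(e) e)
      if (inherits(traj, "error")) {
        out[[length(out) + 1L]] <- structure(
          list(condition_id = cond_id,
               message = conditionMessage(traj)),
          class = "condition_failure")
        next
      }
      for (r in seq_len(replicates)) {
        ds_seed <- (seed * 7919L + cond_idx * 101L + r) %% .Machine$integer.max
        out[[length(out) + 1L]] <- observe(
          traj, sampling_interval = sampling_interval, noise = noise,
          seed = as.integer(ds_seed), condition_id = cond_id,
          replicate = r)
      }
    }
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Tidy CSV of the observations plus a JSON sidecar (`<path>.json`) with
#' the truth parameters, noise specification and seed.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Output CSV path.
#' @return Invisibly, the two paths written.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  utils::write.csv(dataset$observations, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(model = dataset$truth$model,
         params = dataset$truth$params,
         initial = as.numeric(dataset$truth$states[1L, ]),
         noise = unclass(dataset$noise),
         gain = dataset$gain, seed = dataset$seed,
         condition = dataset$condition$id),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, json = sidecar))
}
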