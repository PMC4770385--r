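#' Model registry: state layout per model id
#' @noRd
.model_layout <- function(model) {
  switch(model,
    simplified = list(
      n_state = 1L, names = "n",
      compartment = "population", species = "n"),
    two_compartment = list(
      n_state = 2L, names = c("n_msb", "n_out"),
      compartment = c("inside", "outside"), species = c("n", "n")),
    blam = ,
    blam_dimensional = list(
      n_state = 4L, names = c("n", "s", "a", "b"),
      compartment = rep("culture", 4L), species = c("n", "s", "a", "b")),
    swarmbot = list(
      n_state = 8L,
      names = c("n1", "s1", "a1", "b1", "n2", "s2", "a2", "b2"),
      compartment = rep(c("inside", "outside"), each = 4L),
      species = rep(c("n", "s", "a", "b"), 2L)),
    stop(sprintf("unknown model '%s'", model), call. = FALSE)
  )
}

#' Simulate a swarmbot model over time
#'
#' Integrates one of the package's ODE systems with a stiff-capable solver
#' (`deSolve::ode`, method `"lsoda"`).  For a pulsing [dosing_schedule()]
#' the integration is segmented at every pulse on/off boundary so the
#' square-wave forcing is never stepped over; the dilution rate is constant
#' within each segment.  Output is sampled on a uniform grid plus all pulse
#' boundary instants.
#'
#' @param model One of `"simplified"`, `"two_compartment"`, `"blam"`,
#'   `"blam_dimensional"`, `"swarmbot"`.
#' @param initial Initial state: a single density (`"simplified"`), a pair
#'   `c(n_msb, n_out)` (`"two_compartment"`), `c(n, s, a, b)` (BlaM models)
#'   or a [swarmbot_state()] / 8-vector (`"swarmbot"`).
#' @param params The matching parameter object ([simplified_params()],
#'   [two_compartment_params()], [blam_params()] or
#'   [blam_dimensional_params()]).
#' @param horizon Integration horizon (> 0), in the model's time units.
#' @param schedule A [dosing_schedule()].  Only the `"swarmbot"` model is
#'   subject to perfusion; all other models require a static schedule.
#' @param transport A [transport_params()] object (`"swarmbot"` only).
#' @param n_out Number of uniform output intervals over the horizon.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param clip_negative Magnitude below which solver-induced negative state
#'   values are clamped to zero; values below `-raise_negative` signal a
#'   genuine error instead.
#' @param raise_negative Threshold for treating a negative state value as a
#'   real failure rather than roundoff.
#'
#' @return An object of class `swarm_trajectory`: a list with `times`
#'   (strictly increasing), `states` (one row per time, named columns),
#'   `model`, `params` (full parameter snapshot, including schedule and
#'   transport where applicable) and `solver` metadata.
#' @examples
#' p <- simplified_params()
#' traj <- simulate_model("simplified", initial = 0.8, params = p, horizon = 20)
#' tail(traj$states)
#' @export
simulate_model <- function(model, initial, params, horizon,
                     schedule = dosing_schedule("static"),
                     transport = NULL, n_out = 200,
                     rtol = 1e-8, atol = 1e-10,
                     clip_negative = 1e-12, raise_negative = 1e-9) {
  layout <- .model_layout(model)
  stopifnot(inherits(schedule, "dosing_schedule"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("`horizon` must be a single positive number", call. = FALSE)
  }
  y0 <- as.numeric(initial)
  if (length(y0) != layout$n_state || any(!is.finite(y0)) || any(y0 < 0)) {
    stop(sprintf("initial state for model '%s' must be %d finite non-negative values",
                 model, layout$n_state), call. = FALSE)
  }
  names(y0) <- layout$names
  if (model == "swarmbot") {
    if (is.null(transport)) {
      stop("the swarmbot model needs `transport` parameters", call. = FALSE)
    }
    stopifnot(inherits(transport, "transport_params"))
    stopifnot(inherits(params, "blam_params"))
  } else {
    if (schedule$mode != "static") {
      stop("pulsed dosing applies only to the 'swarmbot' model", call. = FALSE)
    }
    ok <- switch(model,
      simplified = inherits(params, "simplified_params"),
      two_compartment = inherits(params, "two_compartment_params"),
      blam = inherits(params, "blam_params"),
      blam_dimensional = inherits(params, "blam_dimensional_params"))
    if (!ok) stop(sprintf("parameter object does not match model '%s'", model),
                  call. = FALSE)
  }

  clip <- function(y) {
    if (any(y < -raise_negative)) {
      stop(sprintf("state went negative beyond tolerance (min %.3e)", min(y)),
           call. = FALSE)
    }
    y[y < clip_negative & y < 0] <- 0
    pmax(y, 0)
  }
  core <- switch(model,
    simplified = function(y, D) simplified_rate(y, params),
    two_compartment = function(y, D) two_compartment_rates(y, params),
    blam = function(y, D) blam_rhs(y, params),
    blam_dimensional = function(y, D) blam_dimensional_rhs(y, params),
    swarmbot = function(y, D) {
      swarmbot_rhs(y, params, transport, dosing_rate = D,
                   inputs = c(i_s = schedule$i_s, i_a = schedule$i_a))
    })

  grid <- seq(0, horizon, length.out = n_out + 1L)
  if (schedule$mode == "pulsing") {
    k <- seq(0L, ceiling(horizon / schedule$period))
    bounds <- sort(unique(c(k * schedule$period,
                            k * schedule$period + schedule$pulse_duration)))
    bounds <- bounds[bounds > 0 & bounds < horizon]
    segments <- c(0, bounds, horizon)
  } else {
    segments <- c(0, horizon)
  }
  sample_times <- sort(unique(c(grid, segments)))

  times_out <- 0
  states_out <- matrix(y0, nrow = 1L, dimnames = list(NULL, layout$names))
  y <- y0
  for (i in seq_len(length(segments) - 1L)) {
    t0 <- segments[[i]]
    t1 <- segments[[i + 1L]]
    # D is constant on the open segment; evaluate at its midpoint so
    # rounding in the boundary times cannot select the wrong phase
    D <- dilution_rate_at(schedule, (t0 + t1) / 2)
    seg_times <- sort(unique(c(t0, sample_times[sample_times > t0 &
                                                  sample_times < t1], t1)))
    sol <- tryCatch(
      deSolve::ode(
        y = y, times = seg_times,
        func = function(t, y, parms) list(core(clip(y), D)),
        parms = NULL, method = "lsoda", rtol = rtol, atol = atol),
      error = function(e) {
        stop(sprintf("solver failed in segment [%g, %g] for model '%s': %s",
                     t0, t1, model, conditionMessage(e)), call. = FALSE)
      })
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf("solver did not converge near time %g for model '%s'",
                   max(sol[, 1L]), model), call. = FALSE)
    }
    seg_states <- unname(sol[, -1L, drop = FALSE])
    seg_states[seg_states < 0 & seg_states > -raise_negative] <- 0
    if (any(seg_states < 0)) {
      stop(sprintf("state went negative beyond tolerance in segment [%g, %g]",
                   t0, t1), call. = FALSE)
    }
    keep <- sol[, 1L] > t0
    times_out <- c(times_out, sol[keep, 1L])
    states_out <- rbind(states_out, seg_states[keep, , drop = FALSE])
    y <- seg_states[nrow(seg_states), ]
    names(y) <- layout$names
  }
  colnames(states_out) <- layout$names

  snapshot <- list(model_params = unclass(params),
                   schedule = unclass(schedule))
  if (!is.null(transport)) snapshot$transport <- unclass(transport)
  structure(
    list(times = times_out, states = states_out, model = model,
         params = snapshot,
         solver = list(method = "lsoda", rtol = rtol, atol = atol,
                       n_segments = length(segments) - 1L,
                       n_out = n_out)),
    class = "swarm_trajectory"
  )
}

#' Terminal state of a trajectory
#'
#' @param traj A `swarm_trajectory`.
#' @return Named numeric vector: the state at the final time point.
#' @export
terminal_state <- function(traj) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  traj$states[nrow(traj$states), ]
}

#' Per-compartment cell densities of a two-compartment trajectory
#'
#' @param traj A `swarm_trajectory` from the `"two_compartment"` or
#'   `"swarmbot"` model.
#' @return A two-column matrix `inside`, `outside` of cell densities on the
#'   trajectory's time grid.
#' @export
compartment_densities <- function(traj) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  cols <- switch(traj$model,
    two_compartment = c("n_msb", "n_out"),
    swarmbot = c("n1", "n2"),
    stop("trajectory is not from a two-compartment model", call. = FALSE))
  out <- traj$states[, cols, drop = FALSE]
  colnames(out) <- c("inside", "outside")
  out
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  cat(sprintf("<swarm_trajectory> model '%s': %d time points over [0, %g]\n",
              x$model, length(x$times), max(x$times)))
  cat("  terminal state:",
      paste(sprintf("%s = %.4g", colnames(x$states), terminal_state(x)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x A `swarm_trajectory`.
#' @param row.names,optional Unused, present for the generic.
#' @param ... Unused.
#' @return A data frame with columns `time`, `compartment`, `species`,
#'   `value`.
#' @export
as.data.frame.swarm_trajectory <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  layout <- .model_layout(x$model)
  n_t <- length(x$times)
  data.frame(
    time = rep(x$times, times = layout$n_state),
    compartment = rep(layout$compartment, each = n_t),
    species = rep(layout$species, each = n_t),
    value = as.vector(x$states),
    stringsAsFactors = FALSE
  )
}

#' Write a trajectory to disk
#'
#' Writes the tidy long table as CSV and the full parameter snapshot plus
#' solver metadata as a JSON sidecar (`<path>.json`).
#'
#' @param traj A `swarm_trajectory`.
#' @param path Output CSV path.
#' @return Invisibly, the two paths written.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(model = traj$model, params = traj$params, solver = traj$solver),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, json = sidecar))
}
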