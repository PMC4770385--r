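#' Quantify safeguard from a two-compartment trajectory
#'
#' Computes the density difference \eqn{\Delta N(\tau)} between the capsule
#' interior and the chamber on the trajectory grid, its trapezoidal area
#' under the curve (AUC) over the horizon, and a categorical region label
#' from terminal densities:
#' \describe{
#'   \item{no_safeguard}{cells grow both inside and in the chamber;}
#'   \item{safeguard}{cells grow inside but not in the chamber;}
#'   \item{extinction}{cells grow in neither compartment.}
#' }
#' "Growing" means the terminal density reaches `grow_threshold` (a
#' fraction of carrying capacity).  When the terminal \eqn{\Delta N} still
#' exceeds `persist_threshold`, the safeguard is persistent — the AUC keeps
#' accumulating with the horizon ("AUC approaches infinity") — and the
#' `diverging` flag is set.
#'
#' @param traj A `swarm_trajectory` from a two-compartment model
#'   (`"two_compartment"` or `"swarmbot"`).
#' @param grow_threshold Terminal density (fraction of carrying capacity)
#'   above which a compartment counts as grown.
#' @param persist_threshold Terminal \eqn{\Delta N} above which the AUC is
#'   flagged as diverging.
#' @return An object of class `safeguard_result`: list with `delta_series`
#'   (data frame `time`, `delta`), `auc`, `diverging`, `region`, and the
#'   terminal densities.
#' @export
compute_safeguard <- function(traj, grow_threshold = 0.5,
                              persist_threshold = 0.3) {
  dens <- compartment_densities(traj)  # errors on single-compartment input
  delta <- dens[, "inside"] - dens[, "outside"]
  auc <- pracma::trapz(traj$times, delta)
  terminal <- dens[nrow(dens), ]
  grown_in <- terminal[["inside"]] >= grow_threshold
  grown_out <- terminal[["outside"]] >= grow_threshold
  region <- if (grown_in && grown_out) {
    "no_safeguard"
  } else if (grown_in && !grown_out) {
    "safeguard"
  } else {
    "extinction"
  }
  diverging <- region == "safeguard" &&
    delta[length(delta)] >= persist_threshold
  structure(
    list(delta_series = data.frame(time = traj$times, delta = delta),
         auc = auc, diverging = diverging, region = region,
         terminal_inside = terminal[["inside"]],
         terminal_outside = terminal[["outside"]],
         grow_threshold = grow_threshold,
         persist_threshold = persist_threshold),
    class = "safeguard_result"
  )
}

#' @export
print.safeguard_result <- function(x, ...) {
  cat(sprintf("<safeguard_result> region = %s, AUC = %.4g%s\n",
              x$region, x$auc, if (x$diverging) " (diverging)" else ""))
  cat(sprintf("  terminal densities: inside %.4g, outside %.4g\n",
              x$terminal_inside, x$terminal_outside))
  invisible(x)
}

#' Safeguard AUC as a function of the volume ratio
#'
#' Simulates the two-compartment simplified model once per volume ratio
#' from a capsule seeded at `initial[1]` and an (almost) empty chamber, and
#' reports the safeguard AUC, the diverging flag and the region.  Larger
#' chambers dilute escaped cells below their survival threshold, so the
#' AUC increases with \eqn{V_R} and eventually diverges.
#'
#' @param vr_values Ascending vector of positive volume ratios.
#' @param p A [two_compartment_params()] object; its own `v_ratio` is
#'   ignored in favour of `vr_values`.
#' @param initial Initial densities `c(n_msb, n_out)`.
#' @param horizon Integration horizon.
#' @param ... Passed on to [simulate_model()].
#' @return A data frame with columns `v_ratio`, `auc`, `diverging`,
#'   `region`.
#' @export
auc_vs_vr <- function(vr_values, p, initial = c(0.1, 0), horizon = 50,
                      ...) {
  stopifnot(inherits(p, "two_compartment_params"))
  if (any(vr_values <= 0)) stop("`vr_values` must be > 0", call. = FALSE)
  if (is.unsorted(vr_values)) stop("`vr_values` must be ascending",
                                   call. = FALSE)
  if (any(initial < 0)) stop("initial densities must be >= 0",
                             call. = FALSE)
  rows <- lapply(vr_values, function(vr) {
    pv <- two_compartment_params(base = p$base, f_n_cells = p$f_n_cells,
                                 v_ratio = vr)
    traj <- tryCatch(
      simulate_model("two_compartment", initial = initial, params = pv,
                     horizon = horizon, ...),
      error = function(e) {
        stop(sprintf("simulation failed at v_ratio = %g: %s", vr,
                     conditionMessage(e)), call. = FALSE)
      })
    sg <- compute_safeguard(traj)
    data.frame(v_ratio = vr, auc = sg$auc, diverging = sg$diverging,
               region = sg$region, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Phase diagram of safeguard over antibiotic and nutrient feed levels
#'
#' Runs one full two-compartment swarmbot simulation per
#' \eqn{(I_a, I_s)} grid cell under the pulsed dosing template, classifies
#' each cell with [compute_safeguard()], and assembles the three-region
#' phase diagram (no safeguard at low antibiotic, safeguard at intermediate
#' levels, extinction at high levels; the safeguard band narrows as the
#' nutrient feed rises).
#'
#' @param i_a_values,i_s_values Positive scan axes for the antibiotic and
#'   nutrient feed concentrations.
#' @param p A [blam_params()] object.
#' @param tp A [transport_params()] object.
#' @param schedule A pulsing [dosing_schedule()] template; its `i_s` and
#'   `i_a` are replaced cell by cell.
#' @param initial A [swarmbot_state()]; its `s1`/`s2` are reset to the
#'   cell's `i_s` so each condition starts in its own medium.
#' @param horizon Integration horizon.
#' @param grow_threshold,persist_threshold Passed to [compute_safeguard()].
#' @param ... Passed on to [simulate_model()].
#' @return An object of class `heatmap_grid`: list with the axes, an
#'   `auc` matrix (`i_a` in rows, `i_s` in columns), matching `region` and
#'   `diverging` matrices, a `failed` logical matrix (per-cell solver
#'   failures are recorded, not fatal) and the parameter snapshot.
#' @export
scan_heatmap <- function(i_a_values, i_s_values, p = blam_params(),
                         tp = transport_params(),
                         schedule = dosing_schedule("pulsing"),
                         initial = swarmbot_state(n1 = 0.2),
                         horizon = 24, grow_threshold = 0.5,
                         persist_threshold = 0.3, ...) {
  stopifnot(inherits(p, "blam_params"), inherits(tp, "transport_params"),
            inherits(schedule, "dosing_schedule"))
  if (length(i_a_values) == 0L || length(i_s_values) == 0L) {
    stop("scan axes must be non-empty", call. = FALSE)
  }
  if (any(i_a_values < 0) || any(i_s_values <= 0)) {
    stop("`i_a_values` must be >= 0 and `i_s_values` > 0", call. = FALSE)
  }
  n_a <- length(i_a_values)
  n_s <- length(i_s_values)
  auc <- matrix(NA_real_, n_a, n_s)
  region <- matrix(NA_character_, n_a, n_s)
  diverging <- matrix(FALSE, n_a, n_s)
  failed <- matrix(FALSE, n_a, n_s)
  for (j in seq_len(n_s)) {
    for (i in seq_len(n_a)) {
      sched <- dosing_schedule("pulsing", d_pulse = schedule$d_pulse,
                               pulse_duration = schedule$pulse_duration,
                               period = schedule$period,
                               i_s = i_s_values[j], i_a = i_a_values[i])
      init <- as.numeric(initial)
      init[c(2L, 6L)] <- i_s_values[j]
      res <- tryCatch({
        traj <- simulate_model("swarmbot", initial = init, params = p,
                               horizon = horizon, schedule = sched,
                               transport = tp, ...)
        compute_safeguard(traj, grow_threshold, persist_threshold)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed[i, j] <- TRUE
      } else {
        auc[i, j] <- res$auc
        region[i, j] <- res$region
        diverging[i, j] <- res$diverging
      }
    }
  }
  structure(
    list(i_a_values = i_a_values, i_s_values = i_s_values, auc = auc,
         region = region, diverging = diverging, failed = failed,
         params = list(model_params = unclass(p), transport = unclass(tp),
                       schedule = unclass(schedule),
                       initial = as.numeric(initial), horizon = horizon,
                       grow_threshold = grow_threshold,
                       persist_threshold = persist_threshold)),
    class = "heatmap_grid"
  )
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("<heatmap_grid> %d x %d (I_a x I_s) cells\n",
              length(x$i_a_values), length(x$i_s_values)))
  tab <- table(factor(x$region,
                      c("no_safeguard", "safeguard", "extinction")))
  cat("  regions:", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n")
  if (any(x$failed)) cat(sprintf("  %d cell(s) failed\n", sum(x$failed)))
  invisible(x)
}

#' Tidy long-format view of a phase-diagram grid
#'
#' @param x A `heatmap_grid`.
#' @param row.names,optional Unused, present for the generic.
#' @param ... Unused.
#' @return A data frame with columns `i_a`, `i_s`, `auc`, `region`,
#'   `diverging`.
#' @export
as.data.frame.heatmap_grid <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(
    i_a = rep(x$i_a_values, times = length(x$i_s_values)),
    i_s = rep(x$i_s_values, each = length(x$i_a_values)),
    auc = as.vector(x$auc),
    region = as.vector(x$region),
    diverging = as.vector(x$diverging),
    stringsAsFactors = FALSE
  )
}

#' Write a phase-diagram grid to disk
#'
#' Long-format CSV plus a JSON metadata sidecar (`<path>.json`) holding the
#' full parameter snapshot.
#'
#' @param grid A `heatmap_grid`.
#' @param path Output CSV path.
#' @return Invisibly, the two paths written.
#' @export
write_heatmap <- function(grid, path) {
  stopifnot(inherits(grid, "heatmap_grid"))
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(grid$params, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, json = sidecar))
}
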