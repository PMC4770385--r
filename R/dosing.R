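#' Medium dosing schedule
#'
#' Describes the perfusion of fresh medium into the chamber compartment.
#' Under the `"static"` mode the dilution rate \eqn{D(\tau)} is identically
#' zero.  Under the `"pulsing"` mode the chamber is infused in a square
#' wave: \eqn{D(\tau) = d_{pulse}} while \eqn{(\tau \bmod period)} lies in
#' the half-open window `[0, pulse_duration)` and 0 otherwise, mirroring a
#' programmable syringe pump that runs for a fixed time each cycle.  The
#' fresh medium carries nutrient at concentration `i_s` and antibiotic at
#' `i_a`.
#'
#' The default pulsing shape keeps the experimental duty cycle (on for one
#' sixth of each cycle, one cycle per half time unit) with a time-averaged
#' dilution rate of `d_pulse / 6`; see [pulse_schedule_physical()] to derive
#' rates from pump settings in physical units.
#'
#' @param mode `"static"` or `"pulsing"`.
#' @param d_pulse Dilution rate during a pulse (per unit time, >= 0).
#' @param pulse_duration Length of each infusion window (time units).
#' @param period Cycle length, pulse plus delay (time units).
#' @param i_s Nutrient concentration in the fresh medium.
#' @param i_a Antibiotic concentration in the fresh medium.
#'
#' @return An object of class `dosing_schedule`.
#' @examples
#' pulsed <- dosing_schedule("pulsing", d_pulse = 0.9,
#'                           pulse_duration = 1 / 12, period = 0.5,
#'                           i_s = 10, i_a = 0.5)
#' dilution_rate_at(pulsed, c(0, 0.05, 0.25, 0.5))
#' @export
dosing_schedule <- function(mode = c("static", "pulsing"), d_pulse = 0.9,
                            pulse_duration = 1 / 12, period = 0.5,
                            i_s = 10, i_a = 0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(d_pulse), is.numeric(pulse_duration),
            is.numeric(period), is.numeric(i_s), is.numeric(i_a))
  if (d_pulse < 0) stop("`d_pulse` must be >= 0", call. = FALSE)
  if (!(pulse_duration > 0 && pulse_duration <= period)) {
    stop("need 0 < pulse_duration <= period", call. = FALSE)
  }
  if (i_s < 0 || i_a < 0) stop("feed concentrations must be >= 0",
                               call. = FALSE)
  structure(
    list(mode = mode, d_pulse = d_pulse, pulse_duration = pulse_duration,
         period = period, i_s = i_s, i_a = i_a),
    class = "dosing_schedule"
  )
}

#' Instantaneous dilution rate of a dosing schedule
#'
#' @param schedule A [dosing_schedule()].
#' @param tau Time point(s), >= 0.
#' @return \eqn{D(\tau)}, vectorized over `tau`.  A pulse window is
#'   half-open, `[start, start + duration)`, so a time exactly on a pulse
#'   boundary takes the pulse-start value.
#' @export
dilution_rate_at <- function(schedule, tau) {
  stopifnot(inherits(schedule, "dosing_schedule"))
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop("`tau` must be finite and >= 0", call. = FALSE)
  }
  if (schedule$mode == "static") {
    return(rep(0, length(tau)))
  }
  phase <- tau %% schedule$period
  ifelse(phase < schedule$pulse_duration, schedule$d_pulse, 0)
}

#' Time-averaged dilution rate of a schedule
#'
#' @param schedule A [dosing_schedule()].
#' @return The cycle-averaged dilution rate (0 for static schedules).
#' @export
mean_dilution_rate <- function(schedule) {
  stopifnot(inherits(schedule, "dosing_schedule"))
  if (schedule$mode == "static") return(0)
  schedule$d_pulse * schedule$pulse_duration / schedule$period
}

#' Dilution rates from pump settings in physical units
#'
#' Converts a syringe-pump pulse program (flow rate, on-time, delay, device
#' volume) into the during-pulse dilution rate and the effective
#' (time-averaged) dilution rate of the culturing device.  For example,
#' perfusing 4 ul/min for 5 min of every 30-min cycle into a ~20 ul device
#' gives a during-pulse rate of 0.2/min and an effective rate of 2/h.
#'
#' @param flow_ul_min Pump flow rate during the pulse (ul/min).
#' @param pulse_min Pulse duration (min).
#' @param delay_min Delay between pulses (min).
#' @param volume_ul Device (reactor) volume (ul).
#' @return A list with `d_pulse_per_min`, `period_min`,
#'   `average_per_min` and `average_per_h`.
#' @examples
#' pulse_schedule_physical(4, 5, 25, 20)$average_per_h  # 2
#' @export
pulse_schedule_physical <- function(flow_ul_min, pulse_min, delay_min,
                                    volume_ul) {
  stopifnot(flow_ul_min > 0, pulse_min > 0, delay_min >= 0, volume_ul > 0)
  d_pulse <- flow_ul_min / volume_ul
  period <- pulse_min + delay_min
  avg <- d_pulse * pulse_min / period
  list(d_pulse_per_min = d_pulse, period_min = period,
       average_per_min = avg, average_per_h = 60 * avg)
}

#' @export
print.dosing_schedule <- function(x, ...) {
  if (x$mode == "static") {
    cat("Static dosing schedule: D(tau) = 0\n")
  } else {
    cat(sprintf(
      "Pulsing dosing schedule: D = %g for %g of every %g time units (mean %g)\n",
      x$d_pulse, x$pulse_duration, x$period, mean_dilution_rate(x)))
  }
  cat(sprintf("  feed: i_s = %g, i_a = %g\n", x$i_s, x$i_a))
  invisible(x)
}
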