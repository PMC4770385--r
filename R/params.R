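#' Parameters of the simplified collective-survival model
#'
#' The simplified model describes an engineered population whose growth is
#' logistic and whose per-capita death rate decreases with density through a
#' repressing Hill function:
#' \deqn{dN/dt = \mu N (1 - N/N_m) - d \frac{K^\alpha}{N^\alpha + K^\alpha} N}
#' With suitable parameters the model is bistable: extinction and a high
#' "survival" state are separated by an unstable threshold density
#' (the critical density, located by [find_steady_states()]).
#'
#' @param mu Maximum specific growth rate (per unit time).
#' @param n_max Carrying capacity \eqn{N_m} (density units).
#' @param death_max Maximum death rate \eqn{d} (per unit time), attained as
#'   the density approaches zero.
#' @param survival_k Critical threshold parameter \eqn{K} (density units):
#'   the density at which the death rate is half-maximal.
#' @param hill_alpha Hill coefficient \eqn{\alpha} (dimensionless, >= 1)
#'   controlling the steepness of density-dependent protection.
#'
#' @return An object of class `simplified_params`.
#' @examples
#' p <- simplified_params(mu = 1.75, n_max = 1, death_max = 2,
#'                        survival_k = 0.5, hill_alpha = 4)
#' simplified_rate(0.9, p)
#' @export
simplified_params <- function(mu = 1.75, n_max = 1, death_max = 2,
                              survival_k = 0.5, hill_alpha = 4) {
  stopifnot(
    is.numeric(mu), is.numeric(n_max), is.numeric(death_max),
    is.numeric(survival_k), is.numeric(hill_alpha)
  )
  vals <- c(mu = mu, n_max = n_max, death_max = death_max,
            survival_k = survival_k, hill_alpha = hill_alpha)
  if (any(!is.finite(vals))) {
    stop("all simplified-model parameters must be finite", call. = FALSE)
  }
  if (any(vals <= 0)) {
    stop("all simplified-model parameters must be > 0", call. = FALSE)
  }
  if (hill_alpha < 1) {
    stop("`hill_alpha` must be >= 1", call. = FALSE)
  }
  structure(
    list(mu = mu, n_max = n_max, death_max = death_max,
         survival_k = survival_k, hill_alpha = hill_alpha),
    class = "simplified_params"
  )
}

#' Parameters of the two-compartment simplified model
#'
#' Extends [simplified_params()] with passive cell exchange between a small
#' capsule compartment (the swarmbot interior, volume \eqn{V_1}) and a large
#' chamber compartment (volume \eqn{V_2}).  Transport is proportional to the
#' density gradient; the chamber sees the flux scaled by \eqn{1/V_R} where
#' \eqn{V_R = V_2/V_1}.
#'
#' @param base A [simplified_params()] object shared by both compartments.
#' @param f_n_cells Cell transport rate constant \eqn{f_N} (per unit time,
#'   >= 0) across the capsule shell.
#' @param v_ratio Volume ratio \eqn{V_R = V_2/V_1} (> 0).
#'
#' @return An object of class `two_compartment_params`.
#' @examples
#' p <- two_compartment_params(
#'   base = simplified_params(survival_k = 0.01),
#'   f_n_cells = 0.1, v_ratio = 100)
#' two_compartment_rates(c(0.1, 0), p)
#' @export
two_compartment_params <- function(base = simplified_params(survival_k = 0.01),
                                   f_n_cells = 0.1, v_ratio = 100) {
  if (!inherits(base, "simplified_params")) {
    stop("`base` must be a simplified_params object", call. = FALSE)
  }
  stopifnot(is.numeric(f_n_cells), is.numeric(v_ratio))
  if (!is.finite(f_n_cells) || f_n_cells < 0) {
    stop("`f_n_cells` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(v_ratio) || v_ratio <= 0) {
    stop("`v_ratio` must be finite and > 0", call. = FALSE)
  }
  structure(
    list(base = base, f_n_cells = f_n_cells, v_ratio = v_ratio),
    class = "two_compartment_params"
  )
}

#' Dimensional parameters of the full BlaM circuit model
#'
#' The full model tracks cell density \eqn{N}, nutrient \eqn{S}, antibiotic
#' (carbenicillin) \eqn{A} and extracellular beta-lactamase \eqn{B}.  Growth
#' follows Monod kinetics in \eqn{S} with a logistic capacity term; lysis by
#' the beta-lactam increases with the growth rate (cell-wall synthesis is the
#' drug target) and only occurs above a growth-rate threshold; lysed cells
#' release BlaM, which degrades the antibiotic extracellularly by
#' Michaelis-Menten kinetics.
#'
#' Note that `alpha_consume` (the nutrient consumption yield) is unrelated to
#' the Hill coefficient `hill_alpha` of [simplified_params()]; the two models
#' use the same Greek letter for different quantities and the field names keep
#' them apart.
#'
#' @param mu_max Maximum growth rate (per hour).
#' @param k_s Monod half-saturation constant for growth (nutrient units).
#' @param n_m Carrying capacity (density units).
#' @param d_a_max Maximum antibiotic-mediated lysis rate (per hour).
#' @param k_lysis Half-saturation antibiotic concentration for lysis.
#' @param g0_frac Fraction of `mu_max` below which growth is too slow for
#'   lysis to occur (0 <= g0_frac < 1).
#' @param alpha_consume Nutrient consumed per unit of growth per cell.
#' @param k_release Nutrient released per lysed cell.
#' @param v_max Catalytic rate constant of antibiotic degradation by BlaM.
#' @param k_amp Half-saturation antibiotic concentration for the enzymatic
#'   reaction.
#' @param d_b First-order decay rate of BlaM (per hour).
#' @param k_bla BlaM synthesis-and-release rate constant (enzyme per lysed
#'   cell).
#'
#' @return An object of class `blam_dimensional_params`.
#' @seealso [nondimensionalize()] for the mapping onto [blam_params()].
#' @export
blam_dimensional_params <- function(mu_max = 1, k_s = 1, n_m = 1,
                                    d_a_max = 7.69, k_lysis = 0.2,
                                    g0_frac = 0.2, alpha_consume = 2,
                                    k_release = 0.2, v_max = 1,
                                    k_amp = 0.2, d_b = 0.35, k_bla = 0.26) {
  vals <- c(mu_max = mu_max, k_s = k_s, n_m = n_m, d_a_max = d_a_max,
            k_lysis = k_lysis, alpha_consume = alpha_consume,
            k_release = k_release, v_max = v_max, k_amp = k_amp,
            d_b = d_b, k_bla = k_bla)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all BlaM rates and half-constants must be finite and > 0",
         call. = FALSE)
  }
  if (!is.finite(g0_frac) || g0_frac < 0 || g0_frac >= 1) {
    stop("`g0_frac` must satisfy 0 <= g0_frac < 1", call. = FALSE)
  }
  structure(
    list(mu_max = mu_max, k_s = k_s, n_m = n_m, d_a_max = d_a_max,
         k_lysis = k_lysis, g0_frac = g0_frac,
         alpha_consume = alpha_consume, k_release = k_release,
         v_max = v_max, k_amp = k_amp, d_b = d_b, k_bla = k_bla),
    class = "blam_dimensional_params"
  )
}

#' Dimensionless parameters of the full BlaM circuit model
#'
#' Dimensionless form of the BlaM model with state
#' \eqn{(n, s, a, b)} (density, nutrient, antibiotic, enzyme) evolving in
#' rescaled time \eqn{\tau}:
#' \deqn{g = \frac{s}{1+s}(1-n), \qquad
#'       l = \max\!\big(\sigma \tfrac{a}{1+a} (g - g_0),\, 0\big)}
#' \deqn{dn/d\tau = g n - \gamma_1 l n, \quad
#'       ds/d\tau = -\gamma_2 g n + \beta_1 \gamma_1 l n, \quad
#'       da/d\tau = -\frac{b a}{1+a}, \quad
#'       db/d\tau = -\gamma_3 b + \beta_2 \gamma_1 l n}
#'
#' The default values are the package's documented base set, chosen so the
#' model reproduces the qualitative behaviour of the circuit: bistable
#' (density-dependent) survival at antibiotic level `a = 0.4`, unconditional
#' growth without antibiotic, and a low-density growth threshold near
#' `a = 0.2`.  See the package vignette for the calibration rationale.
#'
#' @param gamma1 Lysis rate group \eqn{\gamma_1} (maximum kill rate relative
#'   to the growth rate scale).
#' @param gamma2 Nutrient consumption group \eqn{\gamma_2}.
#' @param gamma3 Enzyme decay group \eqn{\gamma_3}.
#' @param beta1 Nutrient-release-on-lysis yield \eqn{\beta_1}.
#' @param beta2 Enzyme-release-on-lysis yield \eqn{\beta_2}.  Setting
#'   `beta2 = 0` models a strain without the BlaM circuit (no antibiotic
#'   degradation).
#' @param sigma Lysis efficiency \eqn{\sigma}.
#' @param g0 Dimensionless growth-rate threshold \eqn{g_0} below which no
#'   lysis occurs (0 <= g0 < 1).
#'
#' @return An object of class `blam_params`.
#' @examples
#' p <- blam_params()
#' blam_rhs(c(n = 0.5, s = 10, a = 0.4, b = 0), p)
#' @export
blam_params <- function(gamma1 = 7.69, gamma2 = 2, gamma3 = 0.35,
                        beta1 = 0.2, beta2 = 1.3, sigma = 1, g0 = 0.2) {
  vals <- c(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
            beta1 = beta1, beta2 = beta2, sigma = sigma, g0 = g0)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all dimensionless BlaM parameters must be finite and >= 0",
         call. = FALSE)
  }
  if (g0 >= 1) stop("`g0` must be < 1", call. = FALSE)
  structure(as.list(vals), class = "blam_params")
}

#' Membrane transport parameters for the two-compartment swarmbot model
#'
#' Transport of each species across the capsule shell is proportional to its
#' concentration gradient between the capsule interior (compartment 1) and
#' the chamber (compartment 2); the chamber-side flux is scaled by
#' \eqn{1/V_R}.  Rate constants reflect molecular size: cells are orders of
#' magnitude larger than nutrient, antibiotic or enzyme molecules, so
#' `f_n <= f_b` and `f_n <= f_a`, `f_n <= f_s`; the enzyme (a protein) is
#' larger than the small molecules, so `f_b <= f_s`.
#'
#' @param f_n Cell escape/transport rate constant (per dimensionless time).
#' @param f_s Nutrient transport rate constant.
#' @param f_a Antibiotic transport rate constant.
#' @param f_b Enzyme (BlaM) transport rate constant.
#' @param v_ratio Volume ratio \eqn{V_R = V_2/V_1} of chamber to capsule.
#'
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(f_n = 0.05, f_s = 0.3, f_a = 0.2, f_b = 0.3,
                             v_ratio = 10) {
  vals <- c(f_n = f_n, f_s = f_s, f_a = f_a, f_b = f_b)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all transport rate constants must be finite and >= 0",
         call. = FALSE)
  }
  if (!(f_n <= f_b && f_b <= f_s && f_n <= f_a)) {
    stop("transport rates must respect molecular size: f_n <= f_b <= f_s and f_n <= f_a",
         call. = FALSE)
  }
  if (!is.finite(v_ratio) || v_ratio <= 0) {
    stop("`v_ratio` must be finite and > 0", call. = FALSE)
  }
  structure(list(f_n = f_n, f_s = f_s, f_a = f_a, f_b = f_b,
                 v_ratio = v_ratio),
            class = "transport_params")
}

#' Full two-compartment state vector
#'
#' Builds a named, validated 8-component state for the swarmbot model:
#' cell density, nutrient, antibiotic and enzyme inside the capsule
#' (`n1, s1, a1, b1`) and in the chamber (`n2, s2, a2, b2`), all
#' dimensionless.
#'
#' @param n1,s1,a1,b1 Capsule-interior cell density, nutrient, antibiotic
#'   and BlaM concentration.
#' @param n2,s2,a2,b2 The same quantities in the chamber.
#'
#' @return A named numeric vector of class `swarmbot_state`.
#' @export
swarmbot_state <- function(n1 = 0, s1 = 10, a1 = 0, b1 = 0,
                           n2 = 0, s2 = 10, a2 = 0, b2 = 0) {
  x <- c(n1 = n1, s1 = s1, a1 = a1, b1 = b1,
         n2 = n2, s2 = s2, a2 = a2, b2 = b2)
  if (any(!is.finite(x))) stop("state must be finite", call. = FALSE)
  if (any(x < 0)) stop("state must be componentwise >= 0", call. = FALSE)
  structure(x, class = c("swarmbot_state", "numeric"))
}

#' @export
print.simplified_params <- function(x, ...) {
  cat("Simplified collective-survival model parameters\n")
  cat(sprintf("  mu = %g, n_max = %g, death_max = %g, survival_k = %g, hill_alpha = %g\n",
              x$mu, x$n_max, x$death_max, x$survival_k, x$hill_alpha))
  invisible(x)
}

#' @export
print.blam_params <- function(x, ...) {
  cat("Dimensionless BlaM circuit parameters\n")
  cat(sprintf("  gamma1 = %g, gamma2 = %g, gamma3 = %g\n",
              x$gamma1, x$gamma2, x$gamma3))
  cat(sprintf("  beta1 = %g, beta2 = %g, sigma = %g, g0 = %g\n",
              x$beta1, x$beta2, x$sigma, x$g0))
  invisible(x)
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Capsule-shell transport parameters\n")
  cat(sprintf("  f_n = %g, f_s = %g, f_a = %g, f_b = %g, v_ratio = %g\n",
              x$f_n, x$f_s, x$f_a, x$f_b, x$v_ratio))
  invisible(x)
}
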