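#' Rate of change of density in the simplified collective-survival model
#'
#' Evaluates
#' \eqn{\mu n (1 - n/N_m) - d\, K^\alpha/(n^\alpha + K^\alpha)\, n}:
#' logistic growth minus a death term whose per-capita rate is maximal at
#' low density and repressed (Hill-wise) at high density, the mechanism
#' behind density-dependent ("collective") survival.
#'
#' @param n Population density (>= 0); may be a vector.
#' @param p A [simplified_params()] object.
#' @return The time derivative of the density, same length as `n`.
#' @export
simplified_rate <- function(n, p) {
  stopifnot(inherits(p, "simplified_params"))
  if (any(!is.finite(n))) stop("`n` must be finite", call. = FALSE)
  if (any(n < 0)) stop("`n` must be >= 0", call. = FALSE)
  ka <- p$survival_k^p$hill_alpha
  p$mu * n * (1 - n / p$n_max) -
    p$death_max * ka / (n^p$hill_alpha + ka) * n
}

#' Rates for the two-compartment simplified model
#'
#' Both compartments obey the simplified collective-survival dynamics on
#' their local density; cells additionally cross the capsule shell at a rate
#' proportional to the density gradient.  The capsule (density `n_msb`)
#' loses \eqn{f_N (N_{MSB} - N_{Out})}; the chamber (density `n_out`)
#' gains the same flux scaled by \eqn{1/V_R}, so the volume-weighted total
#' cell count is conserved by transport.
#'
#' @param state Numeric vector `c(n_msb, n_out)` of capsule and chamber
#'   densities (>= 0).
#' @param p A [two_compartment_params()] object.
#' @return Numeric vector `c(dn_msb, dn_out)`.
#' @export
two_compartment_rates <- function(state, p) {
  stopifnot(inherits(p, "two_compartment_params"))
  if (length(state) != 2L || any(!is.finite(state))) {
    stop("`state` must be two finite densities", call. = FALSE)
  }
  if (any(state < 0)) stop("densities must be >= 0", call. = FALSE)
  n_msb <- state[[1L]]
  n_out <- state[[2L]]
  flux <- p$f_n_cells * (n_msb - n_out)
  c(simplified_rate(n_msb, p$base) - flux,
    simplified_rate(n_out, p$base) + flux / p$v_ratio)
}

#' Dimensionless growth rate of the BlaM model
#'
#' Monod kinetics in the nutrient with a logistic capacity factor:
#' \eqn{g = s/(1+s)\,(1-n)}.
#'
#' @param s Dimensionless nutrient concentration (>= 0).
#' @param n Dimensionless cell density (>= 0).
#' @return The dimensionless specific growth rate `g`.
#' @export
blam_growth <- function(s, n) {
  if (any(!is.finite(s)) || any(!is.finite(n))) {
    stop("`s` and `n` must be finite", call. = FALSE)
  }
  if (any(s < 0) || any(n < 0)) {
    stop("`s` and `n` must be >= 0", call. = FALSE)
  }
  s / (1 + s) * (1 - n)
}

#' Dimensionless lysis rate of the BlaM model
#'
#' Beta-lactams kill growing cells: the lysis rate saturates in the
#' antibiotic and scales with the excess of the growth rate over a
#' threshold, \eqn{l = \max(\sigma\, a/(1+a)\,(g - g_0),\, 0)}.  Because
#' the saturation factor is non-negative this equals
#' \eqn{\sigma\, a/(1+a)\, \max(g - g_0, 0)}: no lysis without antibiotic
#' or below the growth threshold.
#'
#' @param a Dimensionless antibiotic concentration (>= 0).
#' @param g Dimensionless growth rate, e.g. from [blam_growth()].  Negative
#'   values (density above carrying capacity) are admissible and give zero
#'   lysis.
#' @param p A [blam_params()] object (uses `sigma` and `g0`).
#' @return The dimensionless lysis rate `l`.
#' @export
blam_lysis <- function(a, g, p) {
  stopifnot(inherits(p, "blam_params"))
  if (any(!is.finite(a)) || any(!is.finite(g))) {
    stop("`a` and `g` must be finite", call. = FALSE)
  }
  if (any(a < 0)) {
    stop("`a` must be >= 0", call. = FALSE)
  }
  pmax(p$sigma * a / (1 + a) * (g - p$g0), 0)
}

#' Right-hand side of the dimensionless single-compartment BlaM model
#'
#' @param state Numeric vector `c(n, s, a, b)`: cell density, nutrient,
#'   antibiotic, enzyme; componentwise >= 0.
#' @param p A [blam_params()] object.
#' @return Numeric vector of the four time derivatives
#'   `c(dn, ds, da, db)` with respect to dimensionless time.
#' @export
blam_rhs <- function(state, p) {
  stopifnot(inherits(p, "blam_params"))
  if (length(state) != 4L || any(!is.finite(state))) {
    stop("`state` must be four finite components (n, s, a, b)",
         call. = FALSE)
  }
  if (any(state < 0)) stop("state must be >= 0", call. = FALSE)
  n <- state[[1L]]; s <- state[[2L]]; a <- state[[3L]]; b <- state[[4L]]
  g <- blam_growth(s, n)
  l <- blam_lysis(a, g, p)
  c(g * n - p$gamma1 * l * n,
    -p$gamma2 * g * n + p$beta1 * p$gamma1 * l * n,
    -b * a / (1 + a),
    -p$gamma3 * b + p$beta2 * p$gamma1 * l * n)
}

#' Right-hand side of the dimensional single-compartment BlaM model
#'
#' Growth is Monod-logistic, \eqn{G = \mu_{max} S/(K_s+S)\,(1-N/N_m)};
#' lysis is
#' \eqn{L = d_A\, A/(K_{lysis}+A)\, \max((G - G_0)/\mu_{max}, 0)} with
#' \eqn{G_0 =} `g0_frac` \eqn{\cdot \mu_{max}}; the state evolves as
#' \eqn{dN/dt = GN - LN}, \eqn{dS/dt = -\alpha G N + k_r L N},
#' \eqn{dA/dt = -v_{max} B A/(K_{amp}+A)}, \eqn{dB/dt = -d_B B + k_{bla} L N}.
#'
#' @param state Numeric vector `c(N, S, A, B)`; componentwise >= 0.
#' @param p A [blam_dimensional_params()] object.
#' @return Numeric vector of the four time derivatives (per hour).
#' @seealso [nondimensionalize()] for the correspondence with [blam_rhs()].
#' @export
blam_dimensional_rhs <- function(state, p) {
  stopifnot(inherits(p, "blam_dimensional_params"))
  if (length(state) != 4L || any(!is.finite(state))) {
    stop("`state` must be four finite components (N, S, A, B)",
         call. = FALSE)
  }
  if (any(state < 0)) stop("state must be >= 0", call. = FALSE)
  N <- state[[1L]]; S <- state[[2L]]; A <- state[[3L]]; B <- state[[4L]]
  G <- p$mu_max * S / (p$k_s + S) * (1 - N / p$n_m)
  L <- p$d_a_max * A / (p$k_lysis + A) *
    max(G / p$mu_max - p$g0_frac, 0)
  c(G * N - L * N,
    -p$alpha_consume * G * N + p$k_release * L * N,
    -p$v_max * B * A / (p$k_amp + A),
    -p$d_b * B + p$k_bla * L * N)
}

#' Map dimensional BlaM parameters onto the dimensionless groups
#'
#' Applies the scalings \eqn{n = N/N_m}, \eqn{s = S/K_s},
#' \eqn{a = A/K_{amp}}, \eqn{b = v_{max} B / (\mu_{max} K_{amp})},
#' \eqn{\tau = \mu_{max} t}, under the closure assumption
#' \eqn{K_{lysis} = K_{amp}} (required for the lysis saturation to reduce to
#' \eqn{a/(1+a)}).  The resulting groups are
#' \eqn{\gamma_1 = d_A/\mu_{max}} (with \eqn{\sigma = 1}),
#' \eqn{\gamma_2 = \alpha N_m / K_s},
#' \eqn{\gamma_3 = d_B/\mu_{max}},
#' \eqn{\beta_1 = k_r N_m / K_s},
#' \eqn{\beta_2 = k_{bla} v_{max} N_m / (\mu_{max} K_{amp})}.
#' Dimensional and dimensionless trajectories then coincide after rescaling,
#' which [simulate_model()] users can verify directly (and the package tests do).
#'
#' @param p A [blam_dimensional_params()] object.
#' @param tol Relative tolerance for the `k_lysis == k_amp` closure check.
#' @return A list with elements `params` (a [blam_params()] object) and
#'   `scales` (named vector `n`, `s`, `a`, `b`, `time`: divide dimensional
#'   state/time by these to obtain dimensionless ones).
#' @export
nondimensionalize <- function(p, tol = 1e-8) {
  stopifnot(inherits(p, "blam_dimensional_params"))
  if (abs(p$k_lysis - p$k_amp) > tol * max(p$k_lysis, p$k_amp)) {
    stop("mapping requires k_lysis = k_amp so both saturations share one antibiotic scale",
         call. = FALSE)
  }
  dimensionless <- blam_params(
    gamma1 = p$d_a_max / p$mu_max,
    gamma2 = p$alpha_consume * p$n_m / p$k_s,
    gamma3 = p$d_b / p$mu_max,
    beta1 = p$k_release * p$n_m / p$k_s,
    beta2 = p$k_bla * p$v_max * p$n_m / (p$mu_max * p$k_amp),
    sigma = 1,
    g0 = p$g0_frac
  )
  scales <- c(n = p$n_m, s = p$k_s, a = p$k_amp,
              b = p$mu_max * p$k_amp / p$v_max, time = 1 / p$mu_max)
  list(params = dimensionless, scales = scales)
}

#' Right-hand side of the full two-compartment swarmbot model
#'
#' Each compartment runs the dimensionless BlaM dynamics on its local state.
#' Transport across the capsule shell adds \eqn{f_x (x_2 - x_1)} to each
#' capsule species and \eqn{(f_x/V_R)(x_1 - x_2)} to the corresponding
#' chamber species.  Pulsed medium perfusion dilutes every chamber species
#' at rate `dosing_rate` and replenishes only nutrient and antibiotic at
#' their feed concentrations `i_s` and `i_a`; the capsule interior is
#' shielded from the flow.
#'
#' @param state A [swarmbot_state()] (or named vector
#'   `n1, s1, a1, b1, n2, s2, a2, b2`), componentwise >= 0.
#' @param p A [blam_params()] object.
#' @param tp A [transport_params()] object.
#' @param dosing_rate Instantaneous dilution rate \eqn{D(\tau)} (>= 0).
#' @param inputs Named numeric vector or list with feed concentrations
#'   `i_s` (nutrient) and `i_a` (antibiotic).
#' @return Numeric vector of the eight time derivatives, in state order.
#' @export
swarmbot_rhs <- function(state, p, tp, dosing_rate = 0,
                         inputs = c(i_s = 10, i_a = 0)) {
  stopifnot(inherits(p, "blam_params"), inherits(tp, "transport_params"))
  if (length(state) != 8L || any(!is.finite(state))) {
    stop("`state` must be eight finite components", call. = FALSE)
  }
  if (any(state < 0)) stop("state must be >= 0", call. = FALSE)
  if (!is.finite(dosing_rate) || dosing_rate < 0) {
    stop("`dosing_rate` must be finite and >= 0", call. = FALSE)
  }
  inputs <- as.list(inputs)
  i_s <- inputs$i_s
  i_a <- inputs$i_a
  x1 <- state[1:4]
  x2 <- state[5:8]
  local1 <- blam_rhs(x1, p)
  local2 <- blam_rhs(x2, p)
  f <- c(tp$f_n, tp$f_s, tp$f_a, tp$f_b)
  flux <- f * (x2 - x1)                  # into compartment 1
  d1 <- local1 + flux
  d2 <- local2 - flux / tp$v_ratio - dosing_rate * x2
  d2[2L] <- d2[2L] + dosing_rate * i_s
  d2[3L] <- d2[3L] + dosing_rate * i_a
  c(d1, d2)
}
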