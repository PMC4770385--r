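#' Classify the stability of a fixed point of the simplified model
#'
#' A fixed point is stable when the derivative of the rate function is
#' negative there, unstable when positive.  Near-zero derivatives (within
#' `deriv_tol`) indicate a tangency (saddle-node boundary) and are labelled
#' `"degenerate"` rather than silently assigned.
#'
#' @param n_star A root of [simplified_rate()] (residual below
#'   `residual_tol`).
#' @param p A [simplified_params()] object.
#' @param residual_tol Maximum admissible |rate| at `n_star`.
#' @param deriv_tol Derivative magnitude below which the root is
#'   degenerate.
#' @return One of `"stable"`, `"unstable"`, `"degenerate"`.
#' @export
classify_stability <- function(n_star, p, residual_tol = 1e-8,
                               deriv_tol = 1e-8) {
  stopifnot(inherits(p, "simplified_params"))
  if (abs(simplified_rate(max(n_star, 0), p)) > residual_tol) {
    stop(sprintf("n_star = %g is not a fixed point (|rate| > %g)",
                 n_star, residual_tol), call. = FALSE)
  }
  h <- max(1e-7 * p$n_max, 1e-10)
  lo <- max(n_star - h, 0)
  deriv <- (simplified_rate(n_star + h, p) - simplified_rate(lo, p)) /
    (n_star + h - lo)
  if (abs(deriv) < deriv_tol) return("degenerate")
  if (deriv < 0) "stable" else "unstable"
}

#' Locate and classify all steady states of the simplified model
#'
#' Scans the rate function on a dense grid over the search interval, finds
#' every sign change, refines each bracket with `stats::uniroot` to
#' within `refine_tol`, and classifies each root by the sign of the rate
#' derivative.  The extinction state 0 is always a fixed point and is
#' always included.  When the system is bistable (exactly three states),
#' the middle, unstable one is the critical survival threshold and is
#' returned as `n_ct`.
#'
#' @param p A [simplified_params()] object.
#' @param interval Search interval; must cover `[0, n_max]`.  Default
#'   `c(0, 1.05 * n_max)`.
#' @param n_grid Number of scan points (dense, because Hill-steepened rate
#'   functions can have closely spaced roots).
#' @param refine_tol Absolute tolerance of the root refinement.
#' @return An object of class `steady_state_set`: a list with `states`
#'   (data frame of `density` and `stability`, sorted ascending), `n_ct`
#'   (the unstable threshold density, or `NA` if the system is not
#'   bistable) and `params`.
#' @examples
#' find_steady_states(simplified_params(mu = 1.75, death_max = 2,
#'                                      survival_k = 0.5, hill_alpha = 4))
#' @export
find_steady_states <- function(p, interval = NULL, n_grid = 4096,
                               refine_tol = 1e-10) {
  stopifnot(inherits(p, "simplified_params"))
  if (is.null(interval)) interval <- c(0, 1.05 * p$n_max)
  if (interval[1L] > 0 || interval[2L] < p$n_max) {
    stop("search interval must cover [0, n_max]", call. = FALSE)
  }
  grid <- seq(interval[1L], interval[2L], length.out = n_grid)
  vals <- simplified_rate(grid, p)

  roots <- 0  # extinction is always a fixed point (rate has factor n)
  for (i in seq_len(n_grid - 1L)) {
    v1 <- vals[i]; v2 <- vals[i + 1L]
    if (v1 == 0 && grid[i] > 0) {
      roots <- c(roots, grid[i])
    } else if (v1 * v2 < 0) {
      r <- stats::uniroot(function(n) simplified_rate(n, p),
                          lower = grid[i], upper = grid[i + 1L],
                          tol = refine_tol)
      roots <- c(roots, r$root)
    }
  }
  if (vals[n_grid] == 0 && grid[n_grid] > 0) roots <- c(roots, grid[n_grid])
  roots <- sort(unique(round(roots / refine_tol) * refine_tol))
  # collapse refinements that landed on the same root
  if (length(roots) > 1L) {
    keep <- c(TRUE, diff(roots) > 1e-6 * max(1, p$n_max))
    roots <- roots[keep]
  }
  stability <- vapply(roots, classify_stability, character(1L), p = p,
                      residual_tol = 1e-6)
  states <- data.frame(density = roots, stability = stability,
                       stringsAsFactors = FALSE)
  n_ct <- NA_real_
  if (nrow(states) == 3L && identical(states$stability,
                                      c("stable", "unstable", "stable"))) {
    n_ct <- states$density[2L]
  }
  structure(list(states = states, n_ct = n_ct, params = unclass(p)),
            class = "steady_state_set")
}

#' @export
print.steady_state_set <- function(x, ...) {
  cat(sprintf("<steady_state_set> %d fixed point(s)\n", nrow(x$states)))
  print(x$states, row.names = FALSE)
  if (!is.na(x$n_ct)) {
    cat(sprintf("  critical survival threshold n_ct = %.6g\n", x$n_ct))
  } else {
    cat("  system is not bistable: no critical threshold\n")
  }
  invisible(x)
}

#' Dependence of the critical threshold on the survival parameter K
#'
#' Repeats the steady-state analysis along a sweep of the survival
#' threshold parameter `K`, reporting the critical density where the system
#' is bistable and `NA` where it is not (e.g. when death dominates
#' everywhere and only extinction remains).
#'
#' @param k_values Ascending vector of positive `K` values.
#' @param p A [simplified_params()] object supplying the other parameters
#'   (its own `survival_k` is ignored).
#' @return A data frame with columns `k`, `n_ct` and `regime`
#'   (`"bistable"`, `"extinction_only"`, or `"survival_only"`).
#' @export
n_ct_vs_k <- function(k_values, p) {
  stopifnot(inherits(p, "simplified_params"))
  if (any(k_values <= 0)) stop("`k_values` must be > 0", call. = FALSE)
  if (is.unsorted(k_values)) stop("`k_values` must be ascending",
                                  call. = FALSE)
  rows <- lapply(k_values, function(k) {
    pk <- simplified_params(mu = p$mu, n_max = p$n_max,
                            death_max = p$death_max, survival_k = k,
                            hill_alpha = p$hill_alpha)
    ss <- find_steady_states(pk)
    regime <- if (!is.na(ss$n_ct)) {
      "bistable"
    } else if (nrow(ss$states) == 1L) {
      "extinction_only"
    } else {
      "survival_only"
    }
    data.frame(k = k, n_ct = ss$n_ct, regime = regime,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
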