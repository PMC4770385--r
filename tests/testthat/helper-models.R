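# Shared fixtures: the printed parameter sets of the density models and a
# brute-force root oracle independent of the production root-finder.

fig1c_params <- function() {
  simplified_params(mu = 1.75, n_max = 1, death_max = 2,
                    survival_k = 0.5, hill_alpha = 4)
}

fig1d_params <- function(v_ratio = 10) {
  two_compartment_params(
    base = simplified_params(mu = 1.75, n_max = 1, death_max = 2,
                             survival_k = 0.01, hill_alpha = 4),
    f_n_cells = 0.1, v_ratio = v_ratio)
}

# independent oracle: dense grid scan + bisection, no uniroot, no package
# root-finder
brute_force_roots <- function(p, n_points = 1e5, upper = 1.05 * p$n_max,
                              tol = 1e-8) {
  grid <- seq(0, upper, length.out = n_points)
  vals <- simplified_rate(grid, p)
  roots <- 0
  for (i in seq_len(n_points - 1L)) {
    if (vals[i] * vals[i + 1L] < 0) {
      lo <- grid[i]; hi <- grid[i + 1L]
      flo <- vals[i]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        fm <- simplified_rate(mid, p)
        if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  roots
}

# random parameter sets that are robustly bistable (three fixed points with
# a clear slope at the middle one)
random_bistable_sets <- function(n, seed) {
  out <- list()
  set.seed(seed)
  while (length(out) < n) {
    p <- tryCatch(
      simplified_params(mu = runif(1, 1, 3), n_max = 1,
                        death_max = runif(1, 1.1, 4),
                        survival_k = runif(1, 0.1, 0.7),
                        hill_alpha = sample(c(2, 3, 4, 6), 1)),
      error = function(e) NULL)
    if (is.null(p) || p$death_max <= p$mu) next
    ss <- find_steady_states(p)
    if (is.na(ss$n_ct)) next
    h <- 1e-6
    slope <- (simplified_rate(ss$n_ct + h, p) -
                simplified_rate(max(ss$n_ct - h, 0), p)) / (2 * h)
    if (abs(slope) < 0.05) next
    out[[length(out) + 1L]] <- list(params = p, ss = ss)
  }
  out
}

# flat trajectory at a constant density, for noise-model arithmetic checks
constant_trajectory <- function(value = 1, n_points = 1e4, horizon = 100) {
  times <- seq(0, horizon, length.out = n_points)
  structure(
    list(times = times,
         states = matrix(value, nrow = n_points, ncol = 1L,
                         dimnames = list(NULL, "n")),
         model = "simplified",
         params = list(model_params = unclass(simplified_params()),
                       schedule = unclass(dosing_schedule("static"))),
         solver = list(method = "none")),
    class = "swarm_trajectory")
}
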