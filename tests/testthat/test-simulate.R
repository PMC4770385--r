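test_that("bistable dynamics: initial densities bracketing the threshold diverge", {
  p <- fig1c_params()
  n_ct <- find_steady_states(p)$n_ct
  upper <- max(find_steady_states(p)$states$density)
  expect_gt(n_ct, 0.4)  # 0.4 is on the extinction side
  low <- simulate_model("simplified", 0.4, p, horizon = 100)
  high <- simulate_model("simplified", 0.8, p, horizon = 100)
  expect_lt(terminal_state(low)[["n"]], 1e-3)
  expect_equal(unname(terminal_state(high)[["n"]]), upper,
               tolerance = 1e-3)
})

test_that("trajectories are well-formed and non-negative", {
  traj <- simulate_model("blam", c(0.2, 10, 0.4, 0), blam_params(),
                         horizon = 16)
  expect_true(all(diff(traj$times) > 0))
  expect_true(all(traj$states >= 0))
  expect_identical(nrow(traj$states), length(traj$times))
  df <- as.data.frame(traj)
  expect_named(df, c("time", "compartment", "species", "value"))
  expect_identical(nrow(df), length(traj$times) * 4L)
})

test_that("input validation rejects inadmissible states and mismatched parameters", {
  expect_error(simulate_model("simplified", -0.1, fig1c_params(), 10),
               "non-negative")
  expect_error(simulate_model("simplified", 0.5, blam_params(), 10),
               "does not match")
  expect_error(simulate_model("swarmbot", swarmbot_state(), blam_params(),
                              10), "transport")
  expect_error(simulate_model("blam", c(0.1, 1, 0, 0), blam_params(), 10,
                              schedule = dosing_schedule("pulsing")),
               "swarmbot")
  expect_error(simulate_model("nope", 1, fig1c_params(), 10),
               "unknown model")
})

test_that("halving solver tolerances leaves terminal states unchanged to 1e-6", {
  p <- blam_params()
  tp <- transport_params()
  sched <- dosing_schedule("pulsing", i_s = 6, i_a = 0.6)
  init <- swarmbot_state(n1 = 0.2, s1 = 6, s2 = 6)
  base <- simulate_model("swarmbot", init, p, 12, schedule = sched,
                         transport = tp)
  tight <- simulate_model("swarmbot", init, p, 12, schedule = sched,
                          transport = tp, rtol = 5e-9, atol = 5e-11)
  expect_equal(terminal_state(base), terminal_state(tight),
               tolerance = 1e-6)
})

test_that("segmented integration agrees with single-span integration on smooth schedules", {
  p <- blam_params()
  init <- c(0.3, 8, 0.5, 0)
  traj <- simulate_model("blam", init, p, horizon = 10, n_out = 100)
  direct <- deSolve::ode(
    y = c(n = 0.3, s = 8, a = 0.5, b = 0), times = traj$times,
    func = function(t, y, parms) list(blam_rhs(pmax(y, 0), p)),
    parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-10)
  expect_equal(unname(traj$states), unname(direct[, -1L]),
               tolerance = 1e-6)
})

test_that("pulse boundaries are never stepped over", {
  sched <- dosing_schedule("pulsing", d_pulse = 0.9,
                           pulse_duration = 1 / 12, period = 0.5)
  traj <- simulate_model("swarmbot", swarmbot_state(n1 = 0.2), blam_params(),
                         horizon = 4, schedule = sched,
                         transport = transport_params(), n_out = 40)
  k <- 0:7
  boundaries <- sort(c(k * 0.5, k * 0.5 + 1 / 12))
  boundaries <- boundaries[boundaries <= 4]
  expect_true(all(vapply(boundaries, function(b)
    any(abs(traj$times - b) < 1e-12), logical(1L))))
  expect_identical(traj$solver$n_segments, 16L)
})

test_that("with transport only, every species is conserved over the horizon", {
  # no cells, no enzyme: nutrient and antibiotic move but are not consumed
  tp <- transport_params(f_n = 0.05, f_s = 0.3, f_a = 0.2, f_b = 0.25,
                         v_ratio = 7)
  p_inert <- blam_params(gamma3 = 0)  # enzyme is transported, not degraded
  # nutrient and enzyme together (no cells, no antibiotic: nothing reacts)
  init_sb <- swarmbot_state(n1 = 0, s1 = 9, a1 = 0, b1 = 0.8,
                            n2 = 0, s2 = 1, a2 = 0, b2 = 0.1)
  traj_sb <- simulate_model("swarmbot", init_sb, p_inert, horizon = 30,
                            transport = tp)
  # antibiotic alone (no enzyme to degrade it)
  init_a <- swarmbot_state(a1 = 1.4, s1 = 0, s2 = 0, a2 = 0.2)
  traj_a <- simulate_model("swarmbot", init_a, p_inert, horizon = 30,
                           transport = tp)
  # cells alone (no nutrient: no growth)
  init_n <- swarmbot_state(n1 = 0.7, s1 = 0, n2 = 0.1, s2 = 0)
  traj_n <- simulate_model("swarmbot", init_n, blam_params(), horizon = 30,
                           transport = tp)
  checks <- list(list(traj_sb, "s"), list(traj_sb, "b"),
                 list(traj_a, "a"), list(traj_n, "n"))
  for (chk in checks) {
    total <- chk[[1L]]$states[, paste0(chk[[2L]], "1")] +
      tp$v_ratio * chk[[1L]]$states[, paste0(chk[[2L]], "2")]
    expect_lt(max(abs(total - total[1L])), 1e-9 * max(1, total[1L]))
  }
})

test_that("trajectory export writes a tidy CSV with a JSON parameter sidecar", {
  traj <- simulate_model("simplified", 0.8, fig1c_params(), horizon = 5,
                         n_out = 20)
  path <- file.path(withr::local_tempdir(), "traj.csv")
  out <- write_trajectory(traj, path)
  expect_true(all(file.exists(out)))
  back <- read.csv(path)
  expect_identical(nrow(back), length(traj$times))
  meta <- jsonlite::read_json(out[["json"]], simplifyVector = TRUE)
  expect_identical(meta$model, "simplified")
  expect_equal(meta$params$model_params$mu, 1.75)
})
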