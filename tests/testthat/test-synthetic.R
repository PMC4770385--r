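test_that("zero noise reproduces the sampled truth exactly and respects the gain", {
  traj <- simulate_model("simplified", 0.8, fig1c_params(), horizon = 16,
                         n_out = 320)
  ds <- observe(traj, sampling_interval = 0.5,
                noise = noise_model(scale = 0), seed = 5, gain = 2.5)
  expect_identical(nrow(ds$observations), 33L)
  truth <- approx(traj$times, traj$states[, "n"],
                  xout = ds$observations$time)$y
  expect_equal(ds$observations$observed, 2.5 * truth, tolerance = 1e-12)
})

test_that("observation noise is reproducible from the seed and differs across seeds", {
  traj <- simulate_model("simplified", 0.8, fig1c_params(), horizon = 16)
  a <- observe(traj, 0.5, noise_model(scale = 0.05), seed = 42)
  b <- observe(traj, 0.5, noise_model(scale = 0.05), seed = 42)
  c <- observe(traj, 0.5, noise_model(scale = 0.05), seed = 43)
  expect_identical(a$observations, b$observations)
  expect_false(identical(a$observations$observed,
                         c$observations$observed))
  # the caller's RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(observe(traj, 0.5, noise_model(), seed = 9))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("multiplicative noise has the advertised coefficient of variation and unit mean", {
  flat <- constant_trajectory(value = 1, n_points = 10001)
  ds <- observe(flat, sampling_interval = flat$times[2L],
                noise = noise_model("multiplicative", scale = 0.05),
                seed = 7)
  x <- ds$observations$observed
  expect_gt(length(x), 9000)
  cv <- sd(x) / mean(x)
  expect_lt(abs(cv - 0.05) / 0.05, 0.1)
  expect_lt(abs(mean(x) - 1), 0.005)
})

test_that("censoring at the detection floor is monotone in the floor", {
  flat <- constant_trajectory(value = 0.1, n_points = 2001)
  floors <- c(0, 0.05, 0.1, 0.4)
  floored_fraction <- vapply(floors, function(fl) {
    ds <- observe(flat, sampling_interval = flat$times[2L],
                  noise = noise_model("additive", scale = 0.05,
                                      detection_floor = fl), seed = 3)
    expect_true(all(ds$observations$observed >= fl))
    mean(ds$observations$observed == fl)
  }, numeric(1L))
  expect_true(all(diff(floored_fraction) >= 0))
  expect_equal(floored_fraction[4L], 1)  # floor above all signal
})

test_that("a condition matrix yields tagged datasets sharing truth within conditions", {
  sets <- generate_condition_matrix(
    antibiotic_levels = c(0, 0.6), nutrient_levels = c(4, 10),
    horizon = 8, replicates = 2, sampling_interval = 1, seed = 11)
  expect_length(sets, 8L)
  ids <- vapply(sets, function(d) d$condition$id, character(1L))
  expect_identical(length(unique(ids)), 4L)
  # replicates share the truth trajectory but differ in noise
  same <- sets[ids == ids[1L]]
  expect_identical(same[[1L]]$truth$states, same[[2L]]$truth$states)
  expect_false(identical(same[[1L]]$observations$observed,
                         same[[2L]]$observations$observed))
  # rerunning with the same master seed is bit-for-bit identical
  sets2 <- generate_condition_matrix(
    antibiotic_levels = c(0, 0.6), nutrient_levels = c(4, 10),
    horizon = 8, replicates = 2, sampling_interval = 1, seed = 11)
  expect_identical(lapply(sets, function(d) d$observations),
                   lapply(sets2, function(d) d$observations))
})

test_that("without antibiotic both compartments of every condition grow", {
  sets <- generate_condition_matrix(
    antibiotic_levels = 0, nutrient_levels = c(4, 10),
    horizon = 24, replicates = 1, sampling_interval = 2,
    noise = noise_model(scale = 0), seed = 2)
  for (ds in sets) {
    term <- terminal_state(ds$truth)
    expect_gt(term[["n1"]], 0.5)
    expect_gt(term[["n2"]], 0.5)
  }
})

test_that("dataset export round-trips through CSV plus JSON sidecar", {
  traj <- simulate_model("simplified", 0.8, fig1c_params(), horizon = 16)
  ds <- observe(traj, 0.5, noise_model(scale = 0.05), seed = 21)
  path <- file.path(withr::local_tempdir(), "ds.csv")
  out <- write_dataset(ds, path)
  expect_true(all(file.exists(out)))
  back <- read.csv(path)
  expect_equal(back$observed, ds$observations$observed, tolerance = 1e-12)
  meta <- jsonlite::read_json(out[["json"]], simplifyVector = TRUE)
  expect_identical(meta$seed, 21L)
  expect_equal(meta$noise$scale, 0.05)
})
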