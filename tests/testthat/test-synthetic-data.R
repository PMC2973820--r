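test_that("default schedule reproduces the study trial accounting", {
  d <- default_design()
  for (sess in c("drift", "no_drift")) {
    s <- build_schedule(d, sess, rng_seed = 11)
    expect_equal(sum(s$block_kind == "training"), 207)
    expect_equal(sum(s$block_kind != "training"), 720)
    expect_equal(sum(s$block_kind == "zero_penalty"), 240)
  }
})

test_that("zero-penalty blocks are balanced across the session halves", {
  d <- default_design()
  for (seed in 1:20) {
    s <- build_schedule(d, "drift", rng_seed = seed)
    zb <- unique(s$block_index[s$block_kind == "zero_penalty"])
    zb <- zb - d$n_training_blocks        # experimental block number 1..6
    expect_equal(sum(zb %in% 1:3), 1)
    expect_equal(sum(zb %in% 4:6), 1)
    # training precedes all experimental trials
    expect_lt(max(s$trial_index[s$block_kind == "training"]),
              min(s$trial_index[s$block_kind != "training"]))
  }
})

test_that("degenerate and unsatisfiable block configurations are handled", {
  d0 <- experiment_design(n_zero_penalty_blocks = 0)
  s <- build_schedule(d0, "no_drift", rng_seed = 1)
  expect_equal(sum(s$block_kind == "penalty"), 6 * 120)
  expect_error(build_schedule(experiment_design(n_zero_penalty_blocks = 3),
                              "drift", 1))
  expect_error(experiment_design(penalty_points = 5))
  expect_error(experiment_design(drift_probabilities = c(0.5, 0.5, 0.5)))
})

test_that("schedule labels respect session and block kind", {
  d <- default_design()
  s_nd <- build_schedule(d, "no_drift", rng_seed = 3)
  expect_true(all(s_nd$drift_condition == "none"))
  s_dr <- build_schedule(d, "drift", rng_seed = 3)
  expect_true(all(s_dr$drift_condition %in% c("left", "none", "right")))
  expect_gt(sum(s_dr$drift_condition != "none"), 0)
  expect_true(all(s_dr$penalty_direction[s_dr$block_kind == "training"] ==
                    "none"))
  expect_true(all(s_dr$penalty_direction[s_dr$block_kind != "training"] %in%
                    c("above", "below", "left", "right")))
  expect_true(all(s_dr$penalty_points[s_dr$block_kind == "penalty"] == -5))
  expect_true(all(s_dr$penalty_points[s_dr$block_kind != "penalty"] == 0))
})

test_that("simulate_endpoint applies noise and drift shift as specified", {
  # near-noiseless identity
  sj0 <- subject_spec("static", baseline_sd_mm = 1e-9,
                      mfr_displacement_mm = 0)
  expect_equal(simulate_endpoint(c(1, 2), sj0, "none"), c(1, 2),
               tolerance = 1e-6)
  # analytic mixture variance: sigma = 3, d = sigma * sqrt(3) gives
  # horizontal variance sigma^2 + (2/3) d^2 = 27, vertical 9
  sj <- subject_spec("static", baseline_sd_mm = 3,
                     mfr_displacement_mm = 3 * sqrt(3), rng_seed = 5)
  set.seed(77)
  n <- 3e5
  cond <- sample(c("left", "none", "right"), n, replace = TRUE)
  pts <- do.call(rbind, lapply(c("left", "none", "right"), function(cc) {
    simulate_endpoint(c(0, 0), sj, cc, n = sum(cond == cc))
  }))
  expect_equal(var(pts[, 1]), 27, tolerance = 0.1 * 27)
  expect_equal(var(pts[, 2]), 9, tolerance = 0.1 * 9)
  expect_lt(abs(mean(pts[, 1])), 0.05)
  # d = 0: the drift condition has no effect on the draws
  sj9 <- subject_spec("static", mfr_displacement_mm = 0)
  set.seed(12); a <- simulate_endpoint(c(0, 0), sj9, "left", n = 100)
  set.seed(12); b <- simulate_endpoint(c(0, 0), sj9, "none", n = 100)
  expect_identical(a, b)
})

test_that("datasets are reproducible bit-identically from the seed", {
  d <- default_design()
  sj <- subject_spec("circular", rng_seed = 21)
  ds1 <- simulate_experiment(d, sj)
  ds2 <- simulate_experiment(d, sj)
  expect_identical(ds1, ds2)
  ds3 <- simulate_experiment(d, subject_spec("circular", rng_seed = 22))
  expect_false(identical(ds1$x_mm, ds3$x_mm))
})

test_that("zero-penalty endpoints have the mixture variances and no bias", {
  d <- default_design()
  sj <- subject_spec("circular", rng_seed = 31)
  ds <- simulate_experiment(d, sj)
  zp_dr <- zero_penalty_points(ds, "drift")
  zp_nd <- zero_penalty_points(ds, "no_drift")
  expect_equal(nrow(zp_dr), 240)
  expect_equal(nrow(zp_nd), 240)
  # drift-session horizontal variance ~ 3x baseline; vertical ~ baseline
  expect_gt(var(zp_dr[, 1]) / var(zp_nd[, 1]), 1.8)
  expect_lt(var(zp_dr[, 2]) / var(zp_nd[, 2]), 1.6)
  # unbiased generator: SE per axis is sqrt(var/240)
  expect_lt(abs(mean(zp_dr[, 1])), 4 * sqrt(27 / 240))
  expect_lt(abs(mean(zp_dr[, 2])), 4 * sqrt(9 / 240))
})

test_that("planner kinds shape the per-condition aimpoint shifts", {
  d <- default_design()
  # static planner: all shifts ~ 0
  ds_st <- simulate_experiment(d, subject_spec("static", rng_seed = 41),
                               sessions = "drift")
  summ_st <- delta_aim_summary(ds_st)
  expect_true(all(abs(summ_st$delta_aim_mm) < 4 * summ_st$sem_mm))
  # circular planner: horizontal and vertical shifts statistically equal
  ds_ci <- simulate_experiment(d, subject_spec("circular", rng_seed = 42),
                               sessions = "drift")
  summ_ci <- delta_aim_summary(ds_ci)
  h <- summ_ci$delta_aim_mm[summ_ci$orientation == "horizontal"]
  v <- summ_ci$delta_aim_mm[summ_ci$orientation == "vertical"]
  sems <- summ_ci$sem_mm
  expect_lt(abs(mean(h) - mean(v)), 4 * sqrt(sum(sems^2)) / 2)
  # anisotropic planner: horizontal shift exceeds vertical
  ds_an <- simulate_experiment(d, subject_spec("anisotropic", rng_seed = 43),
                               sessions = "drift")
  summ_an <- delta_aim_summary(ds_an)
  expect_gt(mean(summ_an$delta_aim_mm[summ_an$orientation == "horizontal"]),
            mean(summ_an$delta_aim_mm[summ_an$orientation == "vertical"]) + 2)
})

test_that("dataset CSV and config JSON round-trip", {
  d <- experiment_design(n_experimental_blocks = 2,
                         trials_per_experimental_block = 20,
                         n_zero_penalty_blocks = 2,
                         n_training_blocks = 1,
                         trials_per_training_block = 10)
  sj <- subject_spec("static", rng_seed = 51)
  ds <- simulate_experiment(d, sj)
  path <- tempfile(fileext = ".csv")
  write_endpoint_dataset(ds, path)
  back <- read_endpoint_dataset(path)
  expect_equal(back$x_mm, ds$x_mm)
  expect_equal(back$penalty_direction, ds$penalty_direction)
  unlink(path)

  cfgp <- tempfile(fileext = ".json")
  write_experiment_config(d, list(sj, subject_spec("circular",
                                                   rng_seed = 52)), cfgp)
  cfg <- read_experiment_config(cfgp)
  expect_equal(cfg$design$trials_per_experimental_block, 20)
  expect_equal(length(cfg$subjects), 2)
  expect_equal(cfg$subjects[[2]]$planner_kind, "circular")
  unlink(cfgp)
})
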