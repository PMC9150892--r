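test_that("steady-state magnetization matches closed form and oracle", {
  tis <- default_tis()
  # 90 degrees: denominator collapses to 1
  acq90 <- acquisition_params(tr_ms = 20, flip_deg = 90)
  expect_equal(steady_state_mz(acq90, tis, 1950), 1 - exp(-20 / 1950),
               tolerance = 1e-12)
  # flip -> 0 limit recovers M0
  acq0 <- acquisition_params(tr_ms = 20, flip_deg = 1e-3)
  expect_equal(steady_state_mz(acq0, tis, 1950), 1, tolerance = 1e-6)
  # fixed-point of the pulse-by-pulse recursion
  acq <- acquisition_params(tr_ms = 20, flip_deg = 18)
  expect_equal(steady_state_mz(acq, tis, 1950),
               recursion_mz(20, 1950, 18, 2001), tolerance = 1e-12)
  # invalid parameters
  expect_error(acquisition_params(tr_ms = -1), "tr_ms")
  expect_error(steady_state_mz(acq, tis, -5), "t1_ms")
})

test_that("inflowing blood magnetization follows the RF pulse count", {
  acq <- acquisition_params(tr_ms = 20, flip_deg = 11)
  tis <- default_tis()
  # fewer pulses than one TR: fully relaxed
  expect_equal(inflow_blood_mz(acq, tis, flow_params(delivery_ms = 10)), 1)
  # near-zero flip: no saturation at any delivery
  acq0 <- acquisition_params(tr_ms = 20, flip_deg = 1e-3)
  expect_equal(inflow_blood_mz(acq0, tis, flow_params(2000)), 1,
               tolerance = 1e-6)
  # delivery 1000 ms -> n_RF = 50; value frozen from the recursion oracle
  expect_equal(inflow_blood_mz(acq, tis, flow_params(1000)), 0.5086676,
               tolerance = 1e-6)
  expect_equal(inflow_blood_mz(acq, tis, flow_params(1000)),
               recursion_mz(20, 2100, 11, 50), tolerance = 1e-12)
  expect_error(flow_params(delivery_ms = -1), "delivery")
})

test_that("closed form equals pulse-by-pulse recursion (property)", {
  set.seed(5)
  for (i in 1:200) {
    tr <- runif(1, 5, 50)
    t1 <- runif(1, 500, 3000)
    th <- runif(1, 1, 90)
    n <- sample(1:100, 1)
    acq <- acquisition_params(tr_ms = tr, flip_deg = th,
                              te_ms = min(tr / 2, 4))
    tis <- tissue_params(t1_blood_ms = t1)
    expect_equal(inflow_blood_mz(acq, tis, flow_params(0), n_rf = n),
                 recursion_mz(tr, t1, th, n), tolerance = 1e-10)
  }
  # n_RF -> infinity converges to the blood steady state
  acq <- acquisition_params(tr_ms = 20, flip_deg = 18)
  tis <- default_tis()
  expect_equal(inflow_blood_mz(acq, tis, flow_params(0), n_rf = 1e4),
               steady_state_mz(acq, tis, tis$t1_blood_ms),
               tolerance = 1e-9)
})

test_that("relative FRE has the right fixed points", {
  acq <- acquisition_params(tr_ms = 20, flip_deg = 18)
  # identical T1s and long delivery: blood reaches the tissue steady state
  tis_eq <- tissue_params(t1_blood_ms = 1950, t1_tissue_ms = 1950)
  expect_equal(relative_fre(acq, tis_eq, flow_params(1e6)), 0,
               tolerance = 1e-10)
  # Mz_blood = 2 * tissue steady state gives FRE = 1 by definition
  tis <- default_tis()
  mzt <- steady_state_mz(acq, tis, tis$t1_tissue_ms)
  fre <- relative_fre(acq, tis, flow_params(300))
  mzb <- inflow_blood_mz(acq, tis, flow_params(300))
  expect_equal(fre, mzb / mzt - 1, tolerance = 1e-12)
})

test_that("Ernst angle formula, limits and optimality", {
  expect_equal(round(ernst_angle_deg(20, 1950), 1), 8.2)
  expect_lt(ernst_angle_deg(1e-9, 1950), 1e-3)
  # grid search on the received signal Mz * sin(theta) confirms the
  # analytic optimum (0.01 degree resolution)
  tis <- default_tis()
  for (t1 in c(1950, 2100)) {
    grid <- seq(0.01, 90, by = 0.01)
    vals <- vapply(grid, function(th)
      steady_state_mz(acquisition_params(tr_ms = 20, flip_deg = th),
                      tis, t1) * sin(th * pi / 180), numeric(1))
    expect_equal(grid[which.max(vals)], ernst_angle_deg(20, t1),
                 tolerance = 0.011)
  }
})

test_that("optimal flip angles reproduce the protocol optima", {
  acq <- acquisition_params(tr_ms = 20, flip_deg = 18)
  tis <- default_tis()
  expect_identical(
    vapply(c(100, 300, 500, 1000), function(d)
      optimal_flip_deg(acq, tis, d), numeric(1)),
    c(37, 21, 16, 11))
  expect_error(optimal_flip_deg(acq, tis, 300, grid_step_deg = 0), "grid")
})

test_that("blood dwell time is the voxel transit time", {
  expect_equal(blood_dwell_time_ms(0.3, 30), 10)
  expect_equal(blood_dwell_time_ms(0.1, 1), 100)
  expect_identical(blood_dwell_time_ms(0.3, 0), Inf)
  # monotone: decreasing in velocity, increasing in voxel size
  v <- c(1, 5, 20, 100, 1000)
  l <- c(0.05, 0.1, 0.2, 0.3)
  grid <- outer(l, v, blood_dwell_time_ms)
  expect_true(all(apply(grid, 1, diff) < 0))  # along velocity
  expect_true(all(apply(grid, 2, diff) > 0))  # along voxel size
})

test_that("FRE surface reproduces the protocol-optimization orderings", {
  acq <- acquisition_params(tr_ms = 20, flip_deg = 18)
  tis <- default_tis()
  # single cell agrees with the scalar path
  one <- fre_surface(acq, tis, 300, 18, vary = "flip")
  expect_equal(one$fre, relative_fre(acq, tis, flow_params(300)))
  # longer TR wins beyond ~200 ms delivery at 18 degrees
  tr_tab <- fre_surface(acq, tis, 300, c(10, 20), vary = "tr")
  expect_gt(tr_tab$fre[tr_tab$tr_ms == 20], tr_tab$fre[tr_tab$tr_ms == 10])
  # non-increasing along delivery at fixed TR 20 / flip 18
  tab <- fre_surface(acq, tis, seq(0, 1500, by = 50), 18, vary = "flip")
  expect_true(all(diff(tab$fre) <= 1e-12))
  # strictly decreasing in delivery for flip above the Ernst angle
  tab2 <- fre_surface(acq, tis, seq(20, 1500, by = 20), 30, vary = "flip")
  expect_true(all(diff(tab2$fre) < 0))
  expect_error(fre_surface(acq, tis, numeric(0), 18), "non-empty")
})
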