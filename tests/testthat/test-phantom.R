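test_that("tree generation is deterministic and respects the priors", {
  cfg <- phantom_config()
  t1 <- generate_tree(cfg, seed = 4)
  t2 <- generate_tree(cfg, seed = 4)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # base case: no branching
  t0 <- generate_tree(phantom_config(depth = 0), seed = 1)
  expect_identical(nrow(t0), 1L)
  expect_identical(t0$delivery_offset_ms, cfg$root_delivery_ms)
  # diameters taper, delivery accumulates root -> leaf
  tt <- generate_tree(cfg, seed = 9)
  kids <- which(tt$parent > 0)
  expect_true(all(tt$diameter_mm[kids] <= tt$diameter_mm[tt$parent[kids]]))
  expect_true(all(tt$delivery_offset_ms[kids] >
                    tt$delivery_offset_ms[tt$parent[kids]]))
  # velocity monotone in diameter
  o <- order(tt$diameter_mm)
  expect_true(all(diff(tt$velocity_mm_s[o]) >= 0))
  expect_error(phantom_config(fov_mm = c(0.1, 6, 6)), "field of view")
  expect_error(phantom_config(supersampling = 4), "odd")
})

test_that("sampled branch angles are centred near a right angle", {
  cfg <- phantom_config(depth = 4, min_diameter_mm = 0.01)
  angles <- unlist(lapply(1:40, function(s) {
    tr <- generate_tree(cfg, seed = 1000 + s)
    tr$branch_angle_deg[!is.na(tr$branch_angle_deg)]
  }))
  expect_gt(length(angles), 1000)
  expect_lt(abs(mean(angles) - 90), 5)
})

test_that("rasterizer agrees with the analytic fraction model", {
  # centred axis-aligned cylinders across diameter/voxel ratios
  l <- 0.3
  for (ratio in c(0.5, 0.7, 1.0, 1.5)) {
    cfg <- small_cfg()
    tree <- straight_tree(ratio * l, l)
    maps <- rasterize_fraction_map(tree, cfg)
    centre <- maps$fraction$data[11, 11, 8]
    analytic <- blood_volume_fraction(vessel_voxel_geometry(ratio * l, l))
    expect_lt(abs(centre - analytic), 0.02)
  }
  # empty tree gives an all-zero volume
  empty <- rasterize_fraction_map(NULL, small_cfg())
  expect_true(all(empty$fraction$data == 0))
  expect_true(all(empty$mask$data == 0))
})

test_that("rasterized volume conserves total cylinder volume", {
  cfg <- small_cfg(supersampling = 7)
  tree <- rbind(straight_tree(0.4, 0.3, centre_mm = 2),
                straight_tree(0.25, 0.3, centre_mm = 4.3))
  maps <- rasterize_fraction_map(tree, cfg)
  vox_vol <- cfg$voxel_mm^3
  total <- sum(maps$fraction$data) * vox_vol
  analytic <- sum(pi * (tree$diameter_mm / 2)^2 *
                    sqrt((tree$ex - tree$sx)^2 + (tree$ey - tree$sy)^2 +
                           (tree$ez - tree$sz)^2))
  expect_equal(total / analytic, 1, tolerance = 0.02)
})

test_that("simulated TOF signal hits both compartment limits", {
  acq <- default_acq()
  tis <- default_tis()
  cfg <- small_cfg(acq = acq, tis = tis)
  maps <- rasterize_fraction_map(straight_tree(0.9, 0.3, delivery = 10),
                                 cfg)
  img <- simulate_tof(maps)
  # vessel-free corner: tissue steady state with tissue T2* weighting
  expect_equal(img$data[1, 1, 1],
               steady_state_mz(acq, tis, tis$t1_tissue_ms) *
                 exp(-acq$te_ms[1] / tis$t2s_tissue_ms), tolerance = 1e-12)
  # fully-blood voxel with delivery < TR: unsaturated M0 with artery T2*
  core <- maps$fraction$data == 1
  expect_gt(sum(core), 0)
  expect_equal(unique(img$data[core]),
               tis$m0 * exp(-acq$te_ms[1] / tis$t2s_artery_ms),
               tolerance = 1e-12)
})

test_that("measured FRE on a thin artery matches the model prediction", {
  acq <- default_acq()
  tis <- default_tis(t2s_artery_ms = 33) # isolate the inflow contrast
  cfg <- small_cfg(acq = acq, tis = tis)
  maps <- rasterize_fraction_map(straight_tree(0.3, 0.3), cfg)
  img <- simulate_tof(maps)
  pred <- partial_volume_fre(acq, tis, flow_params(300),
                             vessel_voxel_geometry(0.3, 0.3))
  expect_equal(measure_fre(img, maps$mask) / pred, 1, tolerance = 0.05)
})

test_that("Rician noise has the right statistics and is reproducible", {
  vol <- volume(array(0.5, c(12, 12, 12)), 0.3)
  expect_identical(add_rician_noise(vol, 0, seed = 1)$data, vol$data)
  n1 <- add_rician_noise(vol, 0.1, seed = 31)
  n2 <- add_rician_noise(vol, 0.1, seed = 31)
  expect_identical(n1$data, n2$data)
  expect_false(identical(add_rician_noise(vol, 0.1, seed = 32)$data,
                         n1$data))
  # Rayleigh mean on a zero-signal volume
  zero <- volume(array(0, c(100, 100, 100)), 1)
  r <- add_rician_noise(zero, 1, seed = 7)
  expect_equal(mean(r$data) / sqrt(pi / 2), 1, tolerance = 0.01)
})

test_that("bias field is bounded, smooth and invertible", {
  flat <- volume(array(1, c(43, 43, 43)), 0.3)
  expect_identical(add_bias_field(flat, 0, 6, seed = 1)$volume$data,
                   flat$data)
  b <- add_bias_field(flat, 0.3, 6, seed = 9)
  expect_true(all(b$field >= 0.7 - 1e-12 & b$field <= 1.3 + 1e-12))
  # round trip: normalization restores flatness within 2% (the global
  # scale is not identifiable, so deviation is taken about the median)
  for (sd in c(9, 21)) {
    rec <- bias_normalize(add_bias_field(flat, 0.3, 6, seed = sd)$volume,
                          0.9)
    dev <- rec$data / median(rec$data) - 1
    expect_lt(max(abs(dev)), 0.02)
  }
})

test_that("phantom ground-truth maps are consistent", {
  ph <- build_phantom(phantom_config(), seed = 1)
  expect_true(all(ph$maps$fraction$data >= 0 & ph$maps$fraction$data <= 1))
  # mask voxels carry delivery times and labels
  m <- ph$maps$mask$data > 0
  expect_true(all(ph$maps$label$data[m] %in% c(1, 2)))
  expect_true(all(ph$maps$delivery_ms$data[m] >= ph$config$root_delivery_ms))
  # both kinds are present and reproducible under the same seed
  expect_true(all(c(1, 2) %in% ph$maps$label$data))
  ph2 <- build_phantom(phantom_config(), seed = 1)
  expect_identical(ph$echoes[[1]]$data, ph2$echoes[[1]]$data)
})
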