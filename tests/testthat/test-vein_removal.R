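test_that("two-point T2* estimation inverts the mono-exponential", {
  l <- 0.3
  # S1/S2 = e gives T2* = delta TE
  e1 <- volume(array(exp(1), c(4, 4, 4)), l)
  e2 <- volume(array(1, c(4, 4, 4)), l)
  t2 <- t2star_map(e1, e2, 6.95)
  expect_equal(unique(as.vector(t2$values$data)), 6.95)
  expect_false(any(t2$clamped))
  # degenerate voxels are clamped and flagged
  t2d <- t2star_map(e2, e2, 6.95)
  expect_true(all(t2d$clamped))
  expect_true(all(t2d$values$data == 1000))
  expect_error(t2star_map(e1, volume(array(1, c(5, 4, 4)), l), 6.95),
               "same grid")
  expect_error(t2star_map(e1, e2, 0), "delta_te")
})

test_that("noiseless phantom T2* is recovered exactly in pure voxels", {
  ph <- build_phantom(phantom_config(), seed = 3)
  dte <- diff(ph$config$acq$te_ms)
  t2 <- t2star_map(ph$clean[[1]], ph$clean[[2]], dte)
  vein_core <- ph$maps$label$data == 2 & ph$maps$fraction$data == 1
  art_core <- ph$maps$label$data == 1 & ph$maps$fraction$data == 1
  expect_gt(sum(vein_core), 0)
  expect_gt(sum(art_core), 0)
  expect_equal(max(abs(t2$values$data[vein_core] - 12)), 0,
               tolerance = 1e-6)
  expect_equal(max(abs(t2$values$data[art_core] - 30)), 0,
               tolerance = 1e-6)
})

test_that("voxelwise T2* is median-unbiased within 3% at SNR 20", {
  set.seed(8)
  for (t2true in c(10, 25, 40)) {
    s1 <- exp(-7.05 / t2true)
    s2 <- exp(-14 / t2true)
    sig <- s1 / 20
    n <- 20000
    m1 <- sqrt((s1 + rnorm(n, 0, sig))^2 + rnorm(n, 0, sig)^2)
    m2 <- sqrt((s2 + rnorm(n, 0, sig))^2 + rnorm(n, 0, sig)^2)
    est <- 6.95 / log(m1 / m2)
    expect_equal(median(est) / t2true, 1, tolerance = 0.03)
  }
})

test_that("component percentiles use linear interpolation", {
  l <- 0.3
  vals <- array(1000, c(10, 1, 1))
  vals[1:10] <- 1:10
  comp <- array(1L, c(10, 1, 1))
  t2 <- structure(list(values = volume(vals, l),
                       clamped = array(FALSE, c(10, 1, 1)),
                       delta_te_ms = 6.95, clamp_ms = 1000),
                  class = "t2star_map")
  expect_equal(component_t2star_p90(t2, comp)[["1"]], 9.1)
  # constant component
  t2c <- structure(list(values = volume(array(12, c(4, 1, 1)), l),
                        clamped = array(FALSE, c(4, 1, 1)),
                        delta_te_ms = 6.95, clamp_ms = 1000),
                   class = "t2star_map")
  expect_equal(component_t2star_p90(t2c, array(1L, c(4, 1, 1)))[["1"]], 12)
  # all-clamped component yields NA (and is retained downstream)
  t2a <- structure(list(values = volume(array(1000, c(4, 1, 1)), l),
                        clamped = array(TRUE, c(4, 1, 1)),
                        delta_te_ms = 6.95, clamp_ms = 1000),
                   class = "t2star_map")
  expect_true(is.na(component_t2star_p90(t2a, array(1L, c(4, 1, 1)))[["1"]]))
})

test_that("vein components are removed by their T2* percentile", {
  ph <- build_phantom(phantom_config(), seed = 3)
  ts <- tissue_signal()
  e1 <- add_rician_noise(ph$clean[[1]], ts / 15, seed = 103)
  e2 <- add_rician_noise(ph$clean[[2]], ts / 15, seed = 203)
  seg <- segment_vessels(e1, segmentation_config(ts * 1.7, ts * 1.5, 10))
  t2 <- t2star_map(e1, e2, diff(ph$config$acq$te_ms))
  res <- remove_veins(seg, t2, threshold_ms = 19)
  # true kind of each component by majority ground-truth label
  labs <- seq_len(attr(seg$components, "n_components"))
  truth <- vapply(labs, function(lb) {
    sel <- seg$components == lb & ph$maps$fraction$data > 0.5
    mean(ph$maps$label$data[sel] == 2) > 0.5
  }, logical(1))
  expect_identical(res$decision$venous, truth)
  # masks partition the segmentation
  expect_identical(res$arterial_mask | res$venous_mask, seg$vessel_mask)
  expect_false(any(res$arterial_mask & res$venous_mask))
  # threshold 0 removes nothing; larger thresholds remove supersets
  expect_length(remove_veins(seg, t2, 0)$removed_labels, 0)
  r19 <- remove_veins(seg, t2, 19)$removed_labels
  r45 <- remove_veins(seg, t2, 45)$removed_labels
  expect_true(all(r19 %in% r45))
  expect_gt(length(r45), length(r19))
})

test_that("artery-vein merged components follow the pooled percentile", {
  # two touching cylinders, one enhancing artery (T2* 30), one vein (12):
  # a single component whose fate is set by the pooled 90th percentile
  cfg <- small_cfg()
  tree <- rbind(straight_tree(0.4, 0.3, centre_mm = 2.85, delivery = 250),
                straight_tree(0.4, 0.3, centre_mm = 3.15, delivery = 250,
                              kind = "vein"))
  maps <- rasterize_fraction_map(tree, cfg)
  img1 <- simulate_tof(maps, echo_index = 1)
  img2 <- simulate_tof(maps, echo_index = 2)
  ts <- tissue_signal()
  seg <- segment_vessels(img1, segmentation_config(ts * 1.6, ts * 1.4, 5))
  expect_identical(attr(seg$components, "n_components"), 1L)
  t2 <- t2star_map(img1, img2, diff(cfg$acq$te_ms))
  p90 <- component_t2star_p90(t2, seg$components)
  res <- remove_veins(seg, t2, 19)
  expect_identical(res$decision$venous, unname(p90 < 19))
})

test_that("low-resolution vein masks carry over by component overlap", {
  cfg <- phantom_config()
  ph <- build_phantom(cfg, seed = 3)
  ts <- tissue_signal()
  seg <- segment_vessels(ph$clean[[1]],
                         segmentation_config(ts * 1.7, ts * 1.5, 10))
  # "low-resolution" vein mask: the true vein extent resampled to 0.6 mm
  vein_low <- resample_nearest(
    volume((ph$maps$label$data == 2) * 1, cfg$voxel_mm), 0.6)
  res <- mark_veins_from_lowres(seg, vein_low, cfg$voxel_mm)
  labs <- seq_len(attr(seg$components, "n_components"))
  truth <- vapply(labs, function(lb) {
    sel <- seg$components == lb & ph$maps$fraction$data > 0.5
    mean(ph$maps$label$data[sel] == 2) > 0.5
  }, logical(1))
  expect_identical(res$decision$venous, truth)
})
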