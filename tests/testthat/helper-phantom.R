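# Shared fixtures, all built in code.

default_acq <- function(...) acquisition_params(...)
default_tis <- function(...) tissue_params(...)

# noiseless tissue signal of the default protocol at the first echo
tissue_signal <- function(acq = default_acq(), tis = default_tis()) {
  steady_state_mz(acq, tis, tis$t1_tissue_ms) *
    exp(-acq$te_ms[1] / tis$t2s_tissue_ms)
}

# single straight axis-aligned segment as a vessel-tree data.frame,
# centred on a voxel-centre column near x = y = centre_mm
straight_tree <- function(d_mm, voxel_mm, centre_mm = 3, z0 = 0.6, z1 = 5.4,
                          velocity = 1e6, delivery = 300, kind = "artery") {
  x <- (round(centre_mm / voxel_mm - 0.5) + 0.5) * voxel_mm
  data.frame(sx = x, sy = x, sz = z0, ex = x, ey = x, ez = z1,
             diameter_mm = d_mm, velocity_mm_s = velocity,
             delivery_offset_ms = delivery, kind = kind,
             level = 0L, branch_angle_deg = NA_real_, parent = 0L)
}

small_cfg <- function(voxel_mm = 0.3, ...) {
  phantom_config(fov_mm = c(6, 6, 6), voxel_mm = voxel_mm, ...)
}

# pulse-by-pulse longitudinal magnetization recursion: the independent
# oracle for the closed-form inflow expression
recursion_mz <- function(tr_ms, t1_ms, flip_deg, n_rf, m0 = 1) {
  e1 <- exp(-tr_ms / t1_ms)
  mz <- m0
  if (n_rf > 1)
    for (i in seq_len(n_rf - 1))
      mz <- mz * cos(flip_deg * pi / 180) * e1 + m0 * (1 - e1)
  mz
}

# Monte-Carlo circle/square intersection area (rejection sampling)
mc_overlap_area <- function(d, l, n = 1e6) {
  half <- max(d / 2, l / 2)
  x <- runif(n, -half, half)
  y <- runif(n, -half, half)
  mean(x^2 + y^2 <= (d / 2)^2 & abs(x) <= l / 2 & abs(y) <= l / 2) *
    (2 * half)^2
}
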