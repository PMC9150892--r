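# evaluate `code` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom configuration
#'
#' Stated world of the synthetic angiogram generator: sparse binary
#' branching arterial trees with near-right-angle branches and tapering
#' diameters, thick slowly-refreshed veins, blood velocities monotone in
#' diameter within 10-50 mm/s, blood delivery times from 200 ms at the slab
#' entry upwards, 7 T relaxation parameters, Rician noise and a smooth
#' multiplicative bias field. Defaults are chosen for a 12.8 mm cube at
#' 0.3 mm isotropic resolution so that the full pipeline runs in seconds.
#'
#' @param fov_mm Field of view (mm), length-3.
#' @param voxel_mm Isotropic voxel size (mm).
#' @param acq,tis Parameter bundles ([acquisition_params()],
#'   [tissue_params()]).
#' @param depth Number of branching levels per arterial tree.
#' @param root_diameter_mm Arterial root diameter (mm).
#' @param taper Child/parent diameter ratio at a branch.
#' @param min_diameter_mm Branching stops below this diameter.
#' @param branch_angle_mean_deg,branch_angle_sd_deg Branch-angle prior
#'   (degrees); near-perpendicular by default.
#' @param seg_length_range_mm Uniform range of segment lengths (mm).
#' @param velocity_range_mm_s Velocity bounds (mm/s); velocity is assigned
#'   monotonically in diameter over `diameter_range_mm`.
#' @param diameter_range_mm Diameter range used by the velocity map (mm).
#' @param root_delivery_ms Blood delivery time at the arterial entry (ms).
#' @param n_artery_trees,n_vein_trees Number of trees per kind.
#' @param vein_root_diameter_mm Vein root diameter (mm).
#' @param vein_delivery_ms Delivery time at vein roots (ms); far beyond the
#'   arterial range, so ordinary veins are saturated and show no inflow
#'   enhancement.
#' @param vein_pass_through If TRUE, vein roots keep a short (arterial-like)
#'   delivery time, mimicking through-going sinuses that do show inflow
#'   enhancement.
#' @param noise_sigma Rician noise sigma (image units).
#' @param bias_amplitude Relative amplitude of the multiplicative bias
#'   field.
#' @param bias_scale_mm Spatial scale of the bias field (mm).
#' @param supersampling Odd supersampling factor (points per voxel edge)
#'   of the rasterizer, >= 3.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(fov_mm = c(12.8, 12.8, 12.8), voxel_mm = 0.3,
                           acq = acquisition_params(),
                           tis = tissue_params(),
                           depth = 2, root_diameter_mm = 0.6, taper = 0.75,
                           min_diameter_mm = 0.05,
                           branch_angle_mean_deg = 90,
                           branch_angle_sd_deg = 15,
                           seg_length_range_mm = c(2.5, 4.5),
                           velocity_range_mm_s = c(10, 50),
                           diameter_range_mm = c(0.05, 0.7),
                           root_delivery_ms = 200,
                           n_artery_trees = 2, n_vein_trees = 1,
                           vein_root_diameter_mm = 1.0,
                           vein_delivery_ms = 3000,
                           vein_pass_through = TRUE,
                           noise_sigma = 0, bias_amplitude = 0,
                           bias_scale_mm = 6, supersampling = 7) {
  stop_if_not(length(fov_mm) == 3, all(fov_mm > 0), voxel_mm > 0,
              msg = "fov_mm must be 3 positive lengths, voxel_mm positive")
  stop_if_not(all(fov_mm >= 2 * voxel_mm),
              msg = "degenerate field of view")
  stop_if_not(supersampling >= 3, supersampling %% 2 == 1,
              msg = "supersampling must be odd and >= 3")
  stop_if_not(taper > 0, taper <= 1, msg = "taper must be in (0, 1]")
  structure(list(fov_mm = fov_mm, voxel_mm = voxel_mm, acq = acq, tis = tis,
                 depth = depth, root_diameter_mm = root_diameter_mm,
                 taper = taper, min_diameter_mm = min_diameter_mm,
                 branch_angle_mean_deg = branch_angle_mean_deg,
                 branch_angle_sd_deg = branch_angle_sd_deg,
                 seg_length_range_mm = seg_length_range_mm,
                 velocity_range_mm_s = velocity_range_mm_s,
                 diameter_range_mm = diameter_range_mm,
                 root_delivery_ms = root_delivery_ms,
                 n_artery_trees = n_artery_trees,
                 n_vein_trees = n_vein_trees,
                 vein_root_diameter_mm = vein_root_diameter_mm,
                 vein_delivery_ms = vein_delivery_ms,
                 vein_pass_through = vein_pass_through,
                 noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude,
                 bias_scale_mm = bias_scale_mm,
                 supersampling = supersampling),
            class = "phantom_config")
}

# velocity monotone (linear) in diameter, clipped to the configured range
velocity_from_diameter <- function(cfg, d_mm) {
  dr <- cfg$diameter_range_mm
  vr <- cfg$velocity_range_mm_s
  f <- (pmin(pmax(d_mm, dr[1]), dr[2]) - dr[1]) / (dr[2] - dr[1])
  vr[1] + f * (vr[2] - vr[1])
}

# unit vectors orthogonal to u
orthonormal_pair <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- a - sum(a * u) * u
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  list(v1, v2)
}

#' Generate a synthetic branching vessel tree
#'
#' Binary-branching tree entering the slab on the z = 0 face. Each branch
#' deviates from its parent direction by an angle drawn from a normal prior
#' centred near 90 degrees (truncated to (20, 160)), with uniform azimuth;
#' child diameters shrink by the configured taper; the blood delivery time
#' accumulates parent length over parent velocity along the path from the
#' root. Directions are reflected at an inner margin so trees stay inside
#' the field of view.
#'
#' @param cfg [phantom_config()].
#' @param seed RNG seed (integer); fixed seed gives an identical tree.
#' @param kind `"artery"` or `"vein"`.
#' @param entry_mm Optional entry point on the z = 0 face (length-3, z
#'   ignored); random by default.
#' @param bounds_mm Optional 2 x 3 matrix (rows: lower, upper world
#'   coordinates in mm) confining the tree; [build_phantom()] hands each
#'   tree its own slab of the field of view so that distinct trees cannot
#'   touch and merge into one connected component.
#' @return An object of class `vessel_tree`: a `data.frame` of segments
#'   (endpoints, diameter, velocity, cumulative delivery time, kind,
#'   branch angle) with the config and seed attached as attributes.
#' @export
generate_tree <- function(cfg, seed = 1, kind = c("artery", "vein"),
                          entry_mm = NULL, bounds_mm = NULL) {
  kind <- match.arg(kind)
  with_seed(seed, {
    fov <- cfg$fov_mm
    if (is.null(bounds_mm)) bounds_mm <- rbind(c(0, 0, 0), fov)
    margin <- max(2 * cfg$voxel_mm, 0.04 * min(fov))
    lo <- bounds_mm[1, ] + margin
    hi <- bounds_mm[2, ] - margin
    if (any(hi <= lo)) stop("degenerate tree bounds", call. = FALSE)
    if (is.null(entry_mm))
      entry_mm <- c(runif(1, lo[1] + 0.25 * (hi[1] - lo[1]),
                          hi[1] - 0.25 * (hi[1] - lo[1])),
                    runif(1, lo[2] + 0.25 * (hi[2] - lo[2]),
                          hi[2] - 0.25 * (hi[2] - lo[2])), 0)
    root_d <- if (kind == "vein") cfg$vein_root_diameter_mm else
      cfg$root_diameter_mm
    root_delivery <- if (kind == "vein" && !cfg$vein_pass_through)
      cfg$vein_delivery_ms else cfg$root_delivery_ms
    depth <- if (kind == "vein") min(cfg$depth, 1L) else cfg$depth
    rows <- list()
    emit <- function(start, dir, diam, delivery, level, angle, parent) {
      len <- runif(1, cfg$seg_length_range_mm[1], cfg$seg_length_range_mm[2])
      # reflect direction components that would leave the margin box
      end <- start + len * dir
      for (ax in 1:3) {
        if (end[ax] < lo[ax] || end[ax] > hi[ax]) {
          dir[ax] <- -dir[ax]
          end <- start + len * dir
        }
      }
      end <- pmin(pmax(end, c(lo[1], lo[2], 0)), hi)
      vel <- velocity_from_diameter(cfg, diam)
      rows[[length(rows) + 1L]] <<- data.frame(
        sx = start[1], sy = start[2], sz = start[3],
        ex = end[1], ey = end[2], ez = end[3],
        diameter_mm = diam, velocity_mm_s = vel,
        delivery_offset_ms = delivery, kind = kind,
        level = level, branch_angle_deg = angle, parent = parent)
      id <- length(rows)
      child_d <- diam * cfg$taper
      if (level < depth && child_d >= cfg$min_diameter_mm) {
        seg_time_ms <- 1000 * len / vel
        basis <- orthonormal_pair(dir)
        for (b in 1:2) {
          ang <- rnorm(1, cfg$branch_angle_mean_deg, cfg$branch_angle_sd_deg)
          ang <- min(max(ang, 20), 160)
          phi <- runif(1, 0, 2 * pi)
          perp <- cos(phi) * basis[[1]] + sin(phi) * basis[[2]]
          cdir <- cos(ang * pi / 180) * dir + sin(ang * pi / 180) * perp
          cdir <- cdir / sqrt(sum(cdir^2))
          emit(end, cdir, child_d, delivery + seg_time_ms,
               level + 1L, ang, id)
        }
      }
    }
    emit(entry_mm, c(0, 0, 1), root_d, root_delivery, 0L, NA_real_, 0L)
    tree <- do.call(rbind, rows)
    structure(tree, class = c("vessel_tree", "data.frame"),
              config = cfg, seed = seed)
  })
}

#' Rasterize a vessel tree into per-voxel blood fraction maps
#'
#' Supersampled point-in-cylinder counting: each voxel is subdivided into
#' `supersampling^3` points and the fraction falling inside any vessel
#' lumen becomes the blood volume fraction. Alongside the fraction map the
#' rasterizer emits the per-voxel blood delivery time (delivery offset of
#' the nearest segment axis plus the along-segment transit time; ties go to
#' the smaller segment index), an artery/vein label map (1/2, 0 elsewhere)
#' and a ground-truth vessel mask defined as fraction above half the
#' maximum fraction attainable for the local vessel diameter.
#'
#' @param tree A `vessel_tree` (or the row-bound segments of several).
#' @param cfg [phantom_config()].
#' @return An object of class `phantom_maps`: list of `volume`s
#'   `fraction`, `delivery_ms`, `label`, `mask`.
#' @export
rasterize_fraction_map <- function(tree, cfg) {
  l <- cfg$voxel_mm
  dims <- pmax(1L, as.integer(round(cfg$fov_mm / l)))
  frac <- array(0, dims)
  delivery <- array(NA_real_, dims)
  label <- array(0L, dims)
  diam_near <- array(NA_real_, dims)
  best_dist <- array(Inf, dims)
  s <- cfg$supersampling
  off1 <- ((seq_len(s) - 0.5) / s - 0.5) * l
  offs <- as.matrix(expand.grid(off1, off1, off1))
  if (!is.null(tree) && nrow(tree) > 0) for (i in seq_len(nrow(tree))) {
    A <- c(tree$sx[i], tree$sy[i], tree$sz[i])
    B <- c(tree$ex[i], tree$ey[i], tree$ez[i])
    D <- B - A
    len <- sqrt(sum(D^2))
    if (len < 1e-9) next
    u <- D / len
    r <- tree$diameter_mm[i] / 2
    pad <- r + l
    lo <- pmax(1L, as.integer(floor((pmin(A, B) - pad) / l)) + 1L)
    hi <- pmin(dims, as.integer(ceiling((pmax(A, B) + pad) / l)))
    if (any(lo > hi)) next
    ix <- seq(lo[1], hi[1]); iy <- seq(lo[2], hi[2]); iz <- seq(lo[3], hi[3])
    ctr <- as.matrix(expand.grid(x = (ix - 0.5) * l, y = (iy - 0.5) * l,
                                 z = (iz - 0.5) * l))
    nb <- nrow(ctr)
    count <- numeric(nb)
    for (k in seq_len(nrow(offs))) {
      px <- ctr[, 1] + offs[k, 1]
      py <- ctr[, 2] + offs[k, 2]
      pz <- ctr[, 3] + offs[k, 3]
      wx <- px - A[1]; wy <- py - A[2]; wz <- pz - A[3]
      traw <- wx * u[1] + wy * u[2] + wz * u[3]
      d2 <- pmax(wx^2 + wy^2 + wz^2 - traw^2, 0)
      # antialiased coverage of the exact finite cylinder (no end caps):
      # linear ramps one sub-cell wide across the lumen boundary and the
      # two end faces (~4x more accurate than hard counting at s = 7)
      h <- l / s
      radial <- pmin(pmax((r - sqrt(d2)) / h + 0.5, 0), 1)
      axial <- pmin(pmax(pmin(traw, len - traw) / h + 0.5, 0), 1)
      count <- count + radial * axial
    }
    fr <- count / nrow(offs)
    # voxel-centre axis distance for nearest-segment maps
    wx <- ctr[, 1] - A[1]; wy <- ctr[, 2] - A[2]; wz <- ctr[, 3] - A[3]
    tc <- pmin(pmax(wx * u[1] + wy * u[2] + wz * u[3], 0), len)
    dc <- sqrt((wx - tc * u[1])^2 + (wy - tc * u[2])^2 + (wz - tc * u[3])^2)
    sub <- as.matrix(expand.grid(ix, iy, iz))
    touched <- fr > 0
    if (!any(touched)) next
    subt <- sub[touched, , drop = FALSE]
    frac[subt] <- pmin(1, frac[subt] + fr[touched])
    closer <- touched & dc < best_dist[sub]
    if (any(closer)) {
      subc <- sub[closer, , drop = FALSE]
      best_dist[subc] <- dc[closer]
      delivery[subc] <- tree$delivery_offset_ms[i] +
        1000 * tc[closer] / tree$velocity_mm_s[i]
      label[subc] <- if (tree$kind[i] == "vein") 2L else 1L
      diam_near[subc] <- tree$diameter_mm[i]
    }
  }
  # ground truth: fraction above half of what a centred vessel of the local
  # (nearest-segment) diameter could attain in this voxel size
  mask <- array(FALSE, dims)
  touched <- which(frac > 0 & !is.na(diam_near))
  if (length(touched) > 0) {
    attain <- blood_volume_fraction(
      vessel_voxel_geometry(diam_near[touched], l))
    mask[touched] <- frac[touched] > 0.5 * attain
  }
  structure(list(
    fraction = volume(frac, l),
    delivery_ms = volume(ifelse(is.na(delivery), 0, delivery), l,
                         meta = list(na_as_zero = TRUE)),
    label = volume(label * 1, l),
    mask = volume(mask * 1, l)),
    class = "phantom_maps", config = cfg)
}

#' Simulate a noiseless TOF echo image from phantom maps
#'
#' Two-compartment signal: the blood fraction carries inflow-enhanced
#' magnetization (delivery-time dependent, Eqs. of the signal model) with
#' the artery or vein T2* of its segment, the remainder carries the tissue
#' steady state with tissue T2*:
#' `S = V * Mz_blood(delivery) * exp(-TE/T2*_kind) +
#'      (1 - V) * Mz_tissue * exp(-TE/T2*_tissue)`.
#' Noise and bias are added separately so that downstream tests can use
#' the clean image as reference.
#'
#' @param maps `phantom_maps` from [rasterize_fraction_map()].
#' @param acq,tis Parameter bundles; default to those in the phantom
#'   config.
#' @param echo_index Which entry of `acq$te_ms` to simulate.
#' @return `volume` of magnitude signal.
#' @export
simulate_tof <- function(maps, acq = NULL, tis = NULL, echo_index = 1) {
  cfg <- attr(maps, "config")
  if (is.null(acq)) acq <- cfg$acq
  if (is.null(tis)) tis <- cfg$tis
  check_same_grid(maps$fraction, maps$delivery_ms, "phantom maps")
  check_same_grid(maps$fraction, maps$label, "phantom maps")
  te <- acq$te_ms[echo_index]
  if (is.na(te)) stop("echo_index beyond te_ms", call. = FALSE)
  v <- maps$fraction$data
  lab <- maps$label$data
  mzt <- steady_state_mz(acq, tis, tis$t1_tissue_ms)
  mzb <- inflow_blood_mz(acq, tis,
                         flow_params(delivery_ms = maps$delivery_ms$data))
  t2s_blood <- ifelse(lab == 2, tis$t2s_vein_ms, tis$t2s_artery_ms)
  sig <- v * mzb * exp(-te / t2s_blood) +
    (1 - v) * mzt * exp(-te / tis$t2s_tissue_ms)
  dim(sig) <- dim(v)
  volume(sig, maps$fraction$voxel_mm, affine = maps$fraction$affine)
}

#' Add Rician noise to a magnitude volume
#'
#' The volume is treated as the real channel of a complex image and
#' independent Gaussian noise of standard deviation `sigma` is added to
#' both channels before taking the magnitude:
#' `|signal + n_re + i n_im|`. For zero signal this is Rayleigh noise with
#' mean `sigma * sqrt(pi/2)`.
#'
#' @param vol `volume`.
#' @param sigma Noise standard deviation (image units), >= 0.
#' @param seed RNG seed; a fixed seed reproduces the volume bit-exactly.
#' @return Noisy `volume`.
#' @export
add_rician_noise <- function(vol, sigma, seed = 1) {
  stop_if_not(sigma >= 0, msg = "sigma must be non-negative")
  if (sigma == 0) return(vol)
  n <- length(vol$data)
  with_seed(seed, {
    re <- vol$data + rnorm(n, sd = sigma)
    im <- rnorm(n, sd = sigma)
    out <- sqrt(re^2 + im^2)
    dim(out) <- dim(vol$data)
    volume(out, vol$voxel_mm, affine = vol$affine, meta = vol$meta)
  })
}

#' Multiply a volume by a smooth random bias field
#'
#' Seeded white noise is Gaussian-smoothed at `scale_mm` and linearly
#' rescaled to the range `[1 - amplitude, 1 + amplitude]`, then applied
#' multiplicatively — emulating receive-coil shading.
#'
#' @param vol `volume`.
#' @param amplitude Relative amplitude, >= 0.
#' @param scale_mm Spatial scale of the field (mm).
#' @param seed RNG seed.
#' @return List with the biased `volume` and the `field` itself.
#' @export
add_bias_field <- function(vol, amplitude, scale_mm, seed = 1) {
  stop_if_not(amplitude >= 0, msg = "amplitude must be non-negative")
  if (amplitude == 0)
    return(list(volume = vol, field = array(1, dim(vol$data))))
  l <- require_isotropic(vol)
  field <- with_seed(seed, {
    raw <- array(rnorm(length(vol$data)), dim(vol$data))
    gaussian_smooth3(raw, scale_mm / l)
  })
  rng <- range(field)
  field <- if (diff(rng) < 1e-12) array(1, dim(vol$data)) else
    1 - amplitude + 2 * amplitude * (field - rng[1]) / diff(rng)
  out <- volume(vol$data * field, vol$voxel_mm, affine = vol$affine,
                meta = vol$meta)
  list(volume = out, field = field)
}

#' Build a complete labelled phantom
#'
#' Generates arterial and venous trees, rasterizes them, simulates one
#' image per configured echo time and applies bias field and Rician noise
#' as configured. Ground-truth maps are returned untouched.
#'
#' @param cfg [phantom_config()].
#' @param seed Master RNG seed; per-tree/noise/bias sub-seeds are derived
#'   from it.
#' @return An object of class `tof_phantom`: `tree` (all segments),
#'   `maps` (`phantom_maps`), `echoes` (list of noisy `volume`s),
#'   `clean` (list of noiseless `volume`s), `config`, `seed`.
#' @export
build_phantom <- function(cfg = phantom_config(), seed = 1) {
  trees <- list()
  n_tot <- cfg$n_artery_trees + cfg$n_vein_trees
  # one x-slab of the FOV per tree, so components stay disconnected
  slab <- function(i) {
    w <- cfg$fov_mm[1] / n_tot
    rbind(c((i - 1) * w, 0, 0), c(i * w, cfg$fov_mm[2], cfg$fov_mm[3]))
  }
  for (i in seq_len(cfg$n_artery_trees))
    trees[[length(trees) + 1L]] <- generate_tree(cfg, seed = seed * 1000 + i,
                                                 kind = "artery",
                                                 bounds_mm = slab(i))
  for (i in seq_len(cfg$n_vein_trees))
    trees[[length(trees) + 1L]] <- generate_tree(
      cfg, seed = seed * 1000 + cfg$n_artery_trees + i, kind = "vein",
      bounds_mm = slab(cfg$n_artery_trees + i))
  tree <- if (length(trees) > 0) do.call(rbind, trees) else NULL
  maps <- rasterize_fraction_map(tree, cfg)
  clean <- lapply(seq_along(cfg$acq$te_ms), function(e)
    simulate_tof(maps, echo_index = e))
  echoes <- lapply(seq_along(clean), function(e) {
    v <- clean[[e]]
    if (cfg$bias_amplitude > 0)
      v <- add_bias_field(v, cfg$bias_amplitude, cfg$bias_scale_mm,
                          seed = seed * 100 + 7)$volume
    if (cfg$noise_sigma > 0)
      v <- add_rician_noise(v, cfg$noise_sigma, seed = seed * 100 + 13 + e)
    v
  })
  structure(list(tree = tree, maps = maps, echoes = echoes, clean = clean,
                 config = cfg, seed = seed),
            class = "tof_phantom")
}
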