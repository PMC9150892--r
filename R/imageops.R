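#' @useDynLib pialtof, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif median
#' @importFrom utils write.csv
NULL

gaussian_kernel_1d <- function(sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# "same"-size zero-padded 1D convolution of every line of `a` along `axis`
conv1_fft <- function(a, axis, k) {
  d <- dim(a)
  n <- d[axis]
  nk <- length(k)
  nn <- n + nk - 1
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  pad <- matrix(0, nn, ncol(m))
  pad[seq_len(n), ] <- m
  kf <- stats::fft(c(k, rep(0, nn - nk)))
  conv <- Re(stats::mvfft(stats::mvfft(pad) * kf, inverse = TRUE)) / nn
  off <- (nk - 1) / 2
  out <- array(conv[off + seq_len(n), , drop = FALSE], d[perm])
  aperm(out, order(perm))
}

# 1D convolution of a ones-line with an arbitrary kernel: per-position
# weight moments used for edge correction
conv1_ones_kern <- function(n, k) {
  nk <- length(k)
  nn <- n + nk - 1
  conv <- Re(stats::fft(stats::fft(c(rep(1, n), rep(0, nk - 1))) *
                          stats::fft(c(k, rep(0, n - 1))),
                        inverse = TRUE)) / nn
  conv[(nk - 1) / 2 + seq_len(n)]
}

# replicate a length-n vector along `axis` of a d-shaped array
bcast_axis <- function(v, axis, d) {
  perm <- c(axis, setdiff(1:3, axis))
  arr <- array(v, c(d[axis], d[setdiff(1:3, axis)]))
  aperm(arr, order(perm))
}

#' Gaussian smoothing of a 3D array
#'
#' Separable Gaussian low-pass, one pass per axis, each pass a local-linear
#' (Savitzky-Golay) fit with Gaussian weights: identical to plain Gaussian
#' smoothing in the interior, unbiased to first order at the volume faces
#' where the window is one-sided.
#'
#' @param arr 3D array.
#' @param sigma_vox Gaussian sigma in voxels (scalar).
#' @return Smoothed array of identical shape.
#' @keywords internal
gaussian_smooth3 <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  out <- arr
  for (ax in 1:3) out <- smooth1_ll_pass(out, ax, sigma_vox)
  out
}

smooth1_ll_pass <- function(a, axis, sigma_vox) {
  k <- gaussian_kernel_1d(sigma_vox)
  offs <- seq_along(k) - (length(k) + 1) / 2
  k0 <- k
  k1 <- -offs * k
  k2 <- offs^2 * k
  n <- dim(a)[axis]
  s0 <- conv1_fft(a, axis, k0)
  s1 <- conv1_fft(a, axis, k1)
  t0 <- conv1_ones_kern(n, k0)
  t1 <- conv1_ones_kern(n, k1)
  t2 <- conv1_ones_kern(n, k2)
  det <- t0 * t2 - t1^2
  d <- dim(a)
  (s0 * bcast_axis(t2 / det, axis, d) - s1 * bcast_axis(t1 / det, axis, d))
}

as_mask_array <- function(x) {
  if (inherits(x, "volume")) x <- x$data
  stop_if_not(is.array(x), length(dim(x)) == 3,
              msg = "mask must be a 3D array or volume")
  x != 0
}

#' Label connected components of a binary mask
#'
#' @param mask 3D logical/numeric array or `volume`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array of labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26) {
  stop_if_not(connectivity %in% c(6, 18, 26),
              msg = "connectivity must be 6, 18 or 26")
  m <- as_mask_array(mask)
  lab <- .label_components_cpp(as.logical(m), dim(m), as.integer(connectivity))
  n <- attr(lab, "n_components")
  dim(lab) <- dim(m)
  attr(lab, "n_components") <- n
  lab
}

#' Binary dilation
#'
#' @param mask 3D logical array or `volume`.
#' @param connectivity Structuring element: 6, 18 or 26 (default 26).
#' @return Logical array.
#' @export
dilate_mask <- function(mask, connectivity = 26) {
  m <- as_mask_array(mask)
  out <- .dilate_cpp(as.logical(m), dim(m), as.integer(connectivity))
  dim(out) <- dim(m)
  out
}

#' Maximum intensity projection
#'
#' Per-pixel maximum over a slab of slices along one axis.
#'
#' @param vol `volume` or 3D array.
#' @param axis Projection axis, 1-3.
#' @param slab_range Optional `c(first, last)` slice indices (1-based,
#'   inclusive); default is the full extent.
#' @return 2D matrix of maxima.
#' @export
mip <- function(vol, axis = 3, slab_range = NULL) {
  arr <- if (inherits(vol, "volume")) vol$data else vol
  stop_if_not(axis %in% 1:3, msg = "axis must be 1, 2 or 3")
  n <- dim(arr)[axis]
  if (is.null(slab_range)) slab_range <- c(1L, n)
  if (slab_range[1] < 1 || slab_range[2] > n || slab_range[1] > slab_range[2])
    stop("slab_range outside volume extent", call. = FALSE)
  idx <- list(TRUE, TRUE, TRUE)
  idx[[axis]] <- seq(slab_range[1], slab_range[2])
  slab <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  apply(slab, setdiff(1:3, axis), max)
}

#' Dice similarity coefficient of two binary masks
#'
#' @param a,b Binary masks (arrays or `volume`s) on the same grid.
#' @return `2|A∩B| / (|A|+|B|)`; 1 for two empty masks.
#' @export
dice_coefficient <- function(a, b) {
  ma <- as_mask_array(a)
  mb <- as_mask_array(b)
  stop_if_not(identical(dim(ma), dim(mb)), msg = "masks differ in shape")
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(1)
  2 * sum(ma & mb) / denom
}

#' Nearest-neighbour resampling onto a new isotropic grid
#'
#' Maps each target voxel centre to the source voxel containing it (both
#' grids share the world origin, voxel-centre convention). Used to carry a
#' low-resolution vein mask over to a high-resolution segmentation.
#'
#' @param vol Source `volume`.
#' @param new_voxel_mm Target isotropic voxel size (mm).
#' @param new_dim Optional target grid shape; default covers the source
#'   field of view.
#' @return Resampled `volume`.
#' @export
resample_nearest <- function(vol, new_voxel_mm, new_dim = NULL) {
  l_src <- require_isotropic(vol)
  if (is.null(new_dim))
    new_dim <- pmax(1L, as.integer(round(dim(vol$data) * l_src /
                                           new_voxel_mm)))
  map1 <- function(n_new, n_src) {
    centres <- (seq_len(n_new) - 0.5) * new_voxel_mm
    pmin(pmax(ceiling(centres / l_src), 1L), n_src)
  }
  ix <- map1(new_dim[1], dim(vol$data)[1])
  iy <- map1(new_dim[2], dim(vol$data)[2])
  iz <- map1(new_dim[3], dim(vol$data)[3])
  volume(vol$data[ix, iy, iz, drop = FALSE], voxel_mm = new_voxel_mm)
}
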