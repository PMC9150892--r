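#' Two-echo T2* map
#'
#' Mono-exponential two-point estimate from a dual-echo magnitude pair:
#' `T2* = delta_TE / ln(S1 / S2)`. Voxels where the estimate degenerates
#' (`S2 >= S1`, or non-positive signal, as happens in noise) are clamped to
#' `clamp_ms` and flagged; flagged voxels are excluded from component
#' percentiles downstream.
#'
#' @param echo1,echo2 `volume`s of the first and second echo (same grid);
#'   `echo1` is the shorter echo time.
#' @param delta_te_ms Echo-time difference (ms), > 0.
#' @param clamp_ms Value assigned to degenerate voxels (default 1000).
#' @return An object of class `t2star_map`: `values` (`volume`, ms),
#'   `clamped` (logical array), `delta_te_ms`.
#' @export
t2star_map <- function(echo1, echo2, delta_te_ms, clamp_ms = 1000) {
  stop_if_not(delta_te_ms > 0, msg = "delta_te_ms must be positive")
  check_same_grid(echo1, echo2, "echo volumes")
  s1 <- echo1$data
  s2 <- echo2$data
  bad <- !(s1 > 0) | !(s2 > 0) | s2 >= s1
  t2 <- array(clamp_ms, dim(s1))
  ok <- !bad
  t2[ok] <- delta_te_ms / log(s1[ok] / s2[ok])
  structure(list(values = volume(t2, echo1$voxel_mm, affine = echo1$affine),
                 clamped = bad, delta_te_ms = delta_te_ms,
                 clamp_ms = clamp_ms),
            class = "t2star_map")
}

#' Per-component T2* percentile
#'
#' The 90th (by default) percentile of unclamped T2* values within each
#' connected component of a segmentation. Linear interpolation
#' (`quantile` type 7) is the default convention; components consisting
#' only of clamped voxels get `NA` and are treated as arterial downstream.
#'
#' @param t2map [t2star_map()].
#' @param components Integer label array (0 background), e.g. from
#'   [segment_vessels()] or [label_components()].
#' @param prob Percentile in (0, 1); default 0.9.
#' @param type `stats::quantile` algorithm type (default 7, linear
#'   interpolation).
#' @return Named numeric vector, one entry per component label.
#' @export
component_t2star_p90 <- function(t2map, components, prob = 0.9, type = 7) {
  stop_if_not(inherits(t2map, "t2star_map"),
              msg = "t2map must be a t2star_map")
  labs <- sort(unique(components[components > 0]))
  vals <- t2map$values$data
  ok <- !t2map$clamped
  out <- vapply(labs, function(lb) {
    sel <- components == lb & ok
    if (!any(sel)) return(NA_real_)
    quantile(vals[sel], prob, names = FALSE, type = type)
  }, numeric(1))
  names(out) <- labs
  out
}

#' Remove venous components from a segmentation
#'
#' A connected vessel tree is deemed venous when the 90th percentile of its
#' T2* values falls below `threshold_ms` (deoxygenated venous blood has
#' markedly shorter T2* than arterial blood or tissue). Venous components
#' are removed from the vessel mask; components without any valid T2*
#' estimate are retained (arterial by default). Larger thresholds remove a
#' superset of components. Note the documented failure mode: an artery and
#' a vein artefactually merged into one component are classified jointly by
#' their pooled percentile.
#'
#' @param seg `segmentation_result` from [segment_vessels()].
#' @param t2map [t2star_map()] on the same grid.
#' @param threshold_ms Exclusion threshold (ms); 19 is the usual choice,
#'   27 when merged artery-vein components must be protected.
#' @param prob,type Percentile convention, see [component_t2star_p90()].
#' @return A list of class `vein_removal_result`: `arterial_mask`,
#'   `venous_mask`, `removed_labels`, `p90_ms` (per component),
#'   `decision` data.frame (label, voxels, p90, venous).
#' @export
remove_veins <- function(seg, t2map, threshold_ms = 19, prob = 0.9,
                         type = 7) {
  stop_if_not(threshold_ms >= 0, msg = "threshold_ms must be non-negative")
  comps <- seg$components
  p90 <- component_t2star_p90(t2map, comps, prob = prob, type = type)
  labs <- as.integer(names(p90))
  venous <- !is.na(p90) & p90 < threshold_ms
  removed <- labs[venous]
  venous_mask <- array(comps %in% removed, dim(comps))
  arterial_mask <- seg$vessel_mask & !venous_mask
  decision <- data.frame(
    label = labs,
    voxels = seg$component_sizes[labs],
    p90_t2s_ms = as.numeric(p90),
    venous = venous
  )
  structure(list(arterial_mask = arterial_mask, venous_mask = venous_mask,
                 removed_labels = removed, p90_ms = p90,
                 decision = decision, threshold_ms = threshold_ms),
            class = "vein_removal_result")
}

#' Mark venous components of a high-resolution segmentation from a
#' low-resolution vein mask
#'
#' Auxiliary-scan route for protocols where a second echo is only feasible
#' at low resolution: the low-resolution venous mask is carried to the
#' high-resolution grid by nearest-neighbour resampling and any
#' high-resolution component overlapping it by at least `min_overlap` of
#' its voxels is marked venous.
#'
#' @param seg High-resolution `segmentation_result`.
#' @param vein_mask_low Low-resolution venous mask (`volume`).
#' @param high_voxel_mm Voxel size of the high-resolution grid (mm).
#' @param min_overlap Fraction of component voxels that must overlap
#'   (default 0.5).
#' @return Same structure as [remove_veins()] (without percentiles).
#' @export
mark_veins_from_lowres <- function(seg, vein_mask_low, high_voxel_mm,
                                   min_overlap = 0.5) {
  res <- resample_nearest(vein_mask_low, high_voxel_mm,
                          new_dim = dim(seg$components))
  veins_hi <- as_mask_array(res)
  labs <- seq_len(attr(seg$components, "n_components"))
  venous <- vapply(labs, function(lb) {
    sel <- seg$components == lb
    mean(veins_hi[sel]) >= min_overlap
  }, logical(1))
  removed <- labs[venous]
  venous_mask <- array(seg$components %in% removed, dim(seg$components))
  structure(list(arterial_mask = seg$vessel_mask & !venous_mask,
                 venous_mask = venous_mask, removed_labels = removed,
                 p90_ms = NULL,
                 decision = data.frame(label = labs,
                                       voxels = seg$component_sizes[labs],
                                       venous = venous),
                 threshold_ms = NA_real_),
            class = "vein_removal_result")
}
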