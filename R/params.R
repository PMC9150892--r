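#' Acquisition parameter bundle
#'
#' Sequence parameters of a spoiled 3D gradient-echo (FLASH) time-of-flight
#' acquisition. Angles are degrees at all interfaces; times are milliseconds;
#' lengths are millimetres.
#'
#' @param tr_ms Repetition time TR (ms).
#' @param flip_deg Excitation flip angle (degrees), in (0, 90].
#' @param te_ms Echo time(s) TE (ms); a vector for multi-echo protocols.
#'   All echoes must fit within TR.
#' @param voxel_mm Isotropic voxel edge length (mm).
#' @param phase_blip_ms Time of the phase-encoding blip relative to
#'   excitation (ms); used by the vessel-displacement model.
#' @return An object of class `acquisition_params`.
#' @examples
#' acq <- acquisition_params(tr_ms = 20, flip_deg = 18, te_ms = c(7.05, 14))
#' @export
acquisition_params <- function(tr_ms = 20, flip_deg = 18,
                               te_ms = c(7.05, 14), voxel_mm = 0.3,
                               phase_blip_ms = 2) {
  stop_if_not(is.numeric(tr_ms), length(tr_ms) == 1, tr_ms > 0,
              msg = "tr_ms must be a single positive number")
  stop_if_not(is.numeric(flip_deg), length(flip_deg) == 1,
              flip_deg > 0, flip_deg <= 90,
              msg = "flip_deg must be in (0, 90]")
  stop_if_not(is.numeric(te_ms), all(te_ms > 0), all(te_ms < tr_ms),
              msg = "all te_ms must be positive and smaller than tr_ms")
  stop_if_not(is.numeric(voxel_mm), voxel_mm > 0,
              msg = "voxel_mm must be positive")
  stop_if_not(is.numeric(phase_blip_ms), phase_blip_ms >= 0,
              msg = "phase_blip_ms must be non-negative")
  structure(list(tr_ms = tr_ms, flip_deg = flip_deg, te_ms = te_ms,
                 voxel_mm = voxel_mm, phase_blip_ms = phase_blip_ms),
            class = "acquisition_params")
}

#' Tissue and blood relaxation parameters
#'
#' Longitudinal relaxation times of arterial blood and static tissue and the
#' effective transverse relaxation times used for echo weighting and
#' artery/vein separation. Defaults are 7 T values: T1 blood/tissue
#' 2100/1950 ms; arterial T2* close to tissue, venous T2* markedly shorter
#' because of deoxygenated haemoglobin.
#'
#' @param t1_blood_ms T1 of arterial blood (ms).
#' @param t1_tissue_ms T1 of static tissue (ms).
#' @param m0 Thermal equilibrium magnetization (arbitrary units). All signal
#'   outputs scale linearly in `m0`.
#' @param t2s_tissue_ms,t2s_artery_ms,t2s_vein_ms Effective T2* (ms).
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(t1_blood_ms = 2100, t1_tissue_ms = 1950, m0 = 1,
                          t2s_tissue_ms = 33, t2s_artery_ms = 30,
                          t2s_vein_ms = 12) {
  vals <- c(t1_blood_ms, t1_tissue_ms, t2s_tissue_ms, t2s_artery_ms,
            t2s_vein_ms)
  stop_if_not(all(is.finite(vals)), all(vals > 0),
              msg = "all relaxation times must be positive")
  stop_if_not(is.numeric(m0), m0 > 0, msg = "m0 must be positive")
  structure(list(t1_blood_ms = t1_blood_ms, t1_tissue_ms = t1_tissue_ms,
                 m0 = m0, t2s_tissue_ms = t2s_tissue_ms,
                 t2s_artery_ms = t2s_artery_ms, t2s_vein_ms = t2s_vein_ms),
            class = "tissue_params")
}

#' Blood flow parameters
#'
#' @param delivery_ms Blood delivery time (ms): time from the blood entering
#'   the imaging slab until it reaches the voxel of interest. Determines the
#'   number of RF pulses the blood has experienced.
#' @param velocity_mm_s Blood velocity (mm/s).
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(delivery_ms = 300, velocity_mm_s = 30) {
  stop_if_not(is.numeric(delivery_ms), delivery_ms >= 0,
              msg = "delivery_ms must be non-negative")
  stop_if_not(is.numeric(velocity_mm_s), velocity_mm_s >= 0,
              msg = "velocity_mm_s must be non-negative")
  structure(list(delivery_ms = delivery_ms, velocity_mm_s = velocity_mm_s),
            class = "flow_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("Acquisition: TR", x$tr_ms, "ms, flip", x$flip_deg,
      "deg, TE", paste(x$te_ms, collapse = "/"), "ms, voxel",
      x$voxel_mm, "mm\n")
  invisible(x)
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("Tissue: T1 blood/tissue", x$t1_blood_ms, "/", x$t1_tissue_ms,
      "ms; T2* tissue/artery/vein", x$t2s_tissue_ms, "/", x$t2s_artery_ms,
      "/", x$t2s_vein_ms, "ms; M0", x$m0, "\n")
  invisible(x)
}

#' @export
print.flow_params <- function(x, ...) {
  cat("Flow: delivery", x$delivery_ms, "ms, velocity",
      x$velocity_mm_s, "mm/s\n")
  invisible(x)
}

# internal: compact validator with a single message
stop_if_not <- function(..., msg) {
  conds <- c(...)
  if (!all(conds)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
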