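#' Velocity- and TE-dependent vessel displacement
#'
#' Blood moving along a phase-encoding direction between the phase-encoding
#' blip (at `t_pe_ms` after excitation) and the echo (at `te_ms`) is mapped
#' to a shifted position, displacing the vessel in the reconstructed image:
#' \deqn{\Delta y = -v_y (TE - t_{pe}).}
#' The same relation applies independently to the secondary (slab)
#' phase-encoding axis with that axis's velocity component.
#'
#' @param velocity_mm_s Blood velocity component along the phase-encoding
#'   axis (mm/s); sign follows the axis orientation.
#' @param te_ms Echo time (ms).
#' @param t_pe_ms Phase-encoding blip time (ms); must not exceed `te_ms`.
#' @return Signed displacement (mm); a positive velocity yields a negative
#'   shift.
#' @examples
#' vessel_shift_mm(200, te_ms = 12, t_pe_ms = 2) # -2 mm
#' @export
vessel_shift_mm <- function(velocity_mm_s, te_ms, t_pe_ms) {
  stop_if_not(all(te_ms >= t_pe_ms), all(t_pe_ms >= 0),
              msg = "need te_ms >= t_pe_ms >= 0")
  -velocity_mm_s * (te_ms - t_pe_ms) / 1000
}

#' Displacement magnitude range over a velocity interval
#'
#' Convenience bound for protocol planning: displacement magnitudes in
#' micrometres at the two velocity bounds for a given blip-to-echo delay.
#' For pial-artery velocities of 5-50 mm/s and a 5 ms delay this spans
#' 25-250 um.
#'
#' @param v_min_mm_s,v_max_mm_s Velocity bounds (mm/s), `v_min <= v_max`.
#' @param delay_ms Delay TE - t_pe (ms).
#' @return Named numeric vector `c(min_um, max_um)`.
#' @export
shift_range_um <- function(v_min_mm_s, v_max_mm_s, delay_ms) {
  stop_if_not(v_min_mm_s <= v_max_mm_s, msg = "need v_min <= v_max")
  stop_if_not(delay_ms >= 0, msg = "delay_ms must be non-negative")
  c(min_um = abs(vessel_shift_mm(v_min_mm_s, delay_ms, 0)) * 1000,
    max_um = abs(vessel_shift_mm(v_max_mm_s, delay_ms, 0)) * 1000)
}
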