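#' Steady-state longitudinal magnetization of a spoiled gradient echo
#'
#' Ernst equation for the steady state reached by static spins under a
#' spoiled FLASH sequence:
#' \deqn{M_z^S = M_0 (1 - E_1) / (1 - E_1 \cos\theta), \quad
#'       E_1 = e^{-TR/T_1}.}
#'
#' @param acq [acquisition_params()] (TR, flip angle).
#' @param tis [tissue_params()] (supplies M0).
#' @param t1_ms Longitudinal relaxation time of the spin pool (ms); pass
#'   `tis$t1_tissue_ms` for tissue or `tis$t1_blood_ms` for blood.
#' @return Longitudinal magnetization, in (0, M0].
#' @examples
#' acq <- acquisition_params(tr_ms = 20, flip_deg = 18)
#' steady_state_mz(acq, tissue_params(), t1_ms = 1950)
#' @export
steady_state_mz <- function(acq, tis, t1_ms) {
  stop_if_not(is.numeric(t1_ms), all(t1_ms > 0),
              msg = "t1_ms must be positive")
  e1 <- exp(-acq$tr_ms / t1_ms)
  tis$m0 * (1 - e1) / (1 - e1 * cos(acq$flip_deg * pi / 180))
}

#' Longitudinal magnetization of inflowing blood
#'
#' Blood entering the imaging slab is fully relaxed; each RF pulse and the
#' TR-long recovery interval between pulses drive it towards the blood
#' steady state. Just before the n-th pulse,
#' \deqn{M_z(n) = M_z^{S,blood} +
#'   (e^{-TR/T_{1,blood}}\cos\theta)^{\,n-1}\,(M_0 - M_z^{S,blood}),}
#' with the pulse count set by the blood delivery time,
#' `n = max(1, round(delivery_ms / tr_ms))`. Partial TR intervals are not
#' modelled (plug flow; see the methods vignette).
#'
#' @inheritParams steady_state_mz
#' @param flow [flow_params()] (delivery time).
#' @param n_rf Optional explicit pulse count overriding the delivery-derived
#'   value (used by property tests).
#' @return Longitudinal magnetization of blood just before the n-th pulse.
#' @export
inflow_blood_mz <- function(acq, tis, flow, n_rf = NULL) {
  if (is.null(n_rf)) {
    stop_if_not(flow$delivery_ms >= 0, msg = "delivery_ms must be >= 0")
    n_rf <- pmax(1, round(flow$delivery_ms / acq$tr_ms))
  }
  stop_if_not(all(n_rf >= 1), msg = "n_rf must be >= 1")
  mzs <- steady_state_mz(acq, tis, tis$t1_blood_ms)
  decay <- exp(-acq$tr_ms / tis$t1_blood_ms) * cos(acq$flip_deg * pi / 180)
  mzs + decay^(n_rf - 1) * (tis$m0 - mzs)
}

#' Relative flow-related enhancement (FRE)
#'
#' The fundamental TOF contrast: the difference between inflowing-blood
#' magnetization and the tissue steady state, relative to the tissue steady
#' state, \eqn{(M_z^{blood} - M_z^{S,tissue}) / M_z^{S,tissue}}. The common
#' \eqn{\sin\theta} excitation factor cancels, so the ratio applies to
#' measured signals as well as magnetizations.
#'
#' @inheritParams inflow_blood_mz
#' @return Dimensionless ratio; 0 means blood and tissue are isointense,
#'   1 means twice the tissue signal.
#' @export
relative_fre <- function(acq, tis, flow, n_rf = NULL) {
  mzt <- steady_state_mz(acq, tis, tis$t1_tissue_ms)
  (inflow_blood_mz(acq, tis, flow, n_rf = n_rf) - mzt) / mzt
}

#' Ernst angle
#'
#' Flip angle maximizing the spoiled-GRE steady-state signal:
#' \eqn{\theta_E = \arccos(e^{-TR/T_1})}.
#'
#' @param tr_ms Repetition time (ms).
#' @param t1_ms Longitudinal relaxation time (ms).
#' @return Angle in degrees.
#' @examples
#' ernst_angle_deg(20, 1950) # about 8.2 degrees
#' @export
ernst_angle_deg <- function(tr_ms, t1_ms) {
  stop_if_not(all(tr_ms > 0), all(t1_ms > 0),
              msg = "tr_ms and t1_ms must be positive")
  acos(exp(-tr_ms / t1_ms)) * 180 / pi
}

#' FRE-optimal excitation flip angle
#'
#' Exhaustive grid search for the flip angle in (0, 90] degrees that
#' maximizes [relative_fre()] at fixed TR and blood delivery time. Ties are
#' broken towards the smaller angle; the reported optimum is rounded to the
#' nearest integer degree (set `round_deg = FALSE` for the raw grid argmax).
#'
#' @inheritParams steady_state_mz
#' @param delivery_ms Blood delivery time (ms).
#' @param grid_step_deg Grid resolution (degrees), default 0.05.
#' @param round_deg Round the result to the nearest degree (default TRUE).
#' @return Optimal flip angle in degrees.
#' @examples
#' acq <- acquisition_params(tr_ms = 20, flip_deg = 18)
#' optimal_flip_deg(acq, tissue_params(), delivery_ms = 1000) # 11
#' @export
optimal_flip_deg <- function(acq, tis, delivery_ms, grid_step_deg = 0.05,
                             round_deg = TRUE) {
  stop_if_not(grid_step_deg > 0, msg = "grid_step_deg must be positive")
  grid <- seq(grid_step_deg, 90, by = grid_step_deg)
  if (length(grid) == 0L) stop("empty flip-angle grid", call. = FALSE)
  flow <- flow_params(delivery_ms = delivery_ms)
  vals <- vapply(grid, function(th) {
    a <- acq
    a$flip_deg <- th
    relative_fre(a, tis, flow)
  }, numeric(1))
  best <- grid[which.max(vals)] # which.max returns first (smallest) argmax
  if (round_deg) round(best) else best
}

#' Blood dwell time
#'
#' Average time blood needs to traverse one voxel, `1000 * voxel / velocity`
#' in ms. Determines whether multiple velocity segments per voxel must be
#' modelled; for mesoscopic pial arteries the dwell time is well below
#' typical TR values, so single-segment plug flow suffices.
#'
#' @param voxel_mm Voxel edge length (mm).
#' @param velocity_mm_s Blood velocity (mm/s). Zero velocity yields `Inf`.
#' @return Dwell time (ms); vectorized over both arguments.
#' @export
blood_dwell_time_ms <- function(voxel_mm, velocity_mm_s) {
  stop_if_not(all(voxel_mm > 0), all(velocity_mm_s >= 0),
              msg = "voxel_mm must be positive, velocity_mm_s non-negative")
  ifelse(velocity_mm_s == 0, Inf, 1000 * voxel_mm / velocity_mm_s)
}

#' FRE surface over delivery time and flip angle or TR
#'
#' Dense table of relative FRE over a grid of blood delivery times crossed
#' with either flip angles (`vary = "flip"`) or repetition times
#' (`vary = "tr"`). Used to reproduce protocol-optimization curves: at an
#' 18-degree flip angle, longer TRs win for delivery times beyond roughly
#' 200 ms.
#'
#' @inheritParams steady_state_mz
#' @param delivery_grid Vector of delivery times (ms).
#' @param par_grid Vector of flip angles (deg) or TRs (ms), per `vary`.
#' @param vary Which acquisition parameter `par_grid` refers to.
#' @return `data.frame` with columns tr_ms, flip_deg, delivery_ms, fre.
#' @export
fre_surface <- function(acq, tis, delivery_grid, par_grid,
                        vary = c("flip", "tr")) {
  vary <- match.arg(vary)
  stop_if_not(length(delivery_grid) > 0, length(par_grid) > 0,
              msg = "grids must be non-empty")
  grid <- expand.grid(delivery_ms = delivery_grid, par = par_grid,
                      KEEP.OUT.ATTRS = FALSE)
  fre <- mapply(function(del, p) {
    a <- acq
    if (vary == "flip") a$flip_deg <- p else a$tr_ms <- p
    relative_fre(a, tis, flow_params(delivery_ms = del))
  }, grid$delivery_ms, grid$par)
  data.frame(
    tr_ms = if (vary == "tr") grid$par else acq$tr_ms,
    flip_deg = if (vary == "flip") grid$par else acq$flip_deg,
    delivery_ms = grid$delivery_ms,
    fre = fre
  )
}
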