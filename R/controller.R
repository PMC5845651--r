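#' View-angle controller of the virtual-reality rig
#'
#' Treadmill displacements (dX, dY) set the rate of change of the virtual
#' view angle through an exponential gain: the displacement angle is
#' `Theta = atan2(-dX * sign(dY), |dY|)` and the angular rate is
#' `dtheta/dt = sign(Theta) * min(exp(1.4 * |Theta|^1.2) - 1, pi)` rad/s.
#' The gain damps small displacement angles (stabilizing running down the
#' stem) while still allowing sharp turns into the arms; the rate is capped
#' at pi rad/s. In the rig's raw convention a rightward dX gives a negative
#' angle; session logs store the package-wide convention (positive =
#' rightward), so the sign is flipped once at log-writing time by the
#' simulator, not here.
#'
#' @param dX,dY Treadmill displacement over the step, cm.
#' @param dt Step duration, s (> 0).
#' @return The view-angle increment `dtheta` in radians over the step
#'   (zero when both displacements are zero).
#' @export
#' @examples
#' view_angle_controller(0, 1, 0.01)   # straight ahead: no rotation
#' view_angle_controller(1, 0.5, 0.01) # leftward rotation in raw convention
view_angle_controller <- function(dX, dY, dt) {
  if (dt <= 0) abort("`dt` must be positive.")
  if (dX == 0 && dY == 0) return(0)
  theta_disp <- atan2(-dX * sign(dY), abs(dY))
  rate <- sign(theta_disp) * min(exp(1.4 * abs(theta_disp)^1.2) - 1, pi)
  rate * dt
}
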