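#' Valve orifice area ratio
#'
#' Fraction of the maximal orifice area exposed at leaflet opening angle
#' `theta`: `AR = ((1 - cos theta) / (1 - cos theta_max))^2`, zero when the
#' valve is closed and one when fully open, monotone non-decreasing in
#' between.  Angles slightly outside `[0, theta_max]` (adaptive-solver
#' overshoot) are clamped with a warning.
#'
#' @param theta leaflet opening angle (rad), vectorized.
#' @param theta_max fully-open angle (rad).
#' @return area ratio in `[0, 1]`.
#' @export
#' @examples
#' valve_area_ratio(0, 75 * pi / 180)          # 0
#' valve_area_ratio(75 * pi / 180, 75 * pi / 180)  # 1
valve_area_ratio <- function(theta, theta_max) {
  stopifnot(theta_max > 0)
  if (any(theta < 0 | theta > theta_max)) {
    warning("valve angle outside [0, theta_max]; clamped")
    theta <- pmin(pmax(theta, 0), theta_max)
  }
  ((1 - cos(theta)) / (1 - cos(theta_max)))^2
}

## orifice flow law: Q = CQ * AR * sign(dP) * sqrt(|dP|)
valve_flow <- function(dp, theta, cq, theta_max) {
  theta <- pmin(pmax(theta, 0), theta_max)
  ar <- ((1 - cos(theta)) / (1 - cos(theta_max)))^2
  cq * ar * sign(dp) * sqrt(abs(dp))
}

#' Leaflet angular acceleration
#'
#' Second-order valve dynamics: the angular acceleration is the sum of four
#' torque-like terms - transvalvular pressure (`Kp`), friction (`-Kf
#' dtheta/dt`), drag of the moving blood (`Kb`), and the vortex downstream of
#' the orifice that promotes closure (`Kv`):
#' `Kp dP cos(theta) - Kf omega + Kb Q cos(theta) - Kv Q sin(2 theta)`.
#'
#' @param theta leaflet angle (rad).
#' @param omega angular velocity (rad/s).
#' @param dp transvalvular pressure difference, upstream minus downstream
#'   (mmHg).
#' @param q instantaneous valve flow (ml/s).
#' @param K named list/vector with elements `Kp`, `Kf`, `Kb`, `Kv`.
#' @return angular acceleration (rad/s^2).
#' @export
valve_angle_dynamics <- function(theta, omega, dp, q, K) {
  K <- as.list(K)
  K$Kp * dp * cos(theta) - K$Kf * omega + K$Kb * q * cos(theta) -
    K$Kv * q * sin(2 * theta)
}

## smooth stiff-contact stops used inside the rhs: mirrors src/cardio.c
KSTOP <- 1e6
DSTOP <- 2e3

valve_dyn_clamped <- function(theta, omega, dp, q, K, theta_max) {
  thc <- min(max(theta, 0), theta_max)
  torque <- K$Kp * dp * cos(thc) - K$Kf * omega + K$Kb * q * cos(thc) -
    K$Kv * q * sin(2 * thc)
  if (theta > theta_max) {
    torque <- torque - KSTOP * (theta - theta_max)
    if (omega > 0) torque <- torque - DSTOP * omega
  } else if (theta < 0) {
    torque <- torque - KSTOP * theta
    if (omega < 0) torque <- torque - DSTOP * omega
  }
  c(omega, torque)
}
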