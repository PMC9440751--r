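#' Weight-normalized wing area and wing loading
#'
#' Converts field-unit morphology (wing area in cm^2, body mass in g) to SI
#' and returns the weight-normalized wing area S/mg (m^2 N^-1) together with
#' its exact reciprocal, the wing loading mg/S (N m^-2). S is the total wing
#' area of both wing pairs.
#'
#' @param wing_area_cm2 total wing area (cm^2)
#' @param mass_g body mass (g)
#' @param g gravitational acceleration (m s^-2)
#' @return list with \code{S_over_mg} (m^2 N^-1), \code{wing_loading}
#'   (N m^-2) and \code{weight} (N)
#' @export
weight_normalized_wing_area <- function(wing_area_cm2, mass_g, g = 9.81) {
  if (any(wing_area_cm2 <= 0) || any(mass_g <= 0) || g <= 0)
    stop("wing area, mass and g must be positive")
  S <- wing_area_cm2 * 1e-4          # cm^2 -> m^2
  mg <- (mass_g * 1e-3) * g          # g -> kg -> N
  list(S_over_mg = S / mg, wing_loading = mg / S, weight = mg)
}

#' Weight-normalized aerodynamic thrust of a flapping wing
#'
#' The quasi-steady thrust model for a climbing flapping flyer: the
#' weight-normalized thrust T/mg varies quadratically with the speed of the
#' beating wing and linearly with air density, the weight-normalized wing
#' area, the wing angle of attack, and the angle-of-attack-specific thrust
#' coefficient:
#' \deqn{T/mg = \tfrac12 \rho U_{wing}^2 (S/mg) C_{T\alpha} \alpha}
#' with the conventional 1/2 dynamic-pressure factor and the small-angle
#' linear thrust coefficient C_T = C_Talpha * alpha (alpha in radians).
#'
#' @param U_wing wing speed (m s^-1)
#' @param S_over_mg weight-normalized wing area (m^2 N^-1)
#' @param alpha angle of attack (rad, in [0, pi/2])
#' @param rho air density (kg m^-3); default 1.17, warm air at ~450 m
#'   elevation
#' @param C_T_alpha thrust coefficient slope (per rad); default 1, configurable
#'   because its value is geometry specific
#' @return dimensionless weight-normalized thrust T/mg
#' @export
thrust_ratio <- function(U_wing, S_over_mg, alpha, rho = 1.17,
                         C_T_alpha = 1) {
  if (any(U_wing < 0) || any(S_over_mg < 0) || rho <= 0 || C_T_alpha < 0)
    stop("thrust model inputs must be non-negative (rho positive)")
  if (any(alpha < 0) || any(alpha > pi / 2))
    stop("alpha must be in [0, pi/2] radians")
  0.5 * rho * U_wing^2 * S_over_mg * C_T_alpha * alpha
}

#' Steady-climb force balance
#'
#' Force balance of a climbing flyer at constant speed: thrust (magnitude
#' T/mg, direction \code{angle} degrees above horizontal) against unit weight
#' and an optional weight-normalized drag along the horizontal.
#'
#' @param T_mg weight-normalized thrust (dimensionless, >= 0)
#' @param angle thrust direction above horizontal (deg)
#' @param drag_mg weight-normalized drag opposing horizontal motion
#' @param tol residual tolerance for declaring balance
#' @return list with \code{residual} (named c(horizontal, vertical), in units
#'   of weight) and \code{is_balanced}
#' @export
steady_climb_balance <- function(T_mg, angle, drag_mg = 0, tol = 1e-8) {
  if (T_mg < 0) stop("T/mg must be non-negative")
  a <- deg2rad(angle)
  res <- c(horizontal = T_mg * cos(a) - drag_mg,
           vertical = T_mg * sin(a) - 1)
  list(residual = res, is_balanced = all(abs(res) < tol))
}

#' Climb angle versus body pitch: the helicopter-model relation
#'
#' Under body-fixed force vectoring ("helicopter model") the direction of the
#' aerodynamic thrust is locked to the body, so the climb angle should track
#' the body pitch angle. This fits the ordinary least-squares line of the
#' climb angle on the body pitch angle across wingbeats.
#'
#' @param beta_wingbeat body pitch angles (deg)
#' @param gamma_climb climb angles (deg)
#' @return a regression fit as returned by [linear_regression()]
#' @export
helicopter_prediction <- function(beta_wingbeat, gamma_climb) {
  linear_regression(beta_wingbeat, gamma_climb)
}
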