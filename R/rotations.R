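#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes. Angles are in radians;
#' these are internal building blocks, exported user-facing functions take
#' degrees.
#'
#' @param a rotation angle (rad)
#' @return 3x3 rotation matrix
#' @keywords internal
#' @name rotmat
NULL

#' @rdname rotmat
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0,
           0, ca, sa,
           0, -sa, ca), 3, 3)
}

#' @rdname rotmat
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa,
           0, 1, 0,
           sa, 0, ca), 3, 3)
}

#' @rdname rotmat
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0,
           -sa, ca, 0,
           0, 0, 1), 3, 3)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Body orientation from yaw, pitch and roll
#'
#' Builds the body-to-world rotation for the intrinsic Z (yaw) - Y (pitch) -
#' X (roll) Euler sequence used for the butterfly body. The body x-axis is the
#' long axis pointing toward the head; the world frame is right handed with z
#' up (gravity along -z). Positive pitch raises the head above the horizon, so
#' at pitch = 90 deg the body x-axis maps onto world +z.
#'
#' @param yaw,pitch,roll Euler angles in degrees
#' @return 3x3 body-to-world rotation matrix with attribute
#'   \code{gimbal_warning} set to TRUE when |pitch| > 89.9 deg (yaw and roll
#'   become nearly indistinguishable there; the rotation itself is still
#'   exact).
#' @seealso [body_angles()] for the inverse decomposition.
#' @export
#' @examples
#' R <- body_frame(0, 90, 0)
#' R %*% c(1, 0, 0)  # body long axis points straight up
body_frame <- function(yaw, pitch, roll) {
  stopifnot(is.finite(yaw), is.finite(pitch), is.finite(roll))
  R <- rot_z(deg2rad(yaw)) %*% rot_y(-deg2rad(pitch)) %*% rot_x(deg2rad(roll))
  attr(R, "gimbal_warning") <- abs(pitch) > 89.9
  R
}

#' Decompose a body rotation into yaw, pitch, roll
#'
#' Inverse of [body_frame()]. Pitch is returned in [-90, 90] deg.
#'
#' @param R 3x3 body-to-world rotation matrix
#' @return named numeric vector (yaw, pitch, roll) in degrees
#' @export
body_angles <- function(R) {
  pitch <- asin(max(-1, min(1, R[3, 1])))
  yaw <- atan2(R[2, 1], R[1, 1])
  roll <- atan2(R[3, 2], R[3, 3])
  c(yaw = rad2deg(yaw), pitch = rad2deg(pitch), roll = rad2deg(roll))
}

# Mirror across the body x-z plane (left <-> right).
.mirror_y <- diag(c(1, -1, 1))

#' Wing orientation from stroke, deviation and rotation angles
#'
#' Composes the wing rotation in the body frame from the three conventional
#' wing Euler angles measured relative to the stroke plane: stroke angle phi
#' (sweep within the stroke plane, zero at the lateral transverse axis,
#' positive dorsal), deviation angle theta (elevation of the span axis out of
#' the stroke plane, positive toward the head) and rotation angle H (pitch of
#' the chord about the span axis). The stroke plane is normal to the body long
#' axis (body x). In the reference pose (0, 0, 0) the span axis of a left wing
#' lies along body +y, the chord along body -x (toward the tail) and the wing
#' normal along body +z. Right wings are the mirror image across the body x-z
#' plane, so a bilaterally symmetric stroke uses the same (phi, theta, H) for
#' both sides.
#'
#' @param phi,theta,H wing Euler angles in degrees
#' @param side "left" or "right"
#' @return 3x3 rotation matrix (body frame); columns map the reference wing
#'   axes, i.e. span = R %*% spanref, with spanref = (0, 1, 0) for a left wing
#'   and (0, -1, 0) for a right wing, chord reference (-1, 0, 0) for left and
#'   mirrored for right.
#' @export
wing_rotation <- function(phi, theta, H, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(is.finite(phi), is.finite(theta), is.finite(H))
  R <- rot_x(deg2rad(phi)) %*% rot_z(-deg2rad(theta)) %*% rot_y(deg2rad(H))
  if (side == "right") R <- .mirror_y %*% R %*% .mirror_y
  R
}

#' Wing Euler angles from a wing orientation
#'
#' Inverse of [wing_rotation()]: recovers (phi, theta, H) from the wing
#' rotation matrix in the body frame. When the span axis is parallel to the
#' body long axis (theta = +/-90 deg) the stroke angle is undefined; the
#' result then carries attribute \code{phi_undefined = TRUE} and phi is
#' reported as 0.
#'
#' @param R 3x3 wing rotation matrix as returned by [wing_rotation()]
#' @param side "left" or "right"
#' @return named numeric vector (phi, theta, H) in degrees
#' @export
wing_euler_angles <- function(R, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "right") R <- .mirror_y %*% R %*% .mirror_y
  s <- R %*% c(0, 1, 0)
  theta <- asin(max(-1, min(1, s[1])))
  undef <- abs(abs(s[1]) - 1) < 1e-12
  phi <- if (undef) 0 else atan2(s[3], s[2])
  M <- rot_z(theta) %*% rot_x(-phi) %*% R
  H <- atan2(M[1, 3], M[1, 1])
  out <- c(phi = rad2deg(phi), theta = rad2deg(theta), H = rad2deg(H))
  attr(out, "phi_undefined") <- undef
  out
}

#' Stroke plane of a wing
#'
#' The stroke plane is the plane normal to the body long axis passing through
#' the wing hinge. Hinge positions are fixed in the body frame.
#'
#' @param yaw,pitch,roll body Euler angles (deg)
#' @param position body centroid position in the world frame (m)
#' @param hinge wing hinge position in the body frame (m)
#' @return list with \code{point} (a world-frame point on the plane: the
#'   hinge) and \code{normal} (unit normal: the body long axis in world
#'   coordinates)
#' @export
stroke_plane <- function(yaw, pitch, roll, position = c(0, 0, 0),
                         hinge = c(0, 0, 0)) {
  R <- body_frame(yaw, pitch, roll)
  list(point = as.numeric(position + R %*% hinge),
       normal = as.numeric(R %*% c(1, 0, 0)))
}
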