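#' Configuration for a synthetic climbing flapping flight
#'
#' Defines the ground truth for one simulated climbing flight: an articulated
#' body with four rigid flat-plate wings, filmed (after [project_flight()]) by
#' a multi-camera rig. Defaults emulate the study conditions of a canopy-type
#' Morpho climb: 240 frames/s recording, wingbeat frequency near 3.85 Hz
#' (0.26 s wingbeats), peak-to-peak stroke amplitude 114 deg, body pitch
#' 67 deg, flight speed near 1.56 m/s and a climb angle near 46.7 deg.
#'
#' @param frame_rate camera frame rate (Hz)
#' @param n_wingbeats number of complete wingbeats simulated
#' @param wingbeat_frequency Hz
#' @param stroke_amplitude peak-to-peak stroke amplitude A_phi (deg, in
#'   [0, 180])
#' @param stroke_mean mean stroke angle (deg)
#' @param deviation_mean,deviation_amplitude mean and amplitude of the
#'   deviation angle profile (deg); the deviation oscillates at twice the
#'   wingbeat frequency (a smooth figure-of-eight), the minimal periodic shape
#'   consistent with observed butterfly strokes
#' @param hind_deviation_offset additive deviation offset for the hindwings
#'   (deg)
#' @param rotation_amplitude amplitude of the wing rotation angle (deg); the
#'   rotation profile is sinusoidal at the wingbeat frequency, so its sign
#'   flips between half-strokes
#' @param body_pitch constant body pitch beta (deg)
#' @param heading world yaw of the flight direction (deg)
#' @param initial_speed mean flight speed U0 (m/s)
#' @param climb_angle climb angle gamma (deg); scalar for a constant climb or
#'   length 2 c(start, end) for a linear ramp over the flight
#' @param speed_modulation relative amplitude of the within-wingbeat speed
#'   oscillation (speed = U0 (1 + m sin(2 pi f t)))
#' @param wing_fore,wing_hind \code{wing_model}s for the fore- and hindwing
#' @param hinge_fore,hinge_hind left-wing hinge positions in the body frame
#'   (m); right hinges are mirrored across the body x-z plane
#' @param pixel_noise_sd default digitizing noise used by [project_flight()]
#'   (px)
#' @param position_noise_sd default observation noise used when perturbing the
#'   truth track directly (m)
#' @param seed integer seed; fully determines every stochastic output derived
#'   from this configuration
#' @return object of class \code{flight_sim_config}
#' @export
flight_sim_config <- function(frame_rate = 240,
                              n_wingbeats = 3,
                              wingbeat_frequency = 3.85,
                              stroke_amplitude = 114,
                              stroke_mean = 0,
                              deviation_mean = -10,
                              deviation_amplitude = 12,
                              hind_deviation_offset = -20,
                              rotation_amplitude = 40,
                              body_pitch = 67,
                              heading = 0,
                              initial_speed = 1.56,
                              climb_angle = 46.7,
                              speed_modulation = 0.2,
                              wing_fore = synthetic_wing_outline(0.06, 0.04),
                              wing_hind = synthetic_wing_outline(0.05, 0.045),
                              hinge_fore = c(0.004, 0.006, 0.002),
                              hinge_hind = c(-0.004, 0.006, 0.000),
                              pixel_noise_sd = 0.5,
                              position_noise_sd = 0.002,
                              seed = 1L) {
  num <- c(frame_rate, n_wingbeats, wingbeat_frequency, stroke_amplitude,
           stroke_mean, deviation_mean, deviation_amplitude,
           hind_deviation_offset, rotation_amplitude, body_pitch, heading,
           initial_speed, climb_angle, speed_modulation, hinge_fore,
           hinge_hind, pixel_noise_sd, position_noise_sd, seed)
  if (any(!is.finite(num))) stop("non-finite value in flight configuration")
  stopifnot(frame_rate > 0, n_wingbeats >= 1, wingbeat_frequency > 0,
            stroke_amplitude >= 0, stroke_amplitude <= 180,
            abs(body_pitch) <= 90, initial_speed > 0,
            length(climb_angle) %in% 1:2, all(abs(climb_angle) <= 90),
            speed_modulation >= 0, speed_modulation < 1,
            pixel_noise_sd >= 0, position_noise_sd >= 0)
  structure(list(frame_rate = frame_rate, n_wingbeats = n_wingbeats,
                 wingbeat_frequency = wingbeat_frequency,
                 stroke_amplitude = stroke_amplitude,
                 stroke_mean = stroke_mean,
                 deviation_mean = deviation_mean,
                 deviation_amplitude = deviation_amplitude,
                 hind_deviation_offset = hind_deviation_offset,
                 rotation_amplitude = rotation_amplitude,
                 body_pitch = body_pitch, heading = heading,
                 initial_speed = initial_speed, climb_angle = climb_angle,
                 speed_modulation = speed_modulation,
                 wing_fore = wing_fore, wing_hind = wing_hind,
                 hinge_fore = hinge_fore, hinge_hind = hinge_hind,
                 pixel_noise_sd = pixel_noise_sd,
                 position_noise_sd = position_noise_sd,
                 seed = as.integer(seed)),
            class = "flight_sim_config")
}

# closed-form integrals of U0 (1 + m sin(a t)) against cos/sin(g0 + k t):
# used so that the truth velocity is the exact analytic derivative of the
# truth position (no finite differencing anywhere in the ground truth).
.path_integrals <- function(t, U0, m, a, g0, k) {
  if (abs(k) < 1e-12) {
    C <- cos(g0) * t
    Z <- sin(g0) * t
    Sc <- cos(g0) * (1 - cos(a * t)) / a
    Ss <- sin(g0) * (1 - cos(a * t)) / a
  } else {
    C <- (sin(g0 + k * t) - sin(g0)) / k
    Z <- (cos(g0) - cos(g0 + k * t)) / k
    ap <- a + k; am <- a - k
    Sc <- -cos(ap * t + g0) / (2 * ap) - cos(am * t - g0) / (2 * am) +
      cos(g0) / (2 * ap) + cos(g0) / (2 * am)
    Ss <- sin(am * t - g0) / (2 * am) - sin(ap * t + g0) / (2 * ap) +
      sin(g0) / (2 * am) + sin(g0) / (2 * ap)
  }
  list(horizontal = U0 * (C + m * Sc), vertical = U0 * (Z + m * Ss))
}

#' Simulate a climbing flapping flight with full ground truth
#'
#' Generates one articulated synthetic flight: a body climbing at the
#' configured climb-angle/speed profile (position, velocity and acceleration
#' are analytic, mutually consistent) carrying four rigid wings whose stroke,
#' deviation and rotation angles follow the configured periodic profiles. All
#' ground-truth quantities needed to validate the downstream pipeline are
#' returned: the trajectory, per-frame body and wing Euler angles,
#' stroke-reversal frames, per-wingbeat climb metrics, and per-wingbeat
#' blade-element kinematics summaries.
#'
#' @param config a \code{flight_sim_config}
#' @return object of class \code{synthetic_flight}: list with elements
#'   \code{config}, \code{trajectory} (a \code{smoothed_trajectory} holding
#'   the truth), \code{body} (a \code{body_pose}), \code{wing_poses} (named
#'   list of per-wing angle data.frames), \code{hinges} (named list),
#'   \code{wings} (named list of \code{wing_model}), \code{reversals},
#'   \code{segments}, \code{metrics} (truth per-wingbeat climb metrics) and
#'   \code{kinematics} (truth per-wingbeat blade-element summaries)
#' @export
simulate_flight <- function(config) {
  stopifnot(inherits(config, "flight_sim_config"))
  cf <- config
  f <- cf$wingbeat_frequency
  fr <- cf$frame_rate
  Tend <- cf$n_wingbeats / f
  n <- round(Tend * fr) + 1
  t <- (seq_len(n) - 1) / fr
  a <- 2 * pi * f
  g0 <- deg2rad(cf$climb_angle[1])
  g1 <- deg2rad(cf$climb_angle[length(cf$climb_angle)])
  k <- (g1 - g0) / Tend
  psi <- deg2rad(cf$heading)
  U0 <- cf$initial_speed; m <- cf$speed_modulation

  gam <- g0 + k * t
  U <- U0 * (1 + m * sin(a * t))
  hor <- U * cos(gam)
  vel <- cbind(hor * cos(psi), hor * sin(psi), U * sin(gam))
  dU <- U0 * m * a * cos(a * t)
  acc_along <- cbind(dU * cos(gam) * cos(psi), dU * cos(gam) * sin(psi),
                     dU * sin(gam))
  acc_turn <- cbind(-U * k * sin(gam) * cos(psi), -U * k * sin(gam) * sin(psi),
                    U * k * cos(gam))
  acc <- acc_along + acc_turn
  pint <- .path_integrals(t, U0, m, a, g0, k)
  pos <- cbind(pint$horizontal * cos(psi), pint$horizontal * sin(psi),
               pint$vertical)
  traj <- smoothed_trajectory(pos, vel, acc, fr)
  body <- body_pose(pos, yaw = cf$heading, pitch = cf$body_pitch, roll = 0,
                    frame_rate = fr)

  phi <- cf$stroke_mean + (cf$stroke_amplitude / 2) * cos(a * t)
  theta_fore <- cf$deviation_mean + cf$deviation_amplitude * cos(2 * a * t)
  theta_hind <- theta_fore + cf$hind_deviation_offset
  H <- cf$rotation_amplitude * sin(a * t)
  wp_fore <- data.frame(frame = seq_len(n), phi = phi, theta = theta_fore, H = H)
  wp_hind <- data.frame(frame = seq_len(n), phi = phi, theta = theta_hind, H = H)
  wing_poses <- list(fore_left = wp_fore, fore_right = wp_fore,
                     hind_left = wp_hind, hind_right = wp_hind)
  mirror <- function(h) c(h[1], -h[2], h[3])
  hinges <- list(fore_left = cf$hinge_fore, fore_right = mirror(cf$hinge_fore),
                 hind_left = cf$hinge_hind, hind_right = mirror(cf$hinge_hind))
  wings <- list(fore_left = cf$wing_fore, fore_right = cf$wing_fore,
                hind_left = cf$wing_hind, hind_right = cf$wing_hind)

  # stroke reversals: stroke angle is max at t = j/f, min at t = (j + 1/2)/f
  ev <- data.frame(
    frame = round(c(rbind((0:(cf$n_wingbeats - 1)) / f,
                          ((0:(cf$n_wingbeats - 1)) + 0.5) / f)) * fr) + 1,
    type = rep(c("top", "bottom"), cf$n_wingbeats))
  ev <- rbind(ev, data.frame(frame = round(Tend * fr) + 1, type = "top"))
  segments <- segment_wingbeats(ev, fr)
  metrics <- wingbeat_metrics(traj, segments)

  states <- lapply(wing_ids(), function(w) {
    blade_element_states(wings[[w]], wing_poses[[w]], wing_side(w), body,
                         hinge = hinges[[w]])
  })
  names(states) <- wing_ids()
  kin <- do.call(rbind, lapply(seq_len(nrow(segments)), function(j) {
    s <- summarize_wingbeat(states, wing_poses, body, segments[j, ])
    data.frame(wingbeat = segments$wingbeat[j],
               alpha_fore = s$alpha_wingbeat[["fore"]],
               alpha_hind = s$alpha_wingbeat[["hind"]],
               U_wingbeat = s$U_wingbeat,
               beta_wingbeat = s$beta_wingbeat,
               A_phi_fore = s$A_phi[["fore"]],
               A_phi_hind = s$A_phi[["hind"]])
  }))

  structure(list(config = cf, trajectory = traj, body = body,
                 wing_poses = wing_poses, hinges = hinges, wings = wings,
                 blade_states = states, reversals = ev, segments = segments,
                 metrics = metrics, kinematics = kin),
            class = "synthetic_flight")
}

#' @export
print.synthetic_flight <- function(x, ...) {
  cat("Synthetic climbing flight:", x$config$n_wingbeats, "wingbeats at",
      x$config$wingbeat_frequency, "Hz,", nrow(x$trajectory$position),
      "frames at", x$config$frame_rate, "fps\n")
  cat("  truth gamma_climb:", paste(signif(x$metrics$gamma_climb, 4),
                                    collapse = ", "), "deg\n")
  invisible(x)
}

#' Landmark world positions of a synthetic flight
#'
#' Body centroid plus wing hinge and wing tip of each of the four wings, per
#' frame, in world coordinates.
#'
#' @param flight a \code{synthetic_flight}
#' @return list of n x 3 matrices named by point id
#' @keywords internal
flight_landmarks <- function(flight) {
  body <- flight$body
  n <- body$n
  out <- list(centroid = flight$trajectory$position)
  for (w in wing_ids()) {
    hp <- matrix(NA_real_, n, 3)
    tp <- matrix(NA_real_, n, 3)
    wm <- flight$wings[[w]]
    sref <- if (wing_side(w) == "left") c(0, 1, 0) else c(0, -1, 0)
    tip_loc <- wm$tip[1] * sref + wm$tip[2] * c(-1, 0, 0)
    for (t in seq_len(n)) {
      Rb <- body_frame(body$yaw[t], body$pitch[t], body$roll[t])
      Rw <- wing_rotation(flight$wing_poses[[w]]$phi[t],
                          flight$wing_poses[[w]]$theta[t],
                          flight$wing_poses[[w]]$H[t], side = wing_side(w))
      base <- body$position[t, ] + as.numeric(Rb %*% flight$hinges[[w]])
      hp[t, ] <- base
      tp[t, ] <- base + as.numeric(Rb %*% Rw %*% tip_loc)
    }
    out[[paste0(w, "_hinge")]] <- hp
    out[[paste0(w, "_tip")]] <- tp
  }
  out
}

#' Project a synthetic flight through a camera rig
#'
#' Projects the body centroid and wing landmarks of a synthetic flight through
#' each camera of a rig, optionally adding Gaussian digitizing noise, and
#' returns them in the digitized-views layout used by the readers/writers.
#' Landmarks behind a camera are flagged not visible (their pixels are NA),
#' never projected.
#'
#' @param flight a \code{synthetic_flight}
#' @param cameras list of at least two \code{dlt_camera}
#' @param pixel_noise_sd Gaussian pixel noise SD (px); defaults to the value
#'   in the flight configuration
#' @param seed RNG seed; defaults to the configuration seed
#' @return data.frame of class \code{digitized_views} with columns
#'   \code{camera}, \code{frame}, \code{point_id}, \code{u_px}, \code{v_px},
#'   \code{visible}
#' @export
project_flight <- function(flight, cameras,
                           pixel_noise_sd = flight$config$pixel_noise_sd,
                           seed = flight$config$seed) {
  stopifnot(inherits(flight, "synthetic_flight"))
  if (length(cameras) < 2)
    stop("projecting a flight needs at least 2 cameras, got ", length(cameras))
  if (!is.null(seed)) set.seed(seed)
  lm <- flight_landmarks(flight)
  n <- nrow(lm[[1]])
  out <- do.call(rbind, lapply(seq_along(cameras), function(k) {
    do.call(rbind, lapply(names(lm), function(pid) {
      px <- project_dlt(cameras[[k]], lm[[pid]])
      vis <- attr(px, "valid") & attr(px, "in_front")
      u <- px[, 1]; v <- px[, 2]
      if (pixel_noise_sd > 0) {
        u <- u + stats::rnorm(n, 0, pixel_noise_sd)
        v <- v + stats::rnorm(n, 0, pixel_noise_sd)
      }
      u[!vis] <- NA_real_; v[!vis] <- NA_real_
      data.frame(camera = k, frame = seq_len(n), point_id = pid,
                 u_px = u, v_px = v, visible = as.integer(vis))
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("digitized_views", "data.frame")
  out
}

#' Generate a synthetic calibration point set
#'
#' Random 3D control points spanning a volume, their (optionally noisy) pixel
#' projections in each camera, plus wand point-pairs of fixed known
#' separation, emulating a wand-based calibration recording.
#'
#' @param cameras list of \code{dlt_camera} (the generating rig)
#' @param n_points number of control points (at least 6)
#' @param volume list with components x, y, z, each c(min, max) in metres
#' @param n_wand number of wand pair placements
#' @param wand_length wand length (m)
#' @param pixel_noise_sd Gaussian pixel noise SD (px)
#' @param seed RNG seed
#' @return list with \code{points3d} (n x 3), \code{pixels} (list per camera
#'   of n x 2), \code{wand_a}, \code{wand_b} (3D end points), \code{wand_pixels_a},
#'   \code{wand_pixels_b} (per-camera pixel lists), \code{wand_length}. A
#'   warning is raised if the control points are (near) coplanar.
#' @export
generate_calibration_set <- function(cameras, n_points = 30,
                                     volume = list(x = c(-0.4, 0.4),
                                                   y = c(-0.4, 0.4),
                                                   z = c(0.0, 0.8)),
                                     n_wand = 15, wand_length = 0.5,
                                     pixel_noise_sd = 0, seed = 1L) {
  if (n_points < 6) stop("need at least 6 calibration points per camera")
  set.seed(seed)
  pts <- cbind(stats::runif(n_points, volume$x[1], volume$x[2]),
               stats::runif(n_points, volume$y[1], volume$y[2]),
               stats::runif(n_points, volume$z[1], volume$z[2]))
  ctr <- sweep(pts, 2, colMeans(pts))
  if (qr(ctr)$rank < 3 || min(svd(ctr)$d) < 1e-8 * max(svd(ctr)$d))
    warning("calibration points are (near) coplanar; DLT will be degenerate")
  proj <- function(P) lapply(cameras, function(cam) {
    px <- project_dlt(cam, P)
    if (pixel_noise_sd > 0)
      px <- px + matrix(stats::rnorm(length(px), 0, pixel_noise_sd), ncol = 2)
    px[, , drop = FALSE]
  })
  ctrW <- cbind(stats::runif(n_wand, volume$x[1], volume$x[2]),
                stats::runif(n_wand, volume$y[1], volume$y[2]),
                stats::runif(n_wand, volume$z[1], volume$z[2]))
  dir <- matrix(stats::rnorm(3 * n_wand), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  wa <- ctrW - dir * wand_length / 2
  wb <- ctrW + dir * wand_length / 2
  list(points3d = pts, pixels = proj(pts),
       wand_a = wa, wand_b = wb,
       wand_pixels_a = proj(wa), wand_pixels_b = proj(wb),
       wand_length = wand_length)
}

#' Add observation noise to a truth trajectory
#'
#' Returns the raw (noisy) track a digitizing + triangulation chain would
#' produce from a truth trajectory, for testing smoothers in isolation.
#'
#' @param traj a \code{smoothed_trajectory} (truth)
#' @param sd position noise SD (m)
#' @param seed RNG seed
#' @return n x 3 matrix of noisy positions
#' @export
add_track_noise <- function(traj, sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traj$position + matrix(stats::rnorm(length(traj$position), 0, sd),
                         ncol = 3)
}

#' Simulate paired observations with a linear relation of known strength
#'
#' Draws (x, y) pairs with y = intercept + slope x + Gaussian noise whose SD
#' is tuned so the population R^2 of the regression equals
#' \code{r_squared} (noise SD = |slope| sd(x) sqrt(1/R^2 - 1)). Used to
#' emulate the kinematics-performance regressions (climb angle on body pitch,
#' flight speed on wing speed) at a configured fit strength.
#'
#' @param n number of pairs
#' @param slope,intercept linear relation parameters
#' @param x_mean,x_sd distribution of the predictor
#' @param r_squared target population R^2 (0 < R^2 <= 1)
#' @param seed RNG seed
#' @return data.frame with columns x, y
#' @export
simulate_linear_relation <- function(n, slope, intercept, x_mean, x_sd,
                                     r_squared, seed = NULL) {
  stopifnot(n >= 3, r_squared > 0, r_squared <= 1, x_sd > 0, slope != 0)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n, x_mean, x_sd)
  sd_e <- abs(slope) * x_sd * sqrt(1 / r_squared - 1)
  y <- intercept + slope * x + stats::rnorm(n, 0, sd_e)
  data.frame(x = x, y = y)
}

#' A standard three-camera orthogonal rig
#'
#' Three ideal cameras at distance \code{dist} from the working volume centre,
#' viewing along -x, -y and -z-ish directions (the third camera looks down
#' from above at an oblique angle so its up vector is well defined), in the
#' GoPro-like format used in the study (848 x 480 px).
#'
#' @param center centre of the working volume (m)
#' @param dist camera distance (m)
#' @param focal_px focal length (px)
#' @return list of three \code{dlt_camera}
#' @export
standard_rig <- function(center = c(0, 0, 0.5), dist = 1.5, focal_px = 800) {
  list(
    make_camera(center + c(dist, 0, 0), center, focal_px = focal_px),
    make_camera(center + c(0, dist, 0), center, focal_px = focal_px),
    make_camera(center + c(dist / sqrt(2), dist / sqrt(2), dist), center,
                focal_px = focal_px)
  )
}
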