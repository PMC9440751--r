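#' Per-frame body pose series
#'
#' @param position n x 3 world positions of the body centroid (m)
#' @param yaw,pitch,roll per-frame body Euler angles (deg), scalars recycled
#' @param frame_rate Hz
#' @return object of class \code{body_pose}
#' @export
body_pose <- function(position, yaw, pitch, roll, frame_rate) {
  position <- rbind(position)
  n <- nrow(position)
  yaw <- rep_len(yaw, n); pitch <- rep_len(pitch, n); roll <- rep_len(roll, n)
  stopifnot(all(is.finite(position)), all(is.finite(c(yaw, pitch, roll))),
            all(abs(pitch) <= 90), frame_rate > 0)
  structure(list(position = position, yaw = yaw, pitch = pitch, roll = roll,
                 frame_rate = frame_rate, n = n),
            class = "body_pose")
}

# canonical wing identifiers: fore/hind x left/right
wing_ids <- function() c("fore_left", "fore_right", "hind_left", "hind_right")

wing_side <- function(wing) ifelse(grepl("right", wing), "right", "left")

#' Blade-element speed and angle of attack along a wing-pose series
#'
#' Implements the blade-element analysis: the wing is divided into 10 (by
#' default) equal spanwise elements; each element's translational velocity is
#' obtained by central finite differences (one-sided at the series ends) of
#' its world position, which combines body translation and the frame-to-frame
#' change of body and wing orientation. The angle of attack alpha is the angle
#' between the wing plane and the element's velocity vector,
#' alpha = asin(|v . n| / |v|), always in [0, 90] deg. Elements with (near)
#' zero speed have undefined alpha and are flagged NA.
#'
#' @param wing a \code{wing_model}
#' @param wing_pose data.frame with per-frame columns \code{phi},
#'   \code{theta}, \code{H} (deg) for one wing
#' @param side "left" or "right"
#' @param body a \code{body_pose} with the same number of frames
#' @param hinge wing hinge position in the body frame (m)
#' @param n_elements number of spanwise elements
#' @return data.frame with columns \code{frame}, \code{element}, \code{r}
#'   (spanwise centroid, m), \code{speed} (m s^-1) and \code{alpha} (deg; NA
#'   where undefined)
#' @export
blade_element_states <- function(wing, wing_pose, side, body,
                                 hinge = c(0, 0, 0), n_elements = 10) {
  stopifnot(inherits(wing, "wing_model"), inherits(body, "body_pose"))
  n <- body$n
  if (nrow(wing_pose) != n)
    stop("wing pose series and body pose must cover the same frames")
  if (n < 2) stop("need at least 2 frames to difference velocities")
  elems <- blade_elements(wing, n_elements)
  sref <- if (side == "left") c(0, 1, 0) else c(0, -1, 0)
  cref <- c(-1, 0, 0)
  # world position of every element centroid at every frame
  X <- array(NA_real_, c(n, n_elements, 3))
  Nrm <- array(NA_real_, c(n, 3))
  for (t in seq_len(n)) {
    Rb <- body_frame(body$yaw[t], body$pitch[t], body$roll[t])
    Rw <- wing_rotation(wing_pose$phi[t], wing_pose$theta[t], wing_pose$H[t],
                        side = side)
    RbRw <- Rb %*% Rw
    Nrm[t, ] <- RbRw %*% c(0, 0, 1)
    base <- body$position[t, ] + as.numeric(Rb %*% hinge)
    for (e in seq_len(n_elements)) {
      loc <- elems$r[e] * sref + elems$c[e] * cref
      X[t, e, ] <- base + as.numeric(RbRw %*% loc)
    }
  }
  dt <- 1 / body$frame_rate
  V <- array(NA_real_, dim(X))
  V[1, , ] <- (X[2, , ] - X[1, , ]) / dt
  V[n, , ] <- (X[n, , ] - X[n - 1, , ]) / dt
  if (n > 2) V[2:(n - 1), , ] <- (X[3:n, , ] - X[1:(n - 2), , ]) / (2 * dt)
  out <- do.call(rbind, lapply(seq_len(n), function(t) {
    v <- matrix(V[t, , ], n_elements, 3)
    sp <- sqrt(rowSums(v^2))
    sina <- abs(v %*% Nrm[t, ]) / sp
    alpha <- rad2deg(asin(pmin(1, sina)))
    alpha[sp < 1e-12] <- NA_real_
    data.frame(frame = t, element = seq_len(n_elements), r = elems$r,
               speed = sp, alpha = as.numeric(alpha))
  }))
  rownames(out) <- NULL
  out
}

#' Per-wingbeat wing-kinematics summary
#'
#' Reduces blade-element states and body pose over one wingbeat to the four
#' summary parameters: the wingbeat-specific angle of attack per wing pair
#' (blade-element average alpha at mid-downstroke and mid-upstroke, averaged
#' over the two mid-strokes and the left/right wings), the wingbeat-specific
#' wing speed (mean element speed over all elements of all four wings and all
#' frames of the wingbeat), the mean body pitch angle, and the stroke
#' amplitude A_phi = max(phi) - min(phi) over the wingbeat (averaged within a
#' wing pair).
#'
#' @param states named list of blade-element state data.frames (one per wing,
#'   names from \code{c("fore_left","fore_right","hind_left","hind_right")})
#' @param wing_poses named list of per-wing pose data.frames (columns phi,
#'   theta, H per frame), same names
#' @param body a \code{body_pose}
#' @param segment one row of a \code{wingbeat_segments} table
#' @return list with \code{alpha_wingbeat} (named: fore, hind; deg),
#'   \code{U_wingbeat} (m s^-1), \code{beta_wingbeat} (deg), \code{A_phi}
#'   (named: fore, hind; deg). If alpha is undefined at a mid-stroke frame the
#'   nearest frame with a defined value is used and reported in attribute
#'   \code{alpha_frames_used}.
#' @export
summarize_wingbeat <- function(states, wing_poses, body, segment) {
  stopifnot(inherits(body, "body_pose"))
  idx <- segment$start:segment$end
  mid_ds <- round((segment$start + segment$boundary) / 2)
  mid_us <- round((segment$boundary + segment$end) / 2)

  mean_alpha_at <- function(st, f0) {
    cand <- sort(unique(st$frame[is.finite(st$alpha)]))
    cand <- cand[cand %in% idx]
    if (length(cand) == 0) return(list(a = NA_real_, f = NA_integer_))
    f <- cand[which.min(abs(cand - f0))]
    list(a = mean(st$alpha[st$frame == f], na.rm = TRUE), f = f)
  }
  pairs <- list(fore = c("fore_left", "fore_right"),
                hind = c("hind_left", "hind_right"))
  frames_used <- c()
  alpha_wb <- vapply(pairs, function(w) {
    vals <- unlist(lapply(w, function(wid) {
      ds <- mean_alpha_at(states[[wid]], mid_ds)
      us <- mean_alpha_at(states[[wid]], mid_us)
      frames_used <<- c(frames_used, ds$f, us$f)
      c(ds$a, us$a)
    }))
    mean(vals, na.rm = TRUE)
  }, numeric(1))

  all_speed <- unlist(lapply(states, function(st) st$speed[st$frame %in% idx]))
  U_wb <- mean(all_speed)
  beta_wb <- mean(body$pitch[idx])
  A_phi <- vapply(pairs, function(w) {
    mean(vapply(w, function(wid) {
      ph <- wing_poses[[wid]]$phi[idx]
      max(ph) - min(ph)
    }, numeric(1)))
  }, numeric(1))
  out <- list(alpha_wingbeat = alpha_wb, U_wingbeat = U_wb,
              beta_wingbeat = beta_wb, A_phi = A_phi)
  attr(out, "alpha_frames_used") <- frames_used
  out
}
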