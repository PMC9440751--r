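#' Segment a flight into wingbeats from stroke-reversal frames
#'
#' A wingbeat runs from one top reversal (highest upstroke position) to the
#' next, so a cycle is a downstroke followed by an upstroke; the intervening
#' bottom reversal is the downstroke/upstroke boundary. Reversal events must
#' alternate top/bottom.
#'
#' @param reversals data.frame with columns \code{frame} (integer, 1-based)
#'   and \code{type} ("top" or "bottom"), ordered in time
#' @param frame_rate Hz
#' @return data.frame of class \code{wingbeat_segments} with columns
#'   \code{wingbeat}, \code{start}, \code{boundary}, \code{end} (frames),
#'   \code{dt} (s) and \code{f_wingbeat} (Hz)
#' @export
segment_wingbeats <- function(reversals, frame_rate) {
  stopifnot(is.data.frame(reversals),
            all(c("frame", "type") %in% names(reversals)), frame_rate > 0)
  if (nrow(reversals) < 3)
    stop("need at least 3 reversal events (top, bottom, top)")
  type <- as.character(reversals$type)
  frame <- reversals$frame
  if (is.unsorted(frame, strictly = TRUE))
    stop("reversal frames must be strictly increasing")
  for (i in seq_len(length(type) - 1)) {
    if (type[i] == type[i + 1])
      stop("reversal events must alternate top/bottom; two consecutive '",
           type[i], "' events at index ", i, " (frame ", frame[i], ")")
  }
  tops <- which(type == "top")
  if (length(tops) < 2) stop("need at least two top reversals for one wingbeat")
  segs <- do.call(rbind, lapply(seq_len(length(tops) - 1), function(j) {
    i0 <- tops[j]; i1 <- tops[j + 1]
    data.frame(wingbeat = j, start = frame[i0], boundary = frame[i0 + 1],
               end = frame[i1])
  }))
  segs$dt <- (segs$end - segs$start) / frame_rate
  segs$f_wingbeat <- 1 / segs$dt
  class(segs) <- c("wingbeat_segments", "data.frame")
  segs
}

#' Per-wingbeat climb-performance metrics
#'
#' For each wingbeat segment, computes the eight per-wingbeat parameters:
#' wingbeat frequency (f = 1/dt), the horizontal, vertical and total distance
#' travelled (dX_hor: planar norm of the net horizontal displacement;
#' dX_ver: signed net vertical displacement; dX_total: 3D path length), the
#' corresponding wingbeat-average speeds U_hor, U_ver, U_total (= dX/dt), and
#' the mean climb angle gamma_climb = atan(U_ver / U_hor) in degrees. U_hor is
#' the magnitude of the wingbeat-mean horizontal velocity vector, so the climb
#' angle lies in [-90, 90] deg.
#'
#' @param traj a \code{smoothed_trajectory}
#' @param segments \code{wingbeat_segments} (frames must lie within the
#'   trajectory)
#' @param labels optional named list/data.frame of identifier columns
#'   (microhabitat, species, individual, flight, ...) recycled to all
#'   wingbeats
#' @return data.frame, one row per wingbeat, with the eight metrics plus any
#'   label columns
#' @export
wingbeat_metrics <- function(traj, segments, labels = NULL) {
  stopifnot(inherits(traj, "smoothed_trajectory"))
  n <- nrow(traj$position)
  if (any(segments$start < 1) || any(segments$end > n))
    stop("wingbeat segment outside the trajectory span (frames 1..", n, ")")
  out <- do.call(rbind, lapply(seq_len(nrow(segments)), function(j) {
    s <- segments[j, ]
    idx <- s$start:s$end
    P <- traj$position[idx, , drop = FALSE]
    steps <- diff(P)
    dx_total <- sum(sqrt(rowSums(steps^2)))
    net <- P[nrow(P), ] - P[1, ]
    dx_hor <- sqrt(sum(net[1:2]^2))
    dx_ver <- net[3]
    dt <- s$dt
    u_hor <- dx_hor / dt
    u_ver <- dx_ver / dt
    u_total <- dx_total / dt
    gamma <- rad2deg(atan2(u_ver, u_hor))
    data.frame(wingbeat = s$wingbeat, f_wingbeat = s$f_wingbeat,
               dX_hor = dx_hor, dX_ver = dx_ver, dX_total = dx_total,
               U_hor = u_hor, U_ver = u_ver, U_total = u_total,
               gamma_climb = gamma)
  }))
  if (!is.null(labels)) out <- cbind(as.data.frame(labels), out)
  rownames(out) <- NULL
  out
}

#' Wingbeat-normalized ensemble dynamics of a per-frame metric
#'
#' Aligns wingbeats of different durations by normalizing time separately
#' within the downstroke and the upstroke (linear resampling to a fixed number
#' of samples per stroke phase), then computes the pointwise mean and a
#' Student-t 95\% confidence interval across wingbeats.
#'
#' @param metric numeric vector, one value per video frame
#' @param segments \code{wingbeat_segments}
#' @param n_samples_per_phase samples per stroke phase on the normalized grid
#' @param conf confidence level
#' @return data.frame with columns \code{phase} ("DS"/"US"), \code{frac}
#'   (normalized time within the phase, in [0, 1]), \code{mean}, \code{lo},
#'   \code{hi} and \code{n}. With a single wingbeat the CI columns are NA and
#'   the attribute \code{ci_defined} is FALSE.
#' @export
ensemble_dynamics <- function(metric, segments, n_samples_per_phase = 20,
                              conf = 0.95) {
  m <- nrow(segments)
  if (m < 1) stop("no wingbeats to align")
  grid <- seq(0, 1, length.out = n_samples_per_phase)
  resample <- function(from, to) {
    idx <- from:to
    if (length(idx) < 2) return(rep(metric[from], n_samples_per_phase))
    stats::approx(seq(0, 1, length.out = length(idx)), metric[idx],
                  xout = grid)$y
  }
  M <- t(vapply(seq_len(m), function(j) {
    s <- segments[j, ]
    c(resample(s$start, s$boundary), resample(s$boundary, s$end))
  }, numeric(2 * n_samples_per_phase)))
  mu <- colMeans(M)
  if (m >= 2) {
    se <- apply(M, 2, stats::sd) / sqrt(m)
    tq <- stats::qt(1 - (1 - conf) / 2, df = m - 1)
    lo <- mu - tq * se; hi <- mu + tq * se
    ci_defined <- TRUE
  } else {
    lo <- hi <- rep(NA_real_, length(mu))
    ci_defined <- FALSE
  }
  out <- data.frame(phase = rep(c("DS", "US"), each = n_samples_per_phase),
                    frac = rep(grid, 2), mean = mu, lo = lo, hi = hi, n = m)
  attr(out, "ci_defined") <- ci_defined
  out
}
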