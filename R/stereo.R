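#' Direct linear transformation (DLT) camera model
#'
#' The 11-coefficient DLT maps a world point (x, y, z) in metres to pixel
#' coordinates (u, v):
#' \deqn{u = (L1 x + L2 y + L3 z + L4) / (L9 x + L10 y + L11 z + 1)}
#' \deqn{v = (L5 x + L6 y + L7 z + L8) / (L9 x + L10 y + L11 z + 1)}
#' The 12th (constant) coefficient is fixed at 1, the de-facto normalization
#' of the DLTdv/easyWand tool family.
#'
#' @param L numeric vector of 11 DLT coefficients
#' @param image_size c(width, height) in pixels, optional (used only for
#'   reporting)
#' @param front_sign +1 or -1: the sign of the projection denominator for
#'   points in front of the camera (the fixed L12 = 1 scaling leaves this
#'   sign arbitrary, so it is stored explicitly)
#' @return object of class \code{dlt_camera}
#' @export
dlt_camera <- function(L, image_size = NULL, front_sign = 1) {
  L <- as.numeric(L)
  if (length(L) != 11 || any(!is.finite(L)))
    stop("a DLT camera needs 11 finite coefficients")
  structure(list(L = L, image_size = image_size,
                 front_sign = sign(front_sign)),
            class = "dlt_camera")
}

#' @export
print.dlt_camera <- function(x, ...) {
  cat("DLT camera (11 coefficients, L12 = 1)\n")
  cat("  L:", paste(signif(x$L, 4), collapse = " "), "\n")
  if (!is.null(x$image_size))
    cat("  image size:", paste(x$image_size, collapse = " x "), "px\n")
  if (!is.null(x$rmse))
    cat("  calibration reprojection RMSE:", signif(x$rmse, 4), "px\n")
  invisible(x)
}

#' Construct a synthetic pinhole camera as DLT coefficients
#'
#' Builds an ideal (distortion-free) pinhole camera looking from
#' \code{center} toward \code{look_at} and converts it to the 11-parameter
#' DLT form. Pixel v grows downward, as in image coordinates.
#'
#' @param center camera position in world coordinates (m)
#' @param look_at world point on the optical axis (m)
#' @param focal_px focal length in pixels
#' @param image_size c(width, height) px; the principal point defaults to the
#'   image centre
#' @param up approximate world up direction used to fix camera roll
#' @param principal c(u0, v0) principal point in px
#' @return \code{dlt_camera}
#' @export
make_camera <- function(center, look_at, focal_px = 800,
                        image_size = c(848, 480), up = c(0, 0, 1),
                        principal = image_size / 2) {
  center <- as.numeric(center); look_at <- as.numeric(look_at)
  f <- look_at - center
  nf <- sqrt(sum(f^2))
  if (nf < 1e-12) stop("look_at coincides with the camera center")
  f <- f / nf
  r <- c(f[2] * up[3] - f[3] * up[2],
         f[3] * up[1] - f[1] * up[3],
         f[1] * up[2] - f[2] * up[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-12) stop("up direction is parallel to the optical axis")
  r <- r / nr
  u <- c(r[2] * f[3] - r[3] * f[2],
         r[3] * f[1] - r[1] * f[3],
         r[1] * f[2] - r[2] * f[1])
  # rows of the 3x4 projection (applied to (X - center, 1))
  M <- rbind(focal_px * r + principal[1] * f,
             -focal_px * u + principal[2] * f,   # pixel v points down
             f)
  P <- cbind(M, -M %*% center)
  if (abs(P[3, 4]) < 1e-12)
    stop("camera principal plane passes through the world origin; shift the rig")
  Pn <- P / P[3, 4]
  # in front of the camera: f . (X - center) > 0
  front_sign <- sign(sum(Pn[3, 1:3] * (look_at - center)))
  dlt_camera(c(Pn[1, ], Pn[2, ], Pn[3, 1:3]),
             image_size = image_size, front_sign = front_sign)
}

#' Project world points through a DLT camera
#'
#' @param camera a \code{dlt_camera}
#' @param points3d n x 3 matrix (or length-3 vector) of world points (m)
#' @return n x 2 matrix of pixel coordinates with columns (u, v). Points on
#'   the camera's principal plane (zero denominator) are returned as NA and
#'   flagged in the logical attribute \code{valid}; points behind the camera
#'   are projected but flagged FALSE in attribute \code{in_front}.
#' @export
project_dlt <- function(camera, points3d) {
  stopifnot(inherits(camera, "dlt_camera"))
  P <- rbind(points3d)
  if (ncol(P) != 3 || any(!is.finite(P)))
    stop("points3d must be finite world coordinates (n x 3)")
  L <- camera$L
  den <- P %*% L[9:11] + 1
  valid <- abs(den) > 1e-12
  u <- (P %*% L[1:3] + L[4]) / den
  v <- (P %*% L[5:7] + L[8]) / den
  u[!valid] <- NA_real_; v[!valid] <- NA_real_
  out <- cbind(u = as.numeric(u), v = as.numeric(v))
  attr(out, "valid") <- as.logical(valid)
  attr(out, "in_front") <- as.logical(camera$front_sign * den > 0)
  out
}

#' Estimate DLT coefficients from 3D-2D correspondences
#'
#' Least-squares DLT-11 calibration: the homogeneous 2n x 12 system is solved
#' by SVD after similarity pre-normalization of both the world points and the
#' pixels (for conditioning), and the solution is rescaled so the constant
#' coefficient equals 1.
#'
#' @param points3d n x 3 world coordinates of the calibration points (m)
#' @param pixels n x 2 observed pixel coordinates in this camera
#' @param image_size optional c(width, height) px stored with the result
#' @return \code{dlt_camera} with an extra element \code{rmse}, the
#'   reprojection root-mean-square error (px)
#' @export
estimate_dlt <- function(points3d, pixels, image_size = NULL) {
  X <- rbind(points3d); U <- rbind(pixels)
  ok <- stats::complete.cases(X) & stats::complete.cases(U)
  X <- X[ok, , drop = FALSE]; U <- U[ok, , drop = FALSE]
  n <- nrow(X)
  if (n < 6)
    stop("DLT calibration needs at least 6 point correspondences, got ", n)
  if (qr(cbind(X, 1))$rank < 4)
    stop("calibration points are coplanar (rank-deficient DLT design); ",
         "spread points through the volume")
  # similarity pre-normalization
  cx <- colMeans(X); sx <- mean(sqrt(rowSums(sweep(X, 2, cx)^2)))
  cu <- colMeans(U); su <- mean(sqrt(rowSums(sweep(U, 2, cu)^2)))
  if (su < 1e-12) stop("all pixels identical; degenerate calibration")
  Xn <- sweep(X, 2, cx) * (sqrt(3) / sx)
  Un <- sweep(U, 2, cu) * (sqrt(2) / su)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    x <- c(Xn[i, ], 1)
    A[2 * i - 1, ] <- c(x, rep(0, 4), -Un[i, 1] * x)
    A[2 * i, ] <- c(rep(0, 4), x, -Un[i, 2] * x)
  }
  sv <- svd(A)
  l <- sv$v[, 12]
  Pn <- matrix(l, 3, 4, byrow = TRUE)
  # undo normalizations: T2^-1 %*% Pn %*% T3
  T3 <- rbind(cbind(diag(3) * (sqrt(3) / sx), -(sqrt(3) / sx) * cx), c(0, 0, 0, 1))
  T2inv <- rbind(c(su / sqrt(2), 0, cu[1]),
                 c(0, su / sqrt(2), cu[2]),
                 c(0, 0, 1))
  P <- T2inv %*% Pn %*% T3
  if (abs(P[3, 4]) < 1e-14)
    stop("estimated camera has zero constant coefficient; degenerate geometry")
  P <- P / P[3, 4]
  den <- X %*% P[3, 1:3] + 1
  front_sign <- if (mean(den > 0) >= 0.5) 1 else -1
  cam <- dlt_camera(c(P[1, ], P[2, ], P[3, 1:3]), image_size = image_size,
                    front_sign = front_sign)
  rep_px <- project_dlt(cam, X)
  cam$rmse <- sqrt(mean((rep_px - U)^2))
  cam
}

#' Triangulate 3D points from two or more calibrated views
#'
#' Linear (algebraic) least-squares triangulation from per-camera pixel
#' observations. Frames seen by fewer than two cameras are returned as NA
#' ("missing"), never fabricated.
#'
#' @param cameras list of \code{dlt_camera}
#' @param pixels list, one element per camera, each an n x 2 matrix of pixel
#'   coordinates (NA where the point is not visible in that camera)
#' @return object of class \code{reconstruction3d}: list with \code{points}
#'   (n x 3, m), \code{rmse} (per-frame reprojection RMSE, px) and
#'   \code{n_cameras} (views used per frame)
#' @export
triangulate <- function(cameras, pixels) {
  stopifnot(length(cameras) >= 2, length(cameras) == length(pixels))
  pixels <- lapply(pixels, rbind)
  n <- nrow(pixels[[1]])
  stopifnot(all(vapply(pixels, nrow, 1L) == n))
  pts <- matrix(NA_real_, n, 3)
  rmse <- rep(NA_real_, n)
  ncam <- integer(n)
  for (i in seq_len(n)) {
    A <- NULL; b <- NULL; used <- integer(0)
    for (k in seq_along(cameras)) {
      uv <- pixels[[k]][i, ]
      if (any(!is.finite(uv))) next
      L <- cameras[[k]]$L
      A <- rbind(A,
                 L[1:3] - uv[1] * L[9:11],
                 L[5:7] - uv[2] * L[9:11])
      b <- c(b, uv[1] - L[4], uv[2] - L[8])
      used <- c(used, k)
    }
    ncam[i] <- length(used)
    if (length(used) < 2) next
    x <- qr.solve(A, b)
    pts[i, ] <- x
    res <- unlist(lapply(used, function(k) {
      project_dlt(cameras[[k]], x) - pixels[[k]][i, ]
    }))
    rmse[i] <- sqrt(mean(res^2))
  }
  structure(list(points = pts, rmse = rmse, n_cameras = ncam),
            class = "reconstruction3d")
}

#' @export
print.reconstruction3d <- function(x, ...) {
  ok <- is.finite(x$points[, 1])
  cat("3D reconstruction:", nrow(x$points), "frames,",
      sum(ok), "reconstructed\n")
  if (any(ok))
    cat("  median reprojection RMSE:", signif(stats::median(x$rmse[ok]), 4), "px\n")
  invisible(x)
}

#' Wand-length reconstruction check
#'
#' Diagnostic used after calibration: point pairs with a known physical
#' separation (the two ends of a calibration wand) are triangulated and the
#' distribution of reconstructed-minus-known lengths is reported.
#'
#' @param cameras list of \code{dlt_camera}
#' @param pixels_a,pixels_b per-camera pixel lists (as in [triangulate()]) for
#'   the two wand end points
#' @param known_length true wand length (m)
#' @return list with \code{errors} (m), \code{mean_error}, \code{sd_error},
#'   \code{n}
#' @export
wand_check <- function(cameras, pixels_a, pixels_b, known_length) {
  ra <- triangulate(cameras, pixels_a)
  rb <- triangulate(cameras, pixels_b)
  d <- sqrt(rowSums((ra$points - rb$points)^2))
  err <- d - known_length
  err <- err[is.finite(err)]
  if (length(err) == 0) stop("no wand pair could be reconstructed")
  list(errors = err, mean_error = mean(err),
       sd_error = if (length(err) > 1) stats::sd(err) else NA_real_,
       n = length(err))
}

#' Read and write DLT coefficient files
#'
#' The de-facto DLTdv/easyWand layout: a CSV with 11 rows and one column per
#' camera.
#'
#' @param cameras list of \code{dlt_camera}
#' @param path file path
#' @return \code{read_dlt_csv} returns a list of \code{dlt_camera}
#' @export
write_dlt_csv <- function(cameras, path) {
  m <- vapply(cameras, function(c) c$L, numeric(11))
  colnames(m) <- paste0("cam", seq_along(cameras))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dlt_csv
#' @export
read_dlt_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  if (nrow(m) != 11) stop("a DLT coefficient file must have 11 rows, got ", nrow(m))
  lapply(seq_len(ncol(m)), function(k) dlt_camera(m[, k]))
}
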