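test_that("noiseless DLT calibration recovers the generating camera", {
  cams <- test_rig()
  cal <- generate_calibration_set(cams, n_points = 20, pixel_noise_sd = 0,
                                  seed = 3)
  for (k in seq_along(cams)) {
    est <- estimate_dlt(cal$points3d, cal$pixels[[k]])
    expect_lt(est$rmse, 1e-6)
    # recovered coefficients reproject an independent point like the truth
    p <- c(0.07, -0.11, 0.52)
    expect_equal(project_dlt(est, p), project_dlt(cams[[k]], p),
                 ignore_attr = TRUE, tolerance = 1e-7)
  }
})

test_that("DLT calibration rejects degenerate inputs", {
  cams <- test_rig()
  cal <- generate_calibration_set(cams, n_points = 20, seed = 3)
  expect_error(estimate_dlt(cal$points3d[1:5, ], cal$pixels[[1]][1:5, ]),
               "at least 6")
  flat <- cal$points3d; flat[, 3] <- 0.4
  px <- project_dlt(cams[[1]], flat)
  expect_error(estimate_dlt(flat, px), "coplanar")
})

test_that("DLT estimate is invariant to permutation of calibration points", {
  cams <- test_rig()
  cal <- generate_calibration_set(cams, n_points = 25, pixel_noise_sd = 0.3,
                                  seed = 9)
  set.seed(2)
  perm <- sample(25)
  a <- estimate_dlt(cal$points3d, cal$pixels[[1]])
  b <- estimate_dlt(cal$points3d[perm, ], cal$pixels[[1]][perm, ])
  expect_equal(a$L, b$L, tolerance = 1e-9)
})

test_that("noisy calibration yields reprojection RMSE near the pixel noise", {
  cams <- test_rig()
  rmse <- vapply(1:100, function(s) {
    cal <- generate_calibration_set(cams, n_points = 50, pixel_noise_sd = 0.5,
                                    seed = s)
    estimate_dlt(cal$points3d, cal$pixels[[1]])$rmse
  }, numeric(1))
  expect_gt(median(rmse), 0.3)
  expect_lt(median(rmse), 0.8)
})

test_that("projection handles optical axis and principal plane", {
  cam <- make_camera(c(1.5, 0, 0.5), c(0, 0, 0.5), focal_px = 800,
                     image_size = c(848, 480))
  # point on the optical axis projects to the principal point
  px <- project_dlt(cam, c(0.3, 0, 0.5))
  expect_equal(as.numeric(px), c(424, 240), tolerance = 1e-9)
  # point behind the camera is flagged
  pb <- project_dlt(cam, c(3, 0, 0.5))
  expect_false(attr(pb, "in_front"))
  # a point on the principal plane (denominator zero) is flagged invalid:
  # the plane passes through the camera center orthogonal to the view axis
  pp <- project_dlt(cam, c(1.5, 0.2, 0.5))
  expect_false(attr(pp, "valid"))
  expect_true(all(is.na(pp)))
})

test_that("project and triangulate are mutual inverses without noise", {
  cams <- test_rig()
  set.seed(5)
  pts <- cbind(runif(20, -0.2, 0.2), runif(20, -0.2, 0.2), runif(20, 0.2, 0.6))
  px <- lapply(cams, function(c) project_dlt(c, pts))
  rec <- triangulate(cams, px)
  expect_lt(max(sqrt(rowSums((rec$points - pts)^2))), 1e-9)
  expect_true(all(rec$rmse < 1e-7))
  expect_true(all(rec$n_cameras == 3))
})

test_that("frames with fewer than two views are missing, not fabricated", {
  cams <- test_rig()
  pts <- rbind(c(0, 0, 0.4), c(0.1, 0, 0.4))
  px <- lapply(cams, function(c) project_dlt(c, pts))
  px[[2]][2, ] <- NA; px[[3]][2, ] <- NA
  rec <- triangulate(cams, px)
  expect_true(all(is.finite(rec$points[1, ])))
  expect_true(all(is.na(rec$points[2, ])))
  expect_identical(rec$n_cameras, c(3L, 1L))
})

test_that("triangulation error is millimetric at half-pixel noise and shrinks with more cameras", {
  cams <- test_rig()
  set.seed(11)
  n <- 1000
  pts <- cbind(runif(n, -0.2, 0.2), runif(n, -0.2, 0.2), runif(n, 0.2, 0.6))
  px <- lapply(cams, function(c)
    project_dlt(c, pts) + matrix(rnorm(2 * n, 0, 0.5), n, 2))
  err3 <- sqrt(rowSums((triangulate(cams, px)$points - pts)^2))
  expect_lt(median(err3), 0.005)
  err2 <- sqrt(rowSums((triangulate(cams[1:2], px[1:2])$points - pts)^2))
  expect_lt(median(err3), median(err2))
})

test_that("wand check recovers the known length and exposes a wrong one", {
  cams <- test_rig()
  cal <- generate_calibration_set(cams, n_wand = 15, wand_length = 0.5,
                                  pixel_noise_sd = 0, seed = 7)
  expect_true(all(abs(sqrt(rowSums((cal$wand_a - cal$wand_b)^2)) - 0.5) < 1e-12))
  wc <- wand_check(cams, cal$wand_pixels_a, cal$wand_pixels_b, 0.5)
  expect_lt(max(abs(wc$errors)), 1e-9)
  # wrong known length shifts the mean error by the offset
  wc6 <- wand_check(cams, cal$wand_pixels_a, cal$wand_pixels_b, 0.6)
  expect_equal(wc6$mean_error, -0.1, tolerance = 1e-9)
  # noisy pairs: unbiased within 3 standard errors
  caln <- generate_calibration_set(cams, n_wand = 200, wand_length = 0.5,
                                   pixel_noise_sd = 0.5, seed = 8)
  wcn <- wand_check(cams, caln$wand_pixels_a, caln$wand_pixels_b, 0.5)
  expect_lt(abs(wcn$mean_error), 3 * wcn$sd_error / sqrt(wcn$n))
})

test_that("DLT coefficient files round-trip in the 11-row-per-camera layout", {
  cams <- test_rig()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlt_csv(cams, path)
  back <- read_dlt_csv(path)
  for (k in 1:3) expect_equal(back[[k]]$L, cams[[k]]$L, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(cam1 = 1:5), bad, row.names = FALSE)
  expect_error(read_dlt_csv(bad), "11 rows")
})
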