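test_that("configuration is validated", {
  expect_error(flight_sim_config(stroke_amplitude = 200), "stroke_amplitude")
  expect_error(flight_sim_config(initial_speed = NaN), "non-finite")
  expect_error(flight_sim_config(frame_rate = -1), "frame_rate")
  expect_s3_class(flight_sim_config(), "flight_sim_config")
})

test_that("a 45-degree climb splits speed equally between vertical and horizontal", {
  fl <- simulate_flight(flight_sim_config(climb_angle = 45, initial_speed = 1,
                                          speed_modulation = 0))
  v <- fl$trajectory$velocity
  expect_equal(v[, 1], rep(sqrt(2) / 2, nrow(v)), tolerance = 1e-12)
  expect_equal(v[, 3], rep(sqrt(2) / 2, nrow(v)), tolerance = 1e-12)
  expect_equal(v[, 2], rep(0, nrow(v)), tolerance = 1e-12)
})

test_that("simulation and projection are deterministic in the seed", {
  cfg <- flight_sim_config(n_wingbeats = 2, wingbeat_frequency = 5, seed = 7)
  a <- simulate_flight(cfg)
  b <- simulate_flight(cfg)
  expect_identical(a$trajectory$position, b$trajectory$position)
  expect_identical(a$metrics, b$metrics)
  va <- project_flight(a, test_rig())
  vb <- project_flight(b, test_rig())
  expect_identical(va, vb)
  # different seed changes the noisy pixels
  vc <- project_flight(a, test_rig(), seed = 8)
  expect_false(identical(va$u_px, vc$u_px))
})

test_that("stroke reversals are spaced frame_rate/frequency frames apart", {
  fl <- simulate_flight(flight_sim_config(n_wingbeats = 3,
                                          wingbeat_frequency = 5))
  tops <- fl$reversals$frame[fl$reversals$type == "top"]
  expect_equal(diff(tops), rep(48, 3))
  bottoms <- fl$reversals$frame[fl$reversals$type == "bottom"]
  expect_equal(bottoms - tops[1:3], rep(24, 3))
  expect_identical(nrow(fl$segments), 3L)
})

test_that("noiseless projection reproduces the reprojected truth exactly", {
  fl <- small_flight()
  cams <- test_rig()
  views <- project_flight(fl, cams, pixel_noise_sd = 0)
  v1 <- views[views$camera == 1 & views$point_id == "centroid", ]
  px <- project_dlt(cams[[1]], fl$trajectory$position)
  expect_equal(v1$u_px, px[, 1], tolerance = 1e-12)
  expect_equal(v1$v_px, px[, 2], tolerance = 1e-12)
  expect_error(project_flight(fl, cams[1]), "at least 2")
})

test_that("injected pixel noise has the configured standard deviation", {
  fl <- test_flight()
  cams <- test_rig()
  clean <- project_flight(fl, cams, pixel_noise_sd = 0)
  noisy <- project_flight(fl, cams, pixel_noise_sd = 0.5, seed = 4)
  resid <- c(noisy$u_px - clean$u_px, noisy$v_px - clean$v_px)
  resid <- resid[is.finite(resid)]
  expect_gt(length(resid), 1e4)
  expect_equal(sd(resid), 0.5, tolerance = 0.1)
})

test_that("landmarks behind a camera are flagged missing, not projected", {
  fl <- small_flight()
  # camera placed ahead of the flight, looking away from it
  away <- make_camera(c(-2, 0, 0.3), c(-5, 0, 0.3))
  views <- project_flight(fl, list(away, test_rig()[[1]]), pixel_noise_sd = 0)
  beh <- views[views$camera == 1, ]
  expect_true(all(beh$visible == 0))
  expect_true(all(is.na(beh$u_px)))
  expect_true(all(views$visible[views$camera == 2] == 1))
})

test_that("calibration sets honour wand separation and flag coplanar volumes", {
  cams <- test_rig()
  cal <- generate_calibration_set(cams, n_wand = 10, wand_length = 0.5, seed = 2)
  expect_equal(sqrt(rowSums((cal$wand_a - cal$wand_b)^2)), rep(0.5, 10),
               tolerance = 1e-12)
  expect_error(generate_calibration_set(cams, n_points = 5), "at least 6")
  expect_warning(
    generate_calibration_set(cams, volume = list(x = c(-0.4, 0.4),
                                                 y = c(-0.4, 0.4),
                                                 z = c(0.4, 0.4)), seed = 2),
    "coplanar")
})

test_that("cohorts with zero metric variance collapse onto the group means", {
  tab <- .default_metric_table_zero_sd()
  d <- cohort_design(metric_table = tab, seed = 5)
  co <- generate_cohort(d)
  wb <- co$wingbeats
  can <- wb[wb$microhabitat == "canopy", ]
  expect_equal(can$gamma_climb, rep(46.7, nrow(can)), tolerance = 1e-12)
  expect_equal(can$U_total, rep(1.56, nrow(can)), tolerance = 1e-12)
  und <- wb[wb$microhabitat == "understory", ]
  expect_equal(und$gamma_climb, rep(36.5, nrow(und)), tolerance = 1e-12)
})

test_that("cohort sample means converge to the configured group means", {
  d <- cohort_design(
    individuals_per_species = c(canopy = 5, understory = 3),
    flights_per_individual = c(canopy = 10, understory = 2),
    wingbeats_per_flight = c(canopy = 100, understory = 3),
    variance_fractions = c(species = 0, individual = 0, flight = 0,
                           wingbeat = 1),
    seed = 1)
  wb <- generate_cohort(d)$wingbeats
  g <- wb$gamma_climb[wb$microhabitat == "canopy"]
  expect_gte(length(g), 1e4)
  expect_lt(abs(mean(g) - 46.7), 3 * 17 / sqrt(length(g)))
})

test_that("cohort generation is reproducible and validates the tree", {
  d <- cohort_design(seed = 9)
  expect_identical(generate_cohort(d)$wingbeats, generate_cohort(d)$wingbeats)
  expect_error(
    cohort_design(tree = ape::read.tree(text = "(a:1,b:1);")),
    "tip")
})

test_that("morphology is internally consistent with the aerodynamic conversion", {
  co <- generate_cohort(cohort_design(seed = 2))
  mo <- co$morphology
  wn <- weight_normalized_wing_area(mo$wing_area_cm2, mo$mass_g)
  expect_equal(mo$S_over_mg, wn$S_over_mg, tolerance = 1e-12)
  expect_equal(mo$S_over_mg * mo$wing_loading, rep(1, nrow(mo)),
               tolerance = 1e-12)
})
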