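#' Read digitized point tracks
#'
#' Reads manually digitized 2D tracks in the tidy layout written by
#' [write_digitized_points()]: one row per camera/frame/point with columns
#' \code{frame}, \code{point_id}, \code{camera}, \code{u_px}, \code{v_px},
#' \code{visible}. Rows with \code{visible = 0} are marked missing (pixels set
#' to NA), never zero-filled.
#'
#' @param path CSV file path
#' @return data.frame of class \code{digitized_views}
#' @export
read_digitized_points <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "point_id", "camera", "u_px", "v_px", "visible")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("digitized point file is missing columns: ",
         paste(miss, collapse = ", "))
  key <- interaction(d$camera, d$point_id, drop = TRUE)
  for (k in levels(key)) {
    fr <- d$frame[key == k]
    if (is.unsorted(fr, strictly = TRUE)) {
      bad <- which(key == k)[which(diff(fr) <= 0)[1] + 1]
      stop("non-monotone frame numbers for camera/point ", k,
           " at row ", bad)
    }
  }
  d$u_px[d$visible == 0] <- NA_real_
  d$v_px[d$visible == 0] <- NA_real_
  class(d) <- c("digitized_views", "data.frame")
  d
}

#' @rdname read_digitized_points
#' @param views a \code{digitized_views} data.frame
#' @export
write_digitized_points <- function(views, path) {
  need <- c("frame", "point_id", "camera", "u_px", "v_px", "visible")
  stopifnot(all(need %in% names(views)))
  utils::write.csv(as.data.frame(views)[need], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Extract per-camera pixel tracks for one point id
#'
#' Reshapes a \code{digitized_views} table into the per-camera pixel-list
#' layout consumed by [triangulate()].
#'
#' @param views \code{digitized_views}
#' @param point_id which landmark to extract (default the body centroid)
#' @return list per camera of n x 2 pixel matrices (NA where not visible)
#' @export
pixel_tracks <- function(views, point_id = "centroid") {
  v <- views[views$point_id == point_id, ]
  if (nrow(v) == 0) stop("no rows for point_id '", point_id, "'")
  cams <- sort(unique(v$camera))
  frames <- sort(unique(v$frame))
  lapply(cams, function(k) {
    vk <- v[v$camera == k, ]
    m <- matrix(NA_real_, length(frames), 2)
    idx <- match(vk$frame, frames)
    m[idx, 1] <- vk$u_px; m[idx, 2] <- vk$v_px
    m
  })
}

#' Write per-wingbeat records / morphology / ensemble traces as tidy CSV
#'
#' @param x data.frame
#' @param path file path
#' @return the path, invisibly
#' @export
write_records_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a project configuration file
#'
#' Structured YAML configuration for the pipeline. Recognized top-level keys:
#' \code{seed}, \code{flight} (arguments to [flight_sim_config()]),
#' \code{rig} (center, dist, focal_px for [standard_rig()] or
#' \code{dlt_file}), \code{pixel_noise_sd}, \code{kalman} (process_noise,
#' obs_noise), \code{stats} (n_sim), \code{output_dir}.
#'
#' @param path YAML file
#' @return named list
#' @export
read_project_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration file is not a YAML mapping")
  cfg
}

#' Run the full synthetic-flight analysis pipeline
#'
#' End-to-end composition of the package: simulate a climbing flapping flight,
#' project it through the camera rig with digitizing noise, triangulate the
#' body centroid, Kalman-smooth the 3D track, segment wingbeats at the truth
#' stroke reversals, compute the eight per-wingbeat climb metrics and the
#' blade-element wingbeat kinematics (using the tracked wing angles with the
#' smoothed body trajectory), then generate a hierarchical synthetic cohort
#' and run the group-level statistics battery (sequential ANOVA on climb angle
#' and flight speed, MANOVA over the eight metrics, phylogenetic ANOVA on
#' species means, Wilcoxon on weight-normalized wing area, and the
#' helicopter-model regression). Deterministic given the configuration and
#' seed.
#'
#' @param config named list as returned by [read_project_config()], or a path
#'   to a YAML file
#' @return list with elements \code{flight}, \code{views},
#'   \code{reconstruction}, \code{trajectory}, \code{metrics},
#'   \code{kinematics}, \code{cohort}, \code{stats}, \code{log}
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_project_config(config)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  fl_args <- config$flight %||% list()
  fl_args$seed <- seed
  fcfg <- do.call(flight_sim_config, fl_args)

  stage <- "configure"
  res <- tryCatch({
    if (!is.null(config$rig$dlt_file)) {
      if (!file.exists(config$rig$dlt_file))
        stop("camera file 'rig$dlt_file' not found: ", config$rig$dlt_file)
      cameras <- read_dlt_csv(config$rig$dlt_file)
    } else {
      rig <- config$rig %||% list()
      cameras <- standard_rig(center = rig$center %||% c(0.3, 0, 0.35),
                              dist = rig$dist %||% 1.5,
                              focal_px = rig$focal_px %||% 800)
    }
    stage <- "simulate"
    flight <- simulate_flight(fcfg)
    stage <- "project"
    pn <- config$pixel_noise_sd %||% fcfg$pixel_noise_sd
    views <- project_flight(flight, cameras, pixel_noise_sd = pn, seed = seed)
    stage <- "reconstruct"
    recon <- triangulate(cameras, pixel_tracks(views, "centroid"))
    stage <- "smooth"
    kal <- config$kalman %||% list()
    traj <- kalman_smooth(recon$points, fcfg$frame_rate,
                          process_noise = kal$process_noise %||% 100,
                          obs_noise = kal$obs_noise %||%
                            max(stats::median(recon$rmse, na.rm = TRUE) * 2e-3,
                                5e-4))
    stage <- "wingbeats"
    segments <- segment_wingbeats(flight$reversals, fcfg$frame_rate)
    metrics <- wingbeat_metrics(traj, segments)
    stage <- "kinematics"
    body_est <- body_pose(traj$position, yaw = fcfg$heading,
                          pitch = fcfg$body_pitch, roll = 0,
                          frame_rate = fcfg$frame_rate)
    states <- lapply(wing_ids(), function(w) {
      blade_element_states(flight$wings[[w]], flight$wing_poses[[w]],
                           wing_side(w), body_est,
                           hinge = flight$hinges[[w]])
    })
    names(states) <- wing_ids()
    kin <- do.call(rbind, lapply(seq_len(nrow(segments)), function(j) {
      s <- summarize_wingbeat(states, flight$wing_poses, body_est,
                              segments[j, ])
      data.frame(wingbeat = segments$wingbeat[j],
                 alpha_fore = s$alpha_wingbeat[["fore"]],
                 alpha_hind = s$alpha_wingbeat[["hind"]],
                 U_wingbeat = s$U_wingbeat,
                 beta_wingbeat = s$beta_wingbeat,
                 A_phi_fore = s$A_phi[["fore"]],
                 A_phi_hind = s$A_phi[["hind"]])
    }))
    stage <- "cohort"
    dsn_args <- config$cohort %||% list()
    dsn_args$seed <- seed
    design <- do.call(cohort_design, dsn_args)
    cohort <- generate_cohort(design)
    stage <- "stats"
    wb <- cohort$wingbeats
    n_sim <- config$stats$n_sim %||% 2000
    sp_means <- tapply(wb$gamma_climb, wb$species, mean)
    sp_groups <- design$species
    stats_out <- list(
      anova_gamma = sequential_anova(wb, "gamma_climb"),
      anova_speed = sequential_anova(wb, "U_total"),
      manova = manova_wilks(wb, c("f_wingbeat", "dX_hor", "dX_ver",
                                  "dX_total", "U_hor", "U_ver", "U_total",
                                  "gamma_climb"), "microhabitat"),
      phylo_anova = phylogenetic_anova(sp_means, sp_groups, cohort$tree,
                                       n_sim = n_sim, seed = seed),
      wilcoxon_S_over_mg = wilcoxon_rank_sum(
        cohort$morphology$S_over_mg[cohort$morphology$microhabitat == "canopy"],
        cohort$morphology$S_over_mg[cohort$morphology$microhabitat == "understory"]),
      helicopter = helicopter_prediction(wb$beta_wingbeat, wb$gamma_climb),
      contrast_gamma_pct = percent_difference(
        mean(wb$gamma_climb[wb$microhabitat == "canopy"]),
        mean(wb$gamma_climb[wb$microhabitat == "understory"])))
    list(flight = flight, cameras = cameras, views = views,
         reconstruction = recon,
         trajectory = traj, metrics = metrics, kinematics = kin,
         cohort = cohort, stats = stats_out,
         log = list(seed = seed, stages = "complete",
                    package_version = as.character(utils::packageVersion("climbflight"))))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$output_dir, f)
    write_digitized_points(res$views, out("digitized_points.csv"))
    write_dlt_csv(res$cameras, out("dlt_coefficients.csv"))
    write_records_csv(res$metrics, out("wingbeat_metrics.csv"))
    write_records_csv(res$kinematics, out("wingbeat_kinematics.csv"))
    write_records_csv(res$cohort$wingbeats, out("cohort_wingbeats.csv"))
    write_records_csv(res$cohort$morphology, out("cohort_morphology.csv"))
    ape::write.tree(res$cohort$tree, out("tree.nwk"))
    write_records_csv(res$stats$anova_gamma, out("anova_gamma.csv"))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
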