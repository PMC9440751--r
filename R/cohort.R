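#' Default seven-species phylogeny
#'
#' Topology with the two canopy species forming a clade sister to the five
#' understory species, unit branch lengths (the documented fallback when no
#' calibrated branch lengths are supplied).
#'
#' @return an \pkg{ape} \code{phylo} tree with 7 tips
#' @export
default_tree <- function() {
  ape::read.tree(text = paste0(
    "((cisseis:1,theseus:1):1,",
    "((achilles:1,helenor:1):0.5,(menelaus:1,(deidamia:0.5,sulkowskyi:0.5):0.5):0.5):1);"))
}

# group means and SDs of the per-wingbeat metrics used by the default design
.default_metric_table <- function() {
  data.frame(
    metric = c("gamma_climb", "U_total", "U_ver", "U_hor", "f_wingbeat",
               "dX_hor", "dX_ver", "dX_total", "beta_wingbeat", "A_phi",
               "alpha_wingbeat"),
    canopy_mean = c(46.7, 1.56, 1.07, 1.00, 3.85, 0.26, 0.28, 0.41, 67, 114, 35),
    canopy_sd = c(17, 0.56, 0.46, 0.40, 0.70, 0.10, 0.12, 0.15, 9, 19, 8),
    understory_mean = c(36.5, 1.32, 0.72, 1.02, 4.40, 0.23, 0.16, 0.30, 44, 128, 35),
    understory_sd = c(16, 0.49, 0.35, 0.40, 0.80, 0.10, 0.08, 0.12, 10, 26, 8))
}

#' Hierarchical cohort design
#'
#' Describes the multi-level Gaussian model from which a synthetic cohort of
#' per-wingbeat records is drawn: per-microhabitat means and SDs for each
#' metric, counts at each hierarchy level (species within microhabitat,
#' individuals within species, flights within individual, wingbeats within
#' flight), the partition of the total variance across levels, a species
#' phylogeny on which species-level deviations evolve under Brownian motion,
#' and per-individual morphology. Defaults reproduce the published group
#' means/SDs (climb angle 46.7 +/- 17 vs 36.5 +/- 16 deg, flight speed
#' 1.56 +/- 0.56 vs 1.32 +/- 0.49 m/s, body pitch 67 +/- 9 vs 44 +/- 10 deg,
#' wing area 100.42 +/- 19.27 vs 79.28 +/- 21.15 cm^2, ...) and approximate
#' the study's sampling depth (2 canopy and 5 understory species, 26
#' individuals, 106 + 77 wingbeats).
#'
#' @param metric_table data.frame with columns metric, canopy_mean, canopy_sd,
#'   understory_mean, understory_sd
#' @param species named character vector mapping species name to microhabitat
#'   ("canopy"/"understory"); must match the tree tips
#' @param individuals_per_species,flights_per_individual,wingbeats_per_flight
#'   named numeric vectors c(canopy = , understory = )
#' @param variance_fractions named numeric vector partitioning each metric's
#'   variance over c(species, individual, flight, wingbeat); must sum to 1
#' @param tree \code{phylo} species tree (tips = species names)
#' @param morphology list with mass_mean_g, mass_sd_g, area_mean_cm2 and
#'   area_sd_cm2, each a named c(canopy, understory) vector
#' @param seed integer seed
#' @return object of class \code{cohort_design}
#' @export
cohort_design <- function(metric_table = .default_metric_table(),
                          species = c(cisseis = "canopy", theseus = "canopy",
                                      achilles = "understory",
                                      helenor = "understory",
                                      menelaus = "understory",
                                      deidamia = "understory",
                                      sulkowskyi = "understory"),
                          individuals_per_species = c(canopy = 5, understory = 3),
                          flights_per_individual = c(canopy = 4, understory = 2),
                          wingbeats_per_flight = c(canopy = 3, understory = 3),
                          variance_fractions = c(species = 0.15,
                                                 individual = 0.25,
                                                 flight = 0.20,
                                                 wingbeat = 0.40),
                          tree = default_tree(),
                          morphology = list(
                            mass_mean_g = c(canopy = 0.457, understory = 0.465),
                            mass_sd_g = c(canopy = 0.08, understory = 0.12),
                            area_mean_cm2 = c(canopy = 100.42, understory = 79.28),
                            area_sd_cm2 = c(canopy = 19.27, understory = 21.15)),
                          seed = 1L) {
  stopifnot(all(c("metric", "canopy_mean", "canopy_sd", "understory_mean",
                  "understory_sd") %in% names(metric_table)),
            all(metric_table$canopy_sd >= 0),
            all(metric_table$understory_sd >= 0),
            all(individuals_per_species >= 1),
            all(flights_per_individual >= 1),
            all(wingbeats_per_flight >= 1),
            all(variance_fractions >= 0))
  if (abs(sum(variance_fractions) - 1) > 1e-9)
    stop("variance fractions must sum to 1")
  if (!setequal(names(species), tree$tip.label))
    stop("tree tips do not match the design's species names: ",
         paste(setdiff(tree$tip.label, names(species)), collapse = ", "))
  structure(list(metric_table = metric_table, species = species,
                 individuals_per_species = individuals_per_species,
                 flights_per_individual = flights_per_individual,
                 wingbeats_per_flight = wingbeats_per_flight,
                 variance_fractions = variance_fractions, tree = tree,
                 morphology = morphology, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generate a hierarchical synthetic cohort
#'
#' Draws a cohort of per-wingbeat records under the design's multi-level
#' Gaussian model. For each metric, species-level deviations evolve under
#' Brownian motion on the tree (rate scaled so the expected species-level
#' variance equals its configured fraction of the group variance) around the
#' microhabitat group mean; individual, flight and wingbeat deviations are
#' independent Gaussians carrying the remaining variance fractions.
#' Morphology (mass, wing area) is drawn per individual and the
#' weight-normalized wing area is computed from them exactly.
#'
#' @param design a \code{cohort_design}
#' @return object of class \code{cohort_dataset}: list with \code{wingbeats}
#'   (tidy data.frame: microhabitat, species, individual, flight,
#'   wingbeat_index, then one column per metric), \code{morphology}
#'   (per-individual data.frame) and \code{tree}
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  tab <- design$metric_table
  vf <- design$variance_fractions
  tree <- design$tree
  sp_names <- tree$tip.label
  habitat <- design$species[sp_names]
  C <- ape::vcv(tree)[sp_names, sp_names]
  Lc <- t(chol(C))
  mean_diag <- mean(diag(C))

  # species-level BM deviations, one column per metric
  sp_dev <- sapply(seq_len(nrow(tab)), function(i) {
    sds <- ifelse(habitat == "canopy", tab$canopy_sd[i], tab$understory_sd[i])
    z <- as.numeric(Lc %*% stats::rnorm(length(sp_names)))
    z / sqrt(mean_diag) * sqrt(vf[["species"]]) * sds
  })
  colnames(sp_dev) <- tab$metric

  m <- nrow(tab)
  rows <- list(); morph <- list()
  for (s in seq_along(sp_names)) {
    sp <- sp_names[s]; hb <- habitat[[sp]]
    mu_g <- if (hb == "canopy") tab$canopy_mean else tab$understory_mean
    sd_g <- if (hb == "canopy") tab$canopy_sd else tab$understory_sd
    n_ind <- design$individuals_per_species[[hb]]
    n_fl <- design$flights_per_individual[[hb]]
    n_wb <- design$wingbeats_per_flight[[hb]]
    n_row <- n_ind * n_fl * n_wb
    ind_of <- rep(seq_len(n_ind), each = n_fl * n_wb)
    fl_of <- rep(seq_len(n_ind * n_fl), each = n_wb)
    wb_of <- rep(seq_len(n_wb), times = n_ind * n_fl)
    dev_mat <- function(k, frac) {
      matrix(stats::rnorm(k * m), k, m) %*% diag(sqrt(frac) * sd_g, m)
    }
    ind_dev <- dev_mat(n_ind, vf[["individual"]])
    fl_dev <- dev_mat(n_ind * n_fl, vf[["flight"]])
    wb_dev <- dev_mat(n_row, vf[["wingbeat"]])
    vals <- matrix(mu_g + sp_dev[s, ], n_row, m, byrow = TRUE) +
      ind_dev[ind_of, , drop = FALSE] + fl_dev[fl_of, , drop = FALSE] + wb_dev
    colnames(vals) <- tab$metric
    ind_ids <- sprintf("%s_i%02d", sp, seq_len(n_ind))
    fl_ids <- sprintf("%s_i%02d_f%02d", sp, rep(seq_len(n_ind), each = n_fl),
                      rep(seq_len(n_fl), times = n_ind))
    rows[[s]] <- cbind(
      data.frame(microhabitat = hb, species = sp,
                 individual = ind_ids[ind_of], flight = fl_ids[fl_of],
                 wingbeat_index = wb_of),
      as.data.frame(vals))
    mo <- design$morphology
    mass <- pmax(0.05, stats::rnorm(n_ind, mo$mass_mean_g[[hb]],
                                    mo$mass_sd_g[[hb]]))
    area <- pmax(5, stats::rnorm(n_ind, mo$area_mean_cm2[[hb]],
                                 mo$area_sd_cm2[[hb]]))
    wn <- weight_normalized_wing_area(area, mass)
    morph[[s]] <- data.frame(
      individual = ind_ids, species = sp, microhabitat = hb,
      mass_g = mass, wing_area_cm2 = area,
      S_over_mg = wn$S_over_mg, wing_loading = wn$wing_loading)
  }
  wingbeats <- do.call(rbind, rows)
  rownames(wingbeats) <- NULL
  morphology <- do.call(rbind, morph)
  rownames(morphology) <- NULL
  structure(list(wingbeats = wingbeats, morphology = morphology, tree = tree,
                 design = design),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  wb <- x$wingbeats
  cat("Synthetic cohort:", nrow(wb), "wingbeats,",
      length(unique(wb$individual)), "individuals,",
      length(unique(wb$species)), "species\n")
  cat("  wingbeats per microhabitat:",
      paste(names(table(wb$microhabitat)), table(wb$microhabitat),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
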