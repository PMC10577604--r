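# Synthetic cohorts: per-patient scenes whose spatial structure is driven
# by latent patient effects, with time-to-progression sampled from an
# exponential proportional-hazards model on the TRUE latent features.

#' Configuration of a synthetic cohort
#'
#' Each patient carries standard-normal latent effects `z_coupling` and
#' `z_density`. `z_coupling` sets the parent/offspring coupling strength
#' `kappa = pnorm(z_coupling)`; `z_density` scales the parent phenotype's
#' densities by `exp(density_sd * z_density)`. `hazard_spec` gives
#' log-hazard coefficients on the latent (standardized) features, so a
#' coefficient of -1.5 means a hazard ratio of exp(-1.5) per latent SD.
#' Time to progression is exponential with rate
#' `baseline_hazard * exp(lp)`, administratively censored at
#' `censor_horizon` years.
#'
#' @param n_patients Number of patients (>= 2).
#' @param tiles_per_patient Tiles generated per patient.
#' @param scene SceneConfig template (a [scene_config()]); per-patient
#'   effects modify its coupling/densities.
#' @param parent,offspring Phenotype labels of the coupled pair.
#' @param hazard_spec Named numeric: log-hazard per latent SD, names in
#'   `c("coupling", "density")`.
#' @param density_sd Log-scale SD of the density random effect.
#' @param coupling_sigma_um Offspring displacement scale.
#' @param baseline_hazard Events per year at latent zero.
#' @param censor_horizon Administrative censoring time (years, > 0).
#' @param flipi_probs Probabilities for low/intermediate/high FLIPI.
#' @param treatment_probs Probabilities for R-CHOP / R-CVP.
#' @param seed Integer seed.
#' @return Object of class `fl_cohort_config`.
#' @export
cohort_config <- function(n_patients = 32L, tiles_per_patient = 4L,
                          scene = NULL,
                          parent = "CD8+FOXP3+", offspring = "CD4+CD8+",
                          hazard_spec = c(coupling = -1.5),
                          density_sd = 0.35, coupling_sigma_um = 25,
                          baseline_hazard = 0.15, censor_horizon = 12,
                          flipi_probs = c(low = 3, intermediate = 16,
                                          high = 13) / 32,
                          treatment_probs = c("R-CHOP" = 26, "R-CVP" = 6) / 32,
                          seed = 1L) {
  stopifnot(n_patients >= 2L, tiles_per_patient >= 1L, censor_horizon > 0,
            baseline_hazard > 0)
  if (abs(sum(flipi_probs) - 1) > 1e-8) stop("flipi_probs must sum to 1")
  if (!all(names(hazard_spec) %in% c("coupling", "density")))
    stop("hazard_spec names must be in c('coupling', 'density')")
  if (is.null(scene))
    scene <- scene_config(
      width_um = 1000, height_um = 1000, n_follicles = 3L,
      follicle_radius_range = c(80, 150),
      phenotypes = list(
        "CD8+FOXP3+"      = c(intra = 0.08, inter = 0.25),
        "CD4+CD8+"        = c(intra = 0.08, inter = 0.25),
        "CD4+FOXP3+"      = c(intra = 0.08, inter = 0.25),
        "CD4-CD8+FOXP3-"  = c(intra = 0.3,  inter = 1.0),
        "CD4+CD8-FOXP3-"  = c(intra = 0.4,  inter = 1.2)),
      seed = seed)
  stopifnot(inherits(scene, "fl_scene_config"),
            parent %in% names(scene$phenotypes),
            offspring %in% names(scene$phenotypes))
  structure(list(n_patients = as.integer(n_patients),
                 tiles_per_patient = as.integer(tiles_per_patient),
                 scene = scene, parent = parent, offspring = offspring,
                 hazard_spec = hazard_spec, density_sd = density_sd,
                 coupling_sigma_um = coupling_sigma_um,
                 baseline_hazard = baseline_hazard,
                 censor_horizon = censor_horizon,
                 flipi_probs = flipi_probs,
                 treatment_probs = treatment_probs,
                 seed = as.integer(seed)),
            class = "fl_cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws per-patient latent effects, realizes the per-patient scenes (one
#' [generate_cell_map()] per tile, with the patient's coupling strength and
#' density multiplier) and samples time to progression from the exponential
#' proportional-hazards model on the true latent features. A cohort in
#' which every patient is censored raises a warning, not an error.
#'
#' @param config An [cohort_config()].
#' @param make_scenes Generate the tile scenes (set FALSE when only the
#'   clinical table and true features are needed, e.g. for calibration
#'   studies).
#' @return Object of class `fl_cohort`: `clinical` (patient_id, ttp_years,
#'   event, flipi, treatment), `true_features` (latent effects, kappa,
#'   density multiplier), `scenes` (list patient -> list of `fl_scene`).
#' @export
generate_cohort <- function(config, make_scenes = TRUE) {
  stopifnot(inherits(config, "fl_cohort_config"))
  n <- config$n_patients
  withr::with_seed(config$seed, {
    z_coupling <- stats::rnorm(n)
    z_density <- stats::rnorm(n)
    kappa <- stats::pnorm(z_coupling)
    dens_mult <- exp(config$density_sd * z_density)
    lp <- numeric(n)
    if ("coupling" %in% names(config$hazard_spec))
      lp <- lp + config$hazard_spec[["coupling"]] * z_coupling
    if ("density" %in% names(config$hazard_spec))
      lp <- lp + config$hazard_spec[["density"]] * z_density
    t_event <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
    event <- as.integer(t_event <= config$censor_horizon)
    ttp <- pmin(t_event, config$censor_horizon)
    if (!any(event == 1L)) warning("all patients censored under this spec")
    flipi <- sample(names(config$flipi_probs), n, replace = TRUE,
                    prob = config$flipi_probs)
    treatment <- sample(names(config$treatment_probs), n, replace = TRUE,
                        prob = config$treatment_probs)
    tile_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                    n * config$tiles_per_patient),
                         nrow = n)
    pid <- sprintf("P%03d", seq_len(n))
    clinical <- data.frame(patient_id = pid, ttp_years = ttp, event = event,
                           flipi = flipi, treatment = treatment)
    true_features <- data.frame(patient_id = pid, z_coupling = z_coupling,
                                z_density = z_density, kappa = kappa,
                                density_multiplier = dens_mult)
    scenes <- NULL
    if (make_scenes) {
      scenes <- lapply(seq_len(n), function(i) {
        lapply(seq_len(config$tiles_per_patient), function(t) {
          sc <- config$scene
          ph <- sc$phenotypes
          ph[[config$parent]] <- ph[[config$parent]] * dens_mult[i]
          cfg <- scene_config(
            width_um = sc$width_um, height_um = sc$height_um,
            um_per_px = sc$um_per_px, markers = sc$markers,
            phenotypes = ph, n_follicles = sc$n_follicles,
            follicle_radius_range = sc$follicle_radius_range,
            coupling = list(list(parent = config$parent,
                                 offspring = config$offspring,
                                 kappa = kappa[i],
                                 sigma_um = config$coupling_sigma_um)),
            background = sc$background, blob_radius_um = sc$blob_radius_um,
            noise_sd = sc$noise_sd, intensity_jitter = sc$intensity_jitter,
            seed = tile_seeds[i, t])
          generate_cell_map(cfg)
        })
      })
      names(scenes) <- pid
    }
    structure(list(clinical = clinical, true_features = true_features,
                   scenes = scenes, config = config),
              class = "fl_cohort")
  })
}

#' @export
print.fl_cohort <- function(x, ...) {
  cl <- x$clinical
  cat(sprintf("Synthetic cohort: %d patients, %d events (%.0f%%)\n",
              nrow(cl), sum(cl$event), 100 * mean(cl$event)))
  cat(sprintf("  median follow-up %.2f years; FLIPI low/int/high = %d/%d/%d\n",
              stats::median(cl$ttp_years),
              sum(cl$flipi == "low"), sum(cl$flipi == "intermediate"),
              sum(cl$flipi == "high")))
  if (!is.null(x$scenes))
    cat(sprintf("  %d tiles per patient (%g x %g um)\n",
                x$config$tiles_per_patient, x$config$scene$width_um,
                x$config$scene$height_um))
  invisible(x)
}

#' Write a cohort's clinical table to CSV
#'
#' @param cohort An `fl_cohort`. @param path Output file.
#' @export
write_clinical_csv <- function(cohort, path) {
  utils::write.csv(cohort$clinical, path, row.names = FALSE)
  invisible(path)
}
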