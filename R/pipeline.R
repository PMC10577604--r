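# End-to-end orchestration: per-patient spatial feature extraction from
# cell maps, cell-map schema validation, pipeline runs with a manifest.

#' Extract per-patient spatial features from a cohort's cell maps
#'
#' Runs the geometry -> compartment -> density / co-localization stages on
#' each patient's tiles (the detection/classification stages are bypassed:
#' ground-truth cell maps serve as the per-marker centroid input). Returns
#' one row per patient joined to the clinical table, with feature columns
#' named `<feature>_<compartment>` ready for [run_association_suite()].
#'
#' @param cohort An `fl_cohort` with scenes.
#' @param density_phenotypes Named character: feature base name ->
#'   phenotype label for density features.
#' @param mh_pairs Named list: feature base name -> c(phenotype A,
#'   phenotype B) for Morisita-Horn features.
#' @param compartments Compartments to featurize.
#' @param seed_spacing Quadrat lattice pitch (micrometres).
#' @param raster_um Raster pitch for compartment masks.
#' @return Data frame: clinical columns plus feature columns.
#' @export
cohort_features <- function(cohort,
                            density_phenotypes = c(
                              density_cd8foxp3 = "CD8+FOXP3+",
                              density_cd4foxp3 = "CD4+FOXP3+"),
                            mh_pairs = list(
                              mh_cd8foxp3_cd4cd8 = c("CD8+FOXP3+", "CD4+CD8+"),
                              mh_cd8foxp3_cd4foxp3 = c("CD8+FOXP3+", "CD4+FOXP3+")),
                            compartments = "inter",
                            seed_spacing = 50, raster_um = 8) {
  stopifnot(inherits(cohort, "fl_cohort"), !is.null(cohort$scenes))
  markers <- cohort$config$scene$markers
  rows <- lapply(names(cohort$scenes), function(pid) {
    scenes <- cohort$scenes[[pid]]
    geoms <- lapply(scenes, function(sc)
      compartment_geometry(follicles = lapply(sc$follicles, `[[`, "poly"),
                           width_um = sc$config$width_um,
                           height_um = sc$config$height_um,
                           um_per_px = raster_um))
    names(geoms) <- paste0("tile", seq_along(scenes))
    cells <- do.call(rbind, lapply(seq_along(scenes), function(t) {
      cm <- scenes[[t]]$cells
      cm$compartment <- NULL  # recomputed from geometry
      cm <- assign_compartments(cm, geoms[[t]])
      cbind(tile_id = paste0("tile", t), cm)
    }))
    out <- data.frame(patient_id = pid)
    for (comp in compartments) {
      for (f in names(density_phenotypes))
        out[[paste0(f, "_", comp)]] <-
          cell_density(cells, geoms, density_phenotypes[[f]], comp, markers)
      tess <- lapply(geoms, tessellate_compartment, compartment = comp,
                     seed_spacing = seed_spacing)
      for (f in names(mh_pairs)) {
        mh <- colocalization(cells, mh_pairs[[f]][1L], mh_pairs[[f]][2L],
                             tess, markers)
        out[[paste0(f, "_", comp)]] <- as.numeric(mh$mh)
      }
    }
    out
  })
  merge(cohort$clinical, do.call(rbind, rows), by = "patient_id")
}

#' Validate a cell-map table
#'
#' Checks the column schema (identifier columns, finite coordinates,
#' logical marker columns, unique cell ids within a tile) and reports every
#' violation with its row number; nothing is silently dropped.
#'
#' @param x Data frame or path to a cell-map CSV.
#' @param markers Panel marker vector.
#' @return List of class `fl_validation`: `ok` flag, `issues` data frame
#'   (row, column, problem), `n_rows`.
#' @export
validate_cellmap <- function(x, markers = panel_markers()) {
  if (is.character(x)) x <- utils::read.csv(x)
  issues <- list()
  note <- function(row, column, problem)
    issues[[length(issues) + 1L]] <<- data.frame(row = row, column = column,
                                                 problem = problem)
  need <- c("cell_id", "x_um", "y_um", paste0(markers, "_pos"))
  for (col in need)
    if (!col %in% names(x)) note(NA_integer_, col, "missing column")
  if (!length(issues)) {
    bad <- which(!is.finite(x$x_um) | x$x_um < 0)
    for (r in bad) note(r, "x_um", "non-finite or negative coordinate")
    bad <- which(!is.finite(x$y_um) | x$y_um < 0)
    for (r in bad) note(r, "y_um", "non-finite or negative coordinate")
    for (mk in paste0(markers, "_pos")) {
      v <- x[[mk]]
      ok <- is.logical(v) | v %in% c(0, 1, "TRUE", "FALSE", "true", "false")
      for (r in which(!ok)) note(r, mk, "non-boolean marker entry")
    }
    tid <- if ("tile_id" %in% names(x)) x$tile_id else "tile"
    dup <- which(duplicated(paste(tid, x$cell_id)))
    for (r in dup) note(r, "cell_id", "duplicate cell id within tile")
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(0), column = character(0),
               problem = character(0))
  structure(list(ok = nrow(issues) == 0L, issues = issues, n_rows = nrow(x)),
            class = "fl_validation")
}

#' @export
print.fl_validation <- function(x, ...) {
  if (x$ok) cat(sprintf("Cell map OK: %d rows, 0 issues\n", x$n_rows))
  else {
    cat(sprintf("Cell map has %d issue(s) in %d rows:\n", nrow(x$issues),
                x$n_rows))
    print(utils::head(x$issues, 20L), row.names = FALSE)
  }
  invisible(x)
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a cohort, extracts spatial features, runs the association
#' suite, writes the artifacts (clinical CSV, feature CSV, association
#' results CSV) and a JSON run manifest with config snapshot, package
#' version, per-file checksums and warnings. Stages whose inputs are
#' supplied externally are skipped: passing `features` jumps straight to
#' the association stage.
#'
#' @param out_dir Output directory.
#' @param cohort_cfg An [cohort_config()] (ignored when `features` given).
#' @param features Optional pre-computed feature table (as from
#'   [cohort_features()]).
#' @param feature_names Feature base names for the association suite.
#' @param compartments Compartments to analyze.
#' @param seed Global seed; overrides the cohort config seed.
#' @return Object of class `fl_manifest` (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(out_dir, cohort_cfg = cohort_config(),
                         features = NULL,
                         feature_names = c("density_cd8foxp3",
                                           "density_cd4foxp3",
                                           "mh_cd8foxp3_cd4cd8",
                                           "mh_cd8foxp3_cd4foxp3"),
                         compartments = "inter", seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  wh <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stages <- character(0)
  paths <- list()
  withCallingHandlers({
    if (is.null(features)) {
      if (!is.null(seed)) {
        cohort_cfg$seed <- as.integer(seed)
        cohort_cfg$scene$seed <- as.integer(seed)
      }
      cohort <- generate_cohort(cohort_cfg)
      stages <- c(stages, "synth")
      paths$clinical <- file.path(out_dir, "clinical.csv")
      write_clinical_csv(cohort, paths$clinical)
      features <- cohort_features(cohort, compartments = compartments)
      stages <- c(stages, "compartments", "spatial")
      paths$features <- file.path(out_dir, "features.csv")
      utils::write.csv(features, paths$features, row.names = FALSE)
    } else {
      features <- as.data.frame(features)
    }
    assoc <- run_association_suite(features, feature_names,
                                   compartments = compartments)
    stages <- c(stages, "prognosis")
    paths$associations <- file.path(out_dir, "associations.csv")
    utils::write.csv(as.data.frame(assoc), paths$associations,
                     row.names = FALSE)
  }, warning = wh)
  checksums <- vapply(paths, function(p) unname(tools::md5sum(p)), "")
  manifest <- structure(
    list(package_version =
           as.character(utils::packageVersion("folliscape")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = if (is.null(seed)) cohort_cfg$seed else as.integer(seed),
         stages = stages,
         config = list(n_patients = cohort_cfg$n_patients,
                       tiles_per_patient = cohort_cfg$tiles_per_patient,
                       hazard_spec = as.list(cohort_cfg$hazard_spec),
                       compartments = compartments,
                       feature_names = feature_names),
         outputs = as.list(checksums),
         warnings = warnings_log),
    class = "fl_manifest")
  mj <- manifest
  attr(mj, "class") <- NULL
  jsonlite::write_json(mj, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.fl_manifest <- function(x, ...) {
  cat("Pipeline run manifest (folliscape", x$package_version, ")\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("  outputs:\n")
  for (nm in names(x$outputs))
    cat(sprintf("    %s  %s\n", x$outputs[[nm]], nm))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Thin front end used by the command-line script: maps a YAML mapping onto
#' [cohort_config()] arguments, validating unknown keys.
#'
#' @param path YAML file.
#' @return An `fl_cohort_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(cohort_config))
  bad <- setdiff(names(y), allowed)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$hazard_spec)) y$hazard_spec <- unlist(y$hazard_spec)
  if (!is.null(y$flipi_probs)) y$flipi_probs <- unlist(y$flipi_probs)
  do.call(cohort_config, y)
}
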